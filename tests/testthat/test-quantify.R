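test_that("excretion scaling is exact arithmetic and linear", {
  expect_equal(total_excretion(0, 400), 0)
  expect_equal(total_excretion(0.02, 300, 29), 174)
  expect_equal(total_excretion(0.025, 350, 29), 253.75)
  # linear in each argument
  expect_equal(total_excretion(0.04, 300, 29), 2 * total_excretion(0.02, 300, 29))
  expect_equal(total_excretion(0.02, 600, 29), 2 * total_excretion(0.02, 300, 29))
  expect_equal(total_excretion(0.02, 300, 58), 2 * total_excretion(0.02, 300, 29))
  expect_error(total_excretion(-1, 300), class = "cobaltperm_domain_error")
})

test_that("dose fraction reproduces the published recovery figure", {
  expect_equal(round(dose_fraction(250, 6900), 1), 3.6)
  expect_equal(dose_fraction(0, 6900), 0)
  expect_equal(dose_fraction(6900, 6900), 100)
  expect_error(dose_fraction(10, 0), class = "cobaltperm_domain_error")
})

test_that("cohort excretion from true parameters matches the closed form", {
  sim <- simulate_cohort(seed = 71)
  exc <- cohort_excretion(sim$truth$animals)
  # trapezoid AUC x scaling vs the truth record's closed-form values
  expect_true(all(abs(exc$total_co_mg - sim$truth$animals$total_co_mg) /
                    sim$truth$animals$total_co_mg < 1e-3))
  expect_true(all(exc$dose_fraction_pct > 0))
  # doubling body weight doubles total excretion, dose fixed
  doubled <- sim$truth$animals
  doubled$bw_kg <- 2 * doubled$bw_kg
  exc2 <- cohort_excretion(doubled)
  expect_equal(exc2$total_co_mg, 2 * exc$total_co_mg)
  expect_equal(exc2$auc, exc$auc)
})

test_that("missing body weight names the animal", {
  sim <- simulate_cohort(seed = 72)
  a <- sim$truth$animals
  a$bw_kg[2] <- NA
  expect_error(cohort_excretion(a), a$animal_id[2],
               class = "cobaltperm_domain_error")
})

test_that("hour and day time inputs give the same excretion", {
  sim <- simulate_cohort(seed = 73)
  u_days <- sim$urine
  u_hours <- dplyr::select(sim$urine, -"time_d")  # forces hour conversion
  f1 <- fit_population(u_days, quick_control(), seed = 5)
  f2 <- fit_population(u_hours, quick_control(), seed = 5)
  e1 <- cohort_excretion(f1)
  e2 <- cohort_excretion(f2)
  expect_equal(e1$total_co_mg, e2$total_co_mg)
})

test_that("homogeneous cohorts excrete equally; dose fraction is plausible", {
  des <- cohort_design(breeds = list(Holstein = c(mean = 320, sd = 0),
                                     Jersey = c(mean = 320, sd = 0)))
  tr <- generator_truth(omega = c(A = 0, B = 0, k1 = 0, k2 = 0),
                        sigma = 1e-6)
  sim <- simulate_cohort(des, tr, seed = 74)
  fit <- fit_population(sim$urine, seed = 74)
  exc <- cohort_excretion(fit)
  expect_lt(diff(range(exc$total_co_mg)) / mean(exc$total_co_mg), 0.01)
  # cohorts at the study's scale recover a low-percent fraction of the dose
  expect_true(all(exc$dose_fraction_pct > 1 & exc$dose_fraction_pct < 10))
})
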