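test_that("noiseless homogeneous cohort is recovered within 1%", {
  tr <- generator_truth(omega = c(A = 0, B = 0, k1 = 0, k2 = 0),
                        sigma = 1e-6)
  sim <- simulate_cohort(truth = tr, seed = 2)
  fit <- fit_population(sim$urine, seed = 2)
  est <- exp(fit$model$mu)
  truth <- exp(tr$mu)
  expect_true(all(abs(est - truth) / truth < 0.01))
  # with no heterogeneity every empirical-Bayes curve equals the population
  for (j in c("A", "B", "k1", "k2")) {
    expect_true(all(abs(fit$individual[[j]] - truth[[j]]) / truth[[j]] < 0.01))
  }
})

test_that("SAEM agrees with a direct least-squares fit on replicated data", {
  # two animals with identical, lightly noisy data and additive error: the
  # population mode must match an independent pooled least-squares fit
  tr <- generator_truth(omega = c(A = 0, B = 0, k1 = 0, k2 = 0),
                        sigma = 5e-4, error_model = "additive",
                        noise_floor = 0)
  des <- cohort_design(n_per_cell = 1L,
                       breeds = list(Holstein = c(mean = 315, sd = 0),
                                     Jersey = c(mean = 315, sd = 0)))
  sim <- simulate_cohort(des, tr, seed = 14)
  fit <- fit_population(sim$urine, saem_control(error_model = "additive"),
                        seed = 14)
  dat <- dplyr::filter(sim$urine, time_d > 0)
  ls_fit <- optim(fit$model$mu, function(p) {
    f <- exp(p[1]) * exp(-exp(p[3]) * dat$time_d -
               exp(p[2]) * exp(-exp(p[4]) * dat$time_d))
    sum((dat$ratio - f)^2)
  }, method = "Nelder-Mead", control = list(maxit = 2000, reltol = 1e-12))
  expect_true(all(abs(exp(fit$model$mu) - exp(ls_fit$par)) /
                    exp(ls_fit$par) < 0.02))
  # residual variance matches RSS/N of the least-squares solution
  expect_equal(fit$model$sigma^2, ls_fit$value / nrow(dat),
               tolerance = 0.2)
})

test_that("fits are deterministic and invariant to animal order", {
  sim <- simulate_cohort(seed = 17)
  f1 <- fit_population(sim$urine, quick_control(), seed = 17)
  f2 <- fit_population(sim$urine, quick_control(), seed = 17)
  expect_identical(f1$model, f2$model)
  expect_identical(f1$individual, f2$individual)
  shuffled <- sim$urine[sample(nrow(sim$urine)), ]
  f3 <- fit_population(shuffled, quick_control(), seed = 17)
  expect_identical(f1$model, f3$model)
  expect_identical(f1$individual, f3$individual)
})

test_that("parameter recovery on default cohorts is accurate", {
  errs <- c()
  for (s in c(101, 202)) {
    sim <- simulate_cohort(seed = s)
    fit <- fit_population(sim$urine, seed = s)
    expect_true(fit$converged)
    rep <- truth_report(sim, fit = fit)
    errs <- c(errs, rep$rel_error)
    # random-effect SDs within a factor of ~2 where the truth is non-zero
    om <- sqrt(fit$model$omega2)
    truth_om <- sim$truth$generator$omega
    expect_true(all(om < 2.5 * truth_om + 0.05))
  }
  expect_lt(median(errs), 0.15)
})

test_that("empirical-Bayes estimates shrink an outlying animal", {
  sim <- simulate_cohort(seed = 23)
  g <- sim$truth$generator
  # regenerate one animal from parameters 3 population SDs high in A
  target <- sim$urine$animal_id == sim$urine$animal_id[1]
  p_out <- exp(g$mu + c(3 * g$omega[["A"]], 0, 0, 0))
  t_d <- sim$urine$time_d[target]
  set.seed(77)
  f <- curve_value(excretion_curve(p_out[1], p_out[2], p_out[3], p_out[4]),
                   t_d)
  sim$urine$ratio[target] <- pmax(f * (1 + 0.12 * rnorm(length(f))), 0)
  fit <- fit_population(sim$urine, seed = 23)
  id <- sim$urine$animal_id[1]
  dat <- dplyr::filter(sim$urine, .data$animal_id == id, .data$time_d > 0)
  ls <- optim(log(p_out), function(p) {
    fi <- exp(p[1]) * exp(-exp(p[3]) * dat$time_d -
                exp(p[2]) * exp(-exp(p[4]) * dat$time_d))
    sum((dat$ratio - fi)^2 / pmax(fi, 1e-10)^2)
  }, method = "Nelder-Mead", control = list(maxit = 2000))
  eb_logA <- log(individual_curve(fit, id)$A)
  lo <- min(fit$model$mu[["A"]], ls$par[1]) - 0.02
  hi <- max(fit$model$mu[["A"]], ls$par[1]) + 0.02
  expect_gt(eb_logA, lo)
  expect_lt(eb_logA, hi)
})

test_that("degenerate inputs are flagged or rejected", {
  sim <- simulate_cohort(seed = 31)
  # all-zero animal is excluded with a warning
  z <- sim$urine
  z$ratio[z$animal_id == z$animal_id[1]] <- 0
  expect_warning(fit <- fit_population(z, quick_control(), seed = 1),
                 class = "cobaltperm_excluded_animals")
  expect_false(z$animal_id[1] %in% fit$individual$animal_id)
  # fewer than two usable animals
  one <- dplyr::filter(sim$urine, animal_id == animal_id[1])
  expect_error(fit_population(one, quick_control(), seed = 1),
               class = "cobaltperm_domain_error")
  # unknown animal lookup
  fit2 <- fit_population(sim$urine, quick_control(), seed = 3)
  expect_error(individual_curve(fit2, "nope"),
               class = "cobaltperm_lookup_error")
  c1 <- individual_curve(fit2, fit2$individual$animal_id[2])
  expect_s3_class(c1, "excretion_curve")
})

test_that("combined error model runs and returns two sigma components", {
  tr <- generator_truth(error_model = "combined", sigma = c(0.002, 0.08))
  sim <- suppressWarnings(simulate_cohort(truth = tr, seed = 19))
  fit <- fit_population(sim$urine, quick_control(error_model = "combined"),
                        seed = 19)
  expect_length(fit$model$sigma, 2L)
  expect_true(all(fit$model$sigma > 0))
})

test_that("tidiers expose the fit in standard layouts", {
  sim <- simulate_cohort(seed = 37)
  fit <- fit_population(sim$urine, quick_control(), seed = 37)
  td <- tidy(fit)
  expect_identical(td$parameter, c("A", "B", "k1", "k2"))
  expect_true(all(td$estimate > 0))
  gl <- glance(fit)
  expect_identical(gl$n_animals, 12L)
  aug <- augment(fit)
  expect_true(all(c(".fitted", ".resid", ".fitted_pop") %in% names(aug)))
  expect_equal(aug$.resid, aug$ratio - aug$.fitted)
})
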