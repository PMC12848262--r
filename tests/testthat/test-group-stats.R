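test_that("constant responses give zero F and p = 1", {
  dat <- balanced_2x2(c(5, 5, 5, 5), mse = 0)
  a <- factorial_anova(dat, "y")
  expect_equal(a$terms$statistic, rep(0, 3))
  expect_equal(a$terms$p.value, rep(1, 3))
})

test_that("hand-computed sums of squares are reproduced exactly", {
  # cell means (10, 10, 20, 20), MSE = 3: breed SS = 3*20^2/4 = 300,
  # so F(breed) = 300/3 = 100 on (1, 8) df
  dat <- balanced_2x2(c(10, 10, 20, 20), mse = 3)
  a <- factorial_anova(dat, "y")
  expect_equal(a$mse, 3)
  breed_row <- a$terms[a$terms$term == "breed", ]
  expect_equal(breed_row$statistic, 100)
  expect_equal(breed_row$p.value, pf(100, 1, 8, lower.tail = FALSE))
  expect_equal(a$terms$statistic[a$terms$term == "treatment"], 0)
  expect_equal(a$sem, 1)
  # orthogonality: swapping factor roles permutes but preserves the SS
  b <- factorial_anova(dat, "y", factor_a = "breed", factor_b = "treatment")
  expect_equal(sort(b$terms$sumsq), sort(a$terms$sumsq))
})

test_that("design problems are reported by cell", {
  dat <- balanced_2x2(c(1, 2, 3, 4), mse = 1)
  expect_error(factorial_anova(dat[dat$treatment == 0 |
                                     dat$breed == "Holstein", ], "y"),
               "empty", class = "cobaltperm_domain_error")
  one_per_cell <- dat[c(1, 4, 7, 10), ]
  expect_error(factorial_anova(one_per_cell, "y"),
               class = "cobaltperm_domain_error")
})

test_that("summary-statistic ANOVA equals the raw-data ANOVA exactly", {
  set.seed(314)
  for (r in 1:5) {
    dat <- balanced_2x2(runif(4, 10, 50), mse = runif(1, 0.5, 9))
    dat$y <- dat$y + 0  # exact cell structure
    a_raw <- factorial_anova(dat, "y")
    a_sum <- anova_from_summary(a_raw$cell_means$mean, a_raw$sem,
                                a_raw$n_per_cell,
                                term_names = c("treatment", "breed"))
    expect_equal(a_sum$terms$statistic, a_raw$terms$statistic,
                 tolerance = 1e-10)
    expect_equal(a_sum$terms$p.value, a_raw$terms$p.value, tolerance = 1e-10)
  }
  # degenerate reconstruction: equal cell means
  a0 <- anova_from_summary(c(7, 7, 7, 7), sem = 2, n_per_cell = 3)
  expect_equal(a0$terms$p.value, rep(1, 3))
})

test_that("published cell means and SEM reconstruct the reported p-values", {
  co <- anova_from_summary(c(210, 239, 292, 274), sem = 16.5, n_per_cell = 3)
  expect_equal(round(co$terms$p.value[co$terms$term == "aspirin"], 2), 0.75)
  expect_equal(co$terms$p.value[co$terms$term == "breed"], 0.007,
               tolerance = 0.15)  # printed to one significant figure
  hp <- anova_from_summary(c(356, 369, 407, 443), sem = 118, n_per_cell = 3)
  expect_equal(round(hp$terms$p.value, 2), c(0.84, 0.61, 0.92))
})

test_that("a two-SD aspirin effect is detected in most repetitions", {
  set.seed(2024)
  hits <- 0L
  for (r in 1:200) {
    dat <- balanced_2x2(c(0, 2, 0, 2), mse = 1)  # effect = 2 pooled SD
    dat$y <- dat$y + rnorm(12)
    a <- factorial_anova(dat, "y")
    if (a$terms$p.value[a$terms$term == "treatment"] < 0.05) hits <- hits + 1L
  }
  expect_gt(hits / 200, 0.5)
})

test_that("the aspirin test holds its nominal size under the null", {
  set.seed(271)
  base <- balanced_2x2(c(0, 0, 0, 0), mse = 1)
  rejections <- 0L
  for (r in 1:1000) {
    base$y <- rnorm(12)
    a <- factorial_anova(base, "y")
    if (a$terms$p.value[a$terms$term == "treatment"] < 0.05)
      rejections <- rejections + 1L
  }
  expect_gt(rejections / 1000, 0.03)
  expect_lt(rejections / 1000, 0.07)
})

test_that("a symmetric response drops the three-way interaction first", {
  set.seed(99)
  dat <- tibble::tibble(
    treatment = rep(c(0, 200), 6),
    breed = rep(c("Holstein", "Jersey"), each = 6),
    total_co_mg = rep(c(200, 250, 300), 4),
    y = rnorm(12, 50, 5))
  # cancel the fitted three-way coefficient: its Type II p becomes ~1
  mm <- model.matrix(~ factor(treatment) * breed * total_co_mg, dat)
  fit0 <- lm(dat$y ~ mm - 1)
  dat$y <- dat$y - coef(fit0)[8] * mm[, 8]
  res <- ancova_stepwise(dat, "y")
  expect_equal(res$elimination_path$term[1], "treatment:breed:total_co_mg")
  expect_gt(res$elimination_path$p_at_drop[1], 0.999)
})

test_that("marginality protects main effects under a strong interaction", {
  set.seed(123)
  dat <- tibble::tibble(
    treatment = rep(c(0, 200), 6),
    breed = rep(c("Holstein", "Jersey"), each = 6),
    total_co_mg = runif(12, 150, 350))
  dat$y <- 10 + 2 * (dat$treatment > 0) * dat$total_co_mg + rnorm(12, 0, 4)
  res <- ancova_stepwise(dat, "y")
  expect_true("treatment:total_co_mg" %in% res$final_terms$term)
  expect_true(all(c("treatment", "total_co_mg") %in% res$final_terms$term))
})

test_that("a pure covariate effect is recovered with a positive slope", {
  set.seed(55)
  hits <- 0L
  for (r in 1:25) {
    dat <- tibble::tibble(
      treatment = rep(c(0, 200), 6),
      breed = rep(c("Holstein", "Jersey"), each = 6),
      total_co_mg = rnorm(12, 250, 55))
    dat$y <- 40 + 0.5 * dat$total_co_mg + rnorm(12, 0, 8)
    res <- ancova_stepwise(dat, "y")
    ok <- "total_co_mg" %in% res$final_terms$term &&
      !any(grepl(":", res$final_terms$term)) &&
      res$slope > 0
    if (ok) hits <- hits + 1L
  }
  expect_gt(hits / 25, 0.7)
})

test_that("collinear covariates are reported as rank deficiency", {
  dat <- tibble::tibble(
    treatment = rep(c(0, 200), 6),
    breed = rep(c("Holstein", "Jersey"), each = 6),
    total_co_mg = rep(c(0, 200), 6),  # identical to the treatment dummy
    y = rnorm(12))
  expect_error(ancova_stepwise(dat, "y"),
               class = "cobaltperm_rank_deficient")
})
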