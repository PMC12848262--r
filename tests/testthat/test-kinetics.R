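test_that("curve evaluation matches the closed form at anchor points", {
  # B = 0 collapses to pure exponential decay
  expect_equal(curve_value(excretion_curve(1, 0, 1, 1), 0), 1.0)
  # t = 0 gives A exp(-B) for any parameters
  p <- excretion_curve(0.7, 2.3, 1.1, 9)
  expect_equal(curve_value(p, 0), 0.7 * exp(-2.3))
  # frozen high-precision reference value (40-digit arithmetic)
  expect_equal(curve_value(excretion_curve(2, 3, 0.5, 4), 1),
               1.148205471349474, tolerance = 1e-14)
  # vectorized over a time grid
  tg <- c(0, 0.1, 0.5, 1.5)
  expect_equal(curve_value(p, tg),
               vapply(tg, function(t) curve_value(p, t), numeric(1)))
})

test_that("invalid parameters and negative times are rejected by name", {
  expect_error(excretion_curve(-1, 0, 1, 1), "`A`",
               class = "cobaltperm_domain_error")
  expect_error(excretion_curve(1, -0.1, 1, 1), "`B`",
               class = "cobaltperm_domain_error")
  expect_error(excretion_curve(1, 0, 0, 1), "`k1`",
               class = "cobaltperm_domain_error")
  expect_error(excretion_curve(1, 0, 1, NA), "`k2`",
               class = "cobaltperm_domain_error")
  expect_error(curve_value(excretion_curve(1, 1, 1, 1), -0.5),
               class = "cobaltperm_domain_error")
})

test_that("curve values are positive and bounded by A", {
  set.seed(41)
  for (p in draw_prior_params(50)) {
    v <- curve_value(p, seq(0, 3, by = 0.05))
    expect_true(all(v > 0))
    expect_true(all(v <= p$A))
  }
})

test_that("peak time matches analytic cases and a dense-grid argmax", {
  expect_true(is.na(curve_peak_time(excretion_curve(1, 0, 1, 1))))
  expect_equal(curve_peak_time(excretion_curve(1, exp(1), 1, 1)), 1.0)
  set.seed(7)
  grid <- seq(0, 2, length.out = 40001)
  n_checked <- 0
  while (n_checked < 25) {
    p <- draw_prior_params(1)[[1]]
    if (p$B * p$k2 <= p$k1) next
    n_checked <- n_checked + 1
    tstar <- curve_peak_time(p)
    t_grid <- grid[which.max(curve_value(p, grid))]
    expect_lt(abs(tstar - t_grid), 2 * (grid[2] - grid[1]))
    # local maximum: values just off the peak are lower
    eps <- 1e-4
    fpk <- curve_value(p, tstar)
    expect_gt(fpk, curve_value(p, tstar - eps))
    expect_gt(fpk, curve_value(p, tstar + eps))
  }
})

test_that("closed-form AUC matches elementary and frozen references", {
  expect_equal(curve_auc(excretion_curve(1, 0, 1, 1), t_end = Inf), 1.0)
  expect_equal(curve_auc(excretion_curve(1, 0, 2, 1), t_end = Inf), 0.5)
  # frozen adaptive-quadrature reference (40-digit arithmetic)
  expect_equal(curve_auc(excretion_curve(2, 3, 0.5, 4), t_end = 1.5),
               1.388997326673344, tolerance = 1e-13)
  # B = 0 path with a finite window
  expect_equal(curve_auc(excretion_curve(3, 0, 1.5, 2), t_end = 2),
               3 * (1 - exp(-3)) / 1.5)
})

test_that("trapezoidal AUC converges to the closed form", {
  p <- excretion_curve(1, 0, 1, 1)
  expect_equal(curve_auc(p, t_end = 10, method = "trapezoid",
                         n_grid = 100001L),
               1 - exp(-10), tolerance = 1e-6)
  # refinement study: error decreases monotonically as the grid doubles
  p <- excretion_curve(2, 3, 0.5, 4)
  exact <- curve_auc(p, t_end = 1.5)
  errs <- vapply(2^(4:10) + 1, function(m) {
    abs(curve_auc(p, t_end = 1.5, method = "trapezoid", n_grid = m) - exact)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("trapezoid and closed form agree across the kinetic prior", {
  set.seed(13)
  for (p in draw_prior_params(100)) {
    cf <- curve_auc(p, t_end = 1.5)
    tr <- curve_auc(p, t_end = 1.5, method = "trapezoid", n_grid = 10001L)
    expect_lt(abs(tr - cf) / cf, 1e-4)
  }
})

test_that("AUC input validation", {
  p <- excretion_curve(1, 1, 1, 1)
  expect_error(curve_auc(p, t_end = 0), class = "cobaltperm_domain_error")
  expect_error(curve_auc(p, t_end = -1), class = "cobaltperm_domain_error")
  expect_error(curve_auc(p, t_end = Inf, method = "trapezoid"),
               class = "cobaltperm_domain_error")
  expect_error(curve_auc(p, t_end = 1, method = "trapezoid", n_grid = 1),
               class = "cobaltperm_domain_error")
})
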