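#' SAEM fitting controls
#'
#' Settings for [fit_population()]. Defaults: 300 exploratory iterations
#' (step size 1) followed by 100 smoothing iterations (step size 1/k), one
#' MCMC chain per animal with three Metropolis-within-Gibbs kernels per
#' iteration (independent proposal from the current population distribution,
#' a full-vector random walk, and a componentwise random walk), and a
#' proportional residual-error model. Proposal scales adapt toward a 30%
#' acceptance rate during the exploratory phase.
#'
#' @param n_explore,n_smooth Iterations in the exploratory and smoothing
#'   phases.
#' @param n_kernels Metropolis-within-Gibbs kernel sweeps per iteration.
#' @param error_model `"proportional"` (residual sd = sigma * prediction),
#'   `"additive"` (sd = sigma) or `"combined"` (sd = sigma1 + sigma2 *
#'   prediction).
#' @param include_predose Include the pre-dose (t = 0) sample in the
#'   likelihood? Excluded by default: the curve predicts `A exp(-B) > 0` at
#'   t = 0 while the true pre-dose Co is background, so the sample informs
#'   assay background, not kinetics.
#' @param tol Convergence tolerance: the fit is flagged converged when the
#'   relative change of the parameter vector between the first- and
#'   second-half averages of the smoothing phase stays below `tol` (mean
#'   over parameters). The default 0.1 detects stalled or still-drifting
#'   runs while accommodating the Monte-Carlo noise floor of the
#'   variance components.
#' @param omega_floor Lower bound on random-effect variances.
#' @param grid Optional named list of initialization grids (`A_scale`, `B`,
#'   `k1`, `k2`) for the pooled coarse search.
#' @return A `saem_control` list.
#' @export
saem_control <- function(n_explore = 300L, n_smooth = 100L, n_kernels = 3L,
                         error_model = c("proportional", "additive",
                                         "combined"),
                         include_predose = FALSE, tol = 0.1,
                         omega_floor = 1e-6, grid = NULL) {
  error_model <- match.arg(error_model)
  if (n_explore < 1L || n_smooth < 1L) {
    abort("`n_explore` and `n_smooth` must be >= 1.",
          class = "cobaltperm_domain_error")
  }
  default_grid <- list(A_scale = c(0.8, 1.2, 1.8, 2.7, 4),
                       B = c(0.5, 1, 2, 4, 8),
                       k1 = c(0.5, 1, 2, 4, 8),
                       k2 = c(4, 8, 15, 30, 60))
  if (!is.null(grid)) default_grid <- modifyList(default_grid, grid)
  structure(list(n_explore = as.integer(n_explore),
                 n_smooth = as.integer(n_smooth),
                 n_kernels = as.integer(n_kernels),
                 error_model = error_model,
                 include_predose = include_predose,
                 tol = tol, omega_floor = omega_floor,
                 grid = default_grid),
            class = "saem_control")
}

# Prepare long urine data for fitting: canonical animal order, predose
# handling, exclusion of degenerate animals.
prepare_series <- function(urine, include_predose) {
  req <- c("animal_id", "time_d", "ratio")
  if (!all(req %in% names(urine))) {
    if ("time_h" %in% names(urine) && !"time_d" %in% names(urine)) {
      urine$time_d <- urine$time_h / 24
    }
  }
  missing_cols <- setdiff(req, names(urine))
  if (length(missing_cols)) {
    abort(paste0("urine data lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "cobaltperm_domain_error")
  }
  if (any(urine$ratio < 0, na.rm = TRUE) || anyNA(urine$ratio)) {
    abort("ratios must be non-negative and non-missing.",
          class = "cobaltperm_domain_error")
  }
  urine <- dplyr::arrange(urine, .data$animal_id, .data$time_d)
  if (!include_predose) urine <- dplyr::filter(urine, .data$time_d > 0)

  degenerate <- urine |>
    dplyr::summarise(allzero = all(.data$ratio == 0),
                     .by = "animal_id") |>
    dplyr::filter(.data$allzero)
  if (nrow(degenerate)) {
    warn(paste0("excluding animal(s) with all-zero ratios: ",
                paste(degenerate$animal_id, collapse = ", ")),
         class = "cobaltperm_excluded_animals")
    urine <- dplyr::filter(urine,
                           !.data$animal_id %in% degenerate$animal_id)
  }
  if (dplyr::n_distinct(urine$animal_id) < 2L) {
    abort("at least 2 animals with usable data are required.",
          class = "cobaltperm_domain_error")
  }
  urine
}

# Predictions for stacked observations given a matrix of log-parameters
# phi (n_animals x 4, columns log A, log B, log k1, log k2).
pred_stacked <- function(phi, idx, t) {
  pmax(exp(phi[idx, 1L] - exp(phi[idx, 3L]) * t -
             exp(phi[idx, 2L]) * exp(-exp(phi[idx, 4L]) * t)), 1e-300)
}

obs_loglik_by_animal <- function(phi, idx, t, y, sigma, error_model,
                                 n_animals) {
  f <- pred_stacked(phi, idx, t)
  sdv <- pmax(residual_sd(f, sigma, error_model), 1e-12)
  ll <- dnorm(y, mean = f, sd = sdv, log = TRUE)
  as.numeric(rowsum(ll, idx, reorder = TRUE))
}

prior_loglik <- function(phi, mu, omega2) {
  # independent normals on the log scale, summed by animal
  z <- dnorm(sweep(phi, 2L, mu),
             sd = rep(sqrt(omega2), each = nrow(phi)), log = TRUE)
  rowSums(z)
}

#' Fit the population excretion model by SAEM
#'
#' Fits the excretion curve to all animals simultaneously as a nonlinear
#' mixed-effects model: individual parameters are log-normal around
#' population-typical values with a diagonal random-effect covariance, and
#' residual error follows the control's error model. Estimation is
#' stochastic-approximation EM: individual random effects are sampled by
#' Metropolis-within-Gibbs, sufficient statistics are updated by stochastic
#' approximation, and the M-step updates population means, random-effect
#' variances, and the residual parameter in closed form. Initialization is a
#' deterministic pooled coarse grid search. Animals are processed in
#' `animal_id` order, so estimates do not depend on input row order, and the
#' whole fit is reproducible from `seed`. Empirical-Bayes individual
#' parameters are the posterior modes under the final population estimates.
#'
#' @param urine Long tibble of spot samples with columns `animal_id`,
#'   `time_d` (or `time_h`), `ratio`, and ideally `bw_kg`, `breed`,
#'   `treatment` (carried through to downstream steps).
#' @param control A [saem_control()].
#' @param seed Integer seed (required).
#' @return An object of class `saem_fit` with elements `model` (`mu`,
#'   `omega2`, `sigma`, `error_model`), `individual` (tibble of
#'   empirical-Bayes `A`, `B`, `k1`, `k2` per animal), `loglik_trace`,
#'   `theta_trace`, `converged`, `seed`, `data` (the observations used) and
#'   `animals` (per-animal metadata).
#' @examples
#' sim <- simulate_cohort(seed = 1)
#' fit <- fit_population(sim$urine, saem_control(n_explore = 60,
#'                                               n_smooth = 40), seed = 1)
#' tidy(fit)
#' @export
fit_population <- function(urine, control = saem_control(), seed) {
  stopifnot(inherits(control, "saem_control"))
  if (missing(seed)) abort("`seed` is required.",
                           class = "cobaltperm_domain_error")
  set.seed(as.integer(seed))

  dat <- prepare_series(urine, control$include_predose)
  ids <- sort(unique(dat$animal_id))
  n <- length(ids)
  idx <- match(dat$animal_id, ids)
  t <- dat$time_d
  y <- dat$ratio
  N <- length(y)
  em <- control$error_model

  meta_cols <- intersect(c("breed", "treatment", "bw_kg"), names(dat))
  animals <- dat |>
    dplyr::distinct(.data$animal_id,
                    dplyr::across(dplyr::all_of(meta_cols))) |>
    dplyr::arrange(.data$animal_id)

  ## deterministic pooled grid initialization
  g <- control$grid
  ymax <- max(y)
  best <- NULL; best_ss <- Inf
  for (Av in g$A_scale * ymax) for (Bv in g$B)
    for (k1v in g$k1) for (k2v in g$k2) {
      f <- Av * exp(-k1v * t - Bv * exp(-k2v * t))
      ss <- sum((y - f)^2)
      if (ss < best_ss) { best_ss <- ss; best <- c(Av, Bv, k1v, k2v) }
    }
  mu <- log(best)
  names(mu) <- c("A", "B", "k1", "k2")
  f0 <- pred_stacked(matrix(mu, 1L)[rep(1L, n), , drop = FALSE], idx, t)
  sigma <- switch(em,
    proportional = sqrt(mean(((y - f0) / pmax(f0, 1e-6))^2)),
    additive     = sqrt(mean((y - f0)^2)),
    combined     = c(sqrt(mean((y - f0)^2)) / 2,
                     sqrt(mean(((y - f0) / pmax(f0, 1e-6))^2)) / 2))
  sigma <- pmax(sigma, 1e-6)
  omega2 <- rep(0.1, 4)

  # start individuals spread according to the initial population
  # distribution; initializing them all at mu would make the first M-step
  # collapse omega to the floor and pin the chains there
  phi <- matrix(mu, n, 4, byrow = TRUE, dimnames = list(NULL, names(mu))) +
    matrix(rnorm(n * 4, sd = rep(sqrt(omega2), each = n)), n, 4)
  scales <- matrix(0.4 * sqrt(omega2), n, 4, byrow = TRUE)
  ll_cur <- obs_loglik_by_animal(phi, idx, t, y, sigma, em, n)

  n_iter <- control$n_explore + control$n_smooth
  S1 <- phi
  S2 <- sweep(phi^2, 2L, omega2, "+")  # consistent with omega at start
  Sres <- 0
  Se2 <- numeric(N); Sf <- f0   # per-obs stats for the combined model
  theta_trace <- matrix(NA_real_, n_iter, 4 + 4 + length(sigma))
  ll_trace <- numeric(n_iter)

  accept_step <- function(phi_prop, ll_prop, lp_prop, lp_cur, u) {
    log_alpha <- (ll_prop + lp_prop) - (ll_cur + lp_cur)
    log(u) < log_alpha
  }

  for (k in seq_len(n_iter)) {
    gam <- if (k <= control$n_explore) 1 else 1 / (k - control$n_explore)
    adapt <- k <= control$n_explore
    anneal <- adapt

    for (kern in seq_len(control$n_kernels)) {
      lp_cur <- prior_loglik(phi, mu, omega2)
      ## kernel 1: independent proposal from the population distribution
      phi_p <- matrix(rnorm(n * 4, mean = rep(mu, each = n),
                            sd = rep(sqrt(omega2), each = n)), n, 4)
      ll_p <- obs_loglik_by_animal(phi_p, idx, t, y, sigma, em, n)
      lp_p <- prior_loglik(phi_p, mu, omega2)
      acc <- accept_step(phi_p, ll_p, lp_p, lp_cur, runif(n))
      phi[acc, ] <- phi_p[acc, ]; ll_cur[acc] <- ll_p[acc]

      ## kernel 2: full-vector random walk
      lp_cur <- prior_loglik(phi, mu, omega2)
      phi_p <- phi + scales * matrix(rnorm(n * 4), n, 4)
      ll_p <- obs_loglik_by_animal(phi_p, idx, t, y, sigma, em, n)
      lp_p <- prior_loglik(phi_p, mu, omega2)
      acc <- accept_step(phi_p, ll_p, lp_p, lp_cur, runif(n))
      phi[acc, ] <- phi_p[acc, ]; ll_cur[acc] <- ll_p[acc]
      if (adapt) scales <- scales * exp(0.08 * ((acc * 1) - 0.3))

      ## kernel 3: componentwise random walk
      for (j in 1:4) {
        lp_cur <- prior_loglik(phi, mu, omega2)
        phi_p <- phi
        phi_p[, j] <- phi[, j] + scales[, j] * rnorm(n)
        ll_p <- obs_loglik_by_animal(phi_p, idx, t, y, sigma, em, n)
        lp_p <- prior_loglik(phi_p, mu, omega2)
        acc <- accept_step(phi_p, ll_p, lp_p, lp_cur, runif(n))
        phi[acc, ] <- phi_p[acc, ]; ll_cur[acc] <- ll_p[acc]
        if (adapt) scales[, j] <- scales[, j] * exp(0.08 * ((acc * 1) - 0.3))
      }
    }

    ## stochastic-approximation update of sufficient statistics
    S1 <- S1 + gam * (phi - S1)
    S2 <- S2 + gam * (phi^2 - S2)
    f <- pred_stacked(phi, idx, t)
    res_stat <- switch(em,
      proportional = sum(((y - f) / f)^2),
      additive     = sum((y - f)^2),
      combined     = NA_real_)
    if (em == "combined") {
      Se2 <- Se2 + gam * ((y - f)^2 - Se2)
      Sf <- Sf + gam * (f - Sf)
    } else {
      Sres <- Sres + gam * (res_stat - Sres)
    }

    ## M-step; during exploration, variances may shrink by at most 5% per
    ## iteration (simulated annealing) so the chains can reach individual
    ## modes before the population prior tightens around the mean
    mu <- colMeans(S1)
    omega2_new <- pmax(colMeans(S2) - mu^2, control$omega_floor)
    omega2 <- if (anneal) pmax(omega2_new, 0.95 * omega2) else omega2_new
    if (em == "combined") {
      obj <- function(ls) {
        sdv <- exp(ls[1]) + exp(ls[2]) * Sf
        sum(log(sdv) + Se2 / (2 * sdv^2))
      }
      opt <- optim(log(sigma), obj, method = "Nelder-Mead",
                   control = list(maxit = 200))
      sigma <- pmax(exp(opt$par), 1e-8)
    } else {
      sigma_new <- max(sqrt(Sres / N), 1e-8)
      sigma <- if (anneal) max(sigma_new, sqrt(0.95) * sigma) else sigma_new
    }

    theta_trace[k, ] <- c(mu, omega2, sigma)
    ll_trace[k] <- sum(ll_cur) + sum(prior_loglik(phi, mu, omega2))
  }

  ## convergence: relative drift of the parameter vector across the
  ## smoothing phase, measured on half-phase averages so Monte-Carlo
  ## jitter does not mask (or mimic) a trend
  half <- control$n_smooth %/% 2L
  first_half <- control$n_explore + seq_len(half)
  second_half <- (control$n_explore + half + 1L):n_iter
  m1 <- colMeans(theta_trace[first_half, , drop = FALSE])
  m2 <- colMeans(theta_trace[second_half, , drop = FALSE])
  rel_chg <- abs(m2 - m1) / (abs(m1) + 1e-10)
  converged <- mean(rel_chg) < control$tol

  ## empirical-Bayes modes under the final population estimates
  eb <- t(vapply(seq_len(n), function(i) {
    rows <- idx == i
    ti <- t[rows]; yi <- y[rows]
    nll <- function(p) {
      f <- pmax(exp(p[1L] - exp(p[3L]) * ti -
                      exp(p[2L]) * exp(-exp(p[4L]) * ti)), 1e-300)
      sdv <- pmax(residual_sd(f, sigma, em), 1e-12)
      -sum(dnorm(yi, f, sdv, log = TRUE)) -
        sum(dnorm(p, mu, sqrt(omega2), log = TRUE))
    }
    optim(phi[i, ], nll, method = "Nelder-Mead",
          control = list(maxit = 1000, reltol = 1e-10))$par
  }, numeric(4)))

  individual <- tibble::tibble(animal_id = ids,
                               A = exp(eb[, 1L]), B = exp(eb[, 2L]),
                               k1 = exp(eb[, 3L]), k2 = exp(eb[, 4L]))
  individual <- dplyr::left_join(individual, animals, by = "animal_id")

  structure(list(
    model = list(mu = mu, omega2 = setNames(omega2, names(mu)),
                 sigma = sigma, error_model = em),
    individual = individual,
    loglik_trace = ll_trace,
    theta_trace = theta_trace,
    converged = converged,
    mean_rel_change = mean(rel_chg),
    seed = as.integer(seed),
    control = control,
    data = dat,
    animals = animals), class = "saem_fit")
}

#' @export
print.saem_fit <- function(x, ...) {
  cat(sprintf("<saem_fit>  %d animals, %d observations, error model '%s'\n",
              nrow(x$individual), nrow(x$data), x$model$error_model))
  est <- exp(x$model$mu)
  om <- sqrt(x$model$omega2)
  cat("  population estimates (between-animal SD of log parameter):\n")
  for (j in seq_along(est)) {
    cat(sprintf("    %-3s = %.5g  (omega %.3g)\n",
                names(est)[j], est[j], om[j]))
  }
  cat(sprintf("  sigma = %s,  converged: %s\n",
              paste(signif(x$model$sigma, 4), collapse = ", "),
              x$converged))
  invisible(x)
}

#' Individual fitted curve from a population fit
#'
#' @param fit An `saem_fit`.
#' @param animal_id Animal label present in the fit.
#' @return An [excretion_curve()] with that animal's empirical-Bayes
#'   parameters.
#' @export
individual_curve <- function(fit, animal_id) {
  stopifnot(inherits(fit, "saem_fit"))
  row <- fit$individual[fit$individual$animal_id == animal_id, ]
  if (nrow(row) != 1L) {
    abort(sprintf("animal '%s' not present in the fit.", animal_id),
          class = "cobaltperm_lookup_error")
  }
  excretion_curve(row$A, row$B, row$k1, row$k2)
}
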