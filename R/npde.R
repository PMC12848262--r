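#' Normalized prediction distribution errors
#'
#' Tests the adequacy of a fitted population model by simulating `n_sim`
#' replicate datasets from it at the observed design points, decorrelating
#' observed and simulated values within each animal with the inverse
#' Cholesky factor of the empirical simulated covariance, and transforming
#' each observation's rank among its simulated counterparts through the
#' standard-normal quantile function. Under a correct model the npde are
#' approximately iid standard normal; three tests summarise this: a
#' Shapiro-Wilk normality test, a Wilcoxon signed-rank test of zero median,
#' and a chi-square variance test of unit variance (two-sided, n - 1 df).
#'
#' If an animal's simulated covariance is numerically singular, that animal
#' falls back to marginal (non-decorrelated) standardization with a warning.
#'
#' @param fit An `saem_fit` from [fit_population()].
#' @param urine Observations to evaluate; defaults to the data used in the
#'   fit.
#' @param n_sim Simulation replicates (default 1000, minimum 100).
#' @param seed Integer seed.
#' @return An `npde_report`: list with `npde` (tibble: `animal_id`,
#'   `time_d`, `observed`, `npde`), `shapiro_p`, `wilcoxon_p`,
#'   `fisher_var_p`, `n_sim`, `n_fallback`.
#' @export
compute_npde <- function(fit, urine = NULL, n_sim = 1000L, seed) {
  stopifnot(inherits(fit, "saem_fit"))
  if (missing(seed)) abort("`seed` is required.",
                           class = "cobaltperm_domain_error")
  if (n_sim < 100L) abort("`n_sim` must be >= 100.",
                          class = "cobaltperm_domain_error")
  if (!fit$converged) {
    warn("fit is flagged as not converged; npde may be unreliable.",
         class = "cobaltperm_unconverged")
  }
  dat <- if (is.null(urine)) fit$data
         else prepare_series(urine, fit$control$include_predose)
  set.seed(as.integer(seed))

  ids <- sort(unique(dat$animal_id))
  idx <- match(dat$animal_id, ids)
  n <- length(ids)
  N <- nrow(dat)
  t <- dat$time_d
  y <- dat$ratio
  mu <- fit$model$mu
  om <- sqrt(fit$model$omega2)
  sig <- fit$model$sigma
  em <- fit$model$error_model

  sims <- matrix(NA_real_, N, n_sim)
  for (s in seq_len(n_sim)) {
    phi <- matrix(rnorm(n * 4, mean = rep(mu, each = n),
                        sd = rep(om, each = n)), n, 4)
    f <- pred_stacked(phi, idx, t)
    sims[, s] <- f + residual_sd(f, sig, em) * rnorm(N)
  }

  npde_val <- numeric(N)
  n_fallback <- 0L
  for (i in seq_len(n)) {
    rows <- which(idx == i)
    S <- sims[rows, , drop = FALSE]
    m <- rowMeans(S)
    Sc <- S - m
    V <- Sc %*% t(Sc) / (n_sim - 1)
    dec <- tryCatch({
      L <- t(chol(V))
      list(yd = forwardsolve(L, y[rows] - m),
           Sd = forwardsolve(L, Sc))
    }, error = function(e) NULL)
    if (is.null(dec)) {
      n_fallback <- n_fallback + 1L
      sdv <- pmax(sqrt(diag(V)), 1e-12)
      dec <- list(yd = (y[rows] - m) / sdv, Sd = Sc / sdv)
    }
    # rank of each decorrelated observation among its simulated values,
    # mapped to (0, 1) with a continuity correction
    k_below <- rowSums(dec$Sd < dec$yd)
    npde_val[rows] <- qnorm((k_below + 0.5) / (n_sim + 1))
  }
  if (n_fallback > 0L) {
    warn(sprintf(
      "singular simulated covariance for %d animal(s); marginal standardization used.",
      n_fallback), class = "cobaltperm_npde_fallback")
  }

  fisher_var_test <- function(x) {
    stat <- (length(x) - 1) * var(x)
    p_lo <- pchisq(stat, df = length(x) - 1)
    min(1, 2 * min(p_lo, 1 - p_lo))
  }
  structure(list(
    npde = tibble::tibble(animal_id = dat$animal_id, time_d = t,
                          observed = y, npde = npde_val),
    shapiro_p = shapiro.test(npde_val)$p.value,
    wilcoxon_p = wilcox.test(npde_val, mu = 0, exact = FALSE)$p.value,
    fisher_var_p = fisher_var_test(npde_val),
    n_sim = as.integer(n_sim),
    n_fallback = n_fallback), class = "npde_report")
}

#' @export
print.npde_report <- function(x, ...) {
  cat(sprintf("<npde_report>  %d observations, %d simulations\n",
              nrow(x$npde), x$n_sim))
  cat(sprintf("  normality (Shapiro-Wilk)     p = %.3g\n", x$shapiro_p))
  cat(sprintf("  zero median (Wilcoxon)       p = %.3g\n", x$wilcoxon_p))
  cat(sprintf("  unit variance (chi-square)   p = %.3g\n", x$fisher_var_p))
  if (x$n_fallback > 0)
    cat(sprintf("  (%d animal(s) used marginal standardization)\n",
                x$n_fallback))
  invisible(x)
}
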