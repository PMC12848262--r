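#' Tidy a population fit
#'
#' @param x An `saem_fit`.
#' @param ... Unused.
#' @return Tibble with one row per kinetic parameter: natural-scale
#'   `estimate`, log-scale mean `log_mean`, and between-animal SD of the log
#'   parameter `omega_sd`.
#' @export
tidy.saem_fit <- function(x, ...) {
  tibble::tibble(parameter = names(x$model$mu),
                 estimate = unname(exp(x$model$mu)),
                 log_mean = unname(x$model$mu),
                 omega_sd = unname(sqrt(x$model$omega2)))
}

#' @rdname tidy.saem_fit
#' @export
glance.saem_fit <- function(x, ...) {
  tibble::tibble(n_animals = nrow(x$individual), n_obs = nrow(x$data),
                 error_model = x$model$error_model,
                 sigma = x$model$sigma[1L],
                 iterations = length(x$loglik_trace),
                 converged = x$converged, seed = x$seed)
}

#' @rdname tidy.saem_fit
#' @param data Observations to augment; defaults to the fitting data.
#' @export
augment.saem_fit <- function(x, data = NULL, ...) {
  dat <- if (is.null(data)) x$data else data
  ind <- x$individual
  i <- match(dat$animal_id, ind$animal_id)
  if (anyNA(i)) abort("data contains animals absent from the fit.",
                      class = "cobaltperm_lookup_error")
  phi <- log(as.matrix(ind[, c("A", "B", "k1", "k2")]))
  dat$.fitted <- pred_stacked(phi, i, dat$time_d)
  dat$.fitted_pop <- pred_stacked(matrix(x$model$mu, 1L, 4L),
                                  rep(1L, nrow(dat)), dat$time_d)
  dat$.resid <- dat$ratio - dat$.fitted
  dat
}

#' Tidy an npde report
#'
#' @param x An `npde_report`.
#' @param ... Unused.
#' @return The per-observation npde tibble.
#' @export
tidy.npde_report <- function(x, ...) x$npde

#' @rdname tidy.npde_report
#' @export
glance.npde_report <- function(x, ...) {
  tibble::tibble(shapiro_p = x$shapiro_p, wilcoxon_p = x$wilcoxon_p,
                 fisher_var_p = x$fisher_var_p, n_obs = nrow(x$npde),
                 n_sim = x$n_sim, n_fallback = x$n_fallback)
}

#' Tidy an ANOVA table
#'
#' @param x An `anova_table`.
#' @param ... Unused.
#' @return The term-level tibble (term, df, sum of squares, F, p).
#' @export
tidy.anova_table <- function(x, ...) x$terms

#' @rdname tidy.anova_table
#' @export
glance.anova_table <- function(x, ...) {
  tibble::tibble(response = x$response, df_error = x$df_error, mse = x$mse,
                 sem = x$sem, n_per_cell = x$n_per_cell)
}

#' Tidy a stepwise ANCOVA fit
#'
#' @param x An `ancova_fit`.
#' @param ... Unused.
#' @return The final-model term tibble.
#' @export
tidy.ancova_fit <- function(x, ...) x$final_terms

#' @rdname tidy.ancova_fit
#' @export
glance.ancova_fit <- function(x, ...) {
  tibble::tibble(response = x$response, covariate = x$covariate,
                 slope = x$slope, n_dropped = nrow(x$elimination_path),
                 covariate_retained = x$covariate %in% x$final_terms$term,
                 alpha = x$alpha)
}
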