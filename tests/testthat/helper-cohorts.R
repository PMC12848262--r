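# Shared fixtures, built in code.

# A population "fit" assembled directly from a generator truth record, for
# exercising downstream operations (npde, excretion) against the known
# data-generating model without estimation noise.
truth_as_fit <- function(sim) {
  g <- sim$truth$generator
  a <- sim$truth$animals
  structure(list(
    model = list(mu = g$mu,
                 omega2 = setNames(g$omega^2, c("A", "B", "k1", "k2")),
                 sigma = g$sigma, error_model = g$error_model),
    individual = a[, c("animal_id", "A", "B", "k1", "k2", "breed",
                       "treatment", "bw_kg")],
    loglik_trace = numeric(0), theta_trace = NULL,
    converged = TRUE, mean_rel_change = 0,
    seed = sim$truth$seed, control = saem_control(),
    data = dplyr::filter(sim$urine, time_d > 0),
    animals = a[, c("animal_id", "breed", "treatment", "bw_kg")]),
    class = "saem_fit")
}

# Balanced 2x2 dataset with exact cell means and exact MSE, n = 3 per cell:
# residual pattern (d, -d, 0) in each cell gives SSE = 8 d^2, MSE = d^2.
balanced_2x2 <- function(cell_means, mse) {
  d <- sqrt(mse)
  tibble::tibble(
    treatment = rep(rep(c(0, 200), each = 3), 2),
    breed = rep(c("Holstein", "Jersey"), each = 6),
    y = rep(cell_means, each = 3) + rep(c(d, -d, 0), 4))
}

# Draws from the synthetic-data kinetic prior (log-normal around the default
# generator truth), for property tests over random curve parameters.
draw_prior_params <- function(n) {
  g <- generator_truth()
  purrr::map(seq_len(n), function(i) {
    p <- exp(g$mu + rnorm(4) * g$omega)
    excretion_curve(p[1], p[2], p[3], p[4])
  })
}

quick_control <- function(...) saem_control(n_explore = 80L, n_smooth = 40L, ...)
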