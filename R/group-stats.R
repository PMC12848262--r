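new_anova_table <- function(response, terms, df_error, mse, cell_means, sem,
                            n_per_cell) {
  structure(list(response = response, terms = terms, df_error = df_error,
                 mse = mse, cell_means = cell_means, sem = sem,
                 n_per_cell = n_per_cell),
            class = "anova_table")
}

# F tests against the residual mean square. A term whose sum of squares is
# zero at the scale of the data carries no effect, so F = 0 and p = 1 even
# when the MSE is itself zero (constant response).
term_tests <- function(ss, df, mse, df_error, scale) {
  zero <- ss <= 1e-12 * scale
  f <- ifelse(zero, 0, ss / df / mse)
  p <- ifelse(zero, 1, pf(f, df, df_error, lower.tail = FALSE))
  list(f = f, p = p)
}

#' Two-way factorial ANOVA
#'
#' Ordinary-least-squares fit of `response ~ A + B + A:B` with term F-tests
#' against the residual mean square — the analysis applied to urinary Co
#' excretion and each serum marker (factors: aspirin treatment and breed).
#'
#' @param data Per-animal data frame.
#' @param response Name of the response column (string).
#' @param factor_a,factor_b Names of the two factor columns (defaults
#'   `"treatment"` and `"breed"`); each must have exactly two observed
#'   levels.
#' @return An `anova_table`: term-level df, sums of squares, F and p, the
#'   residual df and mean square, cell means, and (for a balanced design)
#'   the pooled SEM of a cell mean, `sqrt(MSE / n)`.
#' @examples
#' sim <- simulate_cohort(seed = 1)
#' dat <- dplyr::left_join(sim$serum,
#'   sim$truth$animals[, c("animal_id", "total_co_mg")], by = "animal_id")
#' factorial_anova(dat, "total_co_mg")
#' @export
factorial_anova <- function(data, response, factor_a = "treatment",
                            factor_b = "breed") {
  for (col in c(response, factor_a, factor_b)) {
    if (!col %in% names(data)) {
      abort(sprintf("column '%s' not found.", col),
            class = "cobaltperm_domain_error")
    }
  }
  fa <- factor(data[[factor_a]])
  fb <- factor(data[[factor_b]])
  y <- data[[response]]
  if (nlevels(fa) != 2L || nlevels(fb) != 2L) {
    abort("each factor must have exactly two observed levels.",
          class = "cobaltperm_domain_error")
  }
  counts <- table(fa, fb)
  if (any(counts == 0L)) {
    empty <- which(counts == 0L, arr.ind = TRUE)[1L, ]
    abort(sprintf("empty design cell: %s = %s, %s = %s.", factor_a,
                  levels(fa)[empty[1L]], factor_b, levels(fb)[empty[2L]]),
          class = "cobaltperm_domain_error")
  }
  df <- data.frame(y = y, fa = fa, fb = fb)
  mod <- lm(y ~ fa * fb, data = df)
  if (df.residual(mod) == 0L) {
    abort("zero residual degrees of freedom (one observation per cell).",
          class = "cobaltperm_domain_error")
  }
  at <- suppressWarnings(anova(mod))  # perfect-fit warning handled below
  ss <- at$`Sum Sq`[1:3]
  dfs <- at$Df[1:3]
  df_error <- at$Df[4L]
  mse <- at$`Mean Sq`[4L]
  tt <- term_tests(ss, dfs, mse, df_error, scale = sum(y^2))
  term_names <- c(factor_a, factor_b, paste0(factor_a, ":", factor_b))
  terms_tbl <- tibble::tibble(term = term_names, df = dfs, sumsq = ss,
                              statistic = tt$f, p.value = tt$p)
  cm <- tibble::as_tibble(expand.grid(a = levels(fa), b = levels(fb),
                                      KEEP.OUT.ATTRS = FALSE))
  names(cm) <- c(factor_a, factor_b)
  cm$mean <- as.vector(tapply(y, list(fa, fb), mean))
  balanced <- length(unique(as.vector(counts))) == 1L
  n_cell <- if (balanced) as.integer(counts[1L]) else NA_integer_
  sem <- if (balanced) sqrt(mse / n_cell) else NA_real_
  new_anova_table(response, terms_tbl, df_error, mse, cm, sem, n_cell)
}

#' Reconstruct a 2x2 ANOVA from printed cell means and SEM
#'
#' Rebuilds the balanced two-way ANOVA from summary statistics alone, as
#' published tables report them: with n observations per cell and a pooled
#' SEM of a cell mean, `MSE = n * SEM^2`, and each single-df effect sum of
#' squares follows from the corresponding cell-mean contrast,
#' `SS = n * c^2 / 4`. Raw data are not required.
#'
#' @param cell_means Numeric length-4 vector of cell means in the order
#'   (A-low, B1), (A-high, B1), (A-low, B2), (A-high, B2) — e.g. the
#'   published group order H0, H200, J0, J200 — or a 2x2 matrix with factor
#'   A as rows and factor B as columns.
#' @param sem Pooled standard error of a cell mean (must be positive).
#' @param n_per_cell Observations per cell (>= 2).
#' @param term_names Labels for factor A, factor B and their interaction.
#' @return An `anova_table`.
#' @examples
#' # published urinary Co excretion row: means, SEM 16.5, n = 3
#' anova_from_summary(c(210, 239, 292, 274), sem = 16.5, n_per_cell = 3,
#'                    term_names = c("aspirin", "breed"))
#' @export
anova_from_summary <- function(cell_means, sem, n_per_cell,
                               term_names = c("aspirin", "breed")) {
  if (is.matrix(cell_means)) cell_means <- as.vector(cell_means)
  if (length(cell_means) != 4L || anyNA(cell_means)) {
    abort("`cell_means` must hold four non-missing cell means.",
          class = "cobaltperm_domain_error")
  }
  if (!is.numeric(sem) || sem <= 0) {
    abort("`sem` must be > 0.", class = "cobaltperm_domain_error")
  }
  if (n_per_cell < 2L) abort("`n_per_cell` must be >= 2.",
                             class = "cobaltperm_domain_error")
  n <- n_per_cell
  m <- cell_means  # (a1b1, a2b1, a1b2, a2b2)
  c_a <- (m[2L] + m[4L]) - (m[1L] + m[3L])
  c_b <- (m[3L] + m[4L]) - (m[1L] + m[2L])
  c_ab <- (m[2L] - m[1L]) - (m[4L] - m[3L])
  ss <- n * c(c_a, c_b, c_ab)^2 / 4
  mse <- n * sem^2
  df_error <- 4L * (n - 1L)
  tt <- term_tests(ss, rep(1L, 3L), mse, df_error,
                   scale = n * sum(cell_means^2))
  labels <- c(term_names[1L], term_names[2L],
              paste0(term_names[1L], ":", term_names[2L]))
  terms_tbl <- tibble::tibble(term = labels, df = 1L, sumsq = ss,
                              statistic = tt$f, p.value = tt$p)
  cm <- tibble::tibble(a = rep(c("low", "high"), 2L),
                       b = rep(c("B1", "B2"), each = 2L), mean = m)
  names(cm)[1:2] <- term_names
  new_anova_table("(from summary)", terms_tbl, df_error, mse, cm, sem,
                  as.integer(n))
}

#' @export
print.anova_table <- function(x, ...) {
  cat(sprintf("<anova_table>  response: %s\n", x$response))
  tbl <- x$terms
  for (i in seq_len(nrow(tbl))) {
    cat(sprintf("  %-22s df %d  SS %10.4g  F %8.4g  p %.4g\n",
                tbl$term[i], tbl$df[i], tbl$sumsq[i], tbl$statistic[i],
                tbl$p.value[i]))
  }
  cat(sprintf("  residual df %d, MSE %.4g", x$df_error, x$mse))
  if (!is.na(x$sem)) cat(sprintf(", SEM %.4g (n = %d/cell)", x$sem,
                                 x$n_per_cell))
  cat("\n")
  invisible(x)
}

term_order <- function(term) lengths(strsplit(term, ":", fixed = TRUE))

# a term is droppable when it is not contained in any other term still in
# the model (marginality)
droppable_terms <- function(term_labels) {
  vars <- strsplit(term_labels, ":", fixed = TRUE)
  vapply(seq_along(vars), function(i) {
    !any(vapply(seq_along(vars), function(j) {
      j != i && all(vars[[i]] %in% vars[[j]])
    }, logical(1)))
  }, logical(1))
}

#' Stepwise ANCOVA of a serum marker on quantified Co excretion
#'
#' Starts from the full model `response ~ factor_a * factor_b * covariate`
#' (all terms up to the three-way interaction) and removes terms backward:
#' at each step, among terms not contained in any retained higher-order term
#' (marginality protection), the highest-order term with the largest
#' nonsignificant Type II p-value is dropped; elimination stops when every
#' droppable term is significant at `alpha`. This mirrors published practice
#' of starting with the highest-order term and removing nonsignificant
#' (p > 0.05) terms one at a time.
#'
#' @param data Per-animal data frame.
#' @param response Response column name (string).
#' @param covariate Continuous covariate column (default `"total_co_mg"`,
#'   the quantified urinary Co excretion).
#' @param factor_a,factor_b Factor columns (defaults `"treatment"`,
#'   `"breed"`).
#' @param alpha Retention threshold (default 0.05).
#' @return An `ancova_fit`: `elimination_path` (tibble of dropped terms with
#'   the p-value at the drop), `final_terms` (Type II F and p), `slope` (the
#'   covariate coefficient in the final model, or `NA` if the covariate was
#'   eliminated), and the final `lm` object.
#' @export
ancova_stepwise <- function(data, response, covariate = "total_co_mg",
                            factor_a = "treatment", factor_b = "breed",
                            alpha = 0.05) {
  for (col in c(response, covariate, factor_a, factor_b)) {
    if (!col %in% names(data)) {
      abort(sprintf("column '%s' not found.", col),
            class = "cobaltperm_domain_error")
    }
  }
  df <- data.frame(y = data[[response]],
                   fa = factor(data[[factor_a]]),
                   fb = factor(data[[factor_b]]),
                   cv = as.numeric(data[[covariate]]))
  if (length(unique(df$cv)) < 2L) {
    abort("the covariate must take at least 2 distinct values.",
          class = "cobaltperm_domain_error")
  }
  label_map <- c(fa = factor_a, fb = factor_b, cv = covariate)
  pretty <- function(lbl) {
    vapply(strsplit(lbl, ":", fixed = TRUE), function(v) {
      paste(label_map[v], collapse = ":")
    }, character(1))
  }

  current <- "y ~ fa * fb * cv"
  path <- list()
  repeat {
    mod <- lm(as.formula(current), data = df)
    if (anyNA(coef(mod))) {
      abort(paste0("rank-deficient model; aliased: ",
                   paste(names(coef(mod))[is.na(coef(mod))],
                         collapse = ", ")),
            class = "cobaltperm_rank_deficient")
    }
    labels <- attr(terms(mod), "term.labels")
    if (length(labels) == 0L) break
    a2 <- car::Anova(mod, type = 2)
    pvals <- a2$`Pr(>F)`[match(labels, rownames(a2))]
    drop_ok <- droppable_terms(labels)
    cand <- which(drop_ok & pvals > alpha)
    if (length(cand) == 0L) break
    ord <- term_order(labels[cand])
    pick <- cand[order(-ord, -pvals[cand])][1L]
    path[[length(path) + 1L]] <-
      tibble::tibble(term = pretty(labels[pick]), p_at_drop = pvals[pick])
    current <- paste0(current, " - ", labels[pick])
  }

  labels <- attr(terms(mod), "term.labels")
  if (length(labels)) {
    a2 <- car::Anova(mod, type = 2)
    keep <- match(labels, rownames(a2))
    final_terms <- tibble::tibble(
      term = pretty(labels), df = a2$Df[keep], sumsq = a2$`Sum Sq`[keep],
      statistic = a2$`F value`[keep], p.value = a2$`Pr(>F)`[keep])
  } else {
    final_terms <- tibble::tibble(term = character(), df = integer(),
                                  sumsq = numeric(), statistic = numeric(),
                                  p.value = numeric())
  }
  slope <- if ("cv" %in% labels) unname(coef(mod)["cv"]) else NA_real_
  structure(list(
    response = response, covariate = covariate,
    elimination_path = dplyr::bind_rows(path),
    final_terms = final_terms, slope = slope,
    alpha = alpha, model = mod), class = "ancova_fit")
}

#' @export
print.ancova_fit <- function(x, ...) {
  cat(sprintf("<ancova_fit>  %s ~ ... + %s (alpha = %g)\n", x$response,
              x$covariate, x$alpha))
  if (nrow(x$elimination_path)) {
    cat("  dropped:\n")
    for (i in seq_len(nrow(x$elimination_path))) {
      cat(sprintf("    %-28s p = %.3g\n", x$elimination_path$term[i],
                  x$elimination_path$p_at_drop[i]))
    }
  }
  if (nrow(x$final_terms)) {
    cat("  retained:\n")
    for (i in seq_len(nrow(x$final_terms))) {
      cat(sprintf("    %-28s F = %.4g, p = %.3g\n", x$final_terms$term[i],
                  x$final_terms$statistic[i], x$final_terms$p.value[i]))
    }
  } else cat("  retained: (intercept only)\n")
  if (!is.na(x$slope)) {
    cat(sprintf("  covariate slope: %.4g per mg Co\n", x$slope))
  }
  invisible(x)
}
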