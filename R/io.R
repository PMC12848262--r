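#' Read a urine spot-sample CSV
#'
#' Expects columns `animal_id`, `breed`, `treatment`, `bw_kg`, `time_h`, and
#' either `co_creatinine_ratio` (mg Co/mg creatinine) or the pair `co_mg_l`
#' and `creatinine_mg_l`, from which the ratio is computed. Times are in
#' hours at the file boundary and converted to days internally. Duplicate
#' (animal, time) rows and negative or non-numeric values are rejected with
#' the offending row identified.
#'
#' @param path CSV file path.
#' @return Long tibble: `animal_id`, `breed`, `treatment`, `bw_kg`,
#'   `time_h`, `time_d`, `ratio`, sorted by animal and time.
#' @export
read_urine_csv <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "cobaltperm_io_error")
  }
  # base parser: correctly-rounded doubles keep write -> read -> write
  # byte-identical
  raw <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if ("animal_id" %in% names(raw)) raw$animal_id <- as.character(raw$animal_id)
  base_cols <- c("animal_id", "breed", "treatment", "bw_kg", "time_h")
  missing_cols <- setdiff(base_cols, names(raw))
  if (length(missing_cols)) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "cobaltperm_io_error")
  }
  if ("co_creatinine_ratio" %in% names(raw)) {
    raw$ratio <- raw$co_creatinine_ratio
  } else if (all(c("co_mg_l", "creatinine_mg_l") %in% names(raw))) {
    if (any(!is.finite(raw$creatinine_mg_l) | raw$creatinine_mg_l <= 0)) {
      bad <- which(!is.finite(raw$creatinine_mg_l) | raw$creatinine_mg_l <= 0)
      abort(sprintf("non-positive creatinine at row(s) %s.",
                    paste(bad, collapse = ", ")),
            class = "cobaltperm_io_error")
    }
    raw$ratio <- raw$co_mg_l / raw$creatinine_mg_l
  } else {
    abort("need `co_creatinine_ratio`, or both `co_mg_l` and `creatinine_mg_l`.",
          class = "cobaltperm_io_error")
  }
  for (col in c("treatment", "bw_kg", "time_h", "ratio")) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(raw[[col]]))))
    if (length(bad)) {
      abort(sprintf("non-numeric or missing `%s` at row(s) %s.", col,
                    paste(head(bad, 5L), collapse = ", ")),
            class = "cobaltperm_io_error")
    }
  }
  bad <- which(raw$ratio < 0 | raw$time_h < 0)
  if (length(bad)) {
    abort(sprintf("negative ratio or time at row(s) %s.",
                  paste(head(bad, 5L), collapse = ", ")),
          class = "cobaltperm_io_error")
  }
  dup <- duplicated(raw[, c("animal_id", "time_h")])
  if (any(dup)) {
    d <- raw[which(dup)[1L], ]
    abort(sprintf("duplicated sample time: animal '%s' at %g h.",
                  d$animal_id, d$time_h), class = "cobaltperm_io_error")
  }
  out <- tibble::tibble(animal_id = raw$animal_id, breed = raw$breed,
                        treatment = raw$treatment, bw_kg = raw$bw_kg,
                        time_h = raw$time_h, time_d = raw$time_h / 24,
                        ratio = raw$ratio)
  dplyr::arrange(out, .data$animal_id, .data$time_h)
}

#' Write a urine spot-sample CSV
#'
#' @param urine Tibble as returned by [read_urine_csv()] or found in a
#'   `cohort_sim`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_urine_csv <- function(urine, path) {
  out <- tibble::tibble(animal_id = urine$animal_id, breed = urine$breed,
                        treatment = urine$treatment, bw_kg = urine$bw_kg,
                        time_h = urine$time_h,
                        co_creatinine_ratio = urine$ratio)
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a serum-marker CSV
#'
#' Expects `animal_id`, `breed`, `treatment` and one column per marker
#' (`hp_ug_ml`, `lbp_ng_ml`, `fabp2_pg_ml`, `tnf_pg_ml`); extra marker
#' columns are carried through.
#'
#' @param path CSV file path.
#' @return Tibble, one row per animal.
#' @export
read_serum_csv <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "cobaltperm_io_error")
  }
  raw <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if ("animal_id" %in% names(raw)) raw$animal_id <- as.character(raw$animal_id)
  need <- c("animal_id", "breed", "treatment")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "cobaltperm_io_error")
  }
  if (anyDuplicated(raw$animal_id)) {
    abort("duplicated animal_id in serum table.",
          class = "cobaltperm_io_error")
  }
  tibble::as_tibble(raw)
}

#' @rdname read_serum_csv
#' @param serum Serum tibble.
#' @param path Output path.
#' @export
write_serum_csv <- function(serum, path) {
  readr::write_csv(serum, path)
  invisible(path)
}
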