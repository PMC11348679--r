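#' Read a long-form ratings CSV
#'
#' Expected columns: `patient_id`, `scan_id`, `age_years`, `modality`
#' (`T2`/`T1`), `item`, `grade`; one row per graded item. Item labels may
#' use common aliases (`"PLIC"`, `"c.semiovale"`, `"frontal (not central)"`,
#' ...). An optional `age_months` column is accepted instead of `age_years`.
#' Validation errors report the offending row.
#'
#' @param path CSV file path.
#' @param partial tolerate incompletely graded scans (see
#'   [validate_ratings()]).
#' @return validated ratings tibble.
#' @export
read_ratings <- function(path, partial = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  r <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if ("age_months" %in% names(r) && !"age_years" %in% names(r)) {
    r$age_years <- r$age_months / 12
    r$age_months <- NULL
  }
  validate_ratings(r, partial = partial)
}

#' Read ratings from nested JSON
#'
#' The JSON layout is a list of scans, each with `patient_id`, `scan_id`,
#' `age_years` and named grade maps `t2` and `t1`.
#'
#' @inheritParams read_ratings
#' @return validated ratings tibble.
#' @export
read_ratings_json <- function(path, partial = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  scans <- jsonlite::read_json(path, simplifyVector = FALSE)
  r <- purrr::map_dfr(scans, function(s) {
    g2 <- unlist(s$t2)
    g1 <- unlist(s$t1)
    tibble::tibble(
      patient_id = s$patient_id, scan_id = s$scan_id,
      age_years = as.numeric(s$age_years),
      modality = c(rep("T2", length(g2)), rep("T1", length(g1))),
      item = c(names(g2), names(g1)),
      grade = as.integer(c(g2, g1))
    )
  })
  validate_ratings(r, partial = partial)
}

#' Read a rater table CSV
#'
#' Columns: `item`, `subject_id`, `rater_id`, `grade`.
#'
#' @param path CSV file path.
#' @return tibble suitable for [concordance_by_item()].
#' @export
read_rater_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("item", "subject_id", "rater_id", "grade")
  if (!all(need %in% names(d))) {
    stop("rater table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  d
}

#' Read a volumetry norms CSV
#'
#' Schema: `measurement`, `age_low_years`, `age_high_years`, `mean`, `sd`
#' with contiguous bins per measurement.
#'
#' @param path CSV file path.
#' @return validated norms tibble.
#' @export
read_norms <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  validate_norms(readr::read_csv(path, show_col_types = FALSE, progress = FALSE))
}

#' Write a result table deterministically
#'
#' Column order is preserved, rows are written as-is, and floating point
#' values are serialised at fixed precision so identical results produce
#' byte-identical files.
#'
#' @param results data frame of results.
#' @param path output file path.
#' @param format `"csv"` or `"json"`.
#' @param digits significant digits for floating point serialisation.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("csv", "json"), digits = 9) {
  format <- match.arg(format)
  stopifnot(is.data.frame(results))
  out <- as.data.frame(results)
  is_dbl <- vapply(out, is.double, logical(1))
  out[is_dbl] <- lapply(out[is_dbl], function(x) signif(x, digits))
  if (format == "csv") {
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  } else {
    jsonlite::write_json(out, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Ratings in wide form for human review
#'
#' One row per scan, one column per item/modality (e.g. `T2_plic`).
#'
#' @param ratings long-form ratings table.
#' @return wide tibble.
#' @export
ratings_wide <- function(ratings) {
  r <- validate_ratings(ratings, partial = TRUE)
  r$col <- paste(r$modality, r$item, sep = "_")
  keep <- intersect(c("patient_id", "scan_id", "age_years", "subtype"), names(r))
  tidyr::pivot_wider(r[, c(keep, "col", "grade")],
                     names_from = "col", values_from = "grade")
}
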