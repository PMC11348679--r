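#' Severity groups
#'
#' Ordered labels used by both classifiers: `SEVERE` (connatal/transitional
#' spectrum), `CLASSIC_OR_MILDER`, `MILD` (intermediate, PLP0, SPG2, female),
#' plus `INDETERMINATE` when no rule-based signature fires.
#' @return character vector of the four labels.
#' @export
severity_groups <- function() c("SEVERE", "CLASSIC_OR_MILDER", "MILD", "INDETERMINATE")

#' Rule-based severity classification from item grades
#'
#' Evaluates three sufficient-condition imaging signatures in the order
#' MILD, CLASSIC_OR_MILDER, SEVERE and returns the first that fires, else
#' `INDETERMINATE`:
#' \itemize{
#'   \item MILD: medial lemniscus not abnormally T2-hyperintense (grade 1),
#'     frontal white matter at least T2-isointense, and primary visual region
#'     at least T1-isointense.
#'   \item CLASSIC_OR_MILDER: T2-hypointense MCP, at least T2-isointense
#'     centrum semiovale and PLIC, and T1-hyperintense central region,
#'     centrum semiovale, optic radiation and MCP.
#'   \item SEVERE: no T2 item graded 1 or above, PLIC not T1-hyperintense,
#'     and optic radiation and centrum semiovale not even T1-isointense.
#' }
#' The signatures are treated as sufficient conditions with fixed precedence
#' (most specific first), not as a partition of all possible gradings.
#'
#' @param ratings long-form ratings table with complete T2 and T1 grades;
#'   may contain several scans.
#' @return tibble with columns `scan_id` and `rule_group`.
#' @examples
#' classify_rules(pmd_example_ratings())
#' @export
classify_rules <- function(ratings) {
  r <- validate_ratings(ratings)
  g <- function(scan, mod, item) {
    v <- r$grade[r$scan_id == scan & r$modality == mod & r$item == item]
    if (length(v) != 1) stop("missing grade for ", item, " (", mod, ")",
                             call. = FALSE)
    v
  }
  scans <- unique(r$scan_id)
  grp <- vapply(scans, function(s) {
    t2 <- r$grade[r$scan_id == s & r$modality == "T2"]
    if (g(s, "T2", "medial_lemniscus") == 1 &&
        g(s, "T2", "frontal") >= 1 &&
        g(s, "T1", "primary_visual") >= 1) {
      return("MILD")
    }
    if (g(s, "T2", "mcp") == 2 &&
        g(s, "T2", "centrum_semiovale") >= 1 &&
        g(s, "T2", "plic") >= 1 &&
        g(s, "T1", "central_region") == 2 &&
        g(s, "T1", "centrum_semiovale") == 2 &&
        g(s, "T1", "optic_radiation") == 2 &&
        g(s, "T1", "mcp") == 2) {
      return("CLASSIC_OR_MILDER")
    }
    if (all(t2 == 0) &&
        g(s, "T1", "plic") < 2 &&
        g(s, "T1", "optic_radiation") < 1 &&
        g(s, "T1", "centrum_semiovale") < 1) {
      return("SEVERE")
    }
    "INDETERMINATE"
  }, character(1))
  tibble::tibble(scan_id = scans, rule_group = unname(grp))
}

#' Threshold-based severity classification from the combined score
#'
#' Classifies combined first-MRI myelination scores against two half-integer
#' cut-offs derived by ROC analysis: below `severe_vs_classic` (default 6.5)
#' is SEVERE, below `classic_vs_mild` (default 14.5) is CLASSIC_OR_MILDER,
#' otherwise MILD. Intended for first-MRI scores: classic-type scores rise
#' past the upper cut-off on follow-up.
#'
#' @param scores a data frame with a `combined` column (e.g. from
#'   [score_scans()]), or a bare numeric vector of combined scores.
#' @param severe_vs_classic,classic_vs_mild cut-offs; must satisfy
#'   `severe_vs_classic < classic_vs_mild`. Half-integer values mean integer
#'   scores never tie.
#' @return the input tibble with a `threshold_group` column appended (or a
#'   character vector if `scores` was a numeric vector).
#' @examples
#' classify_threshold(score_scans(pmd_example_ratings()))
#' classify_threshold(c(0, 6, 7, 14, 15))
#' @export
classify_threshold <- function(scores, severe_vs_classic = 6.5,
                               classic_vs_mild = 14.5) {
  if (severe_vs_classic >= classic_vs_mild) {
    stop("severe_vs_classic must be below classic_vs_mild", call. = FALSE)
  }
  vec <- if (is.data.frame(scores)) {
    if (!"combined" %in% names(scores)) {
      stop("scores must contain a 'combined' column", call. = FALSE)
    }
    scores$combined
  } else {
    scores
  }
  grp <- ifelse(vec < severe_vs_classic, "SEVERE",
         ifelse(vec < classic_vs_mild, "CLASSIC_OR_MILDER", "MILD"))
  if (is.data.frame(scores)) {
    scores$threshold_group <- grp
    tibble::as_tibble(scores)
  } else {
    grp
  }
}

#' Classify scans by both routes
#'
#' Convenience wrapper combining [classify_rules()] and
#' [classify_threshold()] per scan.
#'
#' @inheritParams classify_rules
#' @inheritParams classify_threshold
#' @return tibble: `scan_id`, `combined`, `rule_group`, `threshold_group`.
#' @export
classify_scans <- function(ratings, severe_vs_classic = 6.5,
                           classic_vs_mild = 14.5) {
  s <- score_scans(ratings)
  rules <- classify_rules(ratings)
  out <- dplyr::left_join(s[, c("scan_id", "combined")], rules, by = "scan_id")
  out$threshold_group <- classify_threshold(out$combined,
                                            severe_vs_classic, classic_vs_mild)
  out
}
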