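#' Compute the T2 myelination sub-score
#'
#' Sum of the seven three-level T2 grades plus the binary medial-lemniscus
#' grade; range 0--15. Higher means more mature myelin.
#'
#' @param ratings long-form ratings table (see [validate_ratings()]); may
#'   contain one or several scans. Only T2 completeness is required.
#' @param partial allow incomplete scans; the sum then covers the graded
#'   items only and is flagged via the `"partial"` attribute.
#' @return integer vector of T2 sums, named by `scan_id` and ordered as the
#'   scans appear in `ratings`.
#' @examples
#' r <- pmd_example_ratings()
#' score_t2(dplyr::filter(r, scan_id == "A"))
#' @export
score_t2 <- function(ratings, partial = FALSE) {
  modality_sum(ratings, "T2", partial = partial)
}

#' Compute the T1 myelination sub-score
#'
#' Sum of the six three-level T1 grades; range 0--12.
#'
#' @inheritParams score_t2
#' @return integer vector of T1 sums, named by `scan_id`.
#' @examples
#' r <- pmd_example_ratings()
#' score_t1(dplyr::filter(r, scan_id == "A"))
#' @export
score_t1 <- function(ratings, partial = FALSE) {
  modality_sum(ratings, "T1", partial = partial)
}

modality_sum <- function(ratings, modality, partial = FALSE) {
  r <- validate_ratings(ratings, require = modality, partial = partial)
  sc <- item_registry[item_registry$scoring & item_registry$modality == modality, ]
  scans <- unique(as.character(ratings$scan_id))
  r <- r[r$modality == modality & r$item %in% sc$item, ]
  f <- factor(r$scan_id, levels = scans)
  rs <- rowsum(r$grade, f)
  out <- stats::setNames(integer(length(scans)), scans)
  out[rownames(rs)] <- as.integer(rs[, 1])
  if (partial) {
    attr(out, "partial") <- stats::setNames(
      tabulate(f, nbins = length(scans)) < nrow(sc), scans)
  }
  out
}

#' Compute T2, T1 and combined myelination scores per scan
#'
#' @inheritParams score_t2
#' @return A tibble with one row per scan: `patient_id`, `scan_id`,
#'   `age_years`, (`subtype` if present in the input), `t2_sum` (0--15),
#'   `t1_sum` (0--12) and `combined` (0--27, the sum of the two). With
#'   `partial = TRUE` two logical columns `t2_partial`/`t1_partial` flag
#'   incompletely graded scans.
#' @examples
#' score_scans(pmd_example_ratings())
#' @export
score_scans <- function(ratings, partial = FALSE) {
  r <- validate_ratings(ratings, partial = partial)
  keep <- intersect(c("patient_id", "scan_id", "age_years", "subtype"), names(r))
  meta <- dplyr::distinct(r[, keep])
  t2 <- score_t2(r, partial = partial)
  t1 <- score_t1(r, partial = partial)
  out <- meta
  out$t2_sum <- as.integer(t2[match(out$scan_id, names(t2))])
  out$t1_sum <- as.integer(t1[match(out$scan_id, names(t1))])
  out$combined <- out$t2_sum + out$t1_sum
  if (partial) {
    out$t2_partial <- attr(t2, "partial")[match(out$scan_id, names(t2))]
    out$t1_partial <- attr(t1, "partial")[match(out$scan_id, names(t1))]
  }
  tibble::as_tibble(out)
}

#' Combined myelination score for a single scan
#'
#' @param ratings ratings for exactly one scan.
#' @return one-row tibble with `t2_sum`, `t1_sum`, `combined`.
#' @examples
#' r <- pmd_example_ratings()
#' score_combined(dplyr::filter(r, scan_id == "D"))
#' @export
score_combined <- function(ratings) {
  s <- score_scans(ratings)
  if (nrow(s) != 1) stop("score_combined() expects ratings for exactly one scan",
                         call. = FALSE)
  s[, c("t2_sum", "t1_sum", "combined")]
}

#' Score change between two scans of the same patient
#'
#' Per-item and total grade changes between an earlier and a later scan,
#' classified as `increase` (combined score rose and neither sub-score fell),
#' `decrease` (combined fell and neither sub-score rose), `stable` (no
#' change) or `mixed`.
#'
#' @param earlier,later ratings tables, each holding one complete scan of the
#'   same patient, with `later` acquired at a strictly higher age.
#' @return one-row tibble: `patient_id`, `age_from`, `age_to`, `t2_delta`,
#'   `t1_delta`, `combined_delta`, `direction`, and `item_deltas` (a
#'   list-column holding the per-item/modality grade changes).
#' @examples
#' r <- pmd_example_ratings()
#' score_delta(dplyr::filter(r, scan_id == "C"), dplyr::filter(r, scan_id == "D"))
#' @export
score_delta <- function(earlier, later) {
  e <- validate_ratings(earlier)
  l <- validate_ratings(later)
  if (length(unique(e$scan_id)) != 1 || length(unique(l$scan_id)) != 1) {
    stop("score_delta() expects exactly one scan on each side", call. = FALSE)
  }
  if (unique(e$patient_id) != unique(l$patient_id)) {
    stop("scans belong to different patients", call. = FALSE)
  }
  if (l$age_years[1] <= e$age_years[1]) {
    stop("later scan must have strictly greater age_years", call. = FALSE)
  }
  se <- score_scans(e)
  sl <- score_scans(l)
  items <- dplyr::inner_join(
    e[, c("modality", "item", "grade")],
    l[, c("modality", "item", "grade")],
    by = c("modality", "item"), suffix = c("_earlier", "_later")
  )
  items$delta <- items$grade_later - items$grade_earlier
  t2d <- sl$t2_sum - se$t2_sum
  t1d <- sl$t1_sum - se$t1_sum
  cd <- sl$combined - se$combined
  direction <- if (cd > 0 && t2d >= 0 && t1d >= 0) {
    "increase"
  } else if (cd < 0 && t2d <= 0 && t1d <= 0) {
    "decrease"
  } else if (cd == 0 && t2d == 0 && t1d == 0 && all(items$delta == 0)) {
    "stable"
  } else {
    "mixed"
  }
  tibble::tibble(
    patient_id = unique(e$patient_id),
    age_from = e$age_years[1], age_to = l$age_years[1],
    t2_delta = t2d, t1_delta = t1d, combined_delta = cd,
    direction = direction,
    item_deltas = list(tibble::as_tibble(items[, c("modality", "item", "delta")]))
  )
}

#' Worked example ratings
#'
#' Four fully graded scans from two patients illustrating the scoring scheme
#' and its longitudinal use: patient P1 (severe, connatal-type presentation)
#' imaged at 0.19 and 0.96 years shows early loss of myelin signal
#' (T2 1 -> 0, T1 5 -> 1); patient P2 (classic-type presentation) imaged at
#' 1.22 and 9.79 years shows progressing though still severely deficient
#' myelination (combined 10 -> 19).
#'
#' @return long-form ratings tibble with four scans (`A`, `B`, `C`, `D`).
#' @examples
#' score_scans(pmd_example_ratings())
#' @export
pmd_example_ratings <- function() {
  t2_items <- c(.tri_items, "frontal", "medial_lemniscus")
  t1_items <- .tri_items
  grades <- list(
    # scan A: P1 at 0.19 y; T2 = 1 (isointense optic radiation), T1 = 5
    A = list(
      t2 = c(central_region = 0, centrum_semiovale = 0, plic = 0,
             optic_radiation = 1, primary_visual = 0, mcp = 0,
             frontal = 0, medial_lemniscus = 0),
      t1 = c(central_region = 0, centrum_semiovale = 1, plic = 2,
             optic_radiation = 1, primary_visual = 0, mcp = 1)
    ),
    # scan B: P1 at 0.96 y; only punctate T1-isointensity in PLIC remains
    B = list(
      t2 = c(central_region = 0, centrum_semiovale = 0, plic = 0,
             optic_radiation = 0, primary_visual = 0, mcp = 0,
             frontal = 0, medial_lemniscus = 0),
      t1 = c(central_region = 0, centrum_semiovale = 0, plic = 1,
             optic_radiation = 0, primary_visual = 0, mcp = 0)
    ),
    # scan C: P2 at 1.22 y; T2 = 1 (isointense PLIC), T1 = 9
    C = list(
      t2 = c(central_region = 0, centrum_semiovale = 0, plic = 1,
             optic_radiation = 0, primary_visual = 0, mcp = 0,
             frontal = 0, medial_lemniscus = 0),
      t1 = c(central_region = 1, centrum_semiovale = 1, plic = 2,
             optic_radiation = 2, primary_visual = 1, mcp = 2)
    ),
    # scan D: P2 at 9.79 y; T2 = 7, full T1 = 12
    D = list(
      t2 = c(central_region = 0, centrum_semiovale = 1, plic = 2,
             optic_radiation = 2, primary_visual = 0, mcp = 2,
             frontal = 0, medial_lemniscus = 0),
      t1 = c(central_region = 2, centrum_semiovale = 2, plic = 2,
             optic_radiation = 2, primary_visual = 2, mcp = 2)
    )
  )
  meta <- tibble::tibble(
    scan_id = c("A", "B", "C", "D"),
    patient_id = c("P1", "P1", "P2", "P2"),
    age_years = c(0.19, 0.96, 1.22, 9.79)
  )
  purrr::map_dfr(meta$scan_id, function(s) {
    m <- meta[meta$scan_id == s, ]
    g <- grades[[s]]
    tibble::tibble(
      patient_id = m$patient_id, scan_id = s, age_years = m$age_years,
      modality = c(rep("T2", length(t2_items)), rep("T1", length(t1_items))),
      item = c(t2_items, t1_items),
      grade = as.integer(c(g$t2[t2_items], g$t1[t1_items]))
    )
  })
}
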