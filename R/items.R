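#' Item registry of the PMD myelination score
#'
#' The score grades "best myelination" of anatomic white-matter structures
#' ("items") relative to cortex (pontine items relative to surrounding
#' brainstem white matter). Eight items are graded on T2-weighted images
#' (seven on a three-level 0--2 scale plus the medial lemniscus on a binary
#' 0--1 scale) and six on T1-weighted images (all three-level), giving
#' sub-score ranges 0--15 (T2), 0--12 (T1) and 0--27 combined.
#'
#' Grade coding: on T2, 0 = hyperintense, 1 = isointense, 2 = hypointense
#' relative to cortex; on T1, 0 = hypointense, 1 = isointense,
#' 2 = hyperintense. The medial lemniscus is binary: 0 = abnormally
#' T2-hyperintense relative to surrounding brainstem, 1 = normal
#' iso-/hypointense. Higher grades always mean more mature myelin.
#'
#' Candidate items that were evaluated during score development but discarded
#' for insufficient inter-rater concordance (anterior limb of the internal
#' capsule, pontine pyramidal tract, simplified genu scoring, peridentate
#' white matter) are kept in the registry flagged `scoring = FALSE`; they are
#' accepted on input but never contribute to a sum.
#'
#' @param scoring_only if `TRUE` (default) return only the 14 item/modality
#'   pairs that enter the score; if `FALSE` include discarded candidates.
#' @return A tibble with columns `item`, `modality` (`"T2"`/`"T1"`), `scale`
#'   (`"three_level"`/`"binary"`), `max_grade` and `scoring`.
#' @examples
#' pmd_items()
#' pmd_items(scoring_only = FALSE)
#' @export
pmd_items <- function(scoring_only = TRUE) {
  reg <- item_registry
  if (scoring_only) reg <- reg[reg$scoring, ]
  reg
}

# three-level items shared by both modalities
.tri_items <- c(
  "central_region", "centrum_semiovale", "plic",
  "optic_radiation", "primary_visual", "mcp"
)

item_registry <- tibble::tibble(
  item = c(
    .tri_items, "frontal", "medial_lemniscus",       # T2
    .tri_items,                                       # T1
    "alic", "pons_pyramidal_tract", "genu_simplified", "peridentate"
  ),
  modality = c(rep("T2", 8L), rep("T1", 6L), rep("T2", 4L)),
  scale = c(
    rep("three_level", 7L), "binary",
    rep("three_level", 6L),
    rep("three_level", 4L)
  ),
  max_grade = ifelse(c(
    rep(FALSE, 7L), TRUE, rep(FALSE, 10L)
  ), 1L, 2L),
  scoring = c(rep(TRUE, 14L), rep(FALSE, 4L))
)

# alias table: accepts the labels used in radiological practice
item_aliases <- c(
  "central region"        = "central_region",
  "central"               = "central_region",
  "pyramidal tract central region" = "central_region",
  "centrum semiovale"     = "centrum_semiovale",
  "c.semiovale"           = "centrum_semiovale",
  "c semiovale"           = "centrum_semiovale",
  "csem"                  = "centrum_semiovale",
  "plic"                  = "plic",
  "posterior limb internal capsule" = "plic",
  "optic radiation"       = "optic_radiation",
  "primary visual"        = "primary_visual",
  "primary visual cortex" = "primary_visual",
  "primary visual region" = "primary_visual",
  "visual"                = "primary_visual",
  "mcp"                   = "mcp",
  "middle cerebellar peduncle" = "mcp",
  "frontal"               = "frontal",
  "frontal (not central)" = "frontal",
  "frontal not central"   = "frontal",
  "medial lemniscus"      = "medial_lemniscus",
  "lemniscus"             = "medial_lemniscus",
  "alic"                  = "alic",
  "anterior limb internal capsule" = "alic",
  "pons pyramidal tract"  = "pons_pyramidal_tract",
  "pyramidal tract pons"  = "pons_pyramidal_tract",
  "genu"                  = "genu_simplified",
  "genu simplified"       = "genu_simplified",
  "peridentate"           = "peridentate",
  "peridentate white matter" = "peridentate"
)

#' Resolve item labels to canonical identifiers
#'
#' Case-insensitive; dots, hyphens and repeated whitespace are collapsed, so
#' `"PLIC"`, `"c.semiovale"` and `"frontal (not central)"` all resolve.
#'
#' @param x character vector of item labels.
#' @return character vector of canonical snake_case identifiers; unknown
#'   labels yield `NA`.
#' @examples
#' resolve_items(c("PLIC", "frontal (not central)", "medial lemniscus"))
#' @export
resolve_items <- function(x) {
  key <- tolower(trimws(as.character(x)))
  key <- gsub("[._-]", " ", key)
  key <- gsub("[()]", "", key)
  key <- gsub("\\s+", " ", trimws(key))
  out <- unname(item_aliases[key])
  # canonical ids themselves are valid input
  canon <- gsub("_", " ", unique(item_registry$item))
  hit <- is.na(out) & key %in% canon
  out[hit] <- gsub(" ", "_", key[hit])
  out
}

#' Validate (and normalise) a ratings table
#'
#' Ratings are held in long form: one row per graded item per modality per
#' scan, with columns `patient_id`, `scan_id`, `age_years`, `modality`
#' (`"T2"` or `"T1"`), `item`, `grade`. Item labels may use common aliases.
#'
#' @param ratings a data frame of ratings in long form.
#' @param require which modalities must be completely graded per scan
#'   (default both). Completeness means all 8 T2 and/or all 6 T1 scoring
#'   items are present.
#' @param partial if `TRUE`, incomplete scans are tolerated (grades still
#'   validated); sums computed from such scans are flagged partial.
#' @return The validated tibble with canonical item names, ordered as input.
#' @export
validate_ratings <- function(ratings, require = c("T2", "T1"),
                             partial = FALSE) {
  stopifnot(is.data.frame(ratings))
  needed <- c("patient_id", "scan_id", "age_years", "modality", "item", "grade")
  missing_cols <- setdiff(needed, names(ratings))
  if (length(missing_cols) > 0) {
    stop("ratings table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  r <- tibble::as_tibble(ratings)
  r$modality <- toupper(trimws(as.character(r$modality)))
  bad_mod <- which(!r$modality %in% c("T2", "T1"))
  if (length(bad_mod) > 0) {
    stop("unknown modality in row(s) ", paste(utils::head(bad_mod, 5), collapse = ", "),
         " (must be T2 or T1)", call. = FALSE)
  }
  canon <- resolve_items(r$item)
  if (anyNA(canon)) {
    bad <- which(is.na(canon))
    stop("unknown item name in row(s) ", paste(utils::head(bad, 5), collapse = ", "),
         ": ", paste(unique(r$item[utils::head(bad, 5)]), collapse = ", "),
         call. = FALSE)
  }
  r$item <- canon

  if (!is.numeric(r$age_years) || anyNA(r$age_years) || any(r$age_years < 0)) {
    stop("age_years must be nonnegative and non-missing", call. = FALSE)
  }

  # item/modality combination must exist in the registry
  reg <- item_registry
  key <- paste(r$item, r$modality)
  reg_key <- paste(reg$item, reg$modality)
  bad <- which(!key %in% reg_key)
  if (length(bad) > 0) {
    stop("item not graded on this modality in row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), ": ",
         paste(unique(key[utils::head(bad, 5)]), collapse = "; "), call. = FALSE)
  }
  maxg <- reg$max_grade[match(key, reg_key)]
  g <- r$grade
  bad <- which(!is.finite(g) | g != floor(g) | g < 0 | g > maxg)
  if (length(bad) > 0) {
    stop("grade out of range for item '", r$item[bad[1]], "' (", r$modality[bad[1]],
         ", allowed 0-", maxg[bad[1]], ") in row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  r$grade <- as.integer(g)

  dup <- duplicated(r[, c("scan_id", "modality", "item")])
  if (any(dup)) {
    stop("duplicate (scan_id, modality, item) in row(s) ",
         paste(utils::head(which(dup), 5), collapse = ", "), call. = FALSE)
  }

  # one age per scan
  ages <- dplyr::distinct(r, .data$scan_id, .data$age_years)
  if (anyDuplicated(ages$scan_id) > 0) {
    stop("inconsistent age_years within a scan_id", call. = FALSE)
  }

  if (!partial) {
    sc <- reg[reg$scoring, ]
    for (mod in intersect(require, c("T2", "T1"))) {
      want <- sc$item[sc$modality == mod]
      got <- r[r$modality == mod & r$item %in% want, ]
      cnt <- table(factor(got$scan_id, levels = unique(r$scan_id)))
      incomplete <- names(cnt)[cnt < length(want)]
      if (length(incomplete) > 0) {
        miss <- setdiff(want, got$item[got$scan_id == incomplete[1]])
        stop("scan '", incomplete[1], "' is missing ", mod, " item(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
      }
    }
  }
  r
}
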