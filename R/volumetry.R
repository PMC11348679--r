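#' Bicaudate ratio
#'
#' Minimum intercaudate distance divided by the transverse width of the
#' inner table of the skull at the same level; a surrogate of supratentorial
#' volume loss (larger = more atrophy). Scale-invariant: both distances in
#' the same unit (mm).
#'
#' @param intercaudate_mm positive minimum intercaudate distance.
#' @param inner_table_mm positive inner-table width; must exceed
#'   `intercaudate_mm`.
#' @return numeric ratio in (0, 1); vectorised.
#' @examples
#' bcr(10, 100)
#' @export
bcr <- function(intercaudate_mm, inner_table_mm) {
  if (any(!is.finite(intercaudate_mm)) || any(!is.finite(inner_table_mm)) ||
      any(intercaudate_mm <= 0) || any(inner_table_mm <= 0)) {
    stop("distances must be positive", call. = FALSE)
  }
  if (any(intercaudate_mm >= inner_table_mm)) {
    stop("intercaudate distance must be smaller than inner-table width",
         call. = FALSE)
  }
  intercaudate_mm / inner_table_mm
}

#' Age-adapted z-score against a binned norms table
#'
#' Norms are supplied as contiguous age bins with mean and SD per
#' measurement type. Mean and SD are linearly interpolated between bin
#' midpoints (constant beyond the outer midpoints), which makes the z-score
#' exact at midpoints and continuous across bin boundaries.
#'
#' @param value measured value(s).
#' @param age_years age(s) in years; must lie inside the norms coverage.
#' @param norms data frame with columns `measurement`, `age_low_years`,
#'   `age_high_years`, `mean`, `sd` (see [synthetic_volumetry_norms()] for
#'   the schema).
#' @param measurement which measurement's norms to use (e.g. `"bcr"`,
#'   `"pons"`).
#' @return numeric vector of z-scores.
#' @examples
#' norms <- synthetic_volumetry_norms()
#' z_score(0.12, 2, norms, "bcr")
#' @export
z_score <- function(value, age_years, norms, measurement) {
  nm <- validate_norms(norms)
  nm <- nm[nm$measurement == measurement, ]
  if (nrow(nm) == 0) {
    stop("no norms for measurement '", measurement, "'", call. = FALSE)
  }
  lo <- min(nm$age_low_years); hi <- max(nm$age_high_years)
  if (any(age_years < lo | age_years > hi)) {
    stop("age outside norms coverage [", lo, ", ", hi, "] years", call. = FALSE)
  }
  mid <- (nm$age_low_years + nm$age_high_years) / 2
  mu <- stats::approx(mid, nm$mean, xout = age_years, rule = 2)$y
  sg <- stats::approx(mid, nm$sd, xout = age_years, rule = 2)$y
  (value - mu) / sg
}

validate_norms <- function(norms) {
  stopifnot(is.data.frame(norms))
  need <- c("measurement", "age_low_years", "age_high_years", "mean", "sd")
  if (!all(need %in% names(norms))) {
    stop("norms table needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(norms$sd <= 0)) stop("norms sd must be positive", call. = FALSE)
  for (mt in unique(norms$measurement)) {
    b <- norms[norms$measurement == mt, ]
    b <- b[order(b$age_low_years), ]
    if (any(b$age_high_years <= b$age_low_years)) {
      stop("degenerate age bin for ", mt, call. = FALSE)
    }
    if (nrow(b) > 1 &&
        any(abs(b$age_low_years[-1] - b$age_high_years[-nrow(b)]) > 1e-9)) {
      stop("norms age bins for ", mt, " must be contiguous", call. = FALSE)
    }
  }
  tibble::as_tibble(norms)
}

#' Synthetic volumetry norms table
#'
#' A smooth, plausibly shaped age-binned norms table for the bicaudate ratio
#' and the anterior-posterior pons diameter, provided so the volumetry
#' pipeline can run and be tested without access to clinical reference
#' norms. **Synthetic -- not for clinical use.**
#'
#' @return norms tibble with columns `measurement`, `age_low_years`,
#'   `age_high_years`, `mean`, `sd` covering ages 0--20 years.
#' @export
synthetic_volumetry_norms <- function() {
  lo <- c(0, 0.5, 1, 2, 4, 8, 14)
  hi <- c(0.5, 1, 2, 4, 8, 14, 20)
  tibble::tibble(
    measurement = rep(c("bcr", "pons"), each = 7),
    age_low_years = rep(lo, 2),
    age_high_years = rep(hi, 2),
    mean = c(0.080, 0.082, 0.084, 0.086, 0.088, 0.092, 0.096,
             14.0, 16.0, 18.0, 20.0, 21.5, 23.0, 24.0),
    sd = c(rep(0.015, 7),
           1.5, 1.5, 1.8, 2.0, 2.0, 2.2, 2.5)
  )
}

#' Compute volumetry surrogates with abnormality flags
#'
#' Adds bicaudate ratio, age-adapted z-scores and the abnormality flags to a
#' table of raw measurements. Flags use strict inequalities: `bcr_increased`
#' requires the z-score to exceed +2 (more than two SD above age norms),
#' `pons_small` requires it to fall below -2 SDS.
#'
#' @param data data frame with columns `age_years`, `intercaudate_mm`,
#'   `inner_table_mm`, and optionally `pons_ap_mm` and `cc_thin` (visual
#'   boolean, passed through).
#' @param norms norms table (see [z_score()]); defaults to the packaged
#'   synthetic norms.
#' @return input tibble with `bcr`, `bcr_z`, `bcr_increased`, and when pons
#'   measurements are present `pons_z`, `pons_small`, appended.
#' @export
flag_volumetry <- function(data, norms = synthetic_volumetry_norms()) {
  stopifnot(is.data.frame(data))
  need <- c("age_years", "intercaudate_mm", "inner_table_mm")
  if (!all(need %in% names(data))) {
    stop("data needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(data)
  out$bcr <- bcr(out$intercaudate_mm, out$inner_table_mm)
  out$bcr_z <- z_score(out$bcr, out$age_years, norms, "bcr")
  # strict boundary: a z-score within float tolerance of 2 is not flagged
  eps <- 1e-8
  out$bcr_increased <- out$bcr_z > 2 + eps
  if ("pons_ap_mm" %in% names(out)) {
    has <- !is.na(out$pons_ap_mm)
    out$pons_z <- NA_real_
    if (any(has)) {
      out$pons_z[has] <- z_score(out$pons_ap_mm[has], out$age_years[has],
                                 norms, "pons")
    }
    out$pons_small <- out$pons_z < -(2 + eps)
  }
  out
}

#' Correlation of BCR z-score with age
#'
#' Pearson correlation with a two-sided test, quantifying the age drift of
#' the supratentorial atrophy surrogate.
#'
#' @param data data frame containing the z-scores and ages.
#' @param z z-score column (tidy-eval; default `bcr_z`).
#' @param age age column (tidy-eval; default `age_years`).
#' @return one-row tibble: `r`, `p_value`, `n`.
#' @export
bcr_age_correlation <- function(data, z = bcr_z, age = age_years) {
  zv <- dplyr::pull(data, {{ z }})
  av <- dplyr::pull(data, {{ age }})
  ok <- stats::complete.cases(zv, av)
  zv <- zv[ok]; av <- av[ok]
  if (length(zv) < 3) stop("need at least 3 complete observations", call. = FALSE)
  if (stats::sd(zv) == 0 || stats::sd(av) == 0) {
    stop("constant input: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(zv, av, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(zv))
}
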