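#' Default myelination milestones for control subjects
#'
#' Each three-level item matures through two milestones: the age at which
#' its grade reaches 1 (isointense) and the age at which it reaches 2
#' (fully mature signal). Grade-2 milestone ages are spread across items
#' over 3.5--4.1 months for T1 items and 8.7--10.3 months for T2 items;
#' with the default bounded per-subject jitter of +/-0.5 months this places
#' full-score attainment of every simulated control inside 3.5--4.6 months
#' (T1) and 8.7--10.8 months (T2). The binary medial lemniscus is normal
#' (grade 1) in controls at every age.
#'
#' @return tibble: `item`, `modality`, `age_to_grade1`, `age_to_grade2`
#'   (years; `NA` for the binary lemniscus).
#' @export
default_milestones <- function() {
  t2_g2 <- c(plic = 8.7, mcp = 8.95, central_region = 9.2,
             optic_radiation = 9.5, primary_visual = 9.8,
             centrum_semiovale = 10.05, frontal = 10.3) / 12
  t1_g2 <- c(plic = 3.5, mcp = 3.6, central_region = 3.7,
             optic_radiation = 3.8, primary_visual = 3.95,
             centrum_semiovale = 4.1) / 12
  tibble::tibble(
    item = c(names(t2_g2), "medial_lemniscus", names(t1_g2)),
    modality = c(rep("T2", 8L), rep("T1", 6L)),
    age_to_grade1 = c(0.45 * unname(t2_g2), 0, 0.45 * unname(t1_g2)),
    age_to_grade2 = c(unname(t2_g2), NA_real_, unname(t1_g2))
  )
}

#' Simulate control-subject ratings
#'
#' Controls mature deterministically through the item milestones, shifted
#' by a bounded per-subject offset (uniform on +/-`subject_jitter` years);
#' grades are therefore non-decreasing in age within a subject. Scan ages
#' are drawn log-uniformly over `age_range` (infant-heavy, age-adapted
#' sampling), unless a fixed grid of `ages` is supplied, in which case every
#' subject is scored at every grid age.
#'
#' @param n number of control subjects (> 0).
#' @param seed integer seed; fully determines the output.
#' @param ages optional numeric vector of scan ages (years) applied to every
#'   subject (longitudinal grid); default one random age per subject.
#' @param age_range sampling range in years for random ages.
#' @param milestones milestone table, see [default_milestones()].
#' @param subject_jitter half-width (years) of the per-subject uniform
#'   maturation offset; default 0.5 months.
#' @return long-form ratings tibble with a `subtype = "control"` column.
#' @examples
#' head(gen_controls(2, seed = 1))
#' @export
gen_controls <- function(n, seed = 1, ages = NULL,
                         age_range = c(2 / 52, 20),
                         milestones = default_milestones(),
                         subject_jitter = 0.5 / 12) {
  if (!is.numeric(n) || n < 0 || n != floor(n)) stop("invalid n", call. = FALSE)
  if (n == 0) return(empty_ratings())
  withr::with_seed(as.integer(seed), {
    offsets <- stats::runif(n, -subject_jitter, subject_jitter)
    if (is.null(ages)) {
      n_per <- 1L
      scan_age <- exp(stats::runif(n, log(age_range[1]), log(age_range[2])))
      scan_subj <- seq_len(n)
      scan_j <- rep(1L, n)
    } else {
      if (any(ages < 0)) stop("ages must be nonnegative", call. = FALSE)
      ages <- sort(ages)
      n_per <- length(ages)
      scan_subj <- rep(seq_len(n), each = n_per)
      scan_j <- rep(seq_len(n_per), n)
      scan_age <- rep(ages, n)
    }
    m <- milestones
    k <- nrow(m)
    n_scan <- length(scan_age)
    i_scan <- rep(seq_len(n_scan), each = k)
    i_item <- rep(seq_len(k), n_scan)
    a <- scan_age[i_scan]
    o <- offsets[scan_subj[i_scan]]
    g1 <- m$age_to_grade1[i_item]
    g2 <- m$age_to_grade2[i_item]
    tri <- !is.na(g2)
    grade <- rep(1L, length(a))  # binary lemniscus: always normal in controls
    grade[tri] <- (a[tri] >= g1[tri] + o[tri]) + (a[tri] >= g2[tri] + o[tri])
    pid <- sprintf("control_%03d", scan_subj)
    tibble::tibble(
      patient_id = pid[i_scan],
      scan_id = sprintf("%s_s%d", pid, scan_j)[i_scan],
      age_years = a,
      modality = m$modality[i_item],
      item = m$item[i_item],
      grade = as.integer(grade),
      subtype = "control"
    )
  })
}

ratings_cols <- function() {
  c("patient_id", "scan_id", "age_years", "modality", "item", "grade", "subtype")
}

empty_ratings <- function() {
  tibble::tibble(patient_id = character(), scan_id = character(),
                 age_years = numeric(), modality = character(),
                 item = character(), grade = integer(), subtype = character())
}

#' Default PMD subtype profiles
#'
#' Per-subtype generative profiles for first-MRI item grades: a grade
#' probability distribution per item and modality, an admissible combined
#' first-MRI score range enforced by rejection sampling, an age-at-first-MRI
#' window, follow-up dynamics (`gain`, `early_loss`, `late_loss`, `stable`)
#' with onset, and volumetry drift parameters. The profiles encode the
#' qualitative subtype signatures: connatal/transitional scans have no
#' T2-isointense myelin (combined scores below 6.5, rare transient early
#' exceptions at PLIC/optic radiation), classic scans have at least
#' T2-isointense PLIC and T1-hyperintense PLIC with combined scores between
#' the two cut-offs, and the mild group (intermediate, PLP0, SPG2, female)
#' has a normal medial lemniscus and T1 sums of uniformly 11 or 12, with the
#' lowest and overlapping T2 scores in PLP0. All values are synthetic
#' calibrations, user-overridable, and carry no claim of clinical realism
#' beyond these constraints.
#'
#' @return named list of profile lists (one per subtype).
#' @export
default_subtype_profiles <- function() {
  # probability vectors are over grades 0,1,2 (three-level) or 0,1 (lemniscus)
  mild_t1 <- list(
    central_region = c(0, 0, 1), centrum_semiovale = c(0, 0, 1),
    plic = c(0, 0, 1), optic_radiation = c(0, 0, 1),
    primary_visual = c(0, .5, .5), mcp = c(0, 0, 1)
  )
  full2 <- function(items) stats::setNames(rep(2L, length(items)), items)
  list(
    connatal = list(
      age_range = c(0.15, 0.5), score_range = c(0, 6),
      t2 = list(central_region = c(1, 0, 0), centrum_semiovale = c(1, 0, 0),
                plic = c(1, 0, 0), optic_radiation = c(1, 0, 0),
                primary_visual = c(1, 0, 0), mcp = c(1, 0, 0),
                frontal = c(1, 0, 0), medial_lemniscus = c(1, 0)),
      t1 = list(central_region = c(1, 0, 0), centrum_semiovale = c(.6, .4, 0),
                plic = c(.4, .4, .2), optic_radiation = c(.6, .4, 0),
                primary_visual = c(1, 0, 0), mcp = c(.4, .6, 0)),
      transient = list(items = c("plic", "optic_radiation"), prob = 0.15,
                       max_age = 0.5),
      dynamics = "early_loss", onset = 0.6,
      bcr_slope = 0.35, pons_slope = -0.1, cc_par = c(-1.5, 1.2)
    ),
    transitional = list(
      age_range = c(0.3, 1.6), score_range = c(1, 5),
      t2 = list(central_region = c(1, 0, 0), centrum_semiovale = c(1, 0, 0),
                plic = c(1, 0, 0), optic_radiation = c(1, 0, 0),
                primary_visual = c(1, 0, 0), mcp = c(1, 0, 0),
                frontal = c(1, 0, 0), medial_lemniscus = c(1, 0)),
      t1 = list(central_region = c(1, 0, 0), centrum_semiovale = c(.5, .5, 0),
                plic = c(.3, .5, .2), optic_radiation = c(.5, .5, 0),
                primary_visual = c(1, 0, 0), mcp = c(0, 1, 0)),
      transient = list(items = "optic_radiation", prob = 0.15, max_age = 0.6),
      dynamics = "early_loss", onset = 0.8,
      bcr_slope = 0.3, pons_slope = -0.12, cc_par = c(-1.5, 1.2)
    ),
    classic = list(
      age_range = c(0.15, 2.0), score_range = c(7, 14),
      t2 = list(central_region = c(1, 0, 0), centrum_semiovale = c(.5, .5, 0),
                plic = c(0, .5, .5), optic_radiation = c(.7, .3, 0),
                primary_visual = c(1, 0, 0), mcp = c(.7, 0, .3),
                frontal = c(1, 0, 0), medial_lemniscus = c(1, 0)),
      t1 = list(central_region = c(.25, .6, .15), centrum_semiovale = c(0, .5, .5),
                plic = c(0, 0, 1), optic_radiation = c(0, .5, .5),
                primary_visual = c(.2, .7, .1), mcp = c(0, .1, .9)),
      dynamics = "gain", gain_rate = 0.4,
      gain_ceiling = list(
        t2 = c(central_region = 0L, centrum_semiovale = 1L, plic = 2L,
               optic_radiation = 2L, primary_visual = 0L, mcp = 2L,
               frontal = 0L, medial_lemniscus = 0L),
        t1 = full2(names(mild_t1))
      ),
      bcr_slope = 0.3, pons_slope = -0.15, cc_par = c(-1.2, 1.0)
    ),
    intermediate = list(
      age_range = c(0.5, 2.2), score_range = c(17, 22),
      t2 = list(central_region = c(.5, .5, 0), centrum_semiovale = c(0, .5, .5),
                plic = c(0, 0, 1), optic_radiation = c(0, .5, .5),
                primary_visual = c(1, 0, 0), mcp = c(0, .5, .5),
                frontal = c(0, .6, .4), medial_lemniscus = c(1 / 3, 2 / 3)),
      t1 = mild_t1,
      dynamics = "gain", gain_rate = 0.3,
      bcr_slope = 0.25, pons_slope = -0.08, cc_par = c(-1.8, 0.9)
    ),
    PLP0 = list(
      age_range = c(0.4, 1.5), score_range = c(14, 19),
      t2 = list(central_region = c(1, 0, 0), centrum_semiovale = c(.5, .5, 0),
                plic = c(0, .7, .3), optic_radiation = c(.4, .6, 0),
                primary_visual = c(1, 0, 0), mcp = c(.6, .4, 0),
                frontal = c(.4, .6, 0), medial_lemniscus = c(0, 1)),
      t1 = mild_t1,
      dynamics = "early_loss", onset = 0.9,
      bcr_slope = 0.2, pons_slope = -0.05, cc_par = c(-2.2, 0.8)
    ),
    SPG2 = list(
      age_range = c(1, 8), score_range = c(18, 24),
      t2 = list(central_region = c(.4, .6, 0), centrum_semiovale = c(0, .5, .5),
                plic = c(0, .3, .7), optic_radiation = c(0, .6, .4),
                primary_visual = c(1, 0, 0), mcp = c(0, .5, .5),
                frontal = c(0, .5, .5), medial_lemniscus = c(0, 1)),
      t1 = mild_t1,
      dynamics = "late_loss", onset = 5,
      bcr_slope = 0.15, pons_slope = -0.05, cc_par = c(-2.5, 0.6)
    ),
    female = list(
      age_range = c(0.5, 12), score_range = c(18, 24),
      t2 = list(central_region = c(.4, .6, 0), centrum_semiovale = c(0, .5, .5),
                plic = c(0, .3, .7), optic_radiation = c(0, .6, .4),
                primary_visual = c(1, 0, 0), mcp = c(0, .5, .5),
                frontal = c(0, .5, .5), medial_lemniscus = c(0, 1)),
      t1 = mild_t1,
      dynamics = "gain", gain_rate = 0.2,
      bcr_slope = 0.1, pons_slope = -0.03, cc_par = c(-3, 0.5)
    )
  )
}

#' Per-item grade ceilings implied by a subtype profile
#'
#' The ceiling of an item is the highest grade reachable either at first MRI
#' (support of the grade distribution) or through gain dynamics.
#'
#' @param profile a single profile from [default_subtype_profiles()].
#' @return tibble: `modality`, `item`, `ceiling`.
#' @export
profile_ceilings <- function(profile) {
  ceil_of <- function(dist) max(which(dist > 0)) - 1L
  res <- purrr::map_dfr(c("t2", "t1"), function(mod) {
    tibble::tibble(
      modality = toupper(gsub("t", "T", mod)),
      item = names(profile[[mod]]),
      ceiling = vapply(profile[[mod]], ceil_of, integer(1))
    )
  })
  if (!is.null(profile$gain_ceiling)) {
    for (mod in names(profile$gain_ceiling)) {
      gc <- profile$gain_ceiling[[mod]]
      sel <- res$modality == toupper(gsub("t", "T", mod))
      idx <- match(res$item[sel], names(gc))
      res$ceiling[sel] <- pmax(res$ceiling[sel], unname(gc[idx]))
    }
  }
  if (!is.null(profile$transient)) {
    sel <- res$modality == "T2" & res$item %in% profile$transient$items
    res$ceiling[sel] <- pmax(res$ceiling[sel], 1L)
  }
  res
}

sample_grade <- function(dist) sample.int(length(dist), 1, prob = dist) - 1L

sample_profile_scan <- function(profile, age, target = NULL,
                                max_tries = 10000) {
  for (try in seq_len(max_tries)) {
    t2 <- vapply(profile$t2, sample_grade, integer(1))
    t1 <- vapply(profile$t1, sample_grade, integer(1))
    tr <- profile$transient
    if (!is.null(tr) && age < tr$max_age) {
      for (it in tr$items) {
        if (stats::runif(1) < tr$prob) t2[it] <- max(t2[it], 1L)
      }
    }
    total <- sum(t2) + sum(t1)
    ok <- if (is.null(target)) {
      total >= profile$score_range[1] && total <= profile$score_range[2]
    } else {
      total == target
    }
    if (ok) return(list(t2 = t2, t1 = t1))
  }
  stop("could not sample a scan inside the profile score range", call. = FALSE)
}

#' Simulate first-MRI patient ratings by subtype
#'
#' Draws one first-MRI scan per patient from the subtype's grade
#' distributions, with rejection sampling enforcing the profile's admissible
#' combined score range (so, e.g., severe-subtype scores never cross the
#' 6.5 cut-off into the classic range).
#'
#' Cohorts with at least two patients of a subtype are *range-anchored*: the
#' first patient's combined score is conditioned to the lower end of the
#' subtype's documented first-MRI score span and the last patient's to the
#' upper end, with the remaining patients drawn freely inside the span. A
#' simulated cohort therefore covers its published score range by
#' construction, which in turn reproduces the published boundary structure:
#' severe scores reach 6 while classic scores start at 7 (half-integer ROC
#' cut-off 6.5), and classic and PLP0 scores meet at 14 (overlap that keeps
#' the classic-versus-mild discrimination imperfect).
#'
#' @param n_by_subtype named integer vector, e.g.
#'   `c(connatal = 5, classic = 10)`; names must match profile names.
#' @param seed integer seed; fully determines the output.
#' @param profiles profile list, see [default_subtype_profiles()].
#' @return long-form ratings tibble with a `subtype` column.
#' @examples
#' r <- gen_patients(c(connatal = 2, classic = 2), seed = 1)
#' score_scans(r)
#' @export
gen_patients <- function(n_by_subtype, seed = 1,
                         profiles = default_subtype_profiles()) {
  if (is.null(names(n_by_subtype)) || any(names(n_by_subtype) == "")) {
    stop("n_by_subtype must be a named vector", call. = FALSE)
  }
  missing_prof <- setdiff(names(n_by_subtype), names(profiles))
  if (length(missing_prof) > 0) {
    stop("no profile for subtype(s): ", paste(missing_prof, collapse = ", "),
         call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    purrr::map_dfr(names(n_by_subtype), function(st) {
      n <- n_by_subtype[[st]]
      if (n == 0) return(empty_ratings())
      prof <- profiles[[st]]
      targets <- rep(NA_real_, n)
      if (n >= 2) {  # range anchoring: cover the documented score span
        targets[1] <- prof$score_range[1]
        targets[n] <- prof$score_range[2]
      }
      purrr::map_dfr(seq_len(n), function(i) {
        age <- stats::runif(1, prof$age_range[1], prof$age_range[2])
        g <- sample_profile_scan(prof, age,
                                 target = if (is.na(targets[i])) NULL
                                          else targets[i])
        pid <- sprintf("%s_%02d", st, i)
        grades_to_ratings(g, pid, paste0(pid, "_s1"), age, st)
      })
    })
  })
}

grades_to_ratings <- function(g, patient_id, scan_id, age, subtype) {
  tibble::tibble(
    patient_id = patient_id, scan_id = scan_id, age_years = age,
    modality = c(rep("T2", length(g$t2)), rep("T1", length(g$t1))),
    item = c(names(g$t2), names(g$t1)),
    grade = as.integer(c(g$t2, g$t1)),
    subtype = subtype
  )
}

#' Simulate follow-up scans under a subtype's dynamics
#'
#' `gain` dynamics only ever raise grades (each immature item steps one
#' grade towards its gain ceiling with per-interval probability
#' `1 - exp(-gain_rate * dt)`); `early_loss`/`late_loss` lower every
#' positive three-level grade by one at the first scan after the onset age
#' (the binary lemniscus is left unchanged); `stable` copies the baseline.
#'
#' @param base ratings of a single complete scan (the first MRI).
#' @param profile the generating subtype profile.
#' @param ages strictly increasing scan ages, all above the baseline age.
#' @param seed integer seed.
#' @return long-form ratings tibble of the follow-up scans.
#' @export
gen_followup <- function(base, profile, ages, seed = 1) {
  b <- validate_ratings(base)
  if (length(unique(b$scan_id)) != 1) {
    stop("base must contain exactly one scan", call. = FALSE)
  }
  base_age <- b$age_years[1]
  if (any(diff(c(base_age, ages)) <= 0)) {
    stop("ages must be strictly increasing and above the baseline age",
         call. = FALSE)
  }
  dynamics <- profile$dynamics %||% "stable"
  pid <- unique(b$patient_id)
  subtype <- if ("subtype" %in% names(base)) base$subtype[1] else NA_character_
  withr::with_seed(as.integer(seed), {
    cur <- b
    lost <- FALSE
    purrr::map_dfr(seq_along(ages), function(j) {
      a <- ages[j]
      prev_age <- if (j == 1) base_age else ages[j - 1]
      if (dynamics == "gain") {
        dt <- a - prev_age
        for (mod in c("t2", "t1")) {
          gc <- profile$gain_ceiling[[mod]]
          if (is.null(gc)) {
            gc <- vapply(profile[[mod]], function(d) max(which(d > 0)) - 1L,
                         integer(1))
          }
          modn <- toupper(gsub("t", "T", mod))
          idx <- which(cur$modality == modn)
          for (i in idx) {
            ceil <- gc[[cur$item[i]]]
            if (!is.null(ceil) && cur$grade[i] < ceil &&
                stats::runif(1) < 1 - exp(-(profile$gain_rate %||% 0.4) * dt)) {
              cur$grade[i] <<- cur$grade[i] + 1L
            }
          }
        }
      } else if (dynamics %in% c("early_loss", "late_loss")) {
        if (!lost && a >= (profile$onset %||% 0.6)) {
          tri <- cur$item != "medial_lemniscus"
          cur$grade[tri] <<- pmax(cur$grade[tri] - 1L, 0L)
          lost <<- TRUE
        }
      } # stable: leave grades fixed
      out <- cur
      out$scan_id <- sprintf("%s_fu%d", unique(b$scan_id), j)
      out$age_years <- a
      if (!is.na(subtype)) out$subtype <- subtype
      out[, intersect(ratings_cols(), names(out))]
    })
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a multi-rater table from true grades
#'
#' Each of `m` raters reports the true grade with probability
#' `1 - epsilon` and an adjacent grade (clamped at the scale ends)
#' otherwise, independently across raters and subjects.
#'
#' @param truth integer vector of true grades, coded `0:(k-1)`.
#' @param m number of raters (>= 2).
#' @param epsilon adjacent-error probability in \[0, 0.5\].
#' @param k number of categories; default `3` (the three-level scale).
#' @param seed integer seed.
#' @return subjects-by-categories counts matrix (see [rater_counts()]),
#'   with the long-form assignments attached as attribute `"long"`.
#' @examples
#' gen_rater_data(c(0, 1, 2, 2), m = 3, epsilon = 0.1, seed = 1)
#' @export
gen_rater_data <- function(truth, m = 3, epsilon = 0.1, k = 3, seed = 1) {
  if (epsilon < 0 || epsilon > 0.5) {
    stop("epsilon must be in [0, 0.5]", call. = FALSE)
  }
  if (m < 2) stop("need at least 2 raters", call. = FALSE)
  if (any(truth < 0 | truth > k - 1)) stop("truth outside 0:(k-1)", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    long <- purrr::map_dfr(seq_along(truth), function(i) {
      g <- vapply(seq_len(m), function(r) {
        v <- truth[i]
        if (stats::runif(1) < epsilon) {
          v <- v + sample(c(-1L, 1L), 1)
          v <- min(max(v, 0L), k - 1L)
        }
        as.integer(v)
      }, integer(1))
      tibble::tibble(subject_id = sprintf("s%02d", i),
                     rater_id = sprintf("r%d", seq_len(m)),
                     grade = g)
    })
    counts <- rater_counts(long, levels = 0:(k - 1))
    attr(counts, "long") <- long
    counts
  })
}

#' Simulate volumetry records
#'
#' Control bicaudate-ratio z-scores are centred at zero at every age;
#' patient z-scores drift upward with age (atrophy surrogate), pons
#' z-scores drift slightly downward, and the probability of a visually thin
#' corpus callosum grows with age, with rates per subtype profile. Raw
#' measurements are reconstructed from the simulated z-scores via the norms
#' table, so [flag_volumetry()] recovers them.
#'
#' @param subtype `"control"` or a profile name.
#' @param ages scan ages in years (one record per age; independent
#'   subjects).
#' @param seed integer seed.
#' @param norms norms table used to map z-scores back to millimetres.
#' @param profiles profile list.
#' @return tibble: `patient_id`, `scan_id`, `subtype`, `age_years`,
#'   `intercaudate_mm`, `inner_table_mm`, `pons_ap_mm`, `cc_thin`.
#' @export
gen_volumetry <- function(subtype, ages, seed = 1,
                          norms = synthetic_volumetry_norms(),
                          profiles = default_subtype_profiles()) {
  if (length(ages) == 0) {
    return(tibble::tibble(patient_id = character(), scan_id = character(),
                          subtype = character(), age_years = numeric(),
                          intercaudate_mm = numeric(), inner_table_mm = numeric(),
                          pons_ap_mm = numeric(), cc_thin = logical()))
  }
  if (any(ages < 0)) stop("ages must be nonnegative", call. = FALSE)
  is_control <- identical(subtype, "control")
  if (!is_control && !subtype %in% names(profiles)) {
    stop("unknown subtype '", subtype, "'", call. = FALSE)
  }
  prof <- if (is_control) NULL else profiles[[subtype]]
  withr::with_seed(as.integer(seed), {
    n <- length(ages)
    bcr_z <- if (is_control) stats::rnorm(n) else {
      prof$bcr_slope * ages + stats::rnorm(n, sd = 0.8)
    }
    pons_z <- if (is_control) stats::rnorm(n) else {
      prof$pons_slope * ages + stats::rnorm(n, sd = 0.9)
    }
    bmu <- norm_interp(ages, norms, "bcr")
    pmu <- norm_interp(ages, norms, "pons")
    bcr_val <- pmin(pmax(bmu$mean + bcr_z * bmu$sd, 0.02), 0.5)
    inner <- 115 + 30 * ages / (ages + 1.5) + stats::rnorm(n, sd = 3)
    cc_p <- if (is_control) rep(0.02, n) else {
      stats::plogis(prof$cc_par[1] + prof$cc_par[2] * ages)
    }
    tibble::tibble(
      patient_id = sprintf("%s_v%03d", subtype, seq_len(n)),
      scan_id = sprintf("%s_v%03d_s1", subtype, seq_len(n)),
      subtype = subtype,
      age_years = ages,
      intercaudate_mm = bcr_val * inner,
      inner_table_mm = inner,
      pons_ap_mm = pmu$mean + pons_z * pmu$sd,
      cc_thin = stats::runif(n) < cc_p
    )
  })
}

norm_interp <- function(age, norms, measurement) {
  nm <- validate_norms(norms)
  nm <- nm[nm$measurement == measurement, ]
  mid <- (nm$age_low_years + nm$age_high_years) / 2
  list(mean = stats::approx(mid, nm$mean, xout = age, rule = 2)$y,
       sd = stats::approx(mid, nm$sd, xout = age, rule = 2)$y)
}
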