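#' Linear weight matrix for ordinal agreement
#'
#' `w[r, s] = 1 - |r - s| / (k - 1)`: full credit on the diagonal, zero for
#' the two extreme categories, linear in between.
#'
#' @param k number of ordinal categories (>= 2).
#' @return a symmetric `k x k` matrix with unit diagonal.
#' @examples
#' linear_weight_matrix(3)
#' @export
linear_weight_matrix <- function(k) {
  if (!is.numeric(k) || length(k) != 1 || k < 2 || k != floor(k)) {
    stop("k must be an integer >= 2", call. = FALSE)
  }
  k <- as.integer(k)
  idx <- seq_len(k)
  1 - abs(outer(idx, idx, "-")) / (k - 1)
}

#' Build a subjects-by-categories count table from long rater data
#'
#' @param data data frame with one row per (subject, rater) assignment,
#'   columns `subject_id`, `rater_id`, `grade` (integer codes; the lowest
#'   observed code maps to category 1 unless `levels` is given).
#' @param levels optional vector of all possible grade values, fixing `k`
#'   even when some categories are unused (important: the chance-agreement
#'   term depends on `k`).
#' @return integer matrix (subjects x categories) whose rows sum to the
#'   common number of raters per subject.
#' @export
rater_counts <- function(data, levels = NULL) {
  stopifnot(is.data.frame(data))
  need <- c("subject_id", "rater_id", "grade")
  if (!all(need %in% names(data))) {
    stop("data must have columns subject_id, rater_id, grade", call. = FALSE)
  }
  if (is.null(levels)) levels <- sort(unique(data$grade))
  if (any(!data$grade %in% levels)) stop("grade outside supplied levels", call. = FALSE)
  tab <- table(factor(data$subject_id, levels = unique(data$subject_id)),
               factor(data$grade, levels = levels))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(rownames(tab), colnames(tab)))
  m
}

#' Linearly weighted multi-rater concordance
#'
#' Chance-corrected agreement for ordinal ratings of `n` subjects by `m`
#' raters each, using linear weights. Observed agreement is the mean over
#' subjects of the weighted proportion of agreeing rater pairs,
#' \deqn{P_i = \sum_{r,s} n_{ir} (n_{is} - \delta_{rs}) w_{rs} / (m (m-1)),}
#' and the default chance term is uniform over the `k` categories,
#' \deqn{P_e = \sum_{r,s} w_{rs} / k^2,}
#' which makes the statistic `s = (P_o - P_e) / (1 - P_e)` robust to the
#' kappa paradoxes caused by skewed or range-restricted category prevalence.
#' A marginal-based (Fleiss-type) chance term is available for comparison
#' via `chance = "marginal"`; it is the paradox-prone classic estimator.
#'
#' @param x counts matrix from [rater_counts()] (subjects x categories, rows
#'   summing to a common `m >= 2`), or a long data frame accepted by
#'   [rater_counts()].
#' @param chance `"uniform"` (default, paradox-robust) or `"marginal"`.
#' @param levels passed to [rater_counts()] when `x` is a data frame.
#' @return one-row tibble: `p_obs`, `p_chance`, `statistic`, `category`
#'   (Cicchetti label), `n_subjects`, `m_raters`, `k_categories`, `chance`.
#' @examples
#' counts <- rbind(c(3, 0, 0), c(2, 0, 1))
#' weighted_concordance(counts)
#' @export
weighted_concordance <- function(x, chance = c("uniform", "marginal"),
                                 levels = NULL) {
  chance <- match.arg(chance)
  counts <- if (is.data.frame(x)) rater_counts(x, levels = levels) else as.matrix(x)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  k <- ncol(counts)
  n <- nrow(counts)
  if (k < 2) stop("need at least 2 categories", call. = FALSE)
  if (n < 1) stop("need at least 1 subject", call. = FALSE)
  m_row <- rowSums(counts)
  if (length(unique(m_row)) != 1) {
    stop("all subjects must be rated by the same number of raters", call. = FALSE)
  }
  m <- m_row[1]
  if (m < 2) stop("need at least 2 raters per subject", call. = FALSE)
  w <- linear_weight_matrix(k)
  p_i <- vapply(seq_len(n), function(i) {
    ni <- counts[i, ]
    pairs <- outer(ni, ni) - diag(ni)     # n_ir (n_is - delta_rs)
    sum(pairs * w) / (m * (m - 1))
  }, numeric(1))
  p_o <- mean(p_i)
  p_e <- if (chance == "uniform") {
    sum(w) / k^2
  } else {
    p <- colSums(counts) / (n * m)
    as.numeric(t(p) %*% w %*% p)
  }
  s <- (p_o - p_e) / (1 - p_e)
  tibble::tibble(
    p_obs = p_o, p_chance = p_e, statistic = s,
    category = as.character(cicchetti_category(s)),
    n_subjects = n, m_raters = as.integer(m), k_categories = as.integer(k),
    chance = chance
  )
}

#' Cicchetti interpretation of an agreement statistic
#'
#' poor (< 0.40), fair (0.40--0.59), good (0.60--0.74),
#' excellent (0.75--1.00). Values above 1 are invalid; negative values
#' (possible for chance-corrected statistics) are poor.
#'
#' @param value numeric vector of agreement statistics (each <= 1).
#' @return factor with levels poor < fair < good < excellent.
#' @examples
#' cicchetti_category(c(0.5, 0.62, 0.39, 0.75))
#' @export
cicchetti_category <- function(value) {
  if (any(value > 1, na.rm = TRUE)) {
    stop("agreement statistic cannot exceed 1", call. = FALSE)
  }
  cut(value, breaks = c(-Inf, 0.40, 0.60, 0.75, 1),
      labels = c("poor", "fair", "good", "excellent"),
      right = FALSE, include.lowest = TRUE, ordered_result = TRUE)
}

#' Retain or discard scoring items by inter-rater concordance
#'
#' Items whose concordance statistic falls below `retain_floor` are
#' discarded; the floor is inclusive (0.60, the lower edge of "good",
#' retains).
#'
#' @param concordance a data frame with columns `item` and `statistic`, or a
#'   named numeric vector.
#' @param retain_floor minimum statistic to retain (default 0.60).
#' @return tibble: `item`, `statistic`, `category`, `retained`.
#' @examples
#' select_items(c(alic = 0.5, genu_simplified = 0.56, peridentate = 0.62))
#' @export
select_items <- function(concordance, retain_floor = 0.60) {
  if (is.numeric(concordance)) {
    concordance <- tibble::tibble(item = names(concordance),
                                  statistic = unname(concordance))
  }
  stopifnot(all(c("item", "statistic") %in% names(concordance)))
  out <- tibble::as_tibble(concordance[, c("item", "statistic")])
  out$category <- as.character(cicchetti_category(out$statistic))
  out$retained <- out$statistic >= retain_floor
  out
}

#' Per-item concordance from a long rater table
#'
#' Applies [weighted_concordance()] within each item of a rater table in the
#' long format `item, subject_id, rater_id, grade` and appends the retention
#' decision of [select_items()].
#'
#' @param data long rater data frame with an `item` column.
#' @param retain_floor passed to [select_items()].
#' @param chance passed to [weighted_concordance()].
#' @param levels passed to [rater_counts()]; defaults per item to the item's
#'   full scale if the item is in the score registry (0--2 or 0--1), else to
#'   the observed grades.
#' @return tibble with one row per item: concordance fields plus `retained`.
#' @export
concordance_by_item <- function(data, retain_floor = 0.60,
                                chance = "uniform", levels = NULL) {
  stopifnot(is.data.frame(data), "item" %in% names(data))
  items <- unique(data$item)
  res <- purrr::map_dfr(items, function(it) {
    d <- data[data$item == it, ]
    lev <- levels
    if (is.null(lev)) {
      canon <- resolve_items(it)
      reg <- item_registry[item_registry$item == canon, ]
      lev <- if (nrow(reg) > 0) 0:max(reg$max_grade) else sort(unique(d$grade))
    }
    cbind(tibble::tibble(item = it),
          weighted_concordance(d, chance = chance, levels = lev))
  })
  sel <- select_items(res[, c("item", "statistic")], retain_floor = retain_floor)
  res$retained <- sel$retained
  tibble::as_tibble(res)
}
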