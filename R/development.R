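#' Wide item-grade matrix for one modality
#'
#' Reshapes a long ratings table into a scans-by-items matrix of ordinal
#' grades for PCA and related analytics.
#'
#' @param ratings long-form ratings table.
#' @param modality `"T2"` or `"T1"`.
#' @return numeric matrix with scan ids as row names and scoring items as
#'   columns.
#' @export
item_matrix <- function(ratings, modality = c("T2", "T1")) {
  modality <- match.arg(modality)
  r <- validate_ratings(ratings, require = modality)
  sc <- item_registry[item_registry$scoring & item_registry$modality == modality, ]
  r <- r[r$modality == modality & r$item %in% sc$item, ]
  wide <- tidyr::pivot_wider(r[, c("scan_id", "item", "grade")],
                             names_from = "item", values_from = "grade")
  m <- as.matrix(wide[, sc$item])
  rownames(m) <- wide$scan_id
  storage.mode(m) <- "double"
  m
}

#' Unifactoriality check by principal component analysis
#'
#' Eigen-decomposes the inter-item correlation matrix (PCA on standardised
#' items) and applies the Kaiser criterion: the item set is unifactorial iff
#' exactly the first eigenvalue exceeds 1. For a valid myelination score all
#' items should load on a single age-driven factor.
#'
#' @param x numeric matrix or data frame, scans in rows, items in columns
#'   (e.g. from [item_matrix()]); at least 3 rows and 2 columns, no constant
#'   column.
#' @return object of class `pmd_pca` with elements `eigenvalues`,
#'   `variance_fraction`, `unifactorial`, `n`, `k`. Use [tidy()] for a
#'   per-component tibble and [glance()] for a one-row summary.
#' @examples
#' set.seed(1)
#' a <- rnorm(50)
#' m <- cbind(a, a + rnorm(50, sd = 0.1), a + rnorm(50, sd = 0.1))
#' glance(pca_unifactorial(m))
#' @export
pca_unifactorial <- function(x) {
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  if (ncol(m) < 2) stop("need at least 2 items", call. = FALSE)
  if (nrow(m) < 3) stop("need at least 3 scans", call. = FALSE)
  if (anyNA(m)) stop("item matrix contains missing values", call. = FALSE)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    nm <- colnames(m)[sds == 0]
    if (is.null(nm)) nm <- which(sds == 0)
    stop("constant item column(s): ", paste(nm, collapse = ", "), call. = FALSE)
  }
  pr <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  ev <- pr$sdev^2
  structure(
    list(
      eigenvalues = ev,
      variance_fraction = ev / sum(ev),
      unifactorial = ev[1] > 1 && all(ev[-1] <= 1),
      n = nrow(m), k = ncol(m)
    ),
    class = "pmd_pca"
  )
}

#' @export
print.pmd_pca <- function(x, ...) {
  cat("PCA unifactoriality check:", x$k, "items,", x$n, "scans\n")
  cat(sprintf("  first component: %.1f%% of variance (eigenvalue %.2f)\n",
              100 * x$variance_fraction[1], x$eigenvalues[1]))
  cat("  unifactorial (Kaiser):", x$unifactorial, "\n")
  invisible(x)
}

#' @rdname pca_unifactorial
#' @param x a `pmd_pca` object.
#' @param ... unused.
#' @method tidy pmd_pca
#' @export
tidy.pmd_pca <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$eigenvalues),
    eigenvalue = x$eigenvalues,
    variance_fraction = x$variance_fraction
  )
}

#' @rdname pca_unifactorial
#' @method glance pmd_pca
#' @export
glance.pmd_pca <- function(x, ...) {
  tibble::tibble(
    n = x$n, k = x$k,
    first_eigenvalue = x$eigenvalues[1],
    first_variance_fraction = x$variance_fraction[1],
    unifactorial = x$unifactorial
  )
}

#' ROC analysis with Youden cut-off
#'
#' AUC by pair counting (ties worth 1/2) and the cut-off maximising Youden's
#' J = sensitivity + specificity - 1, taken as the midpoint between adjacent
#' observed score values -- which yields half-integer cut-offs naturally for
#' integer scores. Because hypomyelination lowers the score, the default
#' direction treats the positive (more affected) class as scoring *lower*.
#'
#' @param data data frame of per-scan scores and class labels.
#' @param score column holding the numeric score (tidy-eval).
#' @param label column holding the class label (tidy-eval).
#' @param positive value of `label` defining the positive class.
#' @param direction `"low"` (default: positives score lower) or `"high"`.
#' @return object of class `pmd_roc`: a one-row tibble with `auc`, `cutoff`,
#'   `sensitivity`, `specificity`, `n_pos`, `n_neg`, `direction`, carrying
#'   the full sensitivity/specificity curve as attribute `"curve"` (used by
#'   [autoplot.pmd_roc()]).
#' @examples
#' d <- tibble::tibble(score = c(1, 2, 3, 7, 8, 9),
#'                     group = rep(c("severe", "classic"), each = 3))
#' roc_analysis(d, score, group, positive = "severe")
#' @export
roc_analysis <- function(data, score, label, positive,
                         direction = c("low", "high")) {
  direction <- match.arg(direction)
  s <- dplyr::pull(data, {{ score }})
  l <- dplyr::pull(data, {{ label }})
  if (!positive %in% l) stop("positive class not present in labels", call. = FALSE)
  pos <- s[l == positive]
  neg <- s[l != positive]
  if (length(pos) == 0 || length(neg) == 0) {
    stop("both classes must be non-empty", call. = FALSE)
  }
  # Mann-Whitney AUC for "positives score high"; ties get 1/2 via mid-ranks
  rk <- rank(c(pos, neg))
  auc_high <- (sum(rk[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
  auc <- if (direction == "high") auc_high else 1 - auc_high
  u <- sort(unique(s))
  cand <- if (length(u) > 1) (u[-length(u)] + u[-1]) / 2 else u
  curve <- purrr::map_dfr(cand, function(cc) {
    if (direction == "low") {
      tibble::tibble(threshold = cc,
                     sensitivity = mean(pos < cc),
                     specificity = mean(neg >= cc))
    } else {
      tibble::tibble(threshold = cc,
                     sensitivity = mean(pos > cc),
                     specificity = mean(neg <= cc))
    }
  })
  curve$youden_j <- curve$sensitivity + curve$specificity - 1
  best <- which.max(curve$youden_j)
  out <- tibble::tibble(
    auc = auc, cutoff = curve$threshold[best],
    sensitivity = curve$sensitivity[best],
    specificity = curve$specificity[best],
    n_pos = length(pos), n_neg = length(neg),
    direction = direction
  )
  attr(out, "curve") <- curve
  class(out) <- c("pmd_roc", class(out))
  out
}

#' @method tidy pmd_roc
#' @export
tidy.pmd_roc <- function(x, ...) attr(x, "curve")

#' @method glance pmd_roc
#' @export
glance.pmd_roc <- function(x, ...) tibble::as_tibble(unclass(x))

#' Pairwise Wilcoxon rank-sum comparisons with Holm adjustment
#'
#' Two-sided Wilcoxon rank-sum tests for every pair of groups, using the
#' exact null distribution when the combined sample size is at most 20 and
#' no ties are present, otherwise the normal approximation with continuity
#' correction; p-values are Holm-adjusted across the pairs.
#'
#' @param data data frame of scores and group labels.
#' @param score numeric score column (tidy-eval).
#' @param group grouping column (tidy-eval); at least two non-empty groups.
#' @return tibble: `group1`, `group2`, `n1`, `n2`, `statistic` (rank-sum W),
#'   `p_value`, `p_adj`.
#' @examples
#' d <- tibble::tibble(s = c(1, 2, 3, 10, 11, 12),
#'                     g = rep(c("a", "b"), each = 3))
#' compare_groups(d, s, g)
#' @export
compare_groups <- function(data, score, group) {
  s <- dplyr::pull(data, {{ score }})
  g <- as.character(dplyr::pull(data, {{ group }}))
  if (anyNA(s) || anyNA(g)) stop("missing values in score or group", call. = FALSE)
  lev <- unique(g)
  if (length(lev) < 2) stop("need at least two groups", call. = FALSE)
  if (any(table(g) < 1)) stop("empty group", call. = FALSE)
  pairs <- utils::combn(lev, 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- s[g == pairs[1, j]]
    b <- s[g == pairs[2, j]]
    use_exact <- (length(a) + length(b) <= 20) &&
      !any(duplicated(c(a, b)))
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, exact = use_exact, correct = TRUE,
                         alternative = "two.sided")
    )
    tibble::tibble(
      group1 = pairs[1, j], group2 = pairs[2, j],
      n1 = length(a), n2 = length(b),
      statistic = unname(wt$statistic), p_value = wt$p.value
    )
  })
  res$p_adj <- stats::p.adjust(res$p_value, method = "holm")
  res
}
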