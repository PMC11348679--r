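# Independent brute-force oracles used to validate the analytic
# implementations on small instances.

# Weighted multi-rater concordance by explicit enumeration of all rater
# pairs per subject (uniform chance term).
oracle_concordance <- function(counts) {
  k <- ncol(counts)
  w <- 1 - abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
  p_i <- apply(counts, 1, function(row) {
    cats <- rep(seq_len(k), row)       # the m category assignments
    pairs <- utils::combn(seq_along(cats), 2)
    mean(w[cbind(cats[pairs[1, ]], cats[pairs[2, ]])])
  })
  p_o <- mean(p_i)
  p_e <- sum(w) / k^2
  list(p_obs = p_o, p_chance = p_e, statistic = (p_o - p_e) / (1 - p_e))
}

# AUC by explicit pair counting, ties worth 1/2.
oracle_auc <- function(pos, neg, direction = "low") {
  tot <- 0
  for (p in pos) {
    for (n in neg) {
      tot <- tot + if (direction == "low") {
        (p < n) + 0.5 * (p == n)
      } else {
        (p > n) + 0.5 * (p == n)
      }
    }
  }
  tot / (length(pos) * length(neg))
}

# A random complete, valid ratings table for one scan.
random_scan_ratings <- function(scan_id = "s1", patient_id = "p1",
                                age = 1) {
  reg <- pmd_items()
  tibble::tibble(
    patient_id = patient_id, scan_id = scan_id, age_years = age,
    modality = reg$modality, item = reg$item,
    grade = vapply(reg$max_grade,
                   function(m) sample(0:m, 1), integer(1))
  )
}

# A random balanced rater counts table.
random_counts <- function(n, m, k) {
  t(vapply(seq_len(n), function(i) {
    tabulate(sample.int(k, m, replace = TRUE), nbins = k)
  }, integer(k)))
}
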