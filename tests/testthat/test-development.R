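test_that("PCA flags rank-1 item sets as unifactorial", {
  set.seed(2)
  a <- rnorm(40)
  m <- cbind(i1 = a, i2 = 2 * a, i3 = -0.5 * a + 3)
  rep_ <- pca_unifactorial(m)
  expect_true(rep_$unifactorial)
  expect_equal(rep_$variance_fraction[1], 1)
  expect_equal(sum(rep_$variance_fraction), 1)
  expect_true(all(rep_$eigenvalues >= -1e-12))
})

test_that("PCA rejects independence as unifactorial", {
  set.seed(3)
  m <- matrix(rnorm(2000 * 5), ncol = 5,
              dimnames = list(NULL, paste0("i", 1:5)))
  rep_ <- pca_unifactorial(m)
  expect_false(rep_$unifactorial)
  expect_true(all(abs(rep_$variance_fraction - 0.2) < 0.05))
  td <- tidy(rep_)
  expect_identical(nrow(td), 5L)
  expect_equal(td$eigenvalue / sum(td$eigenvalue), td$variance_fraction)
})

test_that("PCA errors name constant item columns", {
  m <- cbind(plic = c(1, 1, 1, 1), mcp = c(0, 1, 2, 1))
  expect_error(pca_unifactorial(m), "constant item column.*plic")
  expect_error(pca_unifactorial(m[1:2, ]), "at least 3")
  expect_error(pca_unifactorial(m[, 1, drop = FALSE]), "at least 2")
})

test_that("synthetic control item grades are essentially unifactorial", {
  ctl <- gen_controls(150, seed = 4)
  for (mod in c("T2", "T1")) {
    m <- item_matrix(ctl, mod)
    m <- m[, apply(m, 2, sd) > 0, drop = FALSE]  # lemniscus is constant 1
    rep_ <- pca_unifactorial(m)
    expect_gt(rep_$variance_fraction[1], 0.8)
    expect_true(rep_$unifactorial)
  }
})

test_that("AUC equals brute-force pair counting", {
  set.seed(31)
  for (rep in 1:25) {
    n1 <- sample(2:25, 1); n2 <- sample(2:25, 1)
    d <- tibble::tibble(
      score = c(sample(0:27, n1, TRUE), sample(0:27, n2, TRUE)),
      group = rep(c("pos", "neg"), c(n1, n2))
    )
    dirn <- sample(c("low", "high"), 1)
    got <- roc_analysis(d, score, group, positive = "pos", direction = dirn)
    expect_equal(got$auc, oracle_auc(d$score[d$group == "pos"],
                                     d$score[d$group == "neg"], dirn))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  d <- tibble::tibble(score = sample(0:27, 40, TRUE),
                      group = sample(c("pat", "ctl"), 40, TRUE, c(.4, .6)))
  got <- roc_analysis(d, score, group, positive = "pat", direction = "low")
  ref <- pROC::roc(response = d$group, predictor = d$score,
                   levels = c("pat", "ctl"), direction = "<", quiet = TRUE)
  expect_equal(got$auc, as.numeric(pROC::auc(ref)))
})

test_that("non-overlapping integer classes give midpoint cut-offs", {
  d <- tibble::tibble(score = c(7, 8, 9, 1, 2, 3),
                      group = rep(c("pos", "neg"), each = 3))
  r <- roc_analysis(d, score, group, positive = "pos", direction = "high")
  expect_equal(r$auc, 1)
  expect_equal(r$cutoff, 5)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)

  # severity scores: positives low, boundary values 6 and 7 -> cut-off 6.5
  d2 <- tibble::tibble(score = c(2, 4, 6, 7, 9, 14),
                       group = rep(c("severe", "classic"), each = 3))
  r2 <- roc_analysis(d2, score, group, positive = "severe")
  expect_equal(r2$auc, 1)
  expect_equal(r2$cutoff, 6.5)

  d3 <- tibble::tibble(score = c(2, 4, 1, 3), group = rep(c("p", "n"), each = 2))
  expect_equal(roc_analysis(d3, score, group, positive = "p",
                            direction = "high")$auc, 0.75)

  d4 <- tibble::tibble(score = rep(c(1, 2, 3), 2),
                       group = rep(c("p", "n"), each = 3))
  expect_equal(roc_analysis(d4, score, group, positive = "p")$auc, 0.5)

  d5 <- tibble::tibble(score = 1:3, group = rep("p", 3))
  expect_error(roc_analysis(d5, score, group, positive = "p"), "non-empty")
})

test_that("pairwise Wilcoxon comparisons use exact small-sample p-values", {
  # two identical groups: no evidence at all
  d0 <- tibble::tibble(s = rep(c(1, 2, 3), 2), g = rep(c("a", "b"), each = 3))
  expect_equal(compare_groups(d0, s, g)$p_value, 1)

  # fully separated 3-vs-3: the most extreme of the 20 rank assignments,
  # two-sided exact p = 2/20
  d1 <- tibble::tibble(s = c(1, 2, 3, 10, 11, 12),
                       g = rep(c("a", "b"), each = 3))
  r1 <- compare_groups(d1, s, g)
  expect_equal(r1$p_value, 0.1)
  expect_true(r1$statistic %in% c(0, 9))

  # three groups: three pairs, Holm-adjusted p monotone in raw p
  d2 <- tibble::tibble(
    s = c(1, 2, 3, 4, 10, 11, 12, 13, 30, 31, 32, 33),
    g = rep(c("a", "b", "c"), each = 4)
  )
  r2 <- compare_groups(d2, s, g)
  expect_identical(nrow(r2), 3L)
  expect_equal(r2$p_adj, stats::p.adjust(r2$p_value, "holm"))
  o <- order(r2$p_value)
  expect_true(all(diff(r2$p_adj[o]) >= -1e-12))

  d3 <- tibble::tibble(s = 1:3, g = rep("a", 3))
  expect_error(compare_groups(d3, s, g), "two groups")
})
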