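test_that("worked-example scans reproduce the published sub-scores", {
  r <- pmd_example_ratings()
  a <- dplyr::filter(r, scan_id == "A")
  c_ <- dplyr::filter(r, scan_id == "C")
  d <- dplyr::filter(r, scan_id == "D")

  expect_identical(unname(score_t2(a)), 1L)
  expect_identical(unname(score_t1(a)), 5L)
  expect_identical(unname(score_t2(c_)), 1L)
  expect_identical(unname(score_t1(c_)), 9L)
  expect_identical(unname(score_t2(d)), 7L)
  expect_identical(unname(score_t1(d)), 12L)
  expect_identical(score_combined(d)$combined, 19L)
})

test_that("score extremes hit the scale bounds", {
  reg <- pmd_items()
  mk <- function(g) tibble::tibble(
    patient_id = "p", scan_id = "s", age_years = 1,
    modality = reg$modality, item = reg$item,
    grade = if (g == "max") reg$max_grade else 0L
  )
  s_max <- score_scans(mk("max"))
  expect_identical(c(s_max$t2_sum, s_max$t1_sum, s_max$combined),
                   c(15L, 12L, 27L))
  s_min <- score_scans(mk("min"))
  expect_identical(c(s_min$t2_sum, s_min$t1_sum, s_min$combined),
                   c(0L, 0L, 0L))
})

test_that("sums are bounded, additive, and monotone in single grades", {
  set.seed(42)
  reg <- pmd_items()
  for (rep in 1:25) {
    r <- random_scan_ratings()
    s <- score_scans(r)
    expect_gte(s$t2_sum, 0L); expect_lte(s$t2_sum, 15L)
    expect_gte(s$t1_sum, 0L); expect_lte(s$t1_sum, 12L)
    expect_identical(s$combined, s$t2_sum + s$t1_sum)

    # raising one non-maximal grade by 1 raises its sub-score by exactly 1
    i <- sample(which(r$grade < reg$max_grade[match(
      paste(r$item, r$modality), paste(reg$item, reg$modality))]), 1)
    r2 <- r
    r2$grade[i] <- r2$grade[i] + 1L
    s2 <- score_scans(r2)
    if (r$modality[i] == "T2") {
      expect_identical(s2$t2_sum, s$t2_sum + 1L)
      expect_identical(s2$t1_sum, s$t1_sum)
    } else {
      expect_identical(s2$t1_sum, s$t1_sum + 1L)
      expect_identical(s2$t2_sum, s$t2_sum)
    }
  }
})

test_that("score_delta matches score differences and classifies direction", {
  r <- pmd_example_ratings()
  a <- dplyr::filter(r, scan_id == "A")
  b <- dplyr::filter(r, scan_id == "B")
  c_ <- dplyr::filter(r, scan_id == "C")
  d <- dplyr::filter(r, scan_id == "D")

  ab <- score_delta(a, b)
  expect_identical(ab$t1_delta, -4L)
  expect_identical(ab$direction, "decrease")

  cd <- score_delta(c_, d)
  expect_identical(cd$combined_delta, 9L)
  expect_identical(cd$direction, "increase")

  # delta totals always equal the difference of the two scans' scores
  set.seed(7)
  for (rep in 1:10) {
    e <- random_scan_ratings("e", "px", age = 0.5)
    l <- random_scan_ratings("l", "px", age = 2)
    dl <- score_delta(e, l)
    se <- score_scans(e); sl <- score_scans(l)
    expect_identical(dl$t2_delta, sl$t2_sum - se$t2_sum)
    expect_identical(dl$t1_delta, sl$t1_sum - se$t1_sum)
    expect_identical(dl$combined_delta, sl$combined - se$combined)
    expect_identical(sum(dl$item_deltas[[1]]$delta), dl$combined_delta)
  }

  same <- a
  same$scan_id <- "A2"; same$age_years <- 0.5
  expect_identical(score_delta(a, same)$direction, "stable")

  # one sub-score up, the other down -> mixed
  mx <- a
  mx$scan_id <- "A3"; mx$age_years <- 0.5
  mx$grade[mx$modality == "T2" & mx$item == "plic"] <- 2L        # T2 +2
  mx$grade[mx$modality == "T1" & mx$item == "plic"] <- 0L        # T1 -2
  mx$grade[mx$modality == "T1" & mx$item == "centrum_semiovale"] <- 0L
  expect_identical(score_delta(a, mx)$direction, "mixed")

  other <- a; other$patient_id <- "P9"; other$age_years <- 2
  expect_error(score_delta(a, other), "different patients")
  expect_error(score_delta(b, a), "strictly greater age")
})

test_that("validation refuses malformed ratings and names the problem", {
  r <- pmd_example_ratings()
  a <- dplyr::filter(r, scan_id == "A")

  expect_error(score_t2(dplyr::filter(a, item != "mcp")),
               "missing T2 item.*mcp")
  bad <- a
  bad$grade[bad$item == "plic" & bad$modality == "T2"] <- 3L
  expect_error(score_t2(bad), "out of range.*plic")
  expect_error(validate_ratings(rbind(a, a[1, ])), "duplicate")
  lem_t1 <- a
  lem_t1$modality[lem_t1$item == "medial_lemniscus"] <- "T1"
  expect_error(validate_ratings(lem_t1), "not graded on this modality")
  unk <- a; unk$item[3] <- "cerebellum"
  expect_error(validate_ratings(unk), "unknown item")
  neg <- a; neg$age_years <- -1
  expect_error(validate_ratings(neg), "age_years")

  # partial scoring is opt-in and flagged
  part <- dplyr::filter(a, !(item == "mcp" & modality == "T2"))
  s <- score_t2(part, partial = TRUE)
  expect_identical(as.integer(s), 1L)
  expect_true(attr(s, "partial")[["A"]])
})

test_that("item aliases resolve to canonical identifiers", {
  expect_identical(
    resolve_items(c("PLIC", "MCP", "frontal (not central)",
                    "c.semiovale", "medial lemniscus")),
    c("plic", "mcp", "frontal", "centrum_semiovale", "medial_lemniscus")
  )
  expect_true(is.na(resolve_items("hippocampus")))

  a <- dplyr::filter(pmd_example_ratings(), scan_id == "A")
  a$item[a$item == "plic"] <- "PLIC"
  expect_identical(unname(score_t1(a)), 5L)
})

test_that("the item registry has the published structure", {
  reg <- pmd_items()
  expect_identical(sum(reg$modality == "T2"), 8L)
  expect_identical(sum(reg$modality == "T1"), 6L)
  expect_identical(reg$scale[reg$item == "medial_lemniscus"], "binary")
  expect_identical(sum(reg$max_grade), 27L)
  cand <- pmd_items(scoring_only = FALSE)
  expect_setequal(cand$item[!cand$scoring],
                  c("alic", "pons_pyramidal_tract", "genu_simplified",
                    "peridentate"))
})
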