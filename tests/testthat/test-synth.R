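test_that("generators are fully determined by their seed", {
  expect_identical(gen_controls(5, seed = 9), gen_controls(5, seed = 9))
  expect_false(identical(gen_controls(5, seed = 9), gen_controls(5, seed = 10)))
  nb <- c(connatal = 2, classic = 3)
  expect_identical(gen_patients(nb, seed = 9), gen_patients(nb, seed = 9))
  expect_identical(gen_rater_data(c(0, 1, 2), seed = 9),
                   gen_rater_data(c(0, 1, 2), seed = 9))
  expect_identical(gen_volumetry("classic", c(1, 2), seed = 9),
                   gen_volumetry("classic", c(1, 2), seed = 9))
})

test_that("default milestones sit inside the control maturation windows", {
  m <- default_milestones()
  t2 <- m$age_to_grade2[m$modality == "T2" & !is.na(m$age_to_grade2)] * 12
  t1 <- m$age_to_grade2[m$modality == "T1"] * 12
  expect_true(all(t2 >= 8.7 & t2 <= 10.8))
  expect_true(all(t1 >= 3.5 & t1 <= 4.6))
  expect_true(all(m$age_to_grade1 <= m$age_to_grade2, na.rm = TRUE))
})

test_that("control grades rise monotonically with age to the full score", {
  grid <- seq(0, 1.5, by = 0.05)
  ctl <- gen_controls(8, seed = 21, ages = grid)
  s <- score_scans(ctl)
  for (pid in unique(s$patient_id)) {
    sub <- s[s$patient_id == pid, ]
    sub <- sub[order(sub$age_years), ]
    expect_true(all(diff(sub$t2_sum) >= 0))
    expect_true(all(diff(sub$t1_sum) >= 0))
  }
  # anyone at or beyond one year carries the full combined score
  expect_true(all(s$combined[s$age_years >= 1] == 27L))
  # a newborn is immature on every three-level T2 item
  newborn <- s[s$age_years == 0, ]
  expect_true(all(newborn$t2_sum <= 1L))  # only the lemniscus contributes
})

test_that("patient scans respect profile ceilings and score ranges", {
  profs <- default_subtype_profiles()
  r <- gen_patients(c(connatal = 6, transitional = 4, classic = 8,
                      intermediate = 4, PLP0 = 3, SPG2 = 4, female = 3),
                    seed = 31)
  s <- score_scans(r)
  for (st in unique(s$subtype)) {
    rng <- profs[[st]]$score_range
    sc <- s$combined[s$subtype == st]
    expect_true(all(sc >= rng[1] & sc <= rng[2]), label = st)
    ceil <- profile_ceilings(profs[[st]])
    sub <- dplyr::left_join(r[r$subtype == st, ], ceil,
                            by = c("modality", "item"))
    expect_true(all(sub$grade <= sub$ceiling), label = st)
  }
  # the mild group carries T1 sums of uniformly 11 or 12
  mild <- s$t1_sum[s$subtype %in% c("intermediate", "PLP0", "SPG2", "female")]
  expect_true(all(mild %in% c(11L, 12L)))

  expect_identical(nrow(gen_patients(c(classic = 0), seed = 1)), 0L)
  expect_error(gen_patients(c(unknown = 2), seed = 1), "no profile")
  expect_error(gen_patients(c(2, 3), seed = 1), "named")
})

test_that("follow-up dynamics move scores in the profile's direction", {
  profs <- default_subtype_profiles()

  base_cl <- gen_patients(c(classic = 1), seed = 7)
  fu <- gen_followup(base_cl, profs$classic, ages = c(2, 4, 6, 9), seed = 7)
  traj <- score_scans(dplyr::bind_rows(base_cl, fu))
  traj <- traj[order(traj$age_years), ]
  expect_true(all(diff(traj$combined) >= 0))

  base_cn <- gen_patients(c(connatal = 1), seed = 8)
  s0 <- score_scans(base_cn)$combined
  fu_cn <- gen_followup(base_cn, profs$connatal, ages = c(1, 2), seed = 8)
  s1 <- score_scans(fu_cn)
  if (s0 > 0) expect_true(all(s1$combined < s0))

  stable_prof <- profs$connatal
  stable_prof$dynamics <- "stable"
  fu_st <- gen_followup(base_cn, stable_prof, ages = c(1, 2), seed = 8)
  expect_identical(sort(unique(score_scans(fu_st)$combined)), s0)

  expect_error(gen_followup(base_cn, profs$connatal, ages = c(2, 1)),
               "strictly increasing")
  expect_error(gen_followup(base_cn, profs$connatal, ages = 0.1),
               "strictly increasing")
})

test_that("simulated raters degrade concordance with the error rate", {
  perfect <- gen_rater_data(c(0, 1, 2, 2, 1, 0), m = 3, epsilon = 0, seed = 1)
  expect_equal(weighted_concordance(perfect)$statistic, 1)

  mean_s <- function(eps) {
    mean(vapply(1:30, function(i) {
      counts <- gen_rater_data(c(0, 1, 2, 2, 1, 0), m = 3, epsilon = eps,
                               seed = 1000 + i)
      weighted_concordance(counts)$statistic
    }, numeric(1)))
  }
  expect_lt(mean_s(0.4), mean_s(0.1))

  expect_error(gen_rater_data(c(0, 1), epsilon = 0.7), "epsilon")
  expect_error(gen_rater_data(c(0, 5), k = 3), "truth")
})

test_that("simulated volumetry has null controls and age-drifting patients", {
  ctl <- gen_volumetry("control", runif(300, 0.1, 15), seed = 41)
  expect_true(all(ctl$intercaudate_mm < ctl$inner_table_mm))
  flagged <- flag_volumetry(ctl)
  expect_lt(abs(mean(flagged$bcr_z)), 0.2)

  pat <- gen_volumetry("classic", runif(120, 0, 12), seed = 42)
  res <- bcr_age_correlation(flag_volumetry(pat))
  expect_gt(res$r, 0)
  expect_lt(res$p_value, 0.05)

  empty <- gen_volumetry("classic", numeric(0), seed = 1)
  expect_identical(nrow(empty), 0L)
})
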