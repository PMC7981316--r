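test_that("config validation rejects out-of-range fields", {
  expect_error(generator_config(n_f3 = 0, n_f2 = 0), "not both zero")
  expect_error(generator_config(subgroup_fraction_f2 = 1.2), "\\[0, 1\\]")
  expect_error(generator_config(planted_correlation = 0), "planted_correlation")
  expect_error(generator_config(igm_log_sd = -1), "igm_log_sd")
  expect_error(generator_config(planted_sideeffect_r2 = c(bogus = 0.2)),
               "MEDIS")
})

test_that("default cohort has the study structure", {
  coh <- tiny_cohort(seed = 4, n_f3 = 195, n_f2 = 84)
  expect_equal(nrow(coh$patients), 279)
  counts <- table(coh$assessments$patient_id)
  expect_true(all(counts == 8))
  expect_true(all(coh$assessments$day %in% study_schedule()))
  # inclusion rules at baseline
  f3 <- coh$patients$diagnosis == "F3"
  expect_true(all(coh$patients$baseline_hamd17[f3] >= 15))
  expect_true(all(coh$patients$baseline_panss_g[!f3] >= 21))
  # day 0 present for everyone even with missingness
  coh2 <- generate_cohort(generator_config(n_f3 = 40, n_f2 = 20,
                                           missing_rate = 0.3, seed = 2))
  d0 <- tapply(coh2$assessments$day == 0, coh2$assessments$patient_id, any)
  expect_true(all(d0))
})

test_that("generation is deterministic for a fixed config and seed", {
  a <- tiny_cohort(seed = 77, n_f3 = 30, n_f2 = 20)
  b <- tiny_cohort(seed = 77, n_f3 = 30, n_f2 = 20)
  expect_identical(a$patients, b$patients)
  expect_identical(a$assessments, b$assessments)
  expect_identical(a$truth, b$truth)
  c <- tiny_cohort(seed = 78, n_f3 = 30, n_f2 = 20)
  expect_false(identical(a$patients, c$patients))
})

test_that("planted IgM correlation is calibrated and local to the subgroup", {
  cfg <- generator_config(n_f3 = 0, n_f2 = 2000, planted_correlation = 0.75,
                          missing_rate = 0, igm_missing_rate = 0, seed = 7)
  coh <- generate_cohort(cfg)
  mem <- coh$truth$subgroup
  r_in <- cor(coh$patients$igm[mem], coh$patients$sl[mem])
  r_out <- cor(coh$patients$igm[!mem], coh$patients$sl[!mem])
  expect_gte(r_in, 0.70)
  expect_lte(r_in, 0.80)
  expect_lt(abs(r_out), 0.1)

  # degenerate noiseless limit: exactly linear
  cfg1 <- generator_config(n_f3 = 0, n_f2 = 200, planted_correlation = 1,
                           missing_rate = 0, igm_missing_rate = 0, seed = 3)
  coh1 <- generate_cohort(cfg1)
  m1 <- coh1$truth$subgroup
  expect_equal(cor(coh1$patients$igm[m1], coh1$patients$sl[m1]), 1.0,
               tolerance = 1e-12)
})

test_that("drug counts are calibrated at 10x the study size", {
  coh <- generate_cohort(generator_config(n_f3 = 1950, n_f2 = 840,
                                          seed = 11))
  f3 <- coh$patients$diagnosis == "F3"
  expect_lt(abs(mean(coh$patients$drug_count[f3]) - 3.2), 0.2)
  expect_lt(abs(mean(coh$patients$drug_count[!f3]) - 3.5), 0.3)
})

test_that("ground truth stays out of the analysis-facing tables", {
  coh <- tiny_cohort(seed = 5)
  expect_false(any(c("subgroup", "planted_response") %in%
                     names(coh$patients)))
  expect_false(any(c("subgroup", "planted_response") %in%
                     names(coh$assessments)))
  dir <- withr::local_tempdir()
  paths <- write_cohort(coh, dir, truth = FALSE)
  expect_false(file.exists(file.path(dir, "truth.csv")))
  pat <- read.csv(paths["patients"])
  expect_false("subgroup" %in% names(pat))
})

test_that("cohort_summary reports strata and omits empty ones", {
  coh <- tiny_cohort(seed = 6, n_f3 = 25, n_f2 = 15)
  s <- cohort_summary(coh)
  expect_setequal(s$diagnosis, c("F2", "F3"))
  expect_true(all(s$polypharmacy_pct >= 0 & s$polypharmacy_pct <= 100))

  f2only <- generate_cohort(generator_config(n_f3 = 0, n_f2 = 15,
                                             missing_rate = 0, seed = 1))
  expect_warning(s2 <- cohort_summary(f2only), "F3")
  expect_equal(s2$diagnosis, "F2")

  # all-monotherapy cohort has a 0% polypharmacy share
  mono <- tiny_cohort(seed = 2, n_f3 = 10, n_f2 = 6)
  mono$patients$drug_count <- 1L
  expect_equal(cohort_summary(mono)$polypharmacy_pct, c(0, 0))
})

test_that("igm membership rule plants a pure cutoff", {
  cfg <- generator_config(n_f3 = 0, n_f2 = 120, membership_rule = "igm",
                          missing_rate = 0, igm_missing_rate = 0, seed = 9)
  coh <- generate_cohort(cfg)
  mem <- coh$truth$subgroup
  expect_gte(min(coh$patients$igm[mem]), max(coh$patients$igm[!mem]))
})
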