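test_that("exclude_incomplete counts and percentages are exact", {
  coh <- tiny_cohort(seed = 1, n_f3 = 20, n_f2 = 84)
  # plant exactly 4 missing IgM values among the F2 patients
  f2_ids <- coh$patients$patient_id[coh$patients$diagnosis == "F2"]
  coh$patients$igm[coh$patients$patient_id %in% f2_ids[1:4]] <- NA
  smp <- exclude_incomplete(coh, "F2")
  expect_equal(smp$report$n_total, 84)
  expect_equal(smp$report$n_excluded, 4)
  expect_equal(smp$report$pct_excluded, 4.8)
  expect_equal(smp$report$text, "4 (4.8%)")
  expect_equal(nrow(smp$data), 80)

  # no missing data: unchanged
  coh2 <- tiny_cohort(seed = 2, n_f3 = 15, n_f2 = 10)
  smp2 <- exclude_incomplete(coh2, "F3")
  expect_equal(nrow(smp2$data), 15)
  expect_equal(smp2$report$n_excluded, 0)
})

test_that("16 of 195 excluded reports 8.2 percent", {
  expect_equal(as_percent(16 / 195), 8.2)
  expect_equal(as_percent(4 / 84), 4.8)
})

test_that("subgroup statistics: identity, p-value oracle, fp rate", {
  set.seed(4)
  igm <- rnorm(40, 1, 0.3)
  score <- 30 + 20 * igm + rnorm(40, 0, 4)
  resp <- sample(c("responder", "partial", "non_responder"), 40, TRUE)
  mem <- rep(c(TRUE, FALSE), each = 20)
  st <- subgroup_statistics(mem, igm, score, resp)
  expect_equal(st$variance_explained_pct, 100 * st$r^2)  # exact identity
  ct <- cor.test(igm[mem], score[mem])                   # independent oracle
  expect_equal(st$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(st$p_value, ct$p.value, tolerance = 1e-10)
  expect_equal(st$fp_rate, mean(resp[mem] == "non_responder"))

  # permutation p agrees in order of magnitude with the t-based p
  st2 <- subgroup_statistics(mem, igm, score, resp, permutation_p = TRUE,
                             n_perm = 500)
  expect_lt(st2$p_perm, 0.05)

  expect_error(subgroup_statistics(rep(TRUE, 2), igm[1:2], score[1:2]),
               "at least 3")
  expect_error(subgroup_statistics(rep(TRUE, 5), rep(1, 5), score[1:5]),
               "zero-variance")
  # exact linear members
  st3 <- subgroup_statistics(1:5, igm = 1:40, score = 2 * (1:40) + 3)
  expect_equal(st3$r, 1)
  expect_lt(st3$p_value, 1e-10)
})

test_that("search matches the exhaustive oracle on a tiny instance", {
  smp <- tiny_discovery_sample()
  oracle <- oracle_best_subgroup(smp$data, min_size = 4)
  expect_gt(oracle$size, 0)
  mod <- subgroup_search(smp, min_size = 4, seed = 1)
  expect_true(mod$feasible)
  # objective value (subgroup size) equals the brute-force optimum
  expect_equal(length(mod$members), oracle$size)
  # independent re-check of the returned set's constraints
  d <- smp$data
  mem <- d$patient_id %in% mod$members
  ct <- cor.test(d$igm[mem], d$score[mem])
  expect_lt(ct$p.value, 0.05)
  expect_lte(mean(d$response[mem] == "non_responder"), 0.125)
})

test_that("relaxing the fp ceiling never shrinks the tiny-instance result", {
  smp <- tiny_discovery_sample()
  strict <- subgroup_search(smp, min_size = 4, max_fp_rate = 0.01, seed = 2)
  relaxed <- subgroup_search(smp, min_size = 4, max_fp_rate = 0.3, seed = 2)
  n_strict <- if (strict$feasible) length(strict$members) else 0
  n_relaxed <- if (relaxed$feasible) length(relaxed$members) else 0
  expect_gte(n_relaxed, n_strict)
})

test_that("infeasible constraints give an explicit no-solution result", {
  smp <- tiny_discovery_sample()
  expect_error(subgroup_search(smp, min_size = 50), "infeasible")
  # constant IgM: no cutoff subgroup
  d <- smp$data
  d$igm <- 1.0
  flat <- structure(list(data = d, diagnosis = "F2", report = smp$report),
                    class = "discovery_sample")
  cb <- igm_cutoff_baseline(flat, min_size = 4)
  expect_false(cb$feasible)
  ev <- subgroup_evaluate(cb, flat)
  expect_false(ev$feasible)
  expect_equal(ev$n_members, 0L)
})

test_that("cutoff baseline recovers a planted pure-IgM-threshold subgroup", {
  cfg <- generator_config(n_f3 = 0, n_f2 = 80, membership_rule = "igm",
                          planted_correlation = 0.9, missing_rate = 0,
                          igm_missing_rate = 0, seed = 12)
  coh <- generate_cohort(cfg)
  smp <- exclude_incomplete(coh, "F2")
  cb <- igm_cutoff_baseline(smp)
  expect_true(cb$feasible)
  truth <- coh$truth$subgroup[match(smp$data$patient_id,
                                    coh$truth$patient_id)]
  mem <- smp$data$patient_id %in% cb$members
  jac <- sum(mem & truth) / sum(mem | truth)
  expect_gte(jac, 0.8)
})

test_that("evaluate reports the printed precisions and scatter data", {
  smp <- tiny_discovery_sample()
  mod <- subgroup_search(smp, min_size = 4, seed = 1)
  ev <- subgroup_evaluate(mod, smp)
  expect_true(ev$feasible)
  expect_equal(ev$fraction_pct,
               as_percent(ev$n_members / ev$n_sample))
  expect_equal(ev$variance_explained_pct, round(100 * ev$r^2, 1),
               tolerance = 0.2)
  expect_equal(nrow(ev$scatter), nrow(smp$data))
  expect_equal(sum(ev$scatter$member), ev$n_members)
})

test_that("reported worked-example fractions format as printed", {
  expect_equal(as_percent(18 / 80), 22.5)
  expect_equal(as_percent(35 / 179), 19.6)
})
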