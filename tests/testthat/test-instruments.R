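test_that("severity strata follow the printed boundaries and are monotone", {
  expect_equal(stratify_severity(19, "F3"), "mild")
  expect_equal(stratify_severity(20, "F3"), "moderate")
  expect_equal(stratify_severity(24, "F3"), "moderate")
  expect_equal(stratify_severity(24.5, "F3"), "severe")
  expect_equal(stratify_severity(29, "F2"), "mild")
  expect_equal(stratify_severity(c(30, 40, 41), "F2"),
               c("moderate", "moderate", "severe"))
  # monotone in the score argument
  for (dg in c("F2", "F3")) {
    lv <- match(stratify_severity(seq(0, 60, by = 0.5), dg),
                c("mild", "moderate", "severe"))
    expect_true(all(diff(lv) >= 0))
  }
})

test_that("side-effect bins match the printed scheme", {
  expect_equal(as.character(stratify_side_effects(c(0, 10, 10.1, 30, 30.5,
                                                    40, 45, 50, 50.1))),
               c("none", "none", "mild", "mild", "moderate", "moderate",
                 "severe", "severe", "very_severe"))
  expect_error(stratify_side_effects(-1), "non-negative")
  # total and monotone over the domain
  s <- seq(0, 140, by = 0.25)
  b <- stratify_side_effects(s)
  expect_false(anyNA(b))
  expect_true(all(diff(as.integer(b)) >= 0))
})

test_that("overlap zone uses strict per-diagnosis thresholds", {
  expect_true(classify_overlap(dl = 31, sl = 36, diagnosis = "F2"))
  expect_false(classify_overlap(dl = 31, sl = 35, diagnosis = "F2"))
  expect_false(classify_overlap(dl = 30, sl = 36, diagnosis = "F2"))
  expect_true(classify_overlap(dl = 36, sl = 26, diagnosis = "F3"))
  expect_false(classify_overlap(dl = 35, sl = 26, diagnosis = "F3"))
  expect_false(classify_overlap(dl = 36, sl = 25, diagnosis = "F3"))
})

test_that("percent_reduction is signed and exact", {
  expect_equal(round(percent_reduction(23.1, 14.0), 3), 0.394)
  expect_equal(percent_reduction(17, 17), 0)
  expect_equal(percent_reduction(10, 12), -0.2)
  expect_error(percent_reduction(0, 5), "baseline")
})

test_that("classify_response reproduces the printed definitions", {
  expect_equal(classify_response(c(0, 7, 35), c(20, 15, 10), "F3"),
               "responder")
  expect_equal(classify_response(c(0, 7, 35), c(30, 25, 18), "F2"),
               "responder")
  expect_equal(classify_response(c(0, 7, 35), c(20, 20, 20), "F3"),
               "non_responder")
  expect_equal(classify_response(c(0, 7, 35), c(20, 18, 15), "F3"),
               "partial")
  expect_equal(classify_response(c(0, 7), c(20, 10), "F3"), "dropout")
  expect_error(classify_response(c(0, 7, 14), c(0, 1, 2), "F3"),
               "baseline")
})

test_that("classify_response partitions every eligible series", {
  set.seed(11)
  cats <- c("responder", "partial", "non_responder")
  for (i in 1:300) {
    dg <- sample(c("F2", "F3"), 1)
    days <- sort(sample(study_schedule(), sample(3:8, 1)))
    if (!0 %in% days) days[1] <- 0
    scores <- pmax(1, round(runif(1, 10, 40) * runif(length(days), 0.2,
                                                     1.4)))
    lab <- classify_response(days, scores, dg)
    expect_true(lab %in% cats)
    # strict variant refines, never merges, the default partition
    strict <- classify_response(days, scores, dg,
                                strict_nonresponse = TRUE)
    if (lab != "non_responder") expect_equal(strict, lab)
    if (lab == "non_responder") {
      expect_true(strict %in% c("non_responder", "minimal"))
    }
  }
})

test_that("report_proportions rounds half-away-from-zero to one decimal", {
  expect_equal(report_proportions(rep(c("a", "b"), c(27, 57)))$pct,
               c(32.1, 67.9))
  expect_equal(report_proportions(rep(c("x", "y"), c(60, 135)))$pct,
               c(30.8, 69.2))
  expect_equal(report_proportions(rep("z", 5), levels = c("z", "w"))$pct,
               c(100.0, 0.0))
  expect_error(report_proportions(character(0)), "non-empty")
  # percentages over exhaustive categories sum to 100 +/- 0.1
  set.seed(3)
  for (i in 1:50) {
    x <- sample(letters[1:4], sample(5:200, 1), replace = TRUE)
    expect_lt(abs(sum(report_proportions(x)$pct) - 100), 0.1 + 1e-9)
  }
})
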