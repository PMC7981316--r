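test_that("fit_linear agrees with the normal-equations oracle", {
  set.seed(10)
  for (i in 1:5) {
    n <- sample(30:80, 1)
    X <- data.frame(a = rnorm(n), b = runif(n), c = rnorm(n, 2))
    y <- 1 + 2 * X$a - 0.5 * X$b + rnorm(n)
    fit <- fit_linear(y, X)
    beta <- oracle_ols(y, X)
    expect_equal(unname(fit$coefficients$estimate), unname(beta),
                 tolerance = 1e-8)
  }
})

test_that("R^2 endpoints and nested monotonicity", {
  set.seed(2)
  x <- rnorm(60)
  fit1 <- suppressWarnings(fit_linear(3 * x + 1, data.frame(x = x)))
  expect_equal(fit1$variance_explained_pct, 100, tolerance = 1e-8)

  y <- rnorm(2000)
  fit0 <- fit_linear(y, data.frame(x = rnorm(2000)))
  expect_lt(fit0$variance_explained_pct, 1)

  # nested models never lose variance explained
  z <- rnorm(100); w <- rnorm(100); out <- z + rnorm(100)
  small <- fit_linear(out, data.frame(z = z))
  big <- fit_linear(out, data.frame(z = z, w = w))
  expect_gte(big$variance_explained_pct,
             small$variance_explained_pct - 1e-10)

  expect_error(fit_linear(1:3, data.frame(a = 1:3, b = 1:3, c = 1:3)),
               "n >")
  expect_error(fit_linear(rnorm(20), data.frame(a = 1:20, b = 2 * (1:20))),
               "rank-deficient")
})

test_that("drug/side-effect analysis recovers the planted structure", {
  coh0 <- generate_cohort(generator_config(n_f3 = 30, n_f2 = 20,
                                           side_effect_slope = 0,
                                           seed = 5))
  rep0 <- drug_side_effect_analysis(coh0)
  expect_setequal(rep0$cluster, medis_clusters())

  one <- tiny_cohort(seed = 1, n_f3 = 2, n_f2 = 0)
  one$patients <- one$patients[1, ]
  one$assessments <- one$assessments[one$assessments$patient_id ==
                                       one$patients$patient_id, ]
  expect_error(drug_side_effect_analysis(one), "at least 3")
})

test_that("polypharmacy decomposition: planted ward effects and NN >= linear", {
  coh <- generate_cohort(generator_config(n_f3 = 400, n_f2 = 170,
                                          ward_drug_effect_sd = 1.0,
                                          seed = 21))
  pd <- polypharmacy_determinants(coh, nn_iterations = 4e4, seed = 21)
  expect_gt(pd$ward$variance_explained_pct, 5)
  # the NN sees ward + demographics, so it should capture at least the
  # linear additive demographic share
  expect_gte(pd$nn$variance_explained_pct + 2,
             pd$linear$variance_explained_pct)
  expect_gte(pd$nn$in_sample_pct, pd$nn$variance_explained_pct - 2)

  # constant outcome: all reports zero
  coh$patients$drug_count <- 3L
  pd0 <- polypharmacy_determinants(coh)
  expect_equal(pd0$nn$variance_explained_pct, 0)
  expect_equal(pd0$linear$variance_explained_pct, 0)
})

test_that("cross-validated NN variance is ~0 under a permutation null", {
  coh <- generate_cohort(generator_config(n_f3 = 150, n_f2 = 60, seed = 8))
  set.seed(8)
  coh$patients$drug_count <- sample(coh$patients$drug_count)  # break links
  pd <- polypharmacy_determinants(coh, nn_iterations = 3e4, seed = 8)
  expect_lt(pd$nn$variance_explained_pct, 5)
})
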