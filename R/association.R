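#' Ordinary least squares with a variance-explained report
#'
#' Fits `outcome ~ predictors` by OLS and reports the variance explained
#' (`100 * R^2`) with a per-coefficient table. Backed by [stats::lm()];
#' the test suite checks it against an independent normal-equations
#' solution.
#'
#' @param outcome numeric response vector.
#' @param predictors data.frame (factors allowed; indicator coding with
#'   first-level reference) or numeric matrix.
#' @return object of class `variance_report`: list with `outcome`,
#'   `predictors`, `model` (`"linear"`), `variance_explained_pct`, `n`,
#'   `coefficients` (estimate, se, t, p), `fit`.
#' @export
fit_linear <- function(outcome, predictors, outcome_name = "outcome") {
  predictors <- as.data.frame(predictors)
  n <- length(outcome)
  stopifnot(nrow(predictors) == n)
  if (n <= ncol(model.matrix(~ ., predictors))) {
    stop("need n > number of coefficients")
  }
  dat <- cbind(data.frame(.y = outcome), predictors)
  fit <- lm(.y ~ ., data = dat)
  if (any(is.na(coef(fit)))) {
    stop("rank-deficient design: drop collinear predictors (",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "), ")")
  }
  sm <- summary(fit)
  co <- as.data.frame(sm$coefficients)
  names(co) <- c("estimate", "se", "t", "p")
  structure(list(
    outcome = outcome_name, predictors = names(predictors),
    model = "linear",
    variance_explained_pct = 100 * sm$r.squared,
    n = n, coefficients = co, fit = fit
  ), class = "variance_report")
}

#' @export
print.variance_report <- function(x, ...) {
  cat(sprintf("%s model of '%s' on {%s}: %.1f%% variance explained (n = %d)\n",
              x$model, x$outcome, paste(x$predictors, collapse = ", "),
              round_half_up(x$variance_explained_pct, 1), x$n))
  invisible(x)
}

#' Side-effect variance explained by the number of drugs
#'
#' One univariate linear regression per MEDIS side-effect cluster: the
#' patient's mean cluster score over all assessments regressed on the
#' number of simultaneously prescribed drugs. Reports `100 * R^2` (one
#' decimal) and the slope p-value per cluster.
#'
#' @param cohort a `cohort`.
#' @return data.frame with columns `cluster`, `variance_explained_pct`,
#'   `slope`, `p_value`, `n`.
#' @export
drug_side_effect_analysis <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  p <- cohort$patients
  if (nrow(p) < 3) stop("need at least 3 patients")
  a <- cohort$assessments
  out <- lapply(medis_clusters(), function(cl) {
    col <- paste0("medis_", cl)
    m <- tapply(a[[col]], a$patient_id, mean)
    m <- m[p$patient_id]
    rep <- fit_linear(as.numeric(m), data.frame(drug_count = p$drug_count),
                      outcome_name = col)
    data.frame(cluster = cl,
               variance_explained_pct = round_half_up(
                 rep$variance_explained_pct, 1),
               slope = rep$coefficients["drug_count", "estimate"],
               p_value = rep$coefficients["drug_count", "p"],
               n = rep$n, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Determinants of polypharmacy: linear vs nonlinear decomposition
#'
#' Decomposes the between-patient variance in the number of simultaneously
#' prescribed drugs: (a) a linear additive model on gender, age and
#' diagnosis; (b) the ward share from a ward-indicator-only linear model;
#' (c) a nonlinear sigmoid-network model on all four parameters with
#' interactions, whose variance explained is computed from 10-fold
#' cross-validated out-of-fold predictions only,
#' `100 * max(0, 1 - SSE / SST)` (the in-sample network R^2 is reported as
#' a diagnostic).
#'
#' @param cohort a `cohort`.
#' @param k cross-validation folds (default 10).
#' @param hidden,alpha,nn_iterations network settings.
#' @param seed RNG seed for the fold split and network training.
#' @return list with `linear` and `ward` (`variance_report`s), `nn`
#'   (list with `variance_explained_pct` (CV), `in_sample_pct`, `n`, `k`).
#' @export
polypharmacy_determinants <- function(cohort, k = 10, hidden = NULL,
                                      alpha = 0.6, nn_iterations = 60000,
                                      seed = 1) {
  stopifnot(inherits(cohort, "cohort"))
  p <- cohort$patients
  need <- c("gender", "age", "diagnosis", "ward", "drug_count")
  miss <- setdiff(need, names(p))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  y <- p$drug_count
  if (var(y) == 0) {
    zero <- list(variance_explained_pct = 0)
    return(list(linear = zero, ward = zero,
                nn = list(variance_explained_pct = 0, in_sample_pct = 0,
                          n = nrow(p), k = k)))
  }
  demo <- data.frame(gender = factor(p$gender), age = p$age,
                     diagnosis = factor(p$diagnosis))
  one_level <- vapply(demo, function(col) is.factor(col) &&
                        nlevels(droplevels(col)) < 2, logical(1))
  linear <- fit_linear(y, demo[, !one_level, drop = FALSE],
                       outcome_name = "drug_count")
  ward <- fit_linear(y, data.frame(ward = factor(p$ward)),
                     outcome_name = "drug_count")

  set.seed(seed)
  X <- model.matrix(~ gender + age + diagnosis + factor(ward),
                    data = cbind(demo, ward = p$ward))[, -1, drop = FALSE]
  X <- minmax_scale(X)
  rng <- range(y)
  ys <- if (diff(rng) > 0) (y - rng[1]) / diff(rng) else rep(0, length(y))
  cv <- nn_cross_validate(X, ys, k = k, hidden = hidden, alpha = alpha,
                          max_iterations = nn_iterations)
  pred <- cv$pred[, 1] * diff(rng) + rng[1]
  sst <- sum((y - mean(y))^2)
  cv_pct <- 100 * max(0, 1 - sum((y - pred)^2) / sst)
  fit_full <- nn_train(X, ys, hidden = hidden, alpha = alpha,
                       max_iterations = nn_iterations)
  in_pred <- nn_predict(fit_full, X)[, 1] * diff(rng) + rng[1]
  in_pct <- 100 * max(0, 1 - sum((y - in_pred)^2) / sst)
  list(linear = linear, ward = ward,
       nn = list(variance_explained_pct = cv_pct, in_sample_pct = in_pct,
                 n = nrow(p), k = k))
}
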