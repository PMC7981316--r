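#' Feature set used for subgroup discovery
#'
#' Previous-history syndrome scores (seven SSCL-16 dimensions) plus the two
#' baseline severity totals (HAM-D21 and PANSS-G) that feed the membership
#' network.
#' @return character vector of patient-table column names.
#' @export
discovery_features <- function() {
  c("sscl_thought_disorder", "sscl_delusions", "sscl_hallucinations",
    "sscl_ego_consciousness", "sscl_anergia", "sscl_incongruent_affect",
    "sscl_depressive_syndrome", "baseline_hamd21", "baseline_panss_g")
}

#' Build the analysis sample for one diagnosis, excluding incomplete data
#'
#' Restricts a cohort to one diagnosis class and removes every patient with
#' a missing feature, missing IgM, or a premature dropout (fewer than three
#' assessments, so no response label). Reports the exclusion count and
#' percentage.
#'
#' @param cohort a `cohort`.
#' @param diagnosis `"F2"` or `"F3"`.
#' @return object of class `discovery_sample`: list with `data` (columns
#'   `patient_id`, the [discovery_features()], `igm`, `score` — the
#'   diagnosis-appropriate global syndrome score — and `response`),
#'   `diagnosis`, and `report` (`n_total`, `n_excluded`, `pct_excluded`,
#'   `text`).
#' @export
exclude_incomplete <- function(cohort, diagnosis) {
  diagnosis <- match.arg(diagnosis, c("F2", "F3"))
  p <- cohort$patients[cohort$patients$diagnosis == diagnosis, ]
  if (nrow(p) == 0) stop("no patients with diagnosis ", diagnosis)
  feats <- discovery_features()
  resp <- observed_response(
    structure(list(
      patients = p,
      assessments = cohort$assessments[
        cohort$assessments$patient_id %in% p$patient_id, ]),
      class = "cohort"))
  score <- global_score(p, diagnosis)
  ok <- complete.cases(p[, feats]) & !is.na(p$igm) & !is.na(score) &
    resp != "dropout"
  n_total <- nrow(p)
  n_excl <- sum(!ok)
  if (!any(ok)) stop("all ", diagnosis, " patients excluded: empty sample")
  data <- cbind(
    data.frame(patient_id = p$patient_id[ok], stringsAsFactors = FALSE),
    p[ok, feats],
    data.frame(igm = p$igm[ok], score = score[ok], response = resp[ok],
               stringsAsFactors = FALSE))
  rownames(data) <- NULL
  pct <- as_percent(n_excl / n_total)
  structure(list(
    data = data, diagnosis = diagnosis,
    report = list(n_total = n_total, n_excluded = n_excl,
                  pct_excluded = pct,
                  text = sprintf("%d (%s%%)", n_excl,
                                 format(pct, nsmall = 1)))
  ), class = "discovery_sample")
}

#' @export
print.discovery_sample <- function(x, ...) {
  cat(sprintf("Discovery sample (%s): %d of %d patients; excluded %s\n",
              x$diagnosis, nrow(x$data), x$report$n_total, x$report$text))
  invisible(x)
}

#' Statistics of a candidate subgroup
#'
#' Pearson correlation between IgM and the global syndrome score within the
#' members, its two-sided p-value (t transform, optionally an exact-style
#' permutation p), the false-positive response-prediction rate (observed
#' non-responders among members / member count; membership is read as a
#' prediction of treatment response), and the variance explained,
#' `100 * r^2`.
#'
#' @param members logical vector (or integer indices) selecting members.
#' @param igm per-patient IgM levels.
#' @param score per-patient global syndrome scores.
#' @param response per-patient response labels (`"responder"`,
#'   `"partial"`, `"non_responder"`); may be `NULL`, giving `NA` fp rate.
#' @param permutation_p if `TRUE`, add a permutation p-value (`n_perm`
#'   resamples) — useful for very small member sets.
#' @param n_perm permutation count (default 2000).
#' @return list with `n_members`, `r`, `p_value`, `fp_rate`,
#'   `variance_explained_pct` (and `p_perm` when requested).
#' @export
#' @examples
#' subgroup_statistics(rep(TRUE, 5), igm = 1:5, score = c(1, 2, 3, 4, 5),
#'                     response = rep("responder", 5))$r  # 1
subgroup_statistics <- function(members, igm, score, response = NULL,
                                permutation_p = FALSE, n_perm = 2000) {
  if (!is.logical(members)) {
    idx <- members
    members <- rep(FALSE, length(igm))
    members[idx] <- TRUE
  }
  m <- sum(members)
  if (m < 3) stop("subgroup statistics need at least 3 members")
  x <- igm[members]; y <- score[members]
  if (sd(x) == 0 || sd(y) == 0) {
    stop("zero-variance IgM or score within the subgroup")
  }
  r <- cor(x, y)
  r_cl <- min(1 - 1e-15, max(-1 + 1e-15, r))
  tstat <- r_cl * sqrt((m - 2) / (1 - r_cl^2))
  p <- 2 * pt(-abs(tstat), df = m - 2)
  out <- list(
    n_members = m, r = r, p_value = p,
    fp_rate = if (is.null(response)) NA_real_ else
      mean(response[members] == "non_responder"),
    variance_explained_pct = 100 * r^2
  )
  if (permutation_p) {
    robs <- abs(r)
    hits <- sum(vapply(seq_len(n_perm), function(i) {
      abs(cor(x, sample(y))) >= robs - 1e-12
    }, logical(1)))
    out$p_perm <- (hits + 1) / (n_perm + 1)
  }
  out
}

# Grow a membership along an inclusion order, including observed
# non-responders as they come but stopping outright after
# `max_nonresponders` of them (the discovered subgroups keep a small
# residual of treatment failures; a candidate can never be padded by
# walking arbitrarily deep). Evaluates every visited set and returns the
# best feasible one (max size, ties by r).
.grow_feasible <- function(ord, d, min_size, min_r_pvalue, max_fp_rate,
                           max_nonresponders = 3) {
  n <- length(ord)
  mem <- logical(n)
  n_nr <- 0
  best <- NULL
  sz <- 0
  for (i in ord) {
    if (d$response[i] == "non_responder") {
      n_nr <- n_nr + 1
      if (n_nr > max_nonresponders) break
    }
    mem[i] <- TRUE
    sz <- sz + 1
    if (sz < max(3, min_size)) next
    st <- tryCatch(subgroup_statistics(mem, d$igm, d$score, d$response),
                   error = function(e) NULL)
    if (is.null(st)) next
    if (.feasible(st, min_r_pvalue, max_fp_rate, min_size) &&
        (is.null(best) || st$n_members > best$st$n_members ||
           (st$n_members == best$st$n_members && st$r > best$st$r))) {
      best <- list(members = mem, st = st)
    }
  }
  best
}

# Feature-neighbourhood label proposal: for every patient, form the set
# of that patient and its (q - 1) nearest neighbours in scaled feature
# space and keep the set with the strongest admissible IgM/score
# association. Exploits the working hypothesis that the sought subgroup
# is a clinically coherent subtype, i.e. compact in feature space.
.propose_neighbourhood <- function(X, d, min_size, min_r_pvalue,
                                   max_fp_rate, q) {
  n <- nrow(X)
  q <- max(min_size, min(q, n))
  dist_m <- as.matrix(dist(X))
  best <- NULL
  for (i in seq_len(n)) {
    mem <- logical(n)
    mem[order(dist_m[i, ])[seq_len(q)]] <- TRUE
    st <- tryCatch(subgroup_statistics(mem, d$igm, d$score, d$response),
                   error = function(e) NULL)
    if (is.null(st) || st$r <= 0) next
    fp_ok <- is.na(st$fp_rate) || st$fp_rate <= max_fp_rate
    score <- -log10(st$p_value) - 4 * max(0, ifelse(is.na(st$fp_rate), 0,
                                                    st$fp_rate) -
                                            max_fp_rate)
    if (is.null(best) || score > best$score) {
      best <- list(members = mem, st = st, score = score, fp_ok = fp_ok)
    }
  }
  best
}

# Consensus-line label proposal: repeatedly fit a positive-slope line
# igm ~ score through a small random seed of non-"non_responder"
# patients, grow the largest constraint-satisfying set of small-residual
# patients around it, refit the line on that set, and iterate. Proposes
# labels only; every membership the search returns must still survive the
# cross-validated network route.
.propose_consensus <- function(d, min_size, min_r_pvalue, max_fp_rate,
                               n_draws = 40) {
  n <- nrow(d)
  pool <- which(d$response != "non_responder")
  if (length(pool) < 3) pool <- seq_len(n)
  best <- NULL
  for (b in seq_len(n_draws)) {
    idx <- sample(pool, 3)
    if (sd(d$score[idx]) == 0) next
    cf <- coef(lm(d$igm[idx] ~ d$score[idx]))
    for (refit in 1:3) {
      if (!all(is.finite(cf)) || cf[2] <= 0) break
      res <- abs(d$igm - (cf[1] + cf[2] * d$score))
      cand <- .grow_feasible(order(res), d, min_size, min_r_pvalue,
                             max_fp_rate)
      fitset <- if (!is.null(cand)) which(cand$members) else
        order(res)[seq_len(max(min_size, 12))]
      if (!is.null(cand) &&
          (is.null(best) || cand$st$n_members > best$st$n_members ||
             (cand$st$n_members == best$st$n_members &&
                cand$st$r > best$st$r))) {
        best <- cand
      }
      if (sd(d$score[fitset]) == 0) break
      cf <- coef(lm(d$igm[fitset] ~ d$score[fitset]))
    }
  }
  best
}

# Does a stats list satisfy the search constraints?
.feasible <- function(st, min_r_pvalue, max_fp_rate, min_size) {
  st$n_members >= min_size && st$r > 0 &&
    st$p_value < min_r_pvalue &&
    (is.na(st$fp_rate) || st$fp_rate <= max_fp_rate)
}

# Candidate memberships from cross-validated membership scores: grow
# along descending CV score under the false-positive budget (the local
# threshold adjustment), returning the best feasible set; when nothing is
# feasible, return a steering membership (plain threshold set with the
# best penalized correlation) to relabel the next round.
.scan_thresholds <- function(cv_score, sample_data, min_r_pvalue,
                             max_fp_rate, min_size, max_nonresponders = 3) {
  # candidate memberships are prefixes of the descending cross-validated
  # membership-score order; observed non-responders are carried along as
  # the set's false positives, and growth stops outright once more than
  # `max_nonresponders` of them have been met. Beyond the
  # feature-identifiable core the score ranking is response-agnostic, so
  # the walk meets non-responders at the background rate and terminates —
  # a set padded with feature-anonymous patients is unreachable. Returns the largest feasible set (`best`, the search
  # objective), the most strongly associated admissible set (`strong`,
  # minimum correlation p-value under the false-positive ceiling) used as
  # the relabeling target, and a fallback `steer` set.
  n <- length(cv_score)
  ord <- order(cv_score, decreasing = TRUE)
  mem <- logical(n)
  n_nr <- 0; sz <- 0; overrun <- FALSE
  best <- NULL; strong <- NULL; steer <- NULL
  for (i in ord) {
    if (sample_data$response[i] == "non_responder") {
      # known treatment failures are carried along as the set's false
      # positives; one beyond the allowance marks the end of the
      # trustworthy region
      n_nr <- n_nr + 1
      if (n_nr > max_nonresponders) overrun <- TRUE
    }
    mem[i] <- TRUE
    sz <- sz + 1
    if (sz < max(3, min_size)) next
    st <- tryCatch(
      subgroup_statistics(mem, sample_data$igm, sample_data$score,
                          sample_data$response),
      error = function(e) NULL)
    if (is.null(st)) next
    # past the non-responder budget the walk continues for exploration
    # (relabeling targets) only; the returned subgroup never comes from
    # the overrun region
    if (!overrun &&
        .feasible(st, min_r_pvalue, max_fp_rate, min_size) &&
        (is.null(best) || st$n_members > best$st$n_members ||
           (st$n_members == best$st$n_members && st$r > best$st$r))) {
      best <- list(members = mem, st = st)
    }
    fp_ok <- is.na(st$fp_rate) || st$fp_rate <= max_fp_rate
    if (st$r > 0 && fp_ok &&
        (is.null(strong) || st$p_value < strong$st$p_value)) {
      strong <- list(members = mem, st = st)
    }
    val <- st$r - 2 * max(0, ifelse(is.na(st$fp_rate), 0, st$fp_rate) -
                            max_fp_rate)
    if (is.null(steer) || val > steer$value) {
      steer <- list(members = mem, value = val)
    }
  }
  list(best = best, strong = strong, steer = steer)
}

#' Constrained search for the largest IgM-linked subgroup
#'
#' Searches for the largest patient subgroup satisfying both constraints:
#' (1) a significant positive Pearson correlation between IgM and the
#' global syndrome score within the subgroup (`p < min_r_pvalue`), and
#' (2) a false-positive response-prediction rate at most `max_fp_rate`.
#' Candidate memberships are proposed by thresholding the membership score
#' of a sigmoid backprop network trained on the current membership labels
#' (supervised learning), where out-of-sample membership assignment always
#' uses the 10-fold cross-validated predictions; the threshold is adjusted
#' at every iteration to maximize the feasible subgroup size. Membership
#' is initialized from the patients whose IgM and score ranks co-align,
#' and the whole loop is restarted from jittered initializations, keeping
#' the best feasible iterate found anywhere.
#'
#' @param sample a `discovery_sample` from [exclude_incomplete()].
#' @param min_r_pvalue significance constraint on the correlation
#'   (default 0.05).
#' @param max_fp_rate false-positive rate ceiling (default 0.125, which
#'   admits subgroups at the 5--12% non-responder level).
#' @param min_size smallest admissible subgroup (default 10).
#' @param max_outer_iterations relabel/retrain cycles per restart
#'   (default 12).
#' @param restarts independent initializations (default 4).
#' @param hidden,alpha,nn_iterations network architecture / learning rate /
#'   per-fit online-update budget.
#' @param k cross-validation folds (default 10).
#' @param max_nonresponders number of observed non-responders a candidate
#'   walk may carry before it is cut off (default 3): bounds how deep the
#'   score ranking can be followed, so candidate sets cannot be padded
#'   with patients the clinical features do not identify.
#' @param seed RNG seed for the whole search (default 1).
#' @return object of class `subgroup_model`; when no membership satisfies
#'   the constraints, a model with `feasible = FALSE` and an empty member
#'   set (an explicit no-solution result, never a constraint-violating
#'   set).
#' @export
subgroup_search <- function(sample, min_r_pvalue = 0.05,
                            max_fp_rate = 0.125, min_size = 10,
                            max_outer_iterations = 8, restarts = 3,
                            hidden = 8, alpha = 0.6,
                            nn_iterations = 40000, k = 10, seed = 1,
                            max_nonresponders = 3) {
  stopifnot(inherits(sample, "discovery_sample"))
  d <- sample$data
  n <- nrow(d)
  if (min_size > n) stop("min_size exceeds the sample size: infeasible")
  X <- minmax_scale(d[, discovery_features()])
  set.seed(seed)
  kk <- min(k, n)

  rk_igm <- rank(d$igm) / n
  rk_sc <- rank(d$score) / n
  co_align <- 1 - abs(rk_igm - rk_sc)
  elevation <- (rk_igm + rk_sc) / 2

  best <- NULL
  for (r_i in seq_len(restarts)) {
    # restart 1 starts from the best feature-neighbourhood set, other odd
    # restarts from a consensus-line proposal, even restarts from
    # (jittered) IgM/score co-ranking
    members <- NULL
    if (r_i == 1) {
      prop <- .propose_neighbourhood(X, d, min_size, min_r_pvalue,
                                     max_fp_rate,
                                     q = max(min_size, round(0.22 * n)))
      if (!is.null(prop)) members <- prop$members
    } else if (r_i %% 2 == 1) {
      prop <- .propose_consensus(d, min_size, min_r_pvalue, max_fp_rate)
      if (!is.null(prop)) members <- prop$members
    }
    if (is.null(members)) {
      q <- max(min_size, round(n * runif(1, 0.18, 0.32)))
      init_score <- co_align * elevation + rnorm(n, 0, 0.08 * (r_i > 2))
      members <- init_score >= sort(init_score, decreasing = TRUE)[q]
    }
    miss <- 0
    ema <- NULL
    for (it in seq_len(max_outer_iterations)) {
      y <- as.numeric(members)
      if (sum(y) == 0 || sum(y) == n) break
      # two repeated 10-fold CVs per iteration, smoothed across
      # iterations; the damping suppresses fold-assignment noise so the
      # relabeling loop can settle into a fixed point
      cv_score <- rowMeans(vapply(1:2, function(rep) {
        nn_cross_validate(X, y, k = kk, strata = y, hidden = hidden,
                          alpha = alpha,
                          max_iterations = nn_iterations)$pred[, 1]
      }, numeric(n)))
      ema <- if (is.null(ema)) cv_score else 0.5 * ema + 0.5 * cv_score
      # IgM-consistency weighting (the "predict IgM" reading of the
      # model): patients far from the current members\' IgM ~ score line
      # are down-weighted before thresholding, so membership combines
      # feature evidence with the linear IgM link
      scan_score <- ema
      if (sum(members) >= 5 && sd(d$score[members]) > 0) {
        cf <- coef(lm(d$igm[members] ~ d$score[members]))
        if (all(is.finite(cf)) && cf[2] > 0) {
          res <- abs(d$igm - (cf[1] + cf[2] * d$score))
          sg <- max(sd(res[members]), 1e-6)
          w <- 0.10 + 0.90 * exp(-0.5 * (res / (2.0 * sg))^2)
          scan_score <- ema * w
        }
      }
      scan <- .scan_thresholds(scan_score, d, min_r_pvalue, max_fp_rate,
                               min_size, max_nonresponders)
      if (!is.null(scan$best)) {
        cand <- scan$best
        # self-consistency gate: a candidate only counts when the
        # cross-validated predictions of the network trained on its own
        # labels reproduce it (Jaccard >= 0.7 against the training
        # labels). Sets padded with patients the clinical features cannot
        # identify fail this gate.
        jac <- sum(cand$members & members) / sum(cand$members | members)
        if (jac >= 0.75 &&
            (is.null(best) || cand$st$n_members > best$st$n_members ||
               (cand$st$n_members == best$st$n_members &&
                  cand$st$r > best$st$r))) {
          best <- cand
        }
      }
      # relabel toward the most strongly associated admissible set, or
      # the largest feasible set when that is bigger (relabeling toward a
      # shrunken core invites memorization of the reduced label set)
      if (!is.null(scan$strong) || !is.null(scan$best)) {
        miss <- 0
        pick <- scan$strong
        if (!is.null(scan$best) &&
            (is.null(pick) || scan$best$st$n_members > pick$st$n_members)) {
          pick <- scan$best
        }
        new_members <- pick$members
      } else if (!is.null(scan$steer) && miss < 3) {
        miss <- miss + 1
        new_members <- scan$steer$members
      } else {
        break
      }
      if (identical(new_members, members)) break
      members <- new_members
    }
  }

  constraints <- list(min_r_pvalue = min_r_pvalue,
                      max_fp_rate = max_fp_rate, min_size = min_size)
  if (is.null(best)) {
    return(structure(list(
      feasible = FALSE, diagnosis = sample$diagnosis, members = character(0),
      n_sample = n, constraints = constraints, kind = "nn"),
      class = "subgroup_model"))
  }
  # independent re-check of the returned set against the raw data
  st <- subgroup_statistics(best$members, d$igm, d$score, d$response)
  stopifnot(.feasible(st, min_r_pvalue, max_fp_rate, min_size))
  net <- nn_train(X, as.numeric(best$members), hidden = hidden,
                  alpha = alpha, max_iterations = nn_iterations)
  structure(list(
    feasible = TRUE, diagnosis = sample$diagnosis,
    members = d$patient_id[best$members],
    membership = best$members, n_sample = n,
    fraction = round(st$n_members / n, 3),
    r = st$r, p_value = st$p_value, fp_rate = st$fp_rate,
    variance_explained_pct = st$variance_explained_pct,
    net = net, constraints = constraints, kind = "nn"),
    class = "subgroup_model")
}

#' Best simple IgM-cutoff subgroup (baseline comparator)
#'
#' The best subgroup obtainable by a single IgM threshold (members are all
#' patients at or above the cutoff) under the same constraints as
#' [subgroup_search()]. When membership is driven by clinical features
#' rather than IgM alone, this baseline is expected to fall short of the
#' network search — the reason a simple cutoff is insufficient.
#'
#' @inheritParams subgroup_search
#' @return a `subgroup_model` with `kind = "igm_cutoff"`; `feasible =
#'   FALSE` when no cutoff satisfies the constraints.
#' @export
igm_cutoff_baseline <- function(sample, min_r_pvalue = 0.05,
                                max_fp_rate = 0.125, min_size = 10) {
  stopifnot(inherits(sample, "discovery_sample"))
  d <- sample$data
  n <- nrow(d)
  constraints <- list(min_r_pvalue = min_r_pvalue,
                      max_fp_rate = max_fp_rate, min_size = min_size)
  best <- NULL
  for (t in sort(unique(d$igm), decreasing = TRUE)) {
    mem <- d$igm >= t
    if (sum(mem) < max(3, min_size)) next
    st <- tryCatch(subgroup_statistics(mem, d$igm, d$score, d$response),
                   error = function(e) NULL)
    if (is.null(st) || !.feasible(st, min_r_pvalue, max_fp_rate, min_size))
      next
    if (is.null(best) || st$n_members > best$st$n_members ||
        (st$n_members == best$st$n_members && st$r > best$st$r)) {
      best <- list(members = mem, st = st, cutoff = t)
    }
  }
  if (is.null(best)) {
    return(structure(list(
      feasible = FALSE, diagnosis = sample$diagnosis, members = character(0),
      n_sample = n, constraints = constraints, kind = "igm_cutoff"),
      class = "subgroup_model"))
  }
  st <- best$st
  structure(list(
    feasible = TRUE, diagnosis = sample$diagnosis,
    members = d$patient_id[best$members], membership = best$members,
    n_sample = n, fraction = round(st$n_members / n, 3),
    r = st$r, p_value = st$p_value, fp_rate = st$fp_rate,
    variance_explained_pct = st$variance_explained_pct,
    cutoff = best$cutoff, constraints = constraints, kind = "igm_cutoff"),
    class = "subgroup_model")
}

#' @export
print.subgroup_model <- function(x, ...) {
  lab <- if (x$kind == "nn") "NN subgroup model" else "IgM-cutoff baseline"
  if (!x$feasible) {
    cat(sprintf("%s (%s): no feasible subgroup under the constraints\n",
                lab, x$diagnosis))
    return(invisible(x))
  }
  cat(sprintf(
    "%s (%s): %d/%d members (%.1f%%), r = %.3f (p = %.2g), FP %.1f%%, %.1f%% variance\n",
    lab, x$diagnosis, length(x$members), x$n_sample,
    as_percent(x$fraction), x$r, x$p_value, as_percent(x$fp_rate),
    round_half_up(x$variance_explained_pct, 1)))
  invisible(x)
}

#' Format a subgroup model as a report
#'
#' Re-derives every headline quantity of a fitted subgroup model from the
#' sample (fraction, r, p, false-positive rate, variance explained — all at
#' reporting precision) and exports the scatter data (global score vs IgM
#' with members highlighted).
#'
#' @param model a `subgroup_model`.
#' @param sample the `discovery_sample` the model was fitted on.
#' @return list with `feasible`, `diagnosis`, `n_sample`, `n_members`,
#'   `fraction_pct`, `r`, `p_value`, `fp_pct`, `variance_explained_pct`,
#'   `scatter` (data.frame `patient_id`, `score`, `igm`, `member`).
#' @export
subgroup_evaluate <- function(model, sample) {
  stopifnot(inherits(model, "subgroup_model"),
            inherits(sample, "discovery_sample"))
  d <- sample$data
  if (!model$feasible || length(model$members) == 0) {
    return(list(feasible = FALSE, diagnosis = model$diagnosis,
                n_sample = nrow(d), n_members = 0L,
                fraction_pct = NA_real_, r = NA_real_, p_value = NA_real_,
                fp_pct = NA_real_, variance_explained_pct = NA_real_,
                scatter = data.frame(patient_id = d$patient_id,
                                     score = d$score, igm = d$igm,
                                     member = FALSE)))
  }
  mem <- d$patient_id %in% model$members
  st <- subgroup_statistics(mem, d$igm, d$score, d$response)
  list(
    feasible = TRUE, diagnosis = model$diagnosis,
    n_sample = nrow(d), n_members = st$n_members,
    fraction_pct = as_percent(st$n_members / nrow(d)),
    r = round_half_up(st$r, 3), p_value = st$p_value,
    fp_pct = as_percent(st$fp_rate),
    variance_explained_pct = round_half_up(st$variance_explained_pct, 1),
    scatter = data.frame(patient_id = d$patient_id, score = d$score,
                         igm = d$igm, member = mem,
                         stringsAsFactors = FALSE)
  )
}
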