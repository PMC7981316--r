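#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates every knob of [generate_cohort()]. Defaults encode
#' the design of a naturalistic two-diagnosis inpatient study: 195 patients
#' with depressive disorders (F3) and 84 with schizophrenic disorders (F2),
#' up to 8 assessments at days 0/3/7/10/14/21/28/35, a planted latent
#' subgroup (19.6% of F3, 22.5% of F2) in which serum IgM is linearly
#' linked to the diagnosis-appropriate global syndrome score, ward-driven
#' polypharmacy, and drug-count-driven side-effect scores.
#'
#' @param n_f3,n_f2 patients per diagnosis class (defaults 195 / 84; one
#'   class may be 0, not both).
#' @param subgroup_fraction_f3,subgroup_fraction_f2 planted subgroup
#'   fraction per class, in \[0, 1\] (defaults 0.196 / 0.225; 0 plants no
#'   subgroup, i.e. IgM independent of the clinical picture).
#' @param planted_correlation population Pearson r between IgM and the
#'   global syndrome score within the planted subgroup, in (0, 1\].
#' @param igm_log_mean,igm_log_sd log-scale parameters of the background
#'   log-normal IgM distribution in g/L (defaults 0 / 0.425, i.e. median
#'   1 g/L with ~2.5% of background patients above 2.3 g/L).
#' @param subgroup_igm_shift multiplicative elevation of the planted
#'   subgroup's mean IgM over the background mean (default 1.35).
#' @param n_wards number of hospital wards (default 6: three hospitals with
#'   two wards each); patients are assigned uniformly.
#' @param ward_drug_effect_sd SD of ward-level mean drug-count shifts
#'   (default 0.8 drugs).
#' @param drug_count_mean_f3,drug_count_mean_f2 expected simultaneous
#'   medications (defaults 3.2 / 3.5).
#' @param drug_count_sd_f3,drug_count_sd_f2 total drug-count SD targets
#'   (defaults 2.1 / 1.6).
#' @param side_effect_slope per-drug increment of each MEDIS cluster score
#'   (default 0.55 points per drug).
#' @param side_effect_noise_sd SD of the patient-level side-effect
#'   propensity per cluster (default 2.75); ignored for clusters named in
#'   `planted_sideeffect_r2`.
#' @param planted_sideeffect_r2 optional named vector of population R^2
#'   values (cluster score ~ drug count) to plant per MEDIS cluster; the
#'   propensity SD of each named cluster is derived from the realized
#'   drug-count variance so the planted R^2 holds by construction.
#' @param response_link coefficients of the logistic responder model:
#'   `intercept_f3`, `intercept_f2`, `member` (log-odds bonus for planted
#'   members), `igm` (per g/L above the background mean), `severity` (per
#'   SD of baseline severity), and the conditional partial-improvement
#'   probabilities among non-responders: `partial_member`,
#'   `partial_nonmember_f3`, `partial_nonmember_f2`.
#' @param missing_rate probability that a post-baseline assessment is
#'   missed (default 0.05); day 0 is never dropped.
#' @param igm_missing_rate probability that a patient's IgM level was never
#'   drawn (default 0.05).
#' @param membership_rule how the planted subgroup is selected:
#'   `"features"` (default) plants a discrete clinical subtype whose
#'   previous-history signature (elevated thought disorder, delusions and
#'   disturbed ego consciousness with low incongruent affect and anergia)
#'   makes membership identifiable from several clinical features but
#'   never from IgM alone; `"random"` plants a feature-independent random
#'   subset; `"igm"` plants membership as a pure IgM threshold (the
#'   degenerate case in which the simple-cutoff baseline is optimal).
#' @param seed RNG seed.
#' @return validated list of class `generator_config`.
#' @export
generator_config <- function(n_f3 = 195, n_f2 = 84,
                             subgroup_fraction_f3 = 0.196,
                             subgroup_fraction_f2 = 0.225,
                             planted_correlation = 0.8,
                             igm_log_mean = 0, igm_log_sd = 0.425,
                             subgroup_igm_shift = 1.35,
                             n_wards = 6, ward_drug_effect_sd = 0.8,
                             drug_count_mean_f3 = 3.2,
                             drug_count_mean_f2 = 3.5,
                             drug_count_sd_f3 = 2.1,
                             drug_count_sd_f2 = 1.6,
                             side_effect_slope = 0.55,
                             side_effect_noise_sd = 2.75,
                             planted_sideeffect_r2 = NULL,
                             response_link = NULL,
                             missing_rate = 0.05,
                             igm_missing_rate = 0.05,
                             membership_rule = c("features", "random",
                                                 "igm"),
                             seed = 1) {
  membership_rule <- match.arg(membership_rule)
  if (is.null(response_link)) response_link <- list()
  rl_default <- list(intercept_f3 = qlogis(0.30), intercept_f2 = qlogis(0.174),
                     member = 2.6, igm = 0, severity = 0,
                     partial_member = 0.8, partial_nonmember_f3 = 0.49,
                     partial_nonmember_f2 = 0.33)
  response_link <- utils::modifyList(rl_default, response_link)
  cfg <- list(
    n_f3 = as.integer(n_f3), n_f2 = as.integer(n_f2),
    subgroup_fraction_f3 = subgroup_fraction_f3,
    subgroup_fraction_f2 = subgroup_fraction_f2,
    planted_correlation = planted_correlation,
    igm_log_mean = igm_log_mean, igm_log_sd = igm_log_sd,
    subgroup_igm_shift = subgroup_igm_shift,
    n_wards = as.integer(n_wards),
    ward_drug_effect_sd = ward_drug_effect_sd,
    drug_count_mean_f3 = drug_count_mean_f3,
    drug_count_mean_f2 = drug_count_mean_f2,
    drug_count_sd_f3 = drug_count_sd_f3,
    drug_count_sd_f2 = drug_count_sd_f2,
    side_effect_slope = side_effect_slope,
    side_effect_noise_sd = side_effect_noise_sd,
    planted_sideeffect_r2 = planted_sideeffect_r2,
    response_link = response_link,
    missing_rate = missing_rate,
    igm_missing_rate = igm_missing_rate,
    membership_rule = membership_rule,
    seed = as.integer(seed)
  )
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("invalid config: ", msg,
                                                 call. = FALSE)
  chk(cfg$n_f3 >= 0 && cfg$n_f2 >= 0 && cfg$n_f3 + cfg$n_f2 > 0,
      "cohort sizes must be non-negative and not both zero")
  for (f in c("subgroup_fraction_f3", "subgroup_fraction_f2",
              "missing_rate", "igm_missing_rate")) {
    chk(is.numeric(cfg[[f]]) && cfg[[f]] >= 0 && cfg[[f]] <= 1,
        paste(f, "must lie in [0, 1]"))
  }
  chk(cfg$planted_correlation > 0 && cfg$planted_correlation <= 1,
      "planted_correlation must lie in (0, 1]")
  chk(cfg$n_wards >= 1, "n_wards must be positive")
  chk(cfg$igm_log_sd > 0, "igm_log_sd must be positive")
  chk(cfg$ward_drug_effect_sd >= 0, "ward_drug_effect_sd must be >= 0")
  chk(cfg$drug_count_mean_f3 >= 0 && cfg$drug_count_mean_f2 >= 0,
      "drug count means must be >= 0")
  chk(cfg$side_effect_slope >= 0, "side_effect_slope must be >= 0")
  if (!is.null(cfg$planted_sideeffect_r2)) {
    chk(all(cfg$planted_sideeffect_r2 > 0 & cfg$planted_sideeffect_r2 < 1) &&
          all(names(cfg$planted_sideeffect_r2) %in% medis_clusters()),
        "planted_sideeffect_r2 must be named MEDIS clusters with R2 in (0,1)")
  }
  invisible(cfg)
}

#' Named generator presets
#'
#' * `"study"` — the full default cohort (195 F3 + 84 F2).
#' * `"study_f2"` — an 80-patient F2-only sample with a planted 22.5%
#'   subgroup at r = 0.8 and no missingness; used for subgroup
#'   parameter-recovery experiments.
#' * `"f2_concordance"` — a 100-patient F2-only cohort for concordance
#'   calibration.
#' * `"study_sideeffects"` — the full cohort with planted per-cluster
#'   side-effect R^2 values (sexuality 0.178, gastrointestinal 0.118,
#'   cardiac-respiratory 0.133, cardiovascular 0.184).
#' * `"null_f2"` — an 80-patient F2-only sample with no planted subgroup
#'   (IgM independent of all syndrome scores everywhere).
#'
#' @param name preset name.
#' @param seed RNG seed.
#' @param ... overrides forwarded to [generator_config()].
#' @return a `generator_config`.
#' @export
generator_preset <- function(name = c("study", "study_f2", "f2_concordance",
                                      "study_sideeffects", "null_f2"),
                             seed = 1, ...) {
  name <- match.arg(name)
  args <- switch(name,
    study = list(),
    study_f2 = list(n_f3 = 0, n_f2 = 80, subgroup_fraction_f2 = 0.225,
                    planted_correlation = 0.8, missing_rate = 0,
                    igm_missing_rate = 0),
    f2_concordance = list(n_f3 = 0, n_f2 = 100, subgroup_fraction_f2 = 0,
                          missing_rate = 0, igm_missing_rate = 0),
    study_sideeffects = list(planted_sideeffect_r2 = c(
      sexuality = 0.178, gastrointestinal = 0.118,
      cardiac_respiratory = 0.133, cardiovascular = 0.184)),
    null_f2 = list(n_f3 = 0, n_f2 = 80, subgroup_fraction_f2 = 0,
                   missing_rate = 0, igm_missing_rate = 0)
  )
  do.call(generator_config, c(args, list(seed = seed), list(...)))
}

#' Study visit schedule
#'
#' Assessment days: weekly visits over five weeks plus two extra visits on
#' study days 3 and 10.
#' @return integer vector of days.
#' @export
study_schedule <- function() c(0L, 3L, 7L, 10L, 14L, 21L, 28L, 35L)

# Truncated-normal draws via inverse-CDF; exact for one-sided and
# two-sided truncation.
rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(u, mean, sd)
}

# Per-diagnosis syndrome presence probabilities and mixture locations on
# the normalized [0, 1] scale. Chosen once so that (a) roughly a quarter
# of F3 patients show paranoid symptoms and a third of F2 patients show a
# substantial depressive syndrome, and (b) the F2 key-syndrome concordance
# distribution centres near 0.54 (see the methods vignette).
.syndrome_mixture <- function(diagnosis) {
  dims <- setdiff(sscl_dimensions()$dimension, c("dl", "sl"))
  presence <- if (diagnosis == "F2") {
    c(thought_disorder = 0.50, delusions = 0.48, hallucinations = 0.45,
      ego_consciousness = 0.48, incongruent_affect = 0.50, anergia = 0.50,
      depressive_syndrome = 0.35, manic_syndrome = 0.20, suicide = 0.30)
  } else {
    c(thought_disorder = 0.20, delusions = 0.22, hallucinations = 0.15,
      ego_consciousness = 0.25, incongruent_affect = 0.15, anergia = 0.70,
      depressive_syndrome = 1.00, manic_syndrome = 0.15, suicide = 0.50)
  }
  list(dims = dims, presence = presence[dims],
       present_mean = 0.92, present_sd = 0.20,
       absent_mean = 0.06, absent_sd = 0.05)
}

# Latent DL/SL parameters per diagnosis (mean, sd) and their shared-factor
# loading; also used to standardize the global score inside the planted
# IgM link.
.dlsl_params <- function(diagnosis) {
  if (diagnosis == "F2") {
    list(dl = c(26, 9), sl = c(38, 9), load = sqrt(0.45))
  } else {
    list(dl = c(35.5, 7), sl = c(22, 9), load = sqrt(0.45))
  }
}

.generate_class <- function(cfg, diagnosis, ward_effect, id_offset) {
  n <- if (diagnosis == "F2") cfg$n_f2 else cfg$n_f3
  if (n == 0) return(NULL)
  ids <- sprintf("P%04d", id_offset + seq_len(n))

  female <- rbinom(n, 1, if (diagnosis == "F2") 0.49 else 0.60)
  age <- pmin(75, pmax(18, round(rnorm(
    n, if (diagnosis == "F2") 38.6 else 42.8,
    if (diagnosis == "F2") 12.2 else 12.6))))
  ward <- sample.int(cfg$n_wards, n, replace = TRUE)

  # lifetime syndrome dimensions (presence/severity mixture)
  mix <- .syndrome_mixture(diagnosis)
  reg <- sscl_dimensions()
  prof <- sapply(mix$dims, function(d) {
    present <- rbinom(n, 1, mix$presence[[d]])
    z <- ifelse(present == 1,
                rnorm(n, mix$present_mean, mix$present_sd),
                rnorm(n, mix$absent_mean, mix$absent_sd))
    pmin(1, pmax(0, z)) * reg$max_score[reg$dimension == d]
  })

  # lifetime global scores with a shared severity factor
  dp <- .dlsl_params(diagnosis)
  a <- dp$load; b <- sqrt(1 - dp$load^2)
  z0 <- rnorm(n)
  dl <- pmin(48, pmax(0, dp$dl[1] + dp$dl[2] * (a * z0 + b * rnorm(n))))
  sl <- pmin(80, pmax(0, dp$sl[1] + dp$sl[2] * (a * z0 + b * rnorm(n))))

  # baseline severities; inclusion rules enforced by truncation
  if (diagnosis == "F3") {
    ham17_0 <- rtruncnorm(n, 23.1, 5.7, lo = 15, hi = 52)
    panss_g0 <- rtruncnorm(n, 28, 6, lo = 16, hi = 112)
    panss_p0 <- rtruncnorm(n, 11, 3, lo = 7, hi = 49)
    panss_n0 <- rtruncnorm(n, 14, 4, lo = 7, hi = 49)
  } else {
    ham17_0 <- rtruncnorm(n, 14, 6, lo = 0, hi = 52)
    panss_g0 <- rtruncnorm(n, 35.8, 8.8, lo = 21, hi = 112)
    panss_p0 <- rtruncnorm(n, 22, 5, lo = 7, hi = 49)
    panss_n0 <- rtruncnorm(n, 20, 6, lo = 7, hi = 49)
  }
  ham21_0 <- pmin(66, ham17_0 + rtruncnorm(n, 2.5, 1.5, lo = 0, hi = 10))

  # planted subgroup and IgM
  frac <- if (diagnosis == "F2") cfg$subgroup_fraction_f2 else
    cfg$subgroup_fraction_f3
  n_sub <- round(frac * n)
  igm <- exp(rnorm(n, cfg$igm_log_mean, cfg$igm_log_sd))
  m_bg <- exp(cfg$igm_log_mean + cfg$igm_log_sd^2 / 2)
  sd_bg <- sqrt(exp(cfg$igm_log_sd^2) - 1) * m_bg
  rho <- cfg$planted_correlation
  member <- rep(FALSE, n)
  if (n_sub > 0) {
    if (cfg$membership_rule == "features") {
      # the subgroup is a discrete clinical subtype carrying a
      # distinctive previous-history signature (elevated thought
      # disorder, delusions and disturbed ego consciousness together
      # with low incongruent affect and anergia), so membership is
      # identifiable from the clinical features but never from IgM alone
      member[sample.int(n, n_sub)] <- TRUE
      reg2 <- sscl_dimensions()
      sig <- list(thought_disorder = c(0.55, 0.05),
                  delusions = c(0.55, 0.05),
                  hallucinations = c(0.55, 0.05),
                  ego_consciousness = c(0.55, 0.05),
                  incongruent_affect = c(0.08, 0.05),
                  anergia = c(0.08, 0.05))
      for (dm in names(sig)) {
        prof[member, dm] <- pmin(1, pmax(0, rnorm(
          n_sub, sig[[dm]][1], sig[[dm]][2]))) *
          reg2$max_score[reg2$dimension == dm]
      }
    } else if (cfg$membership_rule == "random") {
      member[sample.int(n, n_sub)] <- TRUE
    } else {  # "igm": membership is exactly an IgM cutoff
      member[order(igm, decreasing = TRUE)[seq_len(n_sub)]] <- TRUE
    }
  }
  if (any(member)) {
    pars <- if (diagnosis == "F2") dp$sl else dp$dl
    if (cfg$membership_rule == "igm") {
      # plant the correlation by rewriting the members' global score as a
      # linear function of their IgM level
      z_igm <- (igm[member] - mean(igm)) / sd(igm)
      new_score <- pars[1] + pars[2] *
        (rho * z_igm + sqrt(1 - rho^2) * rnorm(sum(member)))
      if (diagnosis == "F2") {
        sl[member] <- pmin(80, pmax(0, new_score))
      } else {
        dl[member] <- pmin(48, pmax(0, new_score))
      }
    } else {
      score <- if (diagnosis == "F2") sl else dl
      z <- (score[member] - pars[1]) / pars[2]
      igm[member] <- pmax(0.02, cfg$subgroup_igm_shift * m_bg +
                            sd_bg * (rho * z +
                                       sqrt(1 - rho^2) * rnorm(sum(member))))
    }
  }
  if (cfg$igm_missing_rate > 0) {
    igm[runif(n) < cfg$igm_missing_rate] <- NA_real_
  }

  # ward-driven polypharmacy with weak, partly nonlinear demographics
  mu_d <- if (diagnosis == "F2") cfg$drug_count_mean_f2 else
    cfg$drug_count_mean_f3
  sd_d <- if (diagnosis == "F2") cfg$drug_count_sd_f2 else
    cfg$drug_count_sd_f3
  demo <- 0.25 * female + 0.1 * (age - 40) / 10 +
    0.45 * female * (diagnosis == "F2") + 0.5 * (age > 55)
  resid_sd <- sqrt(max(0.3, sd_d^2 - cfg$ward_drug_effect_sd^2 - 0.15))
  drug_count <- pmin(12, pmax(0, round(
    mu_d + ward_effect[ward] + demo - mean(demo) + rnorm(n, 0, resid_sd))))

  # planted responder status from the logistic link
  rl <- cfg$response_link
  sev <- if (diagnosis == "F2") panss_g0 else ham17_0
  z_sev <- (sev - mean(sev)) / max(sd(sev), 1e-8)
  eta <- (if (diagnosis == "F2") rl$intercept_f2 else rl$intercept_f3) +
    rl$member * member + rl$igm * (ifelse(is.na(igm), m_bg, igm) - m_bg) +
    rl$severity * z_sev
  responder <- rbinom(n, 1, plogis(eta)) == 1
  p_partial <- if (diagnosis == "F2") rl$partial_nonmember_f2 else
    rl$partial_nonmember_f3
  partial <- !responder & (runif(n) < ifelse(member, rl$partial_member,
                                             p_partial))
  planted <- ifelse(responder, "responder",
                    ifelse(partial, "partial", "non_responder"))

  patients <- data.frame(
    patient_id = ids, diagnosis = diagnosis,
    gender = ifelse(female == 1, "female", "male"), age = age,
    ward = ward, drug_count = drug_count, igm = igm,
    stringsAsFactors = FALSE
  )
  prof_df <- as.data.frame(prof)
  names(prof_df) <- paste0("sscl_", mix$dims)
  patients <- cbind(patients, prof_df)
  patients$dl <- dl
  patients$sl <- sl
  patients$baseline_hamd17 <- round(ham17_0, 1)
  patients$baseline_hamd21 <- round(ham21_0, 1)
  patients$baseline_panss_p <- round(panss_p0, 1)
  patients$baseline_panss_n <- round(panss_n0, 1)
  patients$baseline_panss_g <- round(panss_g0, 1)

  truth <- data.frame(patient_id = ids, subgroup = member,
                      planted_response = planted, stringsAsFactors = FALSE)
  list(patients = patients, truth = truth,
       baselines = list(ham17 = ham17_0, ham21 = ham21_0,
                        panss_p = panss_p0, panss_n = panss_n0,
                        panss_g = panss_g0))
}

# Endpoint percent-reduction target per planted response category; margins
# keep observation noise from flipping the observed category.
.target_reduction <- function(planted, diagnosis) {
  thr <- if (diagnosis == "F2") 0.40 else 0.50
  n <- length(planted)
  red <- numeric(n)
  red[planted == "responder"] <- runif(sum(planted == "responder"),
                                       thr + 0.08, 0.85)
  red[planted == "partial"] <- runif(sum(planted == "partial"),
                                     0.25, thr - 0.05)
  red[planted == "non_responder"] <- runif(sum(planted == "non_responder"),
                                           -0.15, 0.15)
  red
}

# Exponential-decay recovery curve: value(t) = B * (f + (1 - f) e^{-l t}),
# with f chosen so the day-35 reduction equals `red`. The decay rate 0.075
# per day puts ~70% of the total improvement within the first two weeks.
.trajectory <- function(baseline, red, lambda, days, lo, hi) {
  f <- (1 - red - exp(-lambda * 35)) / (1 - exp(-lambda * 35))
  val <- baseline * (f + (1 - f) * exp(-lambda * days))
  pmin(hi, pmax(lo, round(val + rnorm(length(days), 0, 0.01 * baseline))))
}

#' Generate a synthetic cohort
#'
#' Draws a complete seeded cohort: patient-level records (demographics,
#' ward, lifetime syndrome profile, IgM, medication count), longitudinal
#' assessment series on the study schedule, and a separate ground-truth
#' table flagging the planted IgM-linked subgroup. Within that subgroup
#' IgM is linear in the diagnosis-appropriate global syndrome score (SL
#' for F2, DL for F3) with the configured population correlation; outside
#' it IgM is independent of every syndrome score. Inclusion rules are
#' enforced at baseline: HAM-D17 >= 15 for F3 and PANSS-G >= 21 for F2.
#'
#' @param config a `generator_config` (default: [generator_config()]).
#' @return object of class `cohort`: list with data.frames `patients`,
#'   `assessments`, `truth`, plus the `config`.
#' @export
#' @examples
#' coh <- generate_cohort(generator_config(n_f3 = 10, n_f2 = 5, seed = 1))
#' nrow(coh$patients)
generate_cohort <- function(config = generator_config()) {
  validate_generator_config(config)
  set.seed(config$seed)
  # ward deviations around the hospital-wide mean drug count (centred so
  # the configured class means are preserved in expectation)
  ward_effect <- rnorm(config$n_wards, 0, config$ward_drug_effect_sd)
  ward_effect <- ward_effect - mean(ward_effect)

  f3 <- .generate_class(config, "F3", ward_effect, 0L)
  f2 <- .generate_class(config, "F2", ward_effect, config$n_f3)
  parts <- Filter(Negate(is.null), list(f3, f2))
  patients <- do.call(rbind, lapply(parts, `[[`, "patients"))
  truth <- do.call(rbind, lapply(parts, `[[`, "truth"))
  rownames(patients) <- rownames(truth) <- NULL

  days <- study_schedule()
  n <- nrow(patients)
  lambda <- 0.075 * exp(rnorm(n, 0, 0.25))

  # per-cluster side-effect propensity: right-skewed (shifted gamma),
  # bounded below, with variance sigma_u^2
  clusters <- medis_clusters()
  V <- var(patients$drug_count)
  m_bar <- 1 + (length(days) - 1) * (1 - config$missing_rate)
  sigma_e <- 0.8
  sigma_u <- setNames(rep(config$side_effect_noise_sd, length(clusters)),
                      clusters)
  if (!is.null(config$planted_sideeffect_r2) && V > 0) {
    for (cl in names(config$planted_sideeffect_r2)) {
      r2 <- config$planted_sideeffect_r2[[cl]]
      s2 <- config$side_effect_slope^2 * V * (1 - r2) / r2 -
        sigma_e^2 / m_bar
      sigma_u[cl] <- sqrt(max(s2, 0.01))
    }
  }
  shape <- 2
  propensity <- sapply(clusters, function(cl) {
    sigma_u[cl] * (rgamma(n, shape, 1) - shape) / sqrt(shape)
  })

  assess <- vector("list", n)
  planted <- truth$planted_response
  for (i in seq_len(n)) {
    di <- patients$diagnosis[i]
    keep <- c(TRUE, runif(length(days) - 1) >= config$missing_rate)
    d <- days[keep]
    red_primary <- .target_reduction(planted[i], di)
    red_other <- red_primary * runif(4, 0.6, 0.9)
    if (di == "F3") {
      ham17 <- .trajectory(patients$baseline_hamd17[i], red_primary,
                           lambda[i], d, 0, 52)
      ham21 <- .trajectory(patients$baseline_hamd21[i], red_other[1],
                           lambda[i], d, 0, 66)
      pp <- .trajectory(patients$baseline_panss_p[i], red_other[2],
                        lambda[i], d, 7, 49)
      pn <- .trajectory(patients$baseline_panss_n[i], red_other[3],
                        lambda[i], d, 7, 49)
      pg <- .trajectory(patients$baseline_panss_g[i], red_other[4],
                        lambda[i], d, 16, 112)
    } else {
      pp <- .trajectory(patients$baseline_panss_p[i], red_primary,
                        lambda[i], d, 7, 49)
      pg <- .trajectory(patients$baseline_panss_g[i], red_other[1],
                        lambda[i], d, 16, 112)
      pn <- .trajectory(patients$baseline_panss_n[i], red_other[2],
                        lambda[i], d, 7, 49)
      ham17 <- .trajectory(patients$baseline_hamd17[i], red_other[3],
                           lambda[i], d, 0, 52)
      ham21 <- .trajectory(patients$baseline_hamd21[i], red_other[4],
                           lambda[i], d, 0, 66)
    }
    medis <- sapply(clusters, function(cl) {
      pmin(18, pmax(0, round(
        1.8 + config$side_effect_slope * patients$drug_count[i] +
          propensity[i, cl] + rnorm(length(d), 0, sigma_e), 1)))
    })
    medis <- matrix(medis, nrow = length(d),
                    dimnames = list(NULL, paste0("medis_", clusters)))
    assess[[i]] <- cbind(
      data.frame(patient_id = patients$patient_id[i], day = d,
                 ham_d17 = ham17, ham_d21 = ham21, panss_p = pp,
                 panss_n = pn, panss_g = pg, stringsAsFactors = FALSE),
      as.data.frame(medis)
    )
  }
  assessments <- do.call(rbind, assess)
  rownames(assessments) <- NULL
  assessments$medis_global <- rowSums(
    assessments[, paste0("medis_", clusters)])

  structure(list(patients = patients, assessments = assessments,
                 truth = truth, config = config),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients (%d F3, %d F2), %d assessments\n",
              nrow(x$patients), sum(x$patients$diagnosis == "F3"),
              sum(x$patients$diagnosis == "F2"), nrow(x$assessments)))
  cat(sprintf("  seed %d, planted subgroup members: %d\n",
              x$config$seed, sum(x$truth$subgroup)))
  invisible(x)
}

#' Diagnosis-appropriate global syndrome score
#'
#' SL (lifetime global schizophrenia) for F2 patients, DL (lifetime global
#' depression) for F3 patients.
#'
#' @param patients patients data.frame (with `dl`, `sl`).
#' @param diagnosis `"F2"` or `"F3"`.
#' @return numeric vector.
#' @export
global_score <- function(patients, diagnosis) {
  diagnosis <- match.arg(diagnosis, c("F2", "F3"))
  if (diagnosis == "F2") patients$sl else patients$dl
}

#' Observed response category for every patient
#'
#' Applies [classify_response()] to each patient's longitudinal series on
#' the diagnosis-appropriate scale (HAM-D17 for F3, PANSS-P for F2).
#'
#' @param cohort a `cohort`.
#' @param strict_nonresponse passed through to [classify_response()].
#' @return character vector aligned with `cohort$patients` (may contain
#'   `"dropout"`).
#' @export
observed_response <- function(cohort, strict_nonresponse = FALSE) {
  vapply(seq_len(nrow(cohort$patients)), function(i) {
    pid <- cohort$patients$patient_id[i]
    di <- cohort$patients$diagnosis[i]
    a <- cohort$assessments[cohort$assessments$patient_id == pid, ]
    col <- if (di == "F2") "panss_p" else "ham_d17"
    classify_response(a$day, a[[col]], di,
                      strict_nonresponse = strict_nonresponse)
  }, character(1))
}

#' Summarize a cohort by diagnosis
#'
#' Per-diagnosis means/SDs of baseline severity and drug count, the
#' polypharmacy share (>= 2 drugs), side-effect prevalence by bin (worst
#' assessment per patient), and observed response-category proportions.
#' Empty diagnosis strata are omitted with a warning.
#'
#' @param cohort a `cohort`.
#' @return data.frame, one row per present diagnosis stratum.
#' @export
cohort_summary <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"), nrow(cohort$patients) > 0)
  out <- lapply(c("F3", "F2"), function(di) {
    p <- cohort$patients[cohort$patients$diagnosis == di, ]
    if (nrow(p) == 0) {
      warning("diagnosis stratum ", di, " is empty; omitted")
      return(NULL)
    }
    base <- if (di == "F2") p$baseline_panss_g else p$baseline_hamd17
    a <- cohort$assessments[cohort$assessments$patient_id %in%
                              p$patient_id, ]
    worst_s <- tapply(a$medis_global, a$patient_id, max)
    bins <- report_proportions(as.character(stratify_side_effects(worst_s)),
                               levels = c("none", "mild", "moderate",
                                          "severe", "very_severe"))
    resp <- observed_response(
      structure(list(patients = p, assessments = a), class = "cohort"))
    eligible <- resp != "dropout"
    rp <- report_proportions(resp[eligible],
                             levels = c("responder", "partial",
                                        "non_responder"))
    data.frame(
      diagnosis = di, n = nrow(p),
      baseline_mean = round(mean(base), 1),
      baseline_sd = round(sd(base), 1),
      drug_count_mean = round(mean(p$drug_count), 2),
      drug_count_sd = round(sd(p$drug_count), 2),
      polypharmacy_pct = as_percent(mean(p$drug_count >= 2)),
      side_effects_any_pct = as_percent(
        sum(bins$n[bins$label != "none"]) / nrow(p)),
      side_effects_severe_pct = as_percent(
        sum(bins$n[bins$label %in% c("severe", "very_severe")]) / nrow(p)),
      responder_pct = rp$pct[rp$label == "responder"],
      partial_pct = rp$pct[rp$label == "partial"],
      non_responder_pct = rp$pct[rp$label == "non_responder"],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, Filter(Negate(is.null), out))
}
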