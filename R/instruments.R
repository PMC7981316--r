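#' Syndrome dimension registry
#'
#' Item counts and score bounds for the nine lifetime syndrome dimensions of
#' the SADS Syndrome Check List (SSCL-16) plus the two lifetime global
#' scores: DL (depression, 12 items) and SL (schizophrenia, 20 items).
#' Items are scored 0--4, so a dimension's maximum is `4 * items`; hence
#' DL in \[0, 48\] and SL in \[0, 80\].
#'
#' @return A data.frame with columns `dimension`, `items`, `max_score`.
#' @export
#' @examples
#' sscl_dimensions()
sscl_dimensions <- function() {
  d <- data.frame(
    dimension = c("thought_disorder", "delusions", "hallucinations",
                  "ego_consciousness", "incongruent_affect", "anergia",
                  "depressive_syndrome", "manic_syndrome", "suicide",
                  "dl", "sl"),
    items = c(6L, 5L, 4L, 4L, 3L, 4L, 8L, 5L, 3L, 12L, 20L),
    stringsAsFactors = FALSE
  )
  d$max_score <- 4L * d$items
  d
}

#' Key schizophrenia syndrome dimensions
#'
#' The core dimensions of schizophrenic disorders used by default in
#' concordance and subgroup analyses.
#' @return Character vector of dimension names.
#' @export
key_syndromes <- function() {
  c("thought_disorder", "delusions", "hallucinations", "ego_consciousness")
}

#' MEDIS side-effect clusters
#'
#' The eight quantitative side-effect clusters of the 48-item Medication and
#' Side Effects Inventory. Each cluster holds 6 items scored 0--3 (cluster
#' score in \[0, 18\]); the global score S is the sum over clusters,
#' S in \[0, 144\].
#' @return Character vector of cluster names.
#' @export
medis_clusters <- function() {
  c("sleep", "appetite", "sexuality", "gastrointestinal", "autonomic",
    "neurological", "cardiovascular", "cardiac_respiratory")
}

# Round half away from zero; base round() is banker's rounding.
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage with the package-wide rounding rule
#'
#' Converts a proportion to a percentage rounded half-away-from-zero to one
#' decimal, the single rounding convention used in every report.
#'
#' @param x numeric proportion(s).
#' @param digits decimals to keep (default 1).
#' @return numeric percentage(s).
#' @export
#' @examples
#' as_percent(27 / 84)   # 32.1
#' as_percent(60 / 195)  # 30.8
as_percent <- function(x, digits = 1) {
  round_half_up(100 * x, digits)
}

#' Stratify baseline severity
#'
#' Patients with depressive disorders (F3) are stratified on the HAM-D17
#' baseline total: mild `< 20`, moderate `20--24` (inclusive), severe
#' `> 24`. Patients with schizophrenic disorders (F2) are stratified on the
#' PANSS-G baseline total: mild `< 30`, moderate `30--40` (inclusive),
#' severe `> 40`.
#'
#' @param baseline day-0 severity total: HAM-D17 for F3, PANSS-G for F2.
#' @param diagnosis `"F2"` or `"F3"`.
#' @return `"mild"`, `"moderate"` or `"severe"` (vectorised over
#'   `baseline`).
#' @export
#' @examples
#' stratify_severity(19, "F3")  # mild
#' stratify_severity(41, "F2")  # severe
stratify_severity <- function(baseline, diagnosis) {
  diagnosis <- match.arg(diagnosis, c("F2", "F3"))
  stopifnot(is.numeric(baseline), all(baseline >= 0))
  cuts <- if (diagnosis == "F3") c(20, 24) else c(30, 40)
  out <- ifelse(baseline < cuts[1], "mild",
                ifelse(baseline <= cuts[2], "moderate", "severe"))
  out
}

#' Stratify the global side-effect score
#'
#' Bins the MEDIS global side-effect score S: none `S <= 10`, mild
#' `10 < S <= 30`, moderate `30 < S <= 40`, severe `40 < S <= 50`,
#' very severe `S > 50`.
#'
#' @param S non-negative global side-effect score(s).
#' @return factor with levels `none < mild < moderate < severe <
#'   very_severe`.
#' @export
#' @examples
#' stratify_side_effects(c(10, 30, 50.1))
stratify_side_effects <- function(S) {
  stopifnot(is.numeric(S))
  if (any(S < 0, na.rm = TRUE)) {
    stop("global side-effect score S must be non-negative")
  }
  cut(S, breaks = c(-Inf, 10, 30, 40, 50, Inf),
      labels = c("none", "mild", "moderate", "severe", "very_severe"),
      ordered_result = TRUE)
}

#' Diagnostic overlap-zone membership
#'
#' A patient lies in the overlap zone of the DL (lifetime global depression)
#' by SL (lifetime global schizophrenia) plane when both lifetime scores are
#' substantial for the *other* diagnosis: strict thresholds `SL > 35 & DL >
#' 30` for F2 patients and `SL > 25 & DL > 35` for F3 patients.
#'
#' @param dl lifetime global depression score(s), 12 items, \[0, 48\].
#' @param sl lifetime global schizophrenia score(s), 20 items, \[0, 80\].
#' @param diagnosis `"F2"` or `"F3"`.
#' @return logical vector.
#' @export
#' @examples
#' classify_overlap(dl = 31, sl = 36, diagnosis = "F2")  # TRUE
classify_overlap <- function(dl, sl, diagnosis) {
  diagnosis <- match.arg(diagnosis, c("F2", "F3"))
  stopifnot(is.numeric(dl), is.numeric(sl))
  if (diagnosis == "F2") sl > 35 & dl > 30 else sl > 25 & dl > 35
}

#' Signed percent reduction from baseline
#'
#' `(baseline - value) / baseline`; negative when the score worsened.
#'
#' @param baseline baseline score, strictly positive.
#' @param value later score.
#' @return signed proportion.
#' @export
#' @examples
#' percent_reduction(23.1, 14.0)  # 0.3939...
percent_reduction <- function(baseline, value) {
  stopifnot(is.numeric(baseline), is.numeric(value))
  if (any(baseline <= 0)) {
    stop("percent_reduction() requires baseline > 0")
  }
  (baseline - value) / baseline
}

#' Classify treatment response from a longitudinal severity series
#'
#' Response is judged on the endpoint reduction of the diagnosis-appropriate
#' scale — HAM-D17 for F3, PANSS-P for F2 — between day 0 and the last
#' available assessment. Responder: reduction `>= 0.50` (F3) or `>= 0.40`
#' (F2); partial: reduction `>= 0.20` below the responder threshold;
#' non-responder otherwise. The three categories partition every eligible
#' series. A series with fewer than `min_assessments` visits is a premature
#' dropout and is flagged `"dropout"` rather than classified.
#'
#' With `strict_nonresponse = TRUE` the non-responder label is restricted to
#' series with no improvement at all (reduction `<= 0`), and sub-20%
#' improvers are labelled `"minimal"`; the default three-way partition is
#' the reporting convention.
#'
#' @param days integer vector of assessment days (must contain 0).
#' @param scores severity totals aligned with `days`.
#' @param diagnosis `"F2"` or `"F3"`.
#' @param min_assessments minimum number of visits required (default 3).
#' @param strict_nonresponse see Details.
#' @return one of `"responder"`, `"partial"`, `"non_responder"`,
#'   `"dropout"` (and `"minimal"` under the strict flag).
#' @export
#' @examples
#' classify_response(c(0, 7, 35), c(20, 16, 10), "F3")  # responder
classify_response <- function(days, scores, diagnosis,
                              min_assessments = 3,
                              strict_nonresponse = FALSE) {
  diagnosis <- match.arg(diagnosis, c("F2", "F3"))
  stopifnot(length(days) == length(scores))
  keep <- !is.na(scores)
  days <- days[keep]; scores <- scores[keep]
  if (!any(days == 0)) stop("series must contain a day-0 baseline")
  if (length(days) < min_assessments) return("dropout")
  o <- order(days)
  days <- days[o]; scores <- scores[o]
  baseline <- scores[days == 0][1]
  if (baseline == 0) stop("baseline score of 0: percent reduction undefined")
  red <- percent_reduction(baseline, scores[length(scores)])
  thr <- if (diagnosis == "F3") 0.50 else 0.40
  if (red >= thr) return("responder")
  if (red >= 0.20) return("partial")
  if (strict_nonresponse && red > 0) return("minimal")
  "non_responder"
}

#' Tabulate category labels as percentages
#'
#' Counts and percentages (`100 * count / total`, rounded
#' half-away-from-zero to one decimal) for a vector of category labels.
#'
#' @param labels non-empty vector (character or factor) of category labels.
#' @param levels optional explicit level ordering; zero-count levels are
#'   kept.
#' @return data.frame with columns `label`, `n`, `pct`.
#' @export
#' @examples
#' report_proportions(rep(c("yes", "no"), c(27, 57)))  # 32.1 / 67.9
report_proportions <- function(labels, levels = NULL) {
  if (length(labels) == 0) stop("report_proportions() needs a non-empty input")
  if (is.null(levels)) levels <- unique(as.character(labels))
  tab <- table(factor(as.character(labels), levels = levels))
  data.frame(
    label = names(tab),
    n = as.integer(tab),
    pct = as_percent(as.integer(tab) / length(labels)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
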