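#' Concordance of two syndrome profiles
#'
#' Multidimensional quantitative agreement of two patients' syndrome
#' profiles: each selected dimension score is normalized by its instrument
#' range, and concordance is `1 - mean(|a_d - b_d|)` over the selected
#' dimensions. The measure is symmetric, lies in \[0, 1\], and equals 1
#' exactly when the two profiles agree on every selected dimension. It is a
#' deliberately simple stand-in for proprietary concordance indices used in
#' twin research; [pairwise_concordance()] accepts any replacement via its
#' `measure` argument.
#'
#' @param a,b named numeric vectors of dimension scores.
#' @param dimensions dimensions to compare (default [key_syndromes()]).
#' @param maxima named vector of dimension maxima; defaults to the
#'   [sscl_dimensions()] registry.
#' @return concordance value in \[0, 1\].
#' @export
#' @examples
#' p <- c(thought_disorder = 12, delusions = 10,
#'        hallucinations = 8, ego_consciousness = 8)
#' profile_concordance(p, p)  # 1
profile_concordance <- function(a, b, dimensions = key_syndromes(),
                                maxima = NULL) {
  if (length(dimensions) == 0) stop("empty dimension set")
  if (is.null(maxima)) {
    reg <- sscl_dimensions()
    maxima <- setNames(reg$max_score, reg$dimension)
  }
  unknown <- setdiff(dimensions, names(maxima))
  if (length(unknown)) {
    stop("unknown dimension(s): ", paste(unknown, collapse = ", "))
  }
  if (!all(dimensions %in% names(a)) || !all(dimensions %in% names(b))) {
    stop("both profiles must contain every selected dimension")
  }
  na <- as.numeric(a[dimensions]) / maxima[dimensions]
  nb <- as.numeric(b[dimensions]) / maxima[dimensions]
  1 - mean(abs(na - nb))
}

#' All pairwise syndrome-profile concordances of a cohort
#'
#' Computes the concordance of every unordered patient pair — `n(n-1)/2`
#' comparisons for `n` patients — and summarizes the distribution.
#'
#' @param x a `cohort` (see [generate_cohort()]) or a numeric matrix /
#'   data.frame of profiles (rows = patients, columns = dimensions).
#' @param dimensions dimensions to compare (default [key_syndromes()]).
#' @param maxima named vector of dimension maxima (see
#'   [profile_concordance()]).
#' @param measure pairwise measure `function(a, b, dimensions, maxima)`;
#'   defaults to [profile_concordance()].
#' @return object of class `concordance_matrix`: list with `pairs`
#'   (data.frame `id_a`, `id_b`, `concordance`), `mean`, `sd`, `n_pairs`,
#'   `n`.
#' @export
#' @examples
#' m <- matrix(c(10, 5, 4, 6, 12, 6, 8, 4), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("p1", "p2"), key_syndromes()))
#' pairwise_concordance(m)$n_pairs  # 1
pairwise_concordance <- function(x, dimensions = key_syndromes(),
                                 maxima = NULL,
                                 measure = profile_concordance) {
  if (inherits(x, "cohort")) {
    prof <- x$patients[, paste0("sscl_", dimensions), drop = FALSE]
    colnames(prof) <- dimensions
    rownames(prof) <- x$patients$patient_id
    x <- prof
  }
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) stop("pairwise concordance needs at least 2 patients")
  ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  idx <- combn(n, 2)
  vals <- vapply(seq_len(ncol(idx)), function(j) {
    measure(x[idx[1, j], ], x[idx[2, j], ], dimensions, maxima)
  }, numeric(1))
  structure(list(
    pairs = data.frame(id_a = ids[idx[1, ]], id_b = ids[idx[2, ]],
                       concordance = vals, stringsAsFactors = FALSE),
    mean = mean(vals), sd = sd(vals),
    n_pairs = length(vals), n = n
  ), class = "concordance_matrix")
}

#' @export
print.concordance_matrix <- function(x, ...) {
  cat(sprintf(
    "Pairwise syndrome-profile concordance: %d patients, %d pairs\n",
    x$n, x$n_pairs))
  cat(sprintf("  mean %.3f, sd %.3f\n", x$mean, x$sd))
  invisible(x)
}
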