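# Shared fixtures and independent oracles. Everything here is built in
# code at test time; oracles deliberately avoid the package's own
# computational paths.

# Small cohort for structural tests.
tiny_cohort <- function(seed = 1, n_f3 = 12, n_f2 = 8, ...) {
  generate_cohort(generator_config(n_f3 = n_f3, n_f2 = n_f2,
                                   missing_rate = 0, igm_missing_rate = 0,
                                   seed = seed, ...))
}

# Deterministic 12-patient discovery sample for the exhaustive search
# oracle: 8 "subtype" patients with clustered features, IgM exactly
# linear in the global score, all responders; 4 background patients with
# distant features, arbitrary IgM and non-response.
tiny_discovery_sample <- function() {
  feats <- discovery_features()
  base <- c(13, 11, 9, 9, 1, 1, 4, 20, 32)  # subtype signature-ish
  off <- seq(-0.8, 0.6, length.out = 8)
  member_X <- t(vapply(off, function(o) base + o, numeric(9)))
  bg_X <- matrix(c(
    0.5, 19, 0.2, 15, 9, 0.3, 25, 30, 52,
    22, 0.4, 15, 0.7, 0.2, 8, 2, 10, 28,
    1.2, 0.8, 0.5, 0.9, 11, 10, 30, 35, 60,
    21, 18, 14, 15, 0.5, 0.4, 1, 25, 45), nrow = 4, byrow = TRUE)
  X <- rbind(member_X, bg_X)
  colnames(X) <- feats
  score <- c(30, 33, 36, 39, 42, 45, 48, 51, 20, 55, 34, 47)
  igm <- c(0.5 + 0.03 * score[1:8] + c(0.01, -0.02, 0.015, 0, -0.01,
                                       0.02, -0.015, 0.005),
           1.9, 0.6, 1.1, 0.8)
  response <- c(rep("responder", 8), rep("non_responder", 4))
  d <- cbind(data.frame(patient_id = sprintf("T%02d", 1:12),
                        stringsAsFactors = FALSE),
             as.data.frame(X),
             data.frame(igm = igm, score = score, response = response,
                        stringsAsFactors = FALSE))
  structure(list(data = d, diagnosis = "F2",
                 report = list(n_total = 12, n_excluded = 0,
                               pct_excluded = 0, text = "0 (0.0%)")),
            class = "discovery_sample")
}

# Independent brute-force oracle for the constrained subgroup objective:
# enumerate all subsets of size >= min_size, check both constraints with
# cor.test (not the package's own p-value path), and return the best
# objective value (max size, ties by r).
oracle_best_subgroup <- function(d, min_size = 4, min_r_pvalue = 0.05,
                                 max_fp_rate = 0.125) {
  n <- nrow(d)
  best_size <- 0L
  best_r <- -Inf
  for (m in seq(min_size, n)) {
    sets <- combn(n, m)
    for (j in seq_len(ncol(sets))) {
      idx <- sets[, j]
      if (sd(d$igm[idx]) == 0 || sd(d$score[idx]) == 0) next
      ct <- suppressWarnings(cor.test(d$igm[idx], d$score[idx]))
      fp <- mean(d$response[idx] == "non_responder")
      if (ct$estimate > 0 && ct$p.value < min_r_pvalue &&
          fp <= max_fp_rate) {
        if (m > best_size || (m == best_size && ct$estimate > best_r)) {
          best_size <- m
          best_r <- unname(ct$estimate)
        }
      }
    }
  }
  list(size = best_size, r = best_r)
}

# Central finite-difference gradient of the squared-error/2 objective for
# one probe; independent of the backprop code path.
fd_gradient <- function(net, x, y, h = 1e-6) {
  loss_of <- function(nn) {
    out <- nn_forward(nn, x)[[length(nn$weights) + 1]]
    0.5 * sum((y - out)^2)
  }
  lapply(seq_along(net$weights), function(l) {
    g <- net$weights[[l]]
    for (i in seq_along(g)) {
      up <- net; up$weights[[l]][i] <- up$weights[[l]][i] + h
      dn <- net; dn$weights[[l]][i] <- dn$weights[[l]][i] - h
      g[i] <- (loss_of(up) - loss_of(dn)) / (2 * h)
    }
    g
  })
}

# Closed-form OLS via the normal equations (independent of stats::lm).
oracle_ols <- function(y, X) {
  Xd <- cbind(1, as.matrix(X))
  solve(t(Xd) %*% Xd, t(Xd) %*% y)[, 1]
}
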