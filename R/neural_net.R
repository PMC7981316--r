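#' Sigmoid activation
#'
#' The logistic activation `1 / (1 + exp(-x))`, mapping the reals into
#' (0, 1) with `sigmoid(0) = 0.5`; saturates (without overflow) at the
#' extremes.
#'
#' @param x numeric vector.
#' @return values in (0, 1).
#' @export
#' @examples
#' sigmoid(0)    # 0.5
#' sigmoid(2)    # 0.8807971
sigmoid <- function(x) {
  1 / (1 + exp(-x))
}

#' Construct a multi-layer sigmoid network
#'
#' Builds the network used throughout the package: an input layer `s_k =
#' x_k`, one to three hidden layers `s_j = sigmoid(sum_k w_jk s_k)` and an
#' output layer `s_i = sigmoid(sum_j w_ij s_j)`. Weights are initialized
#' uniformly in \[-0.5, 0.5\] from the current RNG state. With `bias =
#' TRUE` (the default) every non-output layer is augmented by a constant
#' unit with activation 1, which realizes an intercept without changing the
#' update rules; set `bias = FALSE` for the bare scalar-product form.
#'
#' @param n_input number of input units `N_k`.
#' @param n_output number of output units `N_i`.
#' @param hidden integer vector of hidden-layer sizes (1--3 layers);
#'   default is one hidden layer of `ceiling((N_k + N_i) / 2)` units.
#' @param alpha learning rate, `> 0`.
#' @param bias augment layers with a constant unit? See Details.
#' @return object of class `nn_model`.
#' @export
#' @examples
#' set.seed(1)
#' net <- nn_new(3, 1)
#' net$layer_sizes
nn_new <- function(n_input, n_output, hidden = NULL, alpha = 0.5,
                   bias = TRUE) {
  stopifnot(n_input >= 1, n_output >= 1, alpha > 0)
  if (is.null(hidden)) hidden <- ceiling((n_input + n_output) / 2)
  hidden <- as.integer(hidden)
  if (length(hidden) < 1 || length(hidden) > 3 || any(hidden < 1)) {
    stop("hidden must give 1 to 3 hidden layers of at least 1 unit")
  }
  sizes <- c(n_input, hidden, n_output)
  weights <- vector("list", length(sizes) - 1)
  for (l in seq_along(weights)) {
    nr <- sizes[l + 1]
    nc <- sizes[l] + as.integer(bias)
    weights[[l]] <- matrix(runif(nr * nc, -0.5, 0.5), nrow = nr)
  }
  structure(list(layer_sizes = sizes, weights = weights, alpha = alpha,
                 bias = bias, iterations = 0),
            class = "nn_model")
}

#' @export
print.nn_model <- function(x, ...) {
  cat(sprintf("Sigmoid backprop network %s (alpha = %g, bias = %s)\n",
              paste(x$layer_sizes, collapse = "-"), x$alpha,
              x$bias))
  cat(sprintf("  trained for %g online iterations\n", x$iterations))
  invisible(x)
}

# Augment an activation vector with the constant bias unit when needed.
.aug <- function(a, bias) if (bias) c(a, 1) else a

#' Forward pass (reference implementation)
#'
#' Propagates one input vector through the network, returning every layer's
#' activations. This pure-R path is the reference against which the
#' compiled training loop is tested.
#'
#' @param net an `nn_model`.
#' @param x input vector of length `N_k`.
#' @return list of activation vectors, one per layer; the first element is
#'   `x` itself, the last the network output.
#' @export
nn_forward <- function(net, x) {
  stopifnot(inherits(net, "nn_model"))
  if (length(x) != net$layer_sizes[1]) {
    stop(sprintf("input length %d, expected %d", length(x),
                 net$layer_sizes[1]))
  }
  act <- vector("list", length(net$weights) + 1)
  act[[1]] <- as.numeric(x)
  for (l in seq_along(net$weights)) {
    act[[l + 1]] <- sigmoid(drop(net$weights[[l]] %*% .aug(act[[l]],
                                                           net$bias)))
  }
  act
}

#' Batch prediction
#'
#' @param net an `nn_model`.
#' @param X matrix of inputs (rows = probes).
#' @return matrix of network outputs (rows = probes).
#' @export
nn_predict <- function(net, X) {
  X <- as.matrix(X)
  stopifnot(ncol(X) == net$layer_sizes[1])
  cpp_nn_forward(net$weights, X, net$bias)
}

#' One online backpropagation update (reference implementation)
#'
#' Applies the per-probe gradient-descent update of the squared-error/2
#' objective: `dw_ij = alpha * eps_i * s_j * s_i (1 - s_i)` for the output
#' weights and `dw_jk = alpha * sum_i eps_i * s_k * s_i (1 - s_i) * w_ij *
#' s_j (1 - s_j)` for the hidden weights (extended recursively for deeper
#' nets), with `eps_i = y_i - s_i`. All deltas are computed from the
#' pre-update weights and then applied. This is the gradient-checked
#' reference path; [nn_train()] runs the same update compiled.
#'
#' @param net an `nn_model`.
#' @param x input vector.
#' @param y target vector with entries in \[0, 1\].
#' @param alpha learning rate; defaults to `net$alpha`.
#' @return updated `nn_model` with attribute-free copied weights; the
#'   probe's pre-update loss is attached as `$last_loss`.
#' @export
nn_backprop_step <- function(net, x, y, alpha = net$alpha) {
  stopifnot(inherits(net, "nn_model"))
  if (alpha <= 0) stop("alpha must be > 0")
  act <- nn_forward(net, x)
  L <- length(net$weights)
  y <- as.numeric(y)
  out <- act[[L + 1]]
  eps <- y - out
  delta <- vector("list", L + 1)
  delta[[L + 1]] <- eps * out * (1 - out)
  if (L >= 2) {
    for (l in L:2) {
      w_nobias <- net$weights[[l]][, seq_along(act[[l]]), drop = FALSE]
      delta[[l]] <- drop(crossprod(w_nobias, delta[[l + 1]])) *
        act[[l]] * (1 - act[[l]])
    }
  }
  for (l in seq_len(L)) {
    net$weights[[l]] <- net$weights[[l]] +
      alpha * tcrossprod(delta[[l + 1]], .aug(act[[l]], net$bias))
  }
  net$iterations <- net$iterations + 1
  net$last_loss <- 0.5 * sum(eps^2)
  net
}

#' Train a network by online backpropagation
#'
#' Iterates the per-probe update of [nn_backprop_step()] over the training
#' probes in a freshly shuffled order every epoch, until the running
#' epoch loss changes by less than `tolerance` or `max_iterations` probe
#' updates have been spent. The compiled loop draws its shuffles from R's
#' RNG, so a fixed `set.seed()` gives an identical weight trajectory.
#' With `restarts > 1` the model is re-initialized that many times and the
#' fit with the lowest final loss is kept (useful for multimodal toy
#' problems such as XOR).
#'
#' @param X matrix of inputs (rows = probes), ideally min-max scaled to
#'   \[0, 1\] (see [minmax_scale()]).
#' @param Y matrix (or vector) of targets in \[0, 1\].
#' @param hidden,alpha,bias passed to [nn_new()]; alternatively supply a
#'   ready-made `net`.
#' @param net optional `nn_model` to start from (its architecture wins).
#' @param max_iterations budget of online probe updates (default 2e5).
#' @param tolerance epoch-loss convergence threshold.
#' @param restarts number of random re-initializations (default 1).
#' @return fitted `nn_model` with `$loss_trace` (running loss per epoch)
#'   and `$iterations` updated.
#' @export
nn_train <- function(X, Y, hidden = NULL, alpha = 0.5, bias = TRUE,
                     net = NULL, max_iterations = 2e5, tolerance = 1e-9,
                     restarts = 1) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y), nrow(X) >= 1)
  if (any(Y < 0 | Y > 1)) stop("targets must lie in [0, 1]")
  n <- nrow(X)
  epochs <- max(1L, as.integer(ceiling(max_iterations / n)))
  best <- NULL
  for (r in seq_len(restarts)) {
    this <- if (!is.null(net) && r == 1) {
      net
    } else {
      nn_new(ncol(X), ncol(Y), hidden = hidden, alpha = alpha, bias = bias)
    }
    orders <- matrix(replicate(epochs, sample.int(n)), nrow = n)
    fit <- cpp_nn_train(this$weights, X, Y, this$alpha, epochs, tolerance,
                        this$bias, orders)
    this$weights <- fit$weights
    this$iterations <- this$iterations + fit$iterations
    this$loss_trace <- fit$loss_trace
    final <- fit$loss_trace[length(fit$loss_trace)]
    if (is.null(best) || final < best$final_loss) {
      this$final_loss <- final
      best <- this
    }
  }
  best
}

#' k-fold assignment
#'
#' Splits `n` probes into `k` disjoint, exhaustive folds whose sizes differ
#' by at most one. When `strata` is given, probes are shuffled within each
#' stratum and fold labels dealt cyclically across the concatenated strata,
#' balancing strata over folds as far as the counts allow. Deterministic
#' for a fixed RNG state.
#'
#' @param n number of probes.
#' @param k number of folds (default 10), `2 <= k <= n`.
#' @param strata optional vector of stratification labels, length `n`.
#' @return integer vector of fold labels in `1..k`, length `n`.
#' @export
#' @examples
#' set.seed(1)
#' table(kfold_split(103, 10))  # seven folds of 10, three of 11
kfold_split <- function(n, k = 10, strata = NULL) {
  stopifnot(n >= 1)
  if (k < 2 || k > n) stop("need 2 <= k <= n")
  if (is.null(strata)) {
    ord <- sample.int(n)
  } else {
    stopifnot(length(strata) == n)
    ord <- unlist(lapply(split(seq_len(n), strata), function(ix) {
      if (length(ix) > 1) sample(ix) else ix
    }), use.names = FALSE)
  }
  folds <- integer(n)
  folds[ord] <- rep_len(sample.int(k), n)
  folds
}

#' Min-max scale columns to \[0, 1\]
#'
#' @param X numeric matrix or data.frame.
#' @return matrix with each column mapped to \[0, 1\]; constant columns
#'   become 0.
#' @export
minmax_scale <- function(X) {
  X <- as.matrix(X)
  apply(X, 2, function(col) {
    rng <- range(col)
    if (diff(rng) == 0) return(rep(0, length(col)))
    (col - rng[1]) / diff(rng)
  })
}

#' k-fold cross-validation of the backprop network
#'
#' Trains `k` networks, each on `k - 1` folds, and predicts each held-out
#' fold with the model that never saw it, yielding one out-of-fold
#' prediction per probe and `k` per-fold error estimates.
#'
#' @param X input matrix (rows = probes), already scaled to \[0, 1\].
#' @param Y target matrix/vector in \[0, 1\].
#' @param k number of folds (default 10).
#' @param folds optional precomputed fold labels (from [kfold_split()]).
#' @param strata optional stratification labels for the split.
#' @param ... passed to [nn_train()] (`hidden`, `alpha`, `max_iterations`,
#'   ...).
#' @return list with `pred` (out-of-fold prediction matrix, rows aligned
#'   with `X`), `folds`, `fold_mse` (mean squared error per fold), `mse`
#'   (pooled).
#' @export
nn_cross_validate <- function(X, Y, k = 10, folds = NULL, strata = NULL,
                              ...) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n <- nrow(X)
  if (is.null(folds)) folds <- kfold_split(n, k, strata)
  k <- max(folds)
  if (any(tabulate(folds, k) == 0)) stop("empty fold in fold plan")
  pred <- matrix(NA_real_, n, ncol(Y))
  fold_mse <- numeric(k)
  for (f in seq_len(k)) {
    test <- folds == f
    fit <- nn_train(X[!test, , drop = FALSE], Y[!test, , drop = FALSE], ...)
    pred[test, ] <- nn_predict(fit, X[test, , drop = FALSE])
    fold_mse[f] <- mean((Y[test, ] - pred[test, ])^2)
  }
  list(pred = pred, folds = folds, fold_mse = fold_mse,
       mse = mean((Y - pred)^2))
}
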