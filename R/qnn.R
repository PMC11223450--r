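#' Initialize a quantum neural network
#'
#' A one-hidden-layer feedforward network whose hidden units use a
#' multi-level sigmoid transfer function: unit `r` outputs
#' `b_r = (1/n_s) * sum_{s=1..n_s} sigmoid(beta * (W_r . x - theta_{r,s}))`,
#' a staircase of `n_s` shifted sigmoids whose "quantum intervals"
#' `theta_{r,s}` are learned. With `n_s = 1` and `theta = 0` the unit reduces
#' exactly to a standard sigmoid neuron. A sigmoid readout on the hidden
#' vector produces the class probability.
#'
#' Rows of `theta` are stored sorted ascending (the interval interpretation);
#' training re-sorts after every update.
#'
#' @param input_dim Input dimension.
#' @param n_hidden Number of hidden units (default 8).
#' @param n_s Number of quantum levels per unit (default 3).
#' @param beta Slope factor (> 0, default 1).
#' @param seed Optional seed.
#' @param init_sd Standard deviation of initial weights.
#' @param theta_spread Initial intervals are equally spaced in
#'   `[-theta_spread, theta_spread]` plus noise.
#' @return An object of class `qnn_params`: `W` (`n_hidden x input_dim`),
#'   `theta` (`n_hidden x n_s`), `v` (readout weights), `b_out`, `beta`,
#'   `n_s`.
#' @export
qnn_init <- function(input_dim, n_hidden = 8L, n_s = 3L, beta = 1,
                     seed = NULL, init_sd = 0.5, theta_spread = 1) {
  stopifnot(n_s >= 1, beta > 0)
  if (!is.null(seed)) set.seed(seed)
  base <- if (n_s == 1L) 0 else seq(-theta_spread, theta_spread, length.out = n_s)
  theta <- matrix(rep(base, each = n_hidden), n_hidden, n_s) +
    matrix(rnorm(n_hidden * n_s, sd = 0.1 * theta_spread), n_hidden, n_s)
  theta <- t(apply(theta, 1L, sort))
  if (n_s == 1L) theta <- matrix(theta, n_hidden, 1L)
  structure(
    list(W = matrix(rnorm(n_hidden * input_dim, sd = init_sd), n_hidden),
         theta = theta,
         v = rnorm(n_hidden, sd = init_sd), b_out = 0,
         beta = beta, n_s = as.integer(n_s),
         n_hidden = as.integer(n_hidden), input_dim = as.integer(input_dim)),
    class = "qnn_params"
  )
}

#' @export
print.qnn_params <- function(x, ...) {
  cat("<qnn_params>", x$n_hidden, "hidden units,", x$n_s,
      "quantum levels, beta =", x$beta, "\n")
  invisible(x)
}

#' Hidden activations of the quantum neural network
#'
#' Evaluates the multi-level sigmoid hidden layer for one input vector.
#'
#' @param params A [qnn_init()] object.
#' @param x Numeric input vector of length `input_dim`.
#' @return Numeric vector of `n_hidden` activations in `[0, 1]`.
#' @export
qnn_hidden <- function(params, x) {
  stopifnot(inherits(params, "qnn_params"), length(x) == params$input_dim)
  a <- as.numeric(params$W %*% x)
  rowMeans(sigmoid(params$beta * (a - params$theta)))
}

# Batch forward. X: n x input_dim. Returns probabilities (and caches).
qnn_forward_batch <- function(params, X, cache = FALSE) {
  X <- as.matrix(X)
  A <- params$W %*% t(X)                 # n_hidden x n
  n <- ncol(A)
  B <- matrix(0, params$n_hidden, n)
  S <- if (cache) vector("list", params$n_s) else NULL
  for (s in seq_len(params$n_s)) {
    sig <- sigmoid(params$beta * (A - params$theta[, s]))
    B <- B + sig
    if (cache) S[[s]] <- sig
  }
  B <- B / params$n_s
  p <- sigmoid(as.numeric(crossprod(B, params$v)) + params$b_out)
  if (cache) list(p = p, A = A, B = B, S = S) else p
}

#' Predict with a quantum neural network
#'
#' @param params A [qnn_init()] object.
#' @param x A numeric vector (one sample) or matrix/data frame of samples in
#'   rows.
#' @return Probability vector.
#' @export
qnn_forward <- function(params, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  qnn_forward_batch(params, x)
}

# Analytic gradients of mean cross-entropy w.r.t. W, theta, v, b_out.
qnn_grad <- function(params, X, y) {
  X <- as.matrix(X)
  fwd <- qnn_forward_batch(params, X, cache = TRUE)
  n <- nrow(X)
  dz <- (fwd$p - y) / n                            # length n
  dB <- outer(params$v, dz)                        # n_hidden x n
  dA <- matrix(0, params$n_hidden, ncol(fwd$A))
  dtheta <- matrix(0, params$n_hidden, params$n_s)
  for (s in seq_len(params$n_s)) {
    dsig <- fwd$S[[s]] * (1 - fwd$S[[s]])
    common <- dB * dsig * params$beta / params$n_s
    dA <- dA + common
    dtheta[, s] <- -rowSums(common)
  }
  list(W = unname(dA %*% X),
       theta = dtheta,
       v = as.numeric(fwd$B %*% dz),
       b_out = sum(dz))
}

#' Train a quantum neural network by gradient descent
#'
#' Full-batch gradient descent on mean binary cross-entropy with analytic
#' gradients for the input weights, the readout, and the quantum intervals
#' `theta` (all differentiable through the multi-level sigmoid). After each
#' update the rows of `theta` are re-sorted ascending to preserve the
#' interval ordering. Deterministic given `seed` (initialization only, when
#' `params` is `NULL`).
#'
#' @param params Starting [qnn_init()] object, or `NULL` to initialize.
#' @param x Matrix or data frame of samples in rows.
#' @param y Binary labels.
#' @param epochs Number of full-batch updates.
#' @param lr Learning rate (`lr = 0` leaves the parameters unchanged).
#' @param seed,n_hidden,n_s,beta Used when `params` is `NULL`.
#' @return Updated `qnn_params` with a `"loss"` attribute.
#' @export
qnn_train <- function(params = NULL, x, y, epochs = 100L, lr = 0.5,
                      seed = NULL, n_hidden = 8L, n_s = 3L, beta = 1) {
  X <- as.matrix(x)
  stopifnot(all(y %in% c(0, 1)), nrow(X) == length(y), lr >= 0)
  p <- params %||% qnn_init(ncol(X), n_hidden = n_hidden, n_s = n_s,
                            beta = beta, seed = seed)
  loss <- numeric(epochs)
  for (e in seq_len(epochs)) {
    loss[e] <- cross_entropy(qnn_forward_batch(p, X), y)
    if (!is.finite(loss[e])) {
      stop("training diverged (loss is not finite); lower lr", call. = FALSE)
    }
    g <- qnn_grad(p, X, y)
    p$W <- p$W - lr * g$W
    p$theta <- p$theta - lr * g$theta
    p$v <- p$v - lr * g$v
    p$b_out <- p$b_out - lr * g$b_out
    if (p$n_s > 1L) p$theta <- t(apply(p$theta, 1L, sort))
  }
  attr(p, "loss") <- loss
  p
}
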