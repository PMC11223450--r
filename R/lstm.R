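#' Initialize LSTM weights
#'
#' A single-layer LSTM with hidden size `h` followed by a sigmoid readout of
#' the final hidden state. Each gate has a weight matrix of shape
#' `h x (h + input_dim)` acting on the concatenation `[h_{t-1}, x_t]` and a
#' length-`h` bias. Tabular samples are presented as univariate sequences
#' (`input_dim = 1`): each sample's selected feature values, in fixed column
#' order, form the time steps.
#'
#' @param hidden Hidden state size (default 8).
#' @param input_dim Input dimension per time step (default 1).
#' @param seed Optional seed for the Gaussian initialization.
#' @param init_sd Standard deviation of the initial weights.
#' @return An object of class `lstm_weights`: list of `W_f`, `W_i`, `W_c`,
#'   `W_o`, `b_f`, `b_i`, `b_c`, `b_o`, `w_out`, `b_out`, plus `hidden` and
#'   `input_dim`.
#' @export
lstm_init <- function(hidden = 8L, input_dim = 1L, seed = NULL,
                      init_sd = 0.2) {
  if (!is.null(seed)) set.seed(seed)
  h <- as.integer(hidden); d <- as.integer(input_dim)
  mk <- function() matrix(rnorm(h * (h + d), sd = init_sd), h, h + d)
  structure(
    list(W_f = mk(), W_i = mk(), W_c = mk(), W_o = mk(),
         b_f = rep(0, h), b_i = rep(0, h), b_c = rep(0, h), b_o = rep(0, h),
         w_out = rnorm(h, sd = init_sd), b_out = 0,
         hidden = h, input_dim = d),
    class = "lstm_weights"
  )
}

#' @export
print.lstm_weights <- function(x, ...) {
  cat("<lstm_weights> hidden =", x$hidden, " input_dim =", x$input_dim,
      " (", 4 * x$hidden * (x$hidden + x$input_dim) + 4 * x$hidden +
        x$hidden + 1, "parameters )\n")
  invisible(x)
}

# Batch forward pass. X: n x seq_len matrix (univariate sequences, one row
# per sample). Returns probabilities; with cache = TRUE also every gate
# activation needed for backprop-through-time.
lstm_forward_batch <- function(w, X, cache = FALSE) {
  stopifnot(w$input_dim == 1L)
  X <- as.matrix(X)
  n <- nrow(X); steps <- ncol(X); h <- w$hidden
  H <- matrix(0, h, n); C <- matrix(0, h, n)
  caches <- if (cache) vector("list", steps) else NULL
  for (t in seq_len(steps)) {
    z <- rbind(H, matrix(X[, t], 1L, n))
    f <- sigmoid(w$W_f %*% z + w$b_f)
    i <- sigmoid(w$W_i %*% z + w$b_i)
    cb <- tanh(w$W_c %*% z + w$b_c)
    o <- sigmoid(w$W_o %*% z + w$b_o)
    C_prev <- C
    C <- f * C_prev + i * cb
    tC <- tanh(C)
    H <- o * tC
    if (cache) caches[[t]] <- list(z = z, f = f, i = i, cb = cb, o = o,
                                   C_prev = C_prev, C = C, tC = tC)
  }
  p <- sigmoid(as.numeric(crossprod(H, w$w_out)) + w$b_out)
  if (cache) list(p = p, H = H, caches = caches) else p
}

#' LSTM forward pass
#'
#' Runs the gate recurrences over one sample's sequence with
#' `h_0 = C_0 = 0`:
#' `f_t = sigmoid(W_f [h_{t-1}, x_t] + b_f)`,
#' `i_t = sigmoid(W_i [h_{t-1}, x_t] + b_i)`,
#' `c~_t = tanh(W_c [h_{t-1}, x_t] + b_c)`,
#' `C_t = f_t C_{t-1} + i_t c~_t`,
#' `o_t = sigmoid(W_o [h_{t-1}, x_t] + b_o)`,
#' `h_t = o_t tanh(C_t)`,
#' and returns `sigmoid(w_out . h_T + b_out)`.
#'
#' @param weights An [lstm_init()] object.
#' @param x Numeric vector: the sample's feature sequence.
#' @return Probability in `[0, 1]`.
#' @export
lstm_forward <- function(weights, x) {
  stopifnot(inherits(weights, "lstm_weights"), is.numeric(x))
  lstm_forward_batch(weights, matrix(x, nrow = 1L))
}

# Analytic gradients of mean cross-entropy, full batch, via BPTT.
lstm_grad <- function(w, X, y) {
  fwd <- lstm_forward_batch(w, X, cache = TRUE)
  n <- nrow(as.matrix(X)); steps <- length(fwd$caches); h <- w$hidden
  dz_out <- (fwd$p - y) / n                      # d loss / d readout logit
  g <- list(W_f = 0 * w$W_f, W_i = 0 * w$W_i, W_c = 0 * w$W_c,
            W_o = 0 * w$W_o, b_f = 0 * w$b_f, b_i = 0 * w$b_i,
            b_c = 0 * w$b_c, b_o = 0 * w$b_o,
            w_out = as.numeric(fwd$H %*% dz_out), b_out = sum(dz_out))
  dH <- outer(w$w_out, dz_out)                   # h x n
  dC <- matrix(0, h, n)
  for (t in rev(seq_len(steps))) {
    cc <- fwd$caches[[t]]
    do <- dH * cc$tC * cc$o * (1 - cc$o)
    dC <- dC + dH * cc$o * (1 - cc$tC^2)
    df <- dC * cc$C_prev * cc$f * (1 - cc$f)
    di <- dC * cc$cb * cc$i * (1 - cc$i)
    dcb <- dC * cc$i * (1 - cc$cb^2)
    g$W_f <- g$W_f + tcrossprod(df, cc$z)
    g$W_i <- g$W_i + tcrossprod(di, cc$z)
    g$W_c <- g$W_c + tcrossprod(dcb, cc$z)
    g$W_o <- g$W_o + tcrossprod(do, cc$z)
    g$b_f <- g$b_f + rowSums(df)
    g$b_i <- g$b_i + rowSums(di)
    g$b_c <- g$b_c + rowSums(dcb)
    g$b_o <- g$b_o + rowSums(do)
    dz <- crossprod(w$W_f, df) + crossprod(w$W_i, di) +
      crossprod(w$W_c, dcb) + crossprod(w$W_o, do)
    dH <- dz[seq_len(h), , drop = FALSE]
    dC <- dC * cc$f
  }
  g
}

cross_entropy <- function(p, y) {
  p <- pmin(1 - 1e-12, pmax(1e-12, p))
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Train an LSTM by gradient descent
#'
#' Full-batch gradient descent on mean binary cross-entropy, using analytic
#' backprop-through-time gradients. Deterministic given `seed` (which only
#' controls initialization when `weights` is `NULL`).
#'
#' @param weights Starting [lstm_init()] weights, or `NULL` to initialize
#'   with `hidden` and `seed`.
#' @param x Matrix or data frame, one row per sample; columns are the
#'   sequence steps.
#' @param y Binary labels.
#' @param epochs Number of full-batch updates.
#' @param lr Learning rate (`lr = 0` leaves the weights unchanged).
#' @param seed,hidden Used when `weights` is `NULL`.
#' @return Updated `lstm_weights` with a `"loss"` attribute (per-epoch
#'   training loss, starting at the pre-update loss).
#' @export
lstm_train <- function(weights = NULL, x, y, epochs = 100L, lr = 0.5,
                       seed = NULL, hidden = 8L) {
  X <- as.matrix(x)
  stopifnot(all(y %in% c(0, 1)), nrow(X) == length(y), lr >= 0)
  w <- weights %||% lstm_init(hidden = hidden, seed = seed)
  loss <- numeric(epochs)
  keys <- c("W_f", "W_i", "W_c", "W_o", "b_f", "b_i", "b_c", "b_o",
            "w_out", "b_out")
  for (e in seq_len(epochs)) {
    loss[e] <- cross_entropy(lstm_forward_batch(w, X), y)
    if (!is.finite(loss[e])) {
      stop("training diverged (loss is not finite); lower lr", call. = FALSE)
    }
    g <- lstm_grad(w, X, y)
    for (k in keys) w[[k]] <- w[[k]] - lr * g[[k]]
  }
  attr(w, "loss") <- loss
  w
}

# Flatten / inject the tunable weight scope for metaheuristic search.
lstm_scope_get <- function(w, scope) {
  switch(scope,
    forget_gate = c(as.numeric(w$W_f), w$b_f),
    all_gates = c(as.numeric(w$W_f), w$b_f, as.numeric(w$W_i), w$b_i,
                  as.numeric(w$W_c), w$b_c, as.numeric(w$W_o), w$b_o),
    stop("unknown scope", call. = FALSE))
}

lstm_scope_set <- function(w, scope, theta) {
  take <- function(k) {
    v <- theta[seq_len(k)]
    theta <<- theta[-seq_len(k)]
    v
  }
  nm <- w$hidden * (w$hidden + w$input_dim)
  gates <- if (scope == "forget_gate") "f" else c("f", "i", "c", "o")
  for (gt in gates) {
    w[[paste0("W_", gt)]] <- matrix(take(nm), w$hidden)
    w[[paste0("b_", gt)]] <- take(w$hidden)
  }
  w
}

#' Tune LSTM gate weights with the Self-Improved Aquila Optimizer
#'
#' Second-stage refinement of a trained LSTM: the scoped gate weights
#' (forget gate by default; optionally all four gates) are flattened into a
#' search vector, bounded in `[-bound, bound]`, and minimized against the
#' validation cross-entropy. The first individual of the initial population
#' is the trained weight vector itself and the rest are Gaussian jitters of
#' it, so greedy elitism guarantees the returned weights never score worse
#' than the input on the validation fold. With `n_iter = 0` the weights are
#' returned unchanged.
#'
#' @param weights Trained [lstm_init()] weights.
#' @param x_val,y_val Validation fold (must be non-empty).
#' @param params A [siao_params()] object; `dim` and bounds are overridden.
#' @param scope `"forget_gate"` (default) or `"all_gates"`.
#' @param bound Symmetric box bound on each tuned weight (default 2).
#' @param jitter Standard deviation of initial-population perturbations.
#' @return Tuned `lstm_weights` with attributes `"tuning_trace"` (best-so-far
#'   validation loss) and `"val_loss"` (final value).
#' @export
lstm_tune <- function(weights, x_val, y_val, params,
                      scope = c("forget_gate", "all_gates"), bound = 2,
                      jitter = 0.1) {
  scope <- match.arg(scope)
  X <- as.matrix(x_val)
  if (nrow(X) == 0L || length(y_val) == 0L) {
    stop("empty validation fold", call. = FALSE)
  }
  if (params$n_iter == 0L) {
    attr(weights, "tuning_trace") <- numeric(0)
    return(weights)
  }
  theta0 <- lstm_scope_get(weights, scope)
  D <- length(theta0)
  params$dim <- D
  params$lower <- rep(-bound, D)
  params$upper <- rep(bound, D)
  if (!is.null(params$seed)) set.seed(params$seed)
  init <- rbind(theta0,
                matrix(rep(theta0, params$n_pop - 1L), params$n_pop - 1L,
                       byrow = TRUE) +
                  matrix(rnorm((params$n_pop - 1L) * D, sd = jitter),
                         params$n_pop - 1L, D))
  fitness <- function(theta) {
    cross_entropy(
      lstm_forward_batch(lstm_scope_set(weights, scope, theta), X), y_val)
  }
  params$seed <- NULL  # RNG already positioned; keep the init draw seeded
  fit <- siao_optimize(fitness, params, init = init)
  out <- lstm_scope_set(weights, scope, fit$best)
  attr(out, "tuning_trace") <- fit$history
  attr(out, "val_loss") <- fit$value
  out
}
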