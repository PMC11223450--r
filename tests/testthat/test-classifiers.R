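test_that("zero-weight LSTM outputs exactly 1/2", {
  w <- zero_lstm(hidden = 4)
  expect_equal(lstm_forward(w, c(0.3, 0.7, 0.1)), 0.5)
})

test_that("scalar LSTM matches a hand-rolled gate-by-gate computation", {
  w <- zero_lstm(hidden = 1)
  w$W_f[] <- c(0.5, -0.3)   # [h, x] weights
  w$W_i[] <- c(0.2, 0.4)
  w$W_c[] <- c(-0.6, 0.8)
  w$W_o[] <- c(0.1, 0.9)
  w$b_f <- 0.05; w$b_i <- -0.1; w$b_c <- 0.2; w$b_o <- 0
  w$w_out <- 1.5; w$b_out <- -0.25
  x <- c(0.4, -0.2, 0.9)

  sig <- function(z) 1 / (1 + exp(-z))
  h <- 0; C <- 0
  for (t in 1:3) {
    f <- sig(0.5 * h - 0.3 * x[t] + 0.05)
    i <- sig(0.2 * h + 0.4 * x[t] - 0.1)
    cb <- tanh(-0.6 * h + 0.8 * x[t] + 0.2)
    o <- sig(0.1 * h + 0.9 * x[t] + 0)
    C <- f * C + i * cb
    h <- o * tanh(C)
  }
  expect_equal(lstm_forward(w, x), sig(1.5 * h - 0.25), tolerance = 1e-12)
})

test_that("LSTM internals stay bounded and batch equals per-sample forward", {
  w <- lstm_init(hidden = 5, seed = 31)
  set.seed(32)
  X <- matrix(runif(40), 8, 5)
  batch <- aquilaheart:::lstm_forward_batch(w, X)
  single <- apply(X, 1L, function(x) lstm_forward(w, x))
  expect_equal(batch, single, tolerance = 1e-12)
  expect_true(all(batch > 0 & batch < 1))
})

test_that("LSTM forward is order sensitive", {
  toy <- make_separable(40, seed = 33)
  w <- lstm_train(NULL, toy$X, toy$y, epochs = 40, lr = 0.5, seed = 33)
  x <- c(0.9, 0.1)
  expect_false(isTRUE(all.equal(lstm_forward(w, x), lstm_forward(w, rev(x)))))
})

test_that("LSTM training fits a separable toy set deterministically", {
  toy <- make_separable(80, seed = 34)
  w <- lstm_train(NULL, toy$X, toy$y, epochs = 150, lr = 0.5, seed = 34)
  acc <- mean((aquilaheart:::lstm_forward_batch(w, toy$X) >= 0.5) == toy$y)
  expect_gte(acc, 0.95)
  loss <- attr(w, "loss")
  expect_true(all(diff(loss) <= 1e-6))   # non-increasing within tolerance

  w2 <- lstm_train(NULL, toy$X, toy$y, epochs = 150, lr = 0.5, seed = 34)
  attr(w, "loss") <- NULL; attr(w2, "loss") <- NULL
  expect_equal(w, w2)

  frozen <- lstm_init(hidden = 4, seed = 35)
  same <- lstm_train(frozen, toy$X, toy$y, epochs = 20, lr = 0)
  attr(same, "loss") <- NULL
  expect_equal(same, frozen)
})

test_that("LSTM gradients match central finite differences", {
  set.seed(36)
  X <- matrix(runif(15), 5, 3)
  y <- c(0, 1, 1, 0, 1)
  w <- lstm_init(hidden = 3, seed = 36)
  g <- aquilaheart:::lstm_grad(w, X, y)
  ce <- function(wt) aquilaheart:::cross_entropy(
    aquilaheart:::lstm_forward_batch(wt, X), y)
  eps <- 1e-6
  for (k in c("W_f", "W_i", "W_c", "W_o", "b_f", "b_c", "w_out", "b_out")) {
    idx <- 1L
    wp <- w; wm <- w
    wp[[k]][idx] <- wp[[k]][idx] + eps
    wm[[k]][idx] <- wm[[k]][idx] - eps
    fd <- (ce(wp) - ce(wm)) / (2 * eps)
    expect_equal(g[[k]][idx], fd, tolerance = 1e-4)
  }
})

test_that("SIAO tuning never degrades the validation loss", {
  toy <- make_separable(60, seed = 37)
  w <- lstm_train(NULL, toy$X, toy$y, epochs = 60, lr = 0.5, seed = 37)
  pre <- aquilaheart:::cross_entropy(
    aquilaheart:::lstm_forward_batch(w, toy$X), toy$y)

  untouched <- lstm_tune(w, toy$X, toy$y,
                         siao_params(dim = 1, n_pop = 4, n_iter = 0, seed = 1))
  expect_equal(unclass(untouched)[c("W_f", "b_f")],
               unclass(w)[c("W_f", "b_f")])

  tuned <- lstm_tune(w, toy$X, toy$y,
                     siao_params(dim = 1, n_pop = 6, n_iter = 10, seed = 38))
  expect_lte(attr(tuned, "val_loss"), pre + 1e-12)
  expect_error(lstm_tune(w, toy$X[0, ], numeric(0),
                         siao_params(dim = 1, n_pop = 4, n_iter = 5)),
               "empty validation")
})

test_that("tuning recovers a corrupted forget gate", {
  toy <- make_separable(60, seed = 39)
  w <- lstm_train(NULL, toy$X, toy$y, epochs = 80, lr = 0.5, seed = 39)
  acc <- function(wt) mean((aquilaheart:::lstm_forward_batch(wt, toy$X) >= 0.5)
                           == toy$y)
  base_acc <- acc(w)
  recovered <- sapply(1:5, function(s) {
    set.seed(s + 100)
    bad <- w
    bad$W_f <- bad$W_f + matrix(rnorm(length(bad$W_f), sd = 1.5),
                                nrow(bad$W_f))
    tuned <- lstm_tune(bad, toy$X, toy$y,
                       siao_params(dim = 1, n_pop = 10, n_iter = 40,
                                   seed = s))
    acc(tuned)
  })
  expect_gte(median(recovered), base_acc - 0.05)
})

test_that("QNN hidden activations follow the multi-level sigmoid form", {
  p <- qnn_init(2, n_hidden = 1, n_s = 1, beta = 1, seed = 41)
  p$W[] <- 0; p$theta[] <- 0
  expect_equal(qnn_hidden(p, c(0.3, 0.7)), 0.5)   # sigmoid(0)

  # n_s = 3 direct summation oracle at W.x = 0
  p3 <- qnn_init(2, n_hidden = 1, n_s = 3, beta = 5, seed = 42)
  p3$W[] <- 0
  p3$theta[1, ] <- c(-1, 0, 1)
  sig <- function(z) 1 / (1 + exp(-z))
  expect_equal(qnn_hidden(p3, c(0.2, 0.4)),
               (sig(5 * 1) + sig(0) + sig(-5 * 1)) / 3, tolerance = 1e-12)
})

test_that("single-level QNN is equivalent to a plain sigmoid MLP", {
  set.seed(43)
  p <- qnn_init(4, n_hidden = 6, n_s = 1, beta = 1, seed = 43)
  p$theta[] <- 0
  sig <- function(z) 1 / (1 + exp(-z))
  mlp <- function(x) sig(sum(p$v * sig(as.numeric(p$W %*% x))) + p$b_out)
  X <- matrix(rnorm(400), 100, 4)
  diffs <- abs(qnn_forward(p, X) - apply(X, 1, mlp))
  expect_lt(max(diffs), 1e-12)
})

test_that("QNN analytic gradients match central finite differences", {
  set.seed(44)
  X <- matrix(runif(20), 5, 4)
  y <- c(0, 1, 0, 1, 1)
  p <- qnn_init(4, n_hidden = 3, n_s = 3, beta = 1.5, seed = 44)
  g <- aquilaheart:::qnn_grad(p, X, y)
  ce <- function(pp) aquilaheart:::cross_entropy(
    aquilaheart:::qnn_forward_batch(pp, X), y)
  eps <- 1e-6
  for (k in c("W", "theta", "v", "b_out")) {
    for (idx in seq_along(p[[k]])) {
      pp <- p; pm <- p
      pp[[k]][idx] <- pp[[k]][idx] + eps
      pm[[k]][idx] <- pm[[k]][idx] - eps
      fd <- (ce(pp) - ce(pm)) / (2 * eps)
      expect_equal(g[[k]][idx], fd, tolerance = 1e-4)
    }
  }
})

test_that("QNN training fits a separable toy set and honors lr = 0", {
  toy <- make_separable(80, seed = 45)
  p <- qnn_train(NULL, toy$X, toy$y, epochs = 150, lr = 0.5, seed = 45)
  acc <- mean((qnn_forward(p, toy$X) >= 0.5) == toy$y)
  expect_gte(acc, 0.95)
  expect_true(all(apply(p$theta, 1, function(r) !is.unsorted(r))))

  frozen <- qnn_init(2, seed = 46)
  same <- qnn_train(frozen, toy$X, toy$y, epochs = 10, lr = 0)
  attr(same, "loss") <- NULL
  expect_equal(same, frozen)
})

test_that("hybrid prediction averages probabilities with a >= tie rule", {
  toy <- make_separable(40, seed = 47)
  lw <- lstm_train(NULL, toy$X, toy$y, epochs = 60, lr = 0.5, seed = 47)
  qp <- qnn_train(NULL, toy$X, toy$y, epochs = 60, lr = 0.5, seed = 47)
  m <- hybrid_model(lw, qp)
  pred <- predict(m, toy$X)
  expect_equal(pred$probability, (pred$p_lstm + pred$p_qnn) / 2)
  expect_true(all(pred$probability >= 0 & pred$probability <= 1))
  expect_equal(pred$label, as.integer(pred$probability >= 0.5))

  # arithmetic on the stated example and the tie convention
  expect_equal((0.8 + 0.6) / 2, 0.7)
  zero <- hybrid_model(zero_lstm(3), local({
    q <- qnn_init(2, n_hidden = 2, seed = 48); q$W[] <- 0; q$theta[] <- 0
    q$v[] <- 0; q$b_out <- 0; q
  }))
  tie <- predict(zero, matrix(c(0.5, 0.5), 1))
  expect_equal(tie$probability, 0.5)
  expect_equal(tie$label, 1L)   # tie goes to the positive class

  # identical submodel outputs: the mean is idempotent
  expect_equal(tie$probability, tie$p_lstm)
})

test_that("hybrid models round-trip through JSON", {
  toy <- make_separable(30, seed = 49)
  lw <- lstm_train(NULL, toy$X, toy$y, epochs = 20, lr = 0.5, seed = 49)
  qp <- qnn_train(NULL, toy$X, toy$y, epochs = 20, lr = 0.5, seed = 49)
  m <- hybrid_model(lw, qp, columns = c("x1", "x2"))
  path <- tempfile(fileext = ".json")
  save_hybrid_model(m, path)
  m2 <- load_hybrid_model(path)
  X <- matrix(runif(10), 5, 2)
  expect_equal(predict(m2, X), predict(m, X), tolerance = 1e-12)
})
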