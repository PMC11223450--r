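# Shared fixtures, all built in code at test time.

# Write a tiny processed-Cleveland-style file (14 comma-separated columns).
write_cleveland_fixture <- function(lines, path = tempfile(fileext = ".data")) {
  writeLines(lines, path)
  path
}

cleveland_row <- function(label = 0, fill = 1, n_cols = 14) {
  paste(c(rep(fill, n_cols - 1), label), collapse = ",")
}

# A linearly separable two-feature toy set in [0, 1]^2.
make_separable <- function(n = 80, seed = 1) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  x1 <- runif(n, ifelse(y == 1, 0.6, 0.0), ifelse(y == 1, 1.0, 0.4))
  x2 <- runif(n, ifelse(y == 1, 0.55, 0.05), ifelse(y == 1, 0.95, 0.45))
  list(X = cbind(x1, x2), y = y)
}

# Zeroed LSTM weights of a given hidden size.
zero_lstm <- function(hidden = 4, input_dim = 1) {
  w <- lstm_init(hidden = hidden, input_dim = input_dim, seed = 1)
  for (k in c("W_f", "W_i", "W_c", "W_o", "b_f", "b_i", "b_c", "b_o",
              "w_out")) {
    w[[k]][] <- 0
  }
  w$b_out <- 0
  w
}
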