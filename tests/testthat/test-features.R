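test_that("central tendency matches closed forms on symmetric data", {
  ct <- central_tendency(c(1, 2, 3))
  expect_equal(ct$am, 2)
  expect_equal(ct$median, 2)
  expect_equal(ct$midrange, 2)
  # quartile-based fields undefined below n = 4
  expect_true(is.na(ct$interquartile_mean))
  expect_true(is.na(ct$midhinge))
  expect_true(is.na(ct$trimean))

  ct2 <- central_tendency(c(2, 8))
  expect_equal(ct2$gm, 4)        # sqrt(2 * 8)
  expect_equal(ct2$hm, 3.2)      # 2 / (1/2 + 1/8)

  # gm/hm undefined on nonpositive data
  ct3 <- central_tendency(c(-1, 0, 2, 5))
  expect_true(is.na(ct3$gm) && is.na(ct3$hm))
})

test_that("interquartile mean equals the direct summation oracle", {
  # brute-force summation over sorted indices n/4+1 .. 3n/4
  oracle <- function(x) {
    s <- sort(x)
    n <- length(x)
    (2 / n) * sum(s[(floor(n / 4) + 1):floor(3 * n / 4)])
  }
  expect_equal(central_tendency(1:8)$interquartile_mean,
               (2 / 8) * (3 + 4 + 5 + 6))  # = 4.5, indices 3..6
  set.seed(11)
  for (n in c(4, 8, 12, 13, 20)) {
    x <- runif(n)
    expect_equal(central_tendency(x)$interquartile_mean, oracle(x))
  }
})

test_that("dispersion descriptors match closed forms and the pair oracle", {
  d <- dispersion_stats(c(1, 5))
  expect_equal(d$range, 4)
  expect_equal(d$aad, 2)

  # P1 = 1, P3 = 3 gives QCD = (3 - 1) / (3 + 1)
  d2 <- dispersion_stats(c(1, 1, 1, 3, 3, 3))
  expect_equal(d2$qcd, 0.5)

  # exhaustive pair-enumeration oracle for the mean absolute difference
  mad_oracle <- function(x) {
    tot <- 0
    for (i in seq_along(x)) for (j in seq_along(x)) tot <- tot + abs(x[i] - x[j])
    tot / length(x)^2
  }
  expect_equal(dispersion_stats(c(0, 1, 2))$mad, 8 / 9)
  set.seed(12)
  x <- rnorm(15)
  dd <- dispersion_stats(x)
  expect_equal(dd$mad, mad_oracle(x))
  expect_equal(dd$gini, dd$rmd / 2)

  # undefined flags
  expect_true(is.na(dispersion_stats(c(-1, 1))$cv))
})

test_that("descriptors are order invariant", {
  set.seed(13)
  for (k in 1:5) {
    x <- runif(10)
    expect_equal(central_tendency(x), central_tendency(rev(x)))
    expect_equal(dispersion_stats(x), dispersion_stats(rev(x)))
  }
})

test_that("four-level discretization follows the boundary convention", {
  expect_equal(discretize_levels(c(0.1, 0.3, 1.0, 0.0)), c(1L, 2L, 4L, 1L))
  # upper endpoints are inclusive
  expect_equal(discretize_levels(c(0.25, 0.5, 0.75)), c(1L, 2L, 3L))
  expect_error(discretize_levels(c(0.5, 1.2)), "0, 1")
})

test_that("qualitative variation hits the zero- and maximal-variation limits", {
  lo <- qualitative_variation(rep(2L, 10))
  expect_equal(lo$modvr, 0)
  expect_equal(lo$hrel, 0)
  expect_equal(lo$berger_parker, 1)

  hi <- qualitative_variation(rep(1:4, each = 5))
  expect_equal(hi$modvr, 1)
  expect_equal(hi$hrel, 1)
  expect_equal(hi$simpson_iqv, 1)

  expect_error(qualitative_variation(integer(0)), "empty")
})

test_that("qualitative variation matches the textbook-formula oracle", {
  # counts (2, 1, 1, 0): every index evaluated from its definition
  lev <- c(1L, 1L, 2L, 3L)
  f <- c(2, 1, 1, 0); n <- 4; K <- 4; fm <- 2
  p <- f / n
  pairdiff <- sum(abs(c(f[1]-f[2], f[1]-f[3], f[1]-f[4],
                        f[2]-f[3], f[2]-f[4], f[3]-f[4])))
  qv <- qualitative_variation(lev)
  expect_equal(qv$modvr, K * (n - fm) / (n * (K - 1)))           # 2/3
  expect_equal(qv$avdev, 1 - sum(abs(f - n / K)) / (2 * (n / K) * (K - 1)))
  expect_equal(qv$mndif, 1 - pairdiff / (n * (K - 1)))           # 1/2
  expect_equal(qv$b_index, 1 - sqrt(1 - prod(f * K / n)^(2 / K)))  # 0
  expect_equal(qv$hrel, -sum(p[p > 0] * log2(p[p > 0])) / log2(K))
  expect_equal(qv$simpson_iqv, (K / (K - 1)) * (1 - sum(p^2)))   # 5/6
  expect_equal(qv$berger_parker, 0.5)
  expect_equal(qv$shannon_wiener, -sum(p[p > 0] * log(p[p > 0])))
})

test_that("qualitative variation is invariant under category relabeling", {
  set.seed(14)
  for (k in 1:5) {
    lev <- sample(1:4, 30, replace = TRUE)
    perm <- sample(1:4)
    expect_equal(qualitative_variation(lev), qualitative_variation(perm[lev]),
                 ignore_attr = TRUE)
  }
})

test_that("symmetric uncertainty endpoints are exact", {
  q <- c(0, 0, 1, 1, 0, 1)
  expect_equal(symmetric_uncertainty(q, q), 1)
  # exactly uniform 2x2 joint: independence
  expect_equal(symmetric_uncertainty(c(1, 1, 2, 2), c(0, 1, 0, 1)), 0)
  expect_error(symmetric_uncertainty(1:3, 1:4), "length")
})

test_that("symmetric uncertainty matches the plug-in oracle and is symmetric", {
  # joint counts [[3,1],[1,3]]: frozen value from an exact plug-in evaluation
  q <- rep(c(1, 2), each = 4)
  p <- c(0, 0, 0, 1, 0, 1, 1, 1)
  expect_equal(symmetric_uncertainty(q, p), 0.18872187554086717, tolerance = 1e-12)
  set.seed(15)
  for (k in 1:5) {
    a <- sample(1:4, 40, replace = TRUE)
    b <- sample(0:1, 40, replace = TRUE)
    expect_equal(symmetric_uncertainty(a, b), symmetric_uncertainty(b, a))
    expect_gte(symmetric_uncertainty(a, b), 0)
    expect_lte(symmetric_uncertainty(a, b), 1)
  }
})

test_that("histogram entropy obeys the scale law", {
  set.seed(16)
  x <- rnorm(1e5)
  gap <- entropy_continuous(exp(1) * x) - entropy_continuous(x)
  expect_lt(abs(gap - 1), 0.1)
})

test_that("assembled features have the documented arity and SU scores", {
  set.seed(17)
  n <- 40
  d <- tibble::as_tibble(matrix(runif(n * 12), n, 12), .name_repair = "minimal")
  names(d) <- paste0("a", 1:12)
  d$a13 <- rep(c(0, 1), n / 2)   # attribute identical to the class
  d$y <- rep(c(0L, 1L), n / 2)
  fs <- assemble_features(d)
  # 13 original + 12 CT + 9 D + 8 QV
  expect_equal(ncol(fs$features), 13L + 12L + 9L + 8L)
  expect_equal(nrow(fs$su), 13L)
  expect_equal(fs$su$su[fs$su$attribute == "a13"], 1)
  expect_setequal(unique(fs$family$family), c("original", "CT", "D", "QV"))

  # a constant row has zero spread in every derived dispersion feature
  dc <- d
  dc[1, paste0("a", 1:12)] <- 0.5
  dc[1, "a13"] <- 0.5
  fsc <- assemble_features(dc)
  expect_equal(fsc$features$ct_sd[1], 0)
  expect_equal(fsc$features$d_range[1], 0)
  expect_equal(fsc$features$d_entropy[1], 0)
})

test_that("assembling fewer than 4 attributes drops quartile descriptors", {
  d <- tibble::tibble(a = runif(10), b = runif(10), y = rep(0:1, 5))
  expect_warning(fs <- assemble_features(d), "fewer than 4")
  expect_false("ct_trimean" %in% names(fs$features))
  expect_true("ct_am" %in% names(fs$features))
})
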