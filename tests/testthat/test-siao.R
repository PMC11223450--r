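test_that("Mantegna sigma matches the independent Gamma evaluation", {
  # frozen from a 30-digit evaluation of the closed form at K = 1.5
  expect_equal(levy_sigma(1.5), 0.696574502557697, tolerance = 1e-9)
})

test_that("Levy flight scales, vanishes at s = 0, and is seed-deterministic", {
  set.seed(21)
  expect_equal(levy_flight(6, s = 0), rep(0, 6))
  set.seed(22)
  a <- levy_flight(10)
  set.seed(22)
  b <- levy_flight(10)
  expect_identical(a, b)
  expect_true(all(is.finite(a)))
})

test_that("spiral terms satisfy the radius identity", {
  sp <- spiral_terms(8, omega = 0.005, r1 = 3)
  r <- 3 + 0.00565 * (1:8)
  expect_equal(sp$x^2 + sp$y^2, r^2)
  # omega = 0 pins the angle at 3*pi/2: x = -r, y = 0
  sp0 <- spiral_terms(4, omega = 0, r1 = 2)
  expect_equal(sp0$x, -(2 + 0.00565 * (1:4)))
  expect_equal(sp0$y, rep(0, 4), tolerance = 1e-12)
  expect_error(spiral_terms(4, r1 = 30), "1, 20")
})

test_that("logistic map iterates stay in [0,1] and fixed points reseed", {
  lr <- logistic_rand(0.2, mu = 4)
  expect_equal(lr$value, 0.64)           # 4 * 0.2 * 0.8
  # scaling into bounds per the caller contract
  expect_equal(0 + lr$value * (10 - 0), 6.4)
  state <- 0.3
  vals <- numeric(1000)
  for (i in 1:1000) {
    out <- logistic_rand(state, 4)
    vals[i] <- out$value
    state <- out$state
  }
  expect_true(all(vals >= 0 & vals <= 1))
  expect_warning(logistic_rand(0.75, mu = 4), "fixed point")  # 1 - 1/4
})

test_that("candidate steps reduce to their algebraic special cases", {
  best <- c(0.4, 0.8); m <- c(0.1, 0.3)
  # t = 0, rand = 1: X1 collapses to the population mean
  expect_equal(siao_step_x1(best, m, 0, 100, rand = 1), m)
  # t = T, rand = 0: the (1 - t/T) factor vanishes
  expect_equal(siao_step_x1(best, m, 100, 100, rand = 0), m)
  # zero Levy step and zero rand: X2 returns the random member
  xr <- c(0.9, 0.2)
  sp <- spiral_terms(2)
  expect_equal(siao_step_x2(best, xr, levy = c(0, 0), sp, rand = 0), xr)
  # X3 formula oracle
  r <- c(0.3, 0.6)
  expect_equal(
    siao_step_x3(best, m, 0.1, 0.1, c(0, 0), c(1, 1), 0.5, r),
    (best - m) * 0.1 - r + (1 * 0.5 + 0) * 0.1
  )
  # quality function and movement parameters
  expect_equal(siao_qf(7, 100, rand = 0.5), 1)   # zero exponent
  expect_equal(siao_g2(0, 50), 2)
  expect_equal(siao_g2(50, 50), 0)
  expect_true(all(abs(siao_g1(runif(100))) <= 1))
  # X1 general case against a one-line formula oracle
  set.seed(23)
  rand <- runif(2)
  expect_equal(siao_step_x1(best, m, 10, 40, rand),
               best * (1 - 10 / 40) + (m - best * rand))
})

test_that("optimizer history is non-increasing and flat on constants", {
  const <- siao_optimize(function(x) 3.5,
                         siao_params(dim = 2, n_pop = 5, n_iter = 20, seed = 1))
  expect_equal(const$value, 3.5)
  expect_equal(const$history, rep(3.5, 20))

  for (s in 1:5) {
    fit <- siao_optimize(function(x) sum((x - 0.3)^2),
                         siao_params(dim = 3, lower = -2, upper = 2,
                                     n_pop = 8, n_iter = 60, seed = s))
    expect_true(all(diff(fit$history) <= 0))
    expect_true(all(fit$best >= -2 & fit$best <= 2))
  }
})

test_that("optimizer contracts: zero iterations, rejection, determinism", {
  f <- function(x) sum(x^2)
  none <- siao_optimize(f, siao_params(dim = 2, n_pop = 4, n_iter = 0, seed = 2))
  expect_length(none$history, 0L)
  expect_equal(none$n_evals, 4L)

  # non-finite fitness rejects the candidate but the run continues
  spiky <- function(x) if (x[1] > 0) NaN else sum(x^2)
  fit <- siao_optimize(spiky, siao_params(dim = 2, lower = -1, upper = 1,
                                          n_pop = 6, n_iter = 30, seed = 3))
  expect_gt(fit$n_rejected, 0L)
  expect_true(is.finite(fit$value))

  a <- siao_optimize(f, siao_params(dim = 3, lower = -1, upper = 1,
                                    n_pop = 6, n_iter = 25, seed = 9))
  b <- siao_optimize(f, siao_params(dim = 3, lower = -1, upper = 1,
                                    n_pop = 6, n_iter = 25, seed = 9))
  expect_identical(a$best, b$best)
  expect_identical(a$history, b$history)
})

test_that("phase schedule: exploration steps only in the first two thirds", {
  fit <- siao_optimize(function(x) sum(x^2),
                       siao_params(dim = 2, lower = -1, upper = 1,
                                   n_pop = 5, n_iter = 30, seed = 4),
                       phase_log = TRUE)
  n_explore_iters <- sum(seq_len(30) <= (2 / 3) * 30)   # 20 iterations
  head_phases <- fit$phases[seq_len(n_explore_iters * 5)]
  tail_phases <- fit$phases[-seq_len(n_explore_iters * 5)]
  expect_true(all(head_phases %in% c("X1", "X2")))
  expect_true(all(tail_phases %in% c("X3", "X4")))
})

test_that("disabling chaos and crossover reduces to the baseline optimizer", {
  f <- function(x) sum((x - 0.2)^2)
  mk <- function(chaos, crossover) {
    siao_optimize(f, siao_params(dim = 3, lower = -1, upper = 1, n_pop = 6,
                                 n_iter = 30, seed = 11, chaos = chaos,
                                 crossover = crossover))
  }
  siao <- mk(TRUE, TRUE)
  ao <- mk(FALSE, FALSE)
  # identical RNG stream until the first expanded-exploitation step, so the
  # exploration phase history coincides exactly
  explore <- seq_len(20)
  expect_identical(siao$history[explore], ao$history[explore])
  # crossover adds evaluations; the baseline uses fewer
  expect_lt(ao$n_evals, siao$n_evals)
  expect_true(all(diff(ao$history) <= 0))
})

test_that("cardinality-only selection returns a singleton", {
  fsel <- select_features(matrix(0, 2, 6), function(sel) 0,
                          siao_params(dim = 6, n_pop = 10, n_iter = 40,
                                      seed = 5),
                          weights = c(err = 0, card = 1, su = 0))
  expect_length(fsel$selected, 1L)  # 1/C beats the empty-subset fitness of 1
  expect_length(fsel$trace, 40L)
})

test_that("selection fitness trace is monotone and errors reject candidates", {
  flaky <- function(sel) {
    if (length(sel) > 4) stop("boom")
    length(sel) / 6
  }
  fsel <- select_features(matrix(0, 2, 6), flaky,
                          siao_params(dim = 6, n_pop = 8, n_iter = 30,
                                      seed = 6))
  expect_true(all(diff(fsel$trace) <= 0))
  expect_lte(length(fsel$selected), 4L)
})
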