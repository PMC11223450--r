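#' Parameters for the (Self-Improved) Aquila Optimizer
#'
#' Bundles the control parameters of the eagle-hunting metaheuristic. The
#' exploitation adjustments `alpha` and `delta` default to 0.1, the spiral
#' angle rate `omega` to 0.005, the spiral cycle count `r1` is drawn from
#' `[1, 20]`, and the Levy-flight stability index and scale default to
#' `K = 1.5`, `s = 0.01`. The self-improved variant adds a logistic-map
#' chaotic random number (parameter `logistic_mu`, default 4) in the expanded
#' exploitation step and arithmetic crossover of two random solutions;
#' setting `chaos = FALSE` and `crossover = FALSE` recovers the baseline
#' optimizer.
#'
#' @param dim Problem dimensionality.
#' @param lower,upper Bounds, scalars or length-`dim` vectors.
#' @param n_pop Population size `N` (>= 2).
#' @param n_iter Iteration budget `T` (>= 0; 0 evaluates only the initial
#'   population).
#' @param alpha,delta Exploitation adjustment parameters.
#' @param omega Spiral angle rate.
#' @param r1_range Range of the spiral search-cycle number.
#' @param levy_K Levy stability index in (1, 2].
#' @param levy_s Levy step scale.
#' @param logistic_mu Logistic-map parameter.
#' @param chaos Use the chaotic logistic-map draw in expanded exploitation?
#' @param crossover Perform arithmetic crossover after expanded exploitation?
#' @param seed Optional integer seed.
#' @return An object of class `siao_params`.
#' @export
siao_params <- function(dim, lower = 0, upper = 1, n_pop = 20L, n_iter = 100L,
                        alpha = 0.1, delta = 0.1, omega = 0.005,
                        r1_range = c(1, 20), levy_K = 1.5, levy_s = 0.01,
                        logistic_mu = 4, chaos = TRUE, crossover = TRUE,
                        seed = NULL) {
  stopifnot(dim >= 1, n_pop >= 2, n_iter >= 0,
            levy_K > 1, levy_K <= 2, logistic_mu > 0)
  lower <- rep_len(lower, dim)
  upper <- rep_len(upper, dim)
  if (any(lower >= upper)) stop("lower must be < upper elementwise",
                                call. = FALSE)
  structure(
    list(dim = dim, lower = lower, upper = upper, n_pop = as.integer(n_pop),
         n_iter = as.integer(n_iter), alpha = alpha, delta = delta,
         omega = omega, r1_range = r1_range, levy_K = levy_K, levy_s = levy_s,
         logistic_mu = logistic_mu, chaos = chaos, crossover = crossover,
         seed = seed),
    class = "siao_params"
  )
}

#' Mantegna Levy-flight standard deviation
#'
#' Closed-form sigma of the Mantegna scheme,
#' `sigma = (Gamma(1+K) sin(pi K / 2) / (Gamma((1+K)/2) K 2^((K-1)/2)))^(1/K)`.
#'
#' @param K Stability index in (1, 2].
#' @return A positive scalar (about 0.6966 at `K = 1.5`).
#' @export
levy_sigma <- function(K = 1.5) {
  (gamma(1 + K) * sin(pi * K / 2) /
     (gamma((1 + K) / 2) * K * 2^((K - 1) / 2)))^(1 / K)
}

#' Levy-flight step vector
#'
#' Heavy-tailed random step, one draw per dimension:
#' `s * u * sigma / |v|^(1/K)` with `u, v` standard normal and `sigma` from
#' [levy_sigma()]. Draws of `v` too close to zero are resampled so the step
#' stays finite.
#'
#' @param dim Number of dimensions.
#' @param K Stability index in (1, 2].
#' @param s Step scale.
#' @return Numeric vector of length `dim`.
#' @export
levy_flight <- function(dim, K = 1.5, s = 0.01) {
  u <- rnorm(dim)
  v <- rnorm(dim)
  while (any(abs(v) < 1e-300)) {
    v[abs(v) < 1e-300] <- rnorm(sum(abs(v) < 1e-300))
  }
  s * u * levy_sigma(K) / abs(v)^(1 / K)
}

#' Spiral coordinates of the contour-flight search
#'
#' The logarithmic-spiral terms used in narrowed exploration:
#' `r = r1 + 0.00565 * D1`, `phi = -omega * D1 + 3 pi / 2`,
#' `x = r sin(phi)`, `y = r cos(phi)` with `D1 = 1..dim`.
#'
#' @param dim Number of dimensions.
#' @param omega Angle rate (default 0.005).
#' @param r1 Search-cycle number in `[1, 20]`.
#' @return A list with numeric vectors `x` and `y`.
#' @export
spiral_terms <- function(dim, omega = 0.005, r1 = 10) {
  if (r1 < 1 || r1 > 20) stop("r1 must lie in [1, 20]", call. = FALSE)
  D1 <- seq_len(dim)
  r <- r1 + 0.00565 * D1
  phi <- -omega * D1 + 3 * pi / 2
  list(x = r * sin(phi), y = r * cos(phi))
}

#' Logistic-map chaotic random number
#'
#' One iterate of the logistic map `v = mu * state * (1 - state)`. States at
#' (or numerically indistinguishable from) the map's fixed points `0` and
#' `1 - 1/mu`, or outside `(0, 1)`, are reseeded uniformly with a warning.
#' Callers scale the value into bounds as `lower + v * (upper - lower)`.
#'
#' @param state Current map state in (0, 1).
#' @param mu Map parameter (default 4, the fully chaotic regime).
#' @return A list with `value` in `[0, 1]` and the `state` for the next call
#'   (equal to `value`, reseeded when it hits a fixed point).
#' @export
logistic_rand <- function(state, mu = 4) {
  fixed <- c(0, 1, max(0, 1 - 1 / mu))
  if (any(abs(state - fixed) < 1e-12) || state < 0 || state > 1) {
    warning("logistic-map state at a fixed point; reseeding", call. = FALSE)
    state <- runif(1, 0.05, 0.95)
  }
  value <- mu * state * (1 - state)
  next_state <- value
  if (any(abs(next_state - fixed) < 1e-12)) next_state <- runif(1, 0.05, 0.95)
  list(value = value, state = next_state)
}

# --- candidate-generation steps (pure formula evaluations) -----------------

#' Candidate-generation steps of the Aquila search
#'
#' Pure evaluations of the four position-update rules, exposed so each
#' formula can be exercised deterministically. Random quantities are
#' arguments: scalars where the rule requires a scalar (`qf_rand`, `g1`,
#' `g2`), per-dimension vectors elsewhere.
#'
#' * `siao_step_x1()` expanded exploration (high soar):
#'   `x_best * (1 - t/T) + (x_mean - x_best * rand)`;
#' * `siao_step_x2()` narrowed exploration (contour flight with Levy step):
#'   `x_best * levy + x_rand + (y - x) * rand`;
#' * `siao_step_x3()` expanded exploitation (low-flight descent):
#'   `(x_best - x_mean) * alpha - rand + ((upper - lower) * chaos_value +
#'   lower) * delta`;
#' * `siao_step_x4()` narrowed exploitation (walk-and-grab):
#'   `QF * x_best - g1 * x * rand - g2 * levy + rand * g1` with
#'   `QF = t^((2 qf_rand - 1)/(1 - T)^2)`, `g1 = 2 rand - 1`,
#'   `g2 = 2 (1 - t/T)`.
#'
#' @param x_best Best position found so far.
#' @param x_mean Population mean position.
#' @param x Current position.
#' @param x_rand A randomly chosen population member.
#' @param t,t_max Current iteration and iteration budget.
#' @param rand Per-dimension uniform draws in `[0, 1]`.
#' @param levy Levy-flight step vector ([levy_flight()]).
#' @param spiral Spiral terms ([spiral_terms()]).
#' @param alpha,delta Exploitation adjustments.
#' @param lower,upper Bounds vectors.
#' @param chaos_value Chaotic draw in `[0, 1]` ([logistic_rand()]).
#' @param qf_rand Scalar uniform draw for the quality function.
#' @param g1,g2 Scalar movement and flight-slope parameters.
#' @return The unclamped candidate position vector.
#' @name siao_steps
NULL

#' @rdname siao_steps
#' @export
siao_step_x1 <- function(x_best, x_mean, t, t_max, rand) {
  x_best * (1 - t / t_max) + (x_mean - x_best * rand)
}

#' @rdname siao_steps
#' @export
siao_step_x2 <- function(x_best, x_rand, levy, spiral, rand) {
  x_best * levy + x_rand + (spiral$y - spiral$x) * rand
}

#' @rdname siao_steps
#' @export
siao_step_x3 <- function(x_best, x_mean, alpha, delta, lower, upper,
                         chaos_value, rand) {
  (x_best - x_mean) * alpha - rand + ((upper - lower) * chaos_value + lower) * delta
}

#' @rdname siao_steps
#' @export
siao_step_x4 <- function(x_best, x, t, t_max, qf_rand, g1, g2, levy, rand) {
  qf <- t^((2 * qf_rand - 1) / (1 - t_max)^2)
  qf * x_best - (g1 * x * rand) - g2 * levy + rand * g1
}

#' Quality function and movement parameters of narrowed exploitation
#'
#' `siao_qf(t, t_max, rand) = t^((2 rand - 1)/(1 - t_max)^2)`;
#' `siao_g1(rand) = 2 rand - 1` (prey-tracking movement, in `[-1, 1]`);
#' `siao_g2(t, t_max) = 2 (1 - t/t_max)` (flight slope, decreasing 2 -> 0).
#'
#' @inheritParams siao_steps
#' @name siao_schedule
NULL

#' @rdname siao_schedule
#' @export
siao_qf <- function(t, t_max, rand) t^((2 * rand - 1) / (1 - t_max)^2)

#' @rdname siao_schedule
#' @export
siao_g1 <- function(rand) 2 * rand - 1

#' @rdname siao_schedule
#' @export
siao_g2 <- function(t, t_max) 2 * (1 - t / t_max)

clamp <- function(x, lower, upper) pmin(upper, pmax(lower, x))

#' Minimize a function with the Self-Improved Aquila Optimizer
#'
#' Population search with four phases: for iterations `t <= (2/3) T` a fair
#' coin picks expanded (`X1`) or narrowed (`X2`) exploration; afterwards it
#' picks expanded (`X3`) or narrowed (`X4`) exploitation. Candidate
#' coordinates that leave the search box are resampled uniformly inside the
#' bounds (several update rules take steps larger than small boxes, and hard
#' clamping would pin candidates to the corners); every emitted position
#' therefore lies within the bounds. Candidates are accepted greedily
#' against both the individual's current position and the global best, so
#' the best-so-far trace is non-increasing. In the self-improved variant the `X3` step draws its
#' bound-scaled random number from a logistic chaotic map, and after each
#' `X3` acceptance test an arithmetic crossover of two random distinct
#' solutions (`lambda a + (1-lambda) b` and its mirror, `lambda ~ U(0,1)`)
#' greedily replaces the parents when fitter.
#'
#' Non-finite fitness values (including errors raised by `fitness`, which are
#' caught) reject the candidate and are counted in `n_rejected`.
#'
#' @param fitness Function mapping a length-`dim` numeric vector to a scalar.
#' @param params A [siao_params()] object.
#' @param init Optional matrix (`n_pop x dim`) of initial positions (clamped
#'   into the bounds); default uniform random in the bounds.
#' @param phase_log Record which phase generated each candidate?
#' @return An object of class `siao_fit`: list with `best` (position),
#'   `value`, `history` (best-so-far per iteration, length `n_iter`),
#'   `n_evals`, `n_rejected`, and optionally `phases`.
#' @examples
#' fit <- siao_optimize(function(x) sum(x^2),
#'                      siao_params(dim = 2, lower = -5, upper = 5,
#'                                  n_pop = 10, n_iter = 50, seed = 1))
#' fit$value
#' @export
siao_optimize <- function(fitness, params, init = NULL, phase_log = FALSE) {
  stopifnot(inherits(params, "siao_params"))
  p <- params
  if (!is.null(p$seed)) set.seed(p$seed)
  N <- p$n_pop; D <- p$dim; Tm <- p$n_iter
  lb <- p$lower; ub <- p$upper

  eval_fit <- function(x) {
    f <- tryCatch(fitness(x), error = function(e) NaN)
    if (!is.numeric(f) || length(f) != 1L || !is.finite(f)) NaN else f
  }

  if (is.null(init)) {
    X <- matrix(runif(N * D), N, D)
    X <- sweep(sweep(X, 2L, ub - lb, "*"), 2L, lb, "+")
  } else {
    stopifnot(is.matrix(init), nrow(init) == N, ncol(init) == D)
    X <- pmin(matrix(ub, N, D, byrow = TRUE),
              pmax(matrix(lb, N, D, byrow = TRUE), init))
  }
  fit <- apply(X, 1L, eval_fit)
  n_rejected <- sum(!is.finite(fit))
  fit[!is.finite(fit)] <- Inf
  n_evals <- N
  ib <- which.min(fit)
  best <- X[ib, ]; f_best <- fit[ib]

  chaos_state <- runif(1, 0.05, 0.95)
  history <- numeric(Tm)
  phases <- if (phase_log) character(0) else NULL

  # Bound repair: coordinates that leave the box are resampled uniformly
  # inside it. Several update rules take steps larger than the box (the
  # spiral term alone has magnitude >= r1 >= 1), so hard clamping would pin
  # whole candidates to the corners and stall exploration on small domains;
  # uniform resampling keeps every emitted position inside the bounds while
  # preserving search diversity.
  repair <- function(x) {
    out <- x < lb | x > ub
    if (any(out)) x[out] <- lb[out] + runif(sum(out)) * (ub - lb)[out]
    x
  }

  accept <- function(i, cand) {
    cand <- repair(cand)
    f <- eval_fit(cand)
    n_evals <<- n_evals + 1L
    if (!is.finite(f)) {
      n_rejected <<- n_rejected + 1L
      return(invisible(NULL))
    }
    if (f < fit[i]) {
      X[i, ] <<- cand; fit[i] <<- f
    }
    if (f < f_best) {
      best <<- cand; f_best <<- f
    }
    invisible(NULL)
  }

  for (t in seq_len(Tm)) {
    x_mean <- colMeans(X)
    explore <- t <= (2 / 3) * Tm
    for (i in seq_len(N)) {
      if (explore) {
        if (runif(1) <= 0.5) {
          if (phase_log) phases <- c(phases, "X1")
          cand <- siao_step_x1(best, x_mean, t, Tm, runif(D))
        } else {
          if (phase_log) phases <- c(phases, "X2")
          xr <- X[sample(setdiff(seq_len(N), i), 1L), ]
          r1 <- runif(1, p$r1_range[1], p$r1_range[2])
          cand <- siao_step_x2(best, xr, levy_flight(D, p$levy_K, p$levy_s),
                               spiral_terms(D, p$omega, r1), runif(D))
        }
        accept(i, cand)
      } else {
        if (runif(1) <= 0.5) {
          if (phase_log) phases <- c(phases, "X3")
          if (p$chaos) {
            lr <- logistic_rand(chaos_state, p$logistic_mu)
            chaos_state <- lr$state
            cv <- lr$value
          } else {
            cv <- runif(1)
          }
          cand <- siao_step_x3(best, x_mean, p$alpha, p$delta, lb, ub,
                               cv, runif(D))
          accept(i, cand)
          if (p$crossover && N >= 2) {
            ab <- sample(N, 2L)
            lambda <- runif(1)
            o1 <- lambda * X[ab[1], ] + (1 - lambda) * X[ab[2], ]
            o2 <- (1 - lambda) * X[ab[1], ] + lambda * X[ab[2], ]
            accept(ab[1], o1)
            accept(ab[2], o2)
          }
        } else {
          if (phase_log) phases <- c(phases, "X4")
          cand <- siao_step_x4(best, X[i, ], t, Tm, runif(1), siao_g1(runif(1)),
                               siao_g2(t, Tm), levy_flight(D, p$levy_K, p$levy_s),
                               runif(D))
          accept(i, cand)
        }
      }
    }
    history[t] <- f_best
  }

  structure(
    list(best = best, value = f_best, history = history,
         n_evals = n_evals, n_rejected = n_rejected, phases = phases,
         params = p),
    class = "siao_fit"
  )
}

#' @export
print.siao_fit <- function(x, ...) {
  cat("<siao_fit> dim =", x$params$dim, " best value =",
      format(x$value, digits = 6), "after", length(x$history),
      "iterations (", x$n_evals, "evaluations )\n")
  invisible(x)
}

#' @describeIn siao_optimize Convergence trace as a tibble
#'   (`iteration`, `best_fitness`).
#' @param x A `siao_fit`.
#' @param ... Unused.
#' @method tidy siao_fit
#' @export
tidy.siao_fit <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$history), best_fitness = x$history)
}

#' @describeIn siao_optimize One-row summary of the run.
#' @method glance siao_fit
#' @export
glance.siao_fit <- function(x, ...) {
  tibble::tibble(best_fitness = x$value, n_iter = length(x$history),
                 n_evals = x$n_evals, n_rejected = x$n_rejected)
}

#' @describeIn siao_optimize Convergence plot of the best-so-far fitness.
#' @param object A `siao_fit`.
#' @method autoplot siao_fit
#' @export
autoplot.siao_fit <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$iteration, y = .data$best_fitness)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Iteration", y = "Best fitness",
                  title = "Aquila optimizer convergence") +
    ggplot2::theme_minimal()
}

#' Wrapper feature selection with the Self-Improved Aquila Optimizer
#'
#' Searches the continuous unit hypercube over feature columns; a position is
#' decoded by selecting every column whose coordinate exceeds 0.5. The
#' fitness of a subset `S` over `C` columns is
#' `w_err * eval_fn(S) + w_card * |S| / C - w_su * mean(su[S])`,
#' balancing the wrapper error, subset cardinality and mean symmetric
#' uncertainty relevance; the empty subset is assigned fitness 1.
#'
#' @param x A `feature_set` (from [assemble_features()]), a data frame, or a
#'   numeric matrix of feature columns. Only the column count and (for a
#'   `feature_set`) the stored SU scores are used here; `eval_fn` does the
#'   scoring.
#' @param eval_fn Function mapping an integer vector of selected column
#'   indices to an error in `[0, 1]`. Errors raised by `eval_fn` reject the
#'   candidate.
#' @param params A [siao_params()] object; its `dim`/bounds are overridden to
#'   the column count and `[0, 1]`.
#' @param su Optional per-column relevance scores (defaults to the
#'   `feature_set` column SU, or zeros).
#' @param weights Named vector `c(err =, card =, su =)`;
#'   default `c(0.94, 0.05, 0.01)`.
#' @return An object of class `feature_selection`: list with `selected`
#'   (integer column indices), `columns` (names when available), `fitness`,
#'   `trace` (best-so-far fitness per iteration) and the underlying
#'   `siao_fit`.
#' @export
select_features <- function(x, eval_fn, params,
                            su = NULL,
                            weights = c(err = 0.94, card = 0.05, su = 0.01)) {
  cols <- if (inherits(x, "feature_set")) names(x$features)
          else if (is.data.frame(x)) names(x)
          else if (is.matrix(x)) colnames(x) %||% paste0("V", seq_len(ncol(x)))
          else stop("x must be a feature_set, data frame or matrix",
                    call. = FALSE)
  C <- length(cols)
  su <- su %||% (if (inherits(x, "feature_set")) unname(x$column_su) else
                   rep(0, C))
  stopifnot(length(su) == C, all(c("err", "card", "su") %in% names(weights)))

  fitness <- function(pos) {
    sel <- which(pos > 0.5)
    if (length(sel) == 0L) return(1)
    err <- eval_fn(sel)
    weights[["err"]] * err + weights[["card"]] * length(sel) / C -
      weights[["su"]] * mean(su[sel])
  }
  params$dim <- C
  params$lower <- rep(0, C)
  params$upper <- rep(1, C)
  fit <- siao_optimize(fitness, params)
  selected <- which(fit$best > 0.5)
  structure(
    list(selected = selected, columns = cols[selected], fitness = fit$value,
         trace = fit$history, fit = fit),
    class = "feature_selection"
  )
}

#' @export
print.feature_selection <- function(x, ...) {
  cat("<feature_selection>", length(x$selected), "columns selected, fitness =",
      format(x$fitness, digits = 6), "\n")
  if (length(x$columns)) cat(paste(x$columns, collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn select_features Fitness trace as a tibble.
#' @param x A `feature_selection`.
#' @param ... Unused.
#' @method tidy feature_selection
#' @export
tidy.feature_selection <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$trace), best_fitness = x$trace)
}
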