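#' Central-tendency descriptors of a numeric vector
#'
#' Computes the twelve location summaries used by the feature-extraction
#' stage: arithmetic mean, median, mode (modal 4-level bin mapped back to its
#' bin midpoint), standard deviation, geometric and harmonic means, trimmed
#' mean, interquartile mean, midrange, midhinge, trimean and winsorized mean.
#'
#' Quartiles use linear interpolation on sorted order statistics
#' (`stats::quantile(type = 7)`, the "inclusive" scheme). The interquartile
#' mean follows the summation form `(2/n) * sum(x_(i))` over sorted indices
#' `floor(n/4) + 1 .. floor(3n/4)`; for `n` divisible by 4 this is exactly the
#' mean of the middle half of the data.
#'
#' Undefined entries are returned as `NA`: the quartile-based fields
#' (`interquartile_mean`, `midhinge`, `trimean`) require `n >= 4`, and the
#' geometric/harmonic means require strictly positive data.
#'
#' @param x Numeric vector.
#' @param trim_p Proportion trimmed from each tail for the trimmed mean,
#'   in `[0, 0.25]`. Default 0.1.
#' @param winsor_p Proportion winsorized at each tail. Default 0.1.
#' @return A one-row tibble with columns `am`, `median`, `mode`, `sd`, `gm`,
#'   `hm`, `trimmed_mean`, `interquartile_mean`, `midrange`, `midhinge`,
#'   `trimean`, `winsorized_mean`.
#' @examples
#' central_tendency(c(2, 8))[, c("gm", "hm")]
#' @export
central_tendency <- function(x, trim_p = 0.1, winsor_p = 0.1) {
  stopifnot(is.numeric(x), length(x) >= 1, all(is.finite(x)))
  if (trim_p < 0 || trim_p > 0.25) {
    stop("trim_p must lie in [0, 0.25]", call. = FALSE)
  }
  n <- length(x)
  s <- sort(x)
  am <- mean(x)
  positive <- all(x > 0)
  gm <- if (positive) exp(mean(log(x))) else NA_real_
  hm <- if (positive) n / sum(1 / x) else NA_real_
  if (n >= 4) {
    q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    lo <- floor(n / 4) + 1L
    hi <- floor(3 * n / 4)
    iqm <- (2 / n) * sum(s[lo:hi])
    midhinge <- (q[1] + q[3]) / 2
    trimean <- (q[1] + 2 * q[2] + q[3]) / 4
  } else {
    iqm <- midhinge <- trimean <- NA_real_
  }
  tibble::tibble(
    am = am,
    median = median(x),
    mode = binned_mode(x),
    sd = if (n >= 2) stats::sd(x) else 0,
    gm = gm,
    hm = hm,
    trimmed_mean = mean(x, trim = trim_p),
    interquartile_mean = iqm,
    midrange = (min(x) + max(x)) / 2,
    midhinge = midhinge,
    trimean = trimean,
    winsorized_mean = winsorized_mean(x, winsor_p)
  )
}

# Mode of a continuous vector: modal bin of the 4-level discretization of the
# min-max-rescaled values, mapped back to the bin midpoint on the original
# scale. Constant input returns the constant.
binned_mode <- function(x) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(rng[1])
  lev <- discretize_levels((x - rng[1]) / (rng[2] - rng[1]))
  f <- tabulate(lev, nbins = 4L)
  m <- which.max(f)
  rng[1] + (m - 0.5) / 4 * (rng[2] - rng[1])
}

winsorized_mean <- function(x, p = 0.1) {
  n <- length(x)
  k <- floor(p * n)
  if (k == 0) return(mean(x))
  s <- sort(x)
  s[seq_len(k)] <- s[k + 1]
  s[(n - k + 1):n] <- s[n - k]
  mean(s)
}

#' Dispersion descriptors of a numeric vector
#'
#' Computes the spread summaries of the feature-extraction stage: IQR
#' (`P3 - P1`), range, mean absolute difference
#' `mad = (1/n^2) * sum_i sum_j |x_i - x_j|`, average absolute deviation from
#' the median, coefficient of variation `sd/mean`, quartile coefficient of
#' dispersion `(P3 - P1)/(P3 + P1)`, relative mean difference `mad/mean`, the
#' Gini coefficient `rmd/2`, and the Shannon entropy (natural log) of the
#' 4-level discretization of the min-max-rescaled vector.
#'
#' Undefined entries (`cv`/`rmd`/`gini` at zero mean, `qcd` when
#' `P3 + P1 = 0`) are `NA`.
#'
#' @param x Numeric vector, `length(x) >= 2`.
#' @return A one-row tibble with columns `iqr`, `range`, `mad`, `aad`, `cv`,
#'   `qcd`, `rmd`, `gini`, `entropy`.
#' @examples
#' dispersion_stats(c(1, 5))[, c("range", "aad")]
#' @export
dispersion_stats <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 2, all(is.finite(x)))
  n <- length(x)
  q <- quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  am <- mean(x)
  mad_ <- mean(abs(outer(x, x, "-")))
  rng <- range(x)
  lev <- if (rng[1] == rng[2]) rep(1L, n) else
    discretize_levels((x - rng[1]) / (rng[2] - rng[1]))
  tibble::tibble(
    iqr = q[2] - q[1],
    range = rng[2] - rng[1],
    mad = mad_,
    aad = mean(abs(x - median(x))),
    cv = if (am == 0) NA_real_ else stats::sd(x) / am,
    qcd = if (q[1] + q[2] == 0) NA_real_ else (q[2] - q[1]) / (q[2] + q[1]),
    rmd = if (am == 0) NA_real_ else mad_ / am,
    gini = if (am == 0) NA_real_ else mad_ / am / 2,
    entropy = shannon_entropy(tabulate(lev, nbins = 4L))
  )
}

shannon_entropy <- function(counts, base = exp(1)) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p, base = base))
}

#' Discretize unit-interval values into four ordinal levels
#'
#' Maps normalized values to the four-level scale used for the qualitative
#' variation and entropy descriptors: `[0, 0.25] -> 1`, `(0.25, 0.5] -> 2`,
#' `(0.5, 0.75] -> 3`, `(0.75, 1] -> 4`. Interval upper endpoints are
#' inclusive and 0 maps to level 1 (the deterministic tie rule for boundary
#' values shared by adjacent ranges).
#'
#' @param x Numeric vector with entries in `[0, 1]`.
#' @return Integer vector of levels in `1:4`.
#' @examples
#' discretize_levels(c(0, 0.1, 0.25, 0.3, 0.75, 1))
#' @export
discretize_levels <- function(x) {
  stopifnot(is.numeric(x))
  if (any(x < 0 | x > 1, na.rm = TRUE) || anyNA(x)) {
    stop("values must lie in [0, 1]", call. = FALSE)
  }
  findInterval(x, c(0.25, 0.5, 0.75), left.open = TRUE) + 1L
}

#' Qualitative-variation indices of a 4-level distribution
#'
#' Computes eight standard qualitative-variation (categorical dispersion)
#' indices on the level counts `f_k` of a vector of ordinal levels in `1:4`
#' (`K = 4` categories, modal count `f_m`, `n` observations):
#'
#' * `modvr`: variation ratio around the mode, `K (n - f_m) / (n (K - 1))`;
#' * `avdev`: `1 - sum(|f_k - n/K|) / (2 (n/K) (K - 1))`;
#' * `mndif`: `1 - sum_{k<l} |f_k - f_l| / (n (K - 1))`;
#' * `b_index`: `1 - sqrt(1 - g^2)` with `g = prod(f_k K / n)^(1/K)`;
#' * `hrel`: Shannon entropy (bits) divided by `log2 K`;
#' * `simpson_iqv`: `(K/(K-1)) (1 - sum p_k^2)`;
#' * `berger_parker`: dominance `f_m / n`;
#' * `shannon_wiener`: Shannon entropy in nats, in `[0, log 4]`.
#'
#' All indices depend only on the multiset of counts, so they are invariant
#' under relabeling of the categories.
#'
#' @param levels Integer vector with entries in `1:4`.
#' @return A one-row tibble of the eight indices, with the level counts in
#'   the `"level_counts"` attribute.
#' @examples
#' qualitative_variation(c(1, 1, 2, 3))
#' @export
qualitative_variation <- function(levels) {
  if (length(levels) == 0L) stop("empty input", call. = FALSE)
  if (any(!levels %in% 1:4)) stop("levels must lie in 1:4", call. = FALSE)
  f <- tabulate(as.integer(levels), nbins = 4L)
  n <- sum(f)
  K <- 4
  fm <- max(f)
  p <- f / n
  g <- prod(f * K / n)^(1 / K)
  out <- tibble::tibble(
    modvr = K * (n - fm) / (n * (K - 1)),
    avdev = 1 - sum(abs(f - n / K)) / (2 * (n / K) * (K - 1)),
    mndif = 1 - sum(abs(outer(f, f, "-"))[upper.tri(diag(K))]) / (n * (K - 1)),
    b_index = 1 - sqrt(1 - g^2),
    hrel = shannon_entropy(f, base = 2) / log2(K),
    simpson_iqv = (K / (K - 1)) * (1 - sum(p^2)),
    berger_parker = fm / n,
    shannon_wiener = shannon_entropy(f)
  )
  attr(out, "level_counts") <- f
  out
}

#' Symmetric uncertainty between a feature and the class
#'
#' The normalized mutual-information relevance score
#' `SU(Q, P) = 2 I(Q; P) / (H(Q) + H(P))`, with the mutual information
#' `I(Q; P) = sum PO(q, p) log2( PO(q, p) / (PO(q) PO(p)) )` computed from
#' empirical joint frequencies (`0 log 0 := 0`) and entropies in bits.
#' `SU` lies in `[0, 1]`: 0 for independent variables, 1 when either
#' determines the other; it is symmetric in its arguments. When
#' `H(Q) + H(P) = 0` (both vectors constant) the score is defined as 0.
#'
#' @param q A discrete (or discretized) feature vector.
#' @param p The class vector, same length.
#' @return A scalar in `[0, 1]`.
#' @examples
#' symmetric_uncertainty(c(1, 1, 2, 2), c(0, 0, 1, 1))
#' @export
symmetric_uncertainty <- function(q, p) {
  if (length(q) != length(p)) stop("q and p must have the same length",
                                   call. = FALSE)
  if (length(q) == 0L) stop("empty input", call. = FALSE)
  joint <- table(q, p) / length(q)
  pq <- rowSums(joint)
  pp <- colSums(joint)
  hq <- shannon_entropy(pq[pq > 0] * length(q), base = 2)
  hp <- shannon_entropy(pp[pp > 0] * length(q), base = 2)
  if (hq + hp == 0) return(0)
  outer_p <- outer(pq, pp)
  nz <- joint > 0
  cm <- sum(joint[nz] * log2(joint[nz] / outer_p[nz]))
  min(1, max(0, 2 * cm / (hq + hp)))
}

#' Histogram estimate of differential entropy
#'
#' Equal-width histogram estimator `H = -sum p_k log p_k + log w` (nats),
#' where `w` is the bin width. Under rescaling `y = c x` the estimate obeys
#' the scale law `H(y) - H(x) -> log c` as the sample grows, the behaviour
#' that distinguishes continuous entropy from location-scale-invariant
#' discrete entropy.
#'
#' @param x Numeric vector.
#' @param bins Number of equal-width bins; default `ceiling(n^(1/3)) * 2`.
#' @return Entropy estimate in nats.
#' @export
entropy_continuous <- function(x, bins = NULL) {
  stopifnot(is.numeric(x), length(x) >= 2, all(is.finite(x)))
  n <- length(x)
  bins <- bins %||% (2L * ceiling(n^(1 / 3)))
  rng <- range(x)
  if (rng[1] == rng[2]) return(-Inf)
  w <- (rng[2] - rng[1]) / bins
  idx <- pmin(bins, floor((x - rng[1]) / w) + 1L)
  shannon_entropy(tabulate(idx, nbins = bins)) + log(w)
}

#' Assemble the augmented feature matrix
#'
#' Builds the classifier input from a normalized clean table. For every
#' sample (row-wise over its normalized attribute values) the central
#' tendency descriptors, dispersion descriptors and qualitative-variation
#' indices of the row's 4-level discretization are appended to the original
#' attributes. Per attribute (column-wise) the symmetric uncertainty against
#' the class is computed as the relevance score vector consumed by the
#' feature-selection fitness.
#'
#' Descriptors that are undefined for a particular row (e.g. geometric mean
#' of a row containing zeros) are encoded as 0 in the matrix so classifiers
#' receive complete numeric input; the per-vector descriptor functions keep
#' the `NA` flags. With fewer than 4 attributes the quartile-based row
#' descriptors are excluded with a warning.
#'
#' @param data A normalized tibble (attributes in `[0, 1]`) with binary `y`.
#' @param trim_p,winsor_p Passed to [central_tendency()].
#' @return An object of class `feature_set`: a list with
#'   * `features`: tibble of original + derived columns (no `y`),
#'   * `y`: the class vector,
#'   * `su`: tibble of per-original-attribute symmetric uncertainty,
#'   * `column_su`: named vector of SU for every feature column,
#'   * `family`: tibble mapping each column to `original`/`CT`/`D`/`QV`.
#' @export
assemble_features <- function(data, trim_p = 0.1, winsor_p = 0.1) {
  data <- tibble::as_tibble(data)
  if (!"y" %in% names(data)) stop("data must contain a binary 'y' column",
                                  call. = FALSE)
  attrs <- setdiff(names(data), "y")
  X <- as.matrix(data[attrs])
  if (any(X < -1e-9 | X > 1 + 1e-9)) {
    stop("attributes must be normalized to [0, 1]; see normalize_minmax()",
         call. = FALSE)
  }
  X <- pmin(pmax(X, 0), 1)  # pmax(X, .) keeps the matrix attributes
  n_attr <- length(attrs)
  if (n_attr < 4L) {
    warning("fewer than 4 attributes: quartile-based row descriptors are ",
            "undefined and excluded", call. = FALSE)
  }

  per_row <- function(v) {
    ct <- central_tendency(v, trim_p = trim_p, winsor_p = winsor_p)
    d <- dispersion_stats(v)
    qv <- qualitative_variation(discretize_levels(v))
    c(as.numeric(ct), as.numeric(d), as.numeric(qv))
  }
  ct_names <- names(central_tendency(c(0.1, 0.4, 0.6, 0.9)))
  d_names <- names(dispersion_stats(c(0.1, 0.9)))
  qv_names <- names(qualitative_variation(1:4))
  derived <- t(apply(X, 1L, per_row))
  colnames(derived) <- c(paste0("ct_", ct_names), paste0("d_", d_names),
                         paste0("qv_", qv_names))
  if (n_attr < 4L) {
    derived <- derived[, !colnames(derived) %in%
                         paste0("ct_", c("interquartile_mean", "midhinge",
                                         "trimean")), drop = FALSE]
  }
  derived[is.na(derived)] <- 0

  features <- dplyr::bind_cols(
    tibble::as_tibble(X, .name_repair = "minimal"),
    tibble::as_tibble(derived, .name_repair = "minimal")
  )
  y <- data$y
  su <- vapply(attrs, function(a) {
    symmetric_uncertainty(discretize_levels(features[[a]]), y)
  }, 0)
  column_su <- vapply(names(features), function(a) {
    v <- features[[a]]
    rng <- range(v)
    lv <- if (rng[1] == rng[2]) rep(1L, length(v)) else
      discretize_levels((v - rng[1]) / (rng[2] - rng[1]))
    symmetric_uncertainty(lv, y)
  }, 0)
  family <- tibble::tibble(
    column = names(features),
    family = c(rep("original", n_attr),
               rep("CT", sum(startsWith(colnames(derived), "ct_"))),
               rep("D", length(d_names)),
               rep("QV", length(qv_names)))
  )
  structure(
    list(features = features, y = y,
         su = tibble::tibble(attribute = attrs, su = unname(su)),
         column_su = column_su, family = family),
    class = "feature_set"
  )
}

#' @export
print.feature_set <- function(x, ...) {
  cat("<feature_set> ", nrow(x$features), " samples x ", ncol(x$features),
      " columns (", sum(x$family$family == "original"), " original)\n",
      sep = "")
  cat("top SU attributes:\n")
  print(head(dplyr::arrange(x$su, dplyr::desc(.data$su)), 5))
  invisible(x)
}

#' @describeIn assemble_features Per-attribute symmetric-uncertainty scores
#'   as a tibble.
#' @param x A `feature_set`.
#' @param ... Unused.
#' @method tidy feature_set
#' @export
tidy.feature_set <- function(x, ...) x$su
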