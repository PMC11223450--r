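#' Generate a synthetic clinical table with planted signal
#'
#' Emulates the shape of the small tabular heart-disease benchmarks
#' (13 mixed continuous/ordinal attributes plus a binary label) with fully
#' known ground truth, so every pipeline stage can be validated without
#' external data. Labels are Bernoulli(`class_balance`); informative
#' attributes are class-conditional Gaussians with unit variance and means
#' `-effect_size/2` (class 0) / `+effect_size/2` (class 1); the remaining
#' attributes are standard normal noise independent of the class. Three
#' attributes (`cp`/`slope`/`thal`-style positions 3, 11 and 13 when
#' available, otherwise the last up-to-3 columns) are rendered ordinal by
#' quartile binning into levels 1--4. Missing markers (`NA`, one random cell
#' in each affected row) and verbatim duplicate rows (label included) are
#' then injected at the stated rates. Deterministic given `seed`.
#'
#' @param n_samples Number of base rows.
#' @param n_attributes Number of attributes (default 13).
#' @param informative Integer indices of the planted informative attributes
#'   (default `1:5`).
#' @param effect_size Standardized mean shift of informative attributes
#'   (default 1; 0 gives a null dataset).
#' @param class_balance P(class 1) (default 0.5).
#' @param missing_rate Fraction of rows receiving a missing cell.
#' @param duplicate_rate Fraction of rows duplicated verbatim and appended.
#' @param seed Integer seed.
#' @return A list with
#'   * `data`: tibble of `n_samples * (1 + duplicate_rate)` rows (rounded),
#'     attribute columns `attr1..attrK` plus `label`;
#'   * `truth`: list with `informative`, `ordinal`, `effect_size`,
#'     `n_missing_rows`, `n_duplicates`.
#' @examples
#' g <- generate_heart_data(100, seed = 1)
#' dim(g$data)
#' @export
generate_heart_data <- function(n_samples, n_attributes = 13L,
                                informative = 1:5, effect_size = 1,
                                class_balance = 0.5, missing_rate = 0.02,
                                duplicate_rate = 0.02, seed = NULL) {
  stopifnot(n_samples >= 2, n_attributes >= 1, effect_size >= 0,
            class_balance > 0, class_balance < 1,
            missing_rate >= 0, missing_rate < 1,
            duplicate_rate >= 0, duplicate_rate < 1,
            all(informative %in% seq_len(n_attributes)) ||
              length(informative) == 0)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_samples); k <- as.integer(n_attributes)
  y <- rbinom(n, 1L, class_balance)
  X <- matrix(rnorm(n * k), n, k)
  for (j in informative) {
    X[, j] <- X[, j] + ifelse(y == 1, effect_size / 2, -effect_size / 2)
  }
  ordinal <- if (k >= 13L) c(3L, 11L, 13L) else tail(seq_len(k), min(3L, k))
  for (j in ordinal) {
    br <- unique(quantile(X[, j], c(0, 0.25, 0.5, 0.75, 1), type = 7))
    X[, j] <- as.integer(cut(X[, j], breaks = br, include.lowest = TRUE,
                             labels = FALSE))
  }
  data <- tibble::as_tibble(as.data.frame(X), .name_repair = "minimal")
  names(data) <- paste0("attr", seq_len(k))
  data$label <- y

  n_missing_rows <- round(missing_rate * n)
  if (n_missing_rows > 0) {
    rows <- sample.int(n, n_missing_rows)
    for (r in rows) data[r, sample.int(k, 1L)] <- NA_real_
  }
  n_duplicates <- round(duplicate_rate * n)
  if (n_duplicates > 0) {
    data <- dplyr::bind_rows(data, data[sample.int(n, n_duplicates,
                                                   replace = TRUE), ])
  }
  list(data = data,
       truth = list(informative = informative, ordinal = ordinal,
                    effect_size = effect_size,
                    n_missing_rows = n_missing_rows,
                    n_duplicates = n_duplicates))
}

#' Null dataset: labels independent of all attributes
#'
#' Shortcut for [generate_heart_data()] with `effect_size = 0` and no
#' injected missingness or duplicates, for type-I-error and chance-level
#' checks.
#'
#' @param n Number of rows (>= 10).
#' @param seed Integer seed.
#' @param n_attributes Number of attributes.
#' @return A tibble of attributes plus `label`.
#' @export
null_heart_data <- function(n, seed = NULL, n_attributes = 13L) {
  stopifnot(n >= 10)
  generate_heart_data(n, n_attributes = n_attributes, informative = integer(0),
                      effect_size = 0, missing_rate = 0, duplicate_rate = 0,
                      seed = seed)$data
}
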