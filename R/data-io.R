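#' Read a UCI-style heart-disease table
#'
#' Reads the two table dialects distributed for the classic heart-disease
#' benchmarks: the processed-Cleveland dialect (comma-separated, 13 clinical
#' attributes plus an integer disease-severity label 0--4, `"?"` marking
#' missing cells) and the Statlog dialect (whitespace-separated, labels 1 =
#' absence / 2 = presence, remapped here to 0/1). A generic `"csv"` dialect
#' accepts any comma-separated table whose last column is the label.
#'
#' Missing-value tokens are mapped to `NA`; the number of missing cells is
#' recorded in the `"n_missing_cells"` attribute of the result. Every row must
#' have the same number of fields; a ragged row raises an error naming its
#' line number.
#'
#' @param path Path to a plain-text table.
#' @param dialect One of `"cleveland"`, `"statlog"`, `"csv"`.
#' @param missing_marker Token marking a missing cell (default `"?"`).
#' @return A tibble whose final column is `label` (numeric). Attributes
#'   `"missing_marker"`, `"n_missing_cells"` and `"dialect"` describe the
#'   parse.
#' @examples
#' path <- tempfile(fileext = ".csv")
#' writeLines(c("63,1,1,145,1", "67,1,4,160,2", "41,0,2,?,0"), path)
#' raw <- read_heart_data(path, dialect = "csv")
#' attr(raw, "n_missing_cells")
#' @export
read_heart_data <- function(path,
                            dialect = c("cleveland", "statlog", "csv"),
                            missing_marker = "?") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop("no records in ", path, call. = FALSE)
  }
  split_fun <- if (dialect == "statlog") {
    function(l) strsplit(trimws(l), "[[:space:]]+")[[1]]
  } else {
    function(l) trimws(strsplit(l, ",", fixed = TRUE)[[1]])
  }
  fields <- lapply(lines, split_fun)
  arity <- length(fields[[1]])
  if (dialect %in% c("cleveland", "statlog") && arity != 14L) {
    stop("expected 14 columns for the ", dialect, " dialect, found ", arity,
         " at line 1", call. = FALSE)
  }
  if (arity < 2L) {
    stop("need at least one attribute plus a label column", call. = FALSE)
  }
  bad <- which(vapply(fields, length, 1L) != arity)
  if (length(bad) > 0L) {
    stop("malformed row: expected ", arity, " columns, found ",
         length(fields[[bad[1]]]), " at line ", bad[1], call. = FALSE)
  }
  mat <- do.call(rbind, fields)
  n_missing <- sum(mat == missing_marker)
  mat[mat == missing_marker] <- NA_character_
  num <- suppressWarnings(apply(mat, 2L, as.numeric))
  num <- matrix(num, nrow = nrow(mat))
  bad_cell <- which(is.na(num) & !is.na(mat), arr.ind = TRUE)
  if (nrow(bad_cell) > 0L) {
    stop("non-numeric value '", mat[bad_cell[1, 1], bad_cell[1, 2]],
         "' at line ", bad_cell[1, 1], call. = FALSE)
  }
  nms <- heart_attribute_names(arity)
  out <- tibble::as_tibble(as.data.frame(num), .name_repair = "minimal")
  names(out) <- nms
  if (dialect == "statlog") {
    lab <- out$label
    if (any(!lab %in% c(1, 2), na.rm = TRUE)) {
      stop("statlog labels must be 1 (absence) or 2 (presence)", call. = FALSE)
    }
    out$label <- lab - 1
  }
  attr(out, "missing_marker") <- missing_marker
  attr(out, "n_missing_cells") <- n_missing
  attr(out, "dialect") <- dialect
  out
}

heart_attribute_names <- function(arity) {
  if (arity == 14L) {
    c("age", "sex", "cp", "trestbps", "chol", "fbs", "restecg", "thalach",
      "exang", "oldpeak", "slope", "ca", "thal", "label")
  } else {
    c(paste0("attr", seq_len(arity - 1L)), "label")
  }
}

#' Preprocess a raw clinical table
#'
#' The cleaning stage of the pipeline: rows containing any missing value are
#' dropped, exact duplicate rows (all attributes and the label) are dropped
#' keeping the first occurrence, and the label is binarized (`y = 1` when
#' `label > label_threshold`, matching the usual presence/absence reading of
#' the Cleveland 0--4 severity codes).
#'
#' @param raw A data frame whose last/label column is named `label` (or `y`
#'   from a previous call, making the operation idempotent).
#' @param label_threshold Labels strictly greater than this become class 1.
#' @return A tibble of numeric attributes plus a binary `y` column, with a
#'   `"report"` attribute: a list with `missing_dropped`, `duplicates_dropped`,
#'   `n_kept` and `single_class`. Retrieve it with [preprocess_report()].
#' @examples
#' tbl <- tibble::tibble(a = c(1, 1, NA, 2, 2), b = 1, label = c(0, 0, 1, 2, 3))
#' clean <- preprocess_heart(tbl)
#' preprocess_report(clean)
#' @export
preprocess_heart <- function(raw, label_threshold = 0) {
  raw <- tibble::as_tibble(raw)
  lab_col <- if ("label" %in% names(raw)) "label" else if ("y" %in% names(raw)) "y" else
    stop("no 'label' (or 'y') column found", call. = FALSE)
  if (ncol(raw) < 2L) stop("need at least one attribute plus a label", call. = FALSE)

  complete <- stats::complete.cases(raw)
  missing_dropped <- sum(!complete)
  kept <- raw[complete, , drop = FALSE]
  dup <- duplicated(kept)
  duplicates_dropped <- sum(dup)
  kept <- kept[!dup, , drop = FALSE]
  if (nrow(kept) == 0L) {
    stop("empty after preprocessing: every row was missing or duplicated",
         call. = FALSE)
  }
  y <- as.integer(kept[[lab_col]] > label_threshold)
  out <- kept[setdiff(names(kept), c("label", "y"))]
  out$y <- y
  single_class <- length(unique(y)) < 2L
  if (single_class) {
    warning("only one class present after preprocessing", call. = FALSE)
  }
  attr(out, "report") <- list(
    missing_dropped = missing_dropped,
    duplicates_dropped = duplicates_dropped,
    n_kept = nrow(out),
    single_class = single_class
  )
  out
}

#' @rdname preprocess_heart
#' @param clean A table returned by [preprocess_heart()].
#' @export
preprocess_report <- function(clean) attr(clean, "report")

#' Min-max normalization to the unit interval
#'
#' Maps each attribute column to `[0, 1]` via `(x - min) / (max - min)`.
#' Constant columns map to 0 with a warning. When `stats` (the
#' `"norm_stats"` attribute of a previously normalized training table) is
#' supplied, the stored training minima/maxima are reused and the result is
#' clamped to `[0, 1]`, so held-out data are transformed without leakage.
#'
#' @param data A data frame; a `y` column, if present, is passed through.
#' @param stats Optional tibble with columns `attribute`, `min`, `max`.
#' @return The normalized tibble with a `"norm_stats"` attribute (retrieve
#'   with [norm_stats()]).
#' @examples
#' tr <- normalize_minmax(tibble::tibble(a = c(2, 4, 6), y = c(0, 1, 1)))
#' normalize_minmax(tibble::tibble(a = 5, y = 0), stats = norm_stats(tr))
#' @export
normalize_minmax <- function(data, stats = NULL) {
  data <- tibble::as_tibble(data)
  cols <- setdiff(names(data), "y")
  if (is.null(stats)) {
    mins <- vapply(data[cols], min, 0)
    maxs <- vapply(data[cols], max, 0)
    if (any(maxs == mins)) {
      warning("constant attribute(s) mapped to 0: ",
              paste(cols[maxs == mins], collapse = ", "), call. = FALSE)
    }
    stats <- tibble::tibble(attribute = cols, min = mins, max = maxs)
  } else {
    stats <- stats[match(cols, stats$attribute), , drop = FALSE]
    if (anyNA(stats$min)) stop("normalization stats missing for some attributes",
                               call. = FALSE)
  }
  for (k in seq_along(cols)) {
    rng <- stats$max[k] - stats$min[k]
    v <- if (rng == 0) rep(0, nrow(data)) else (data[[cols[k]]] - stats$min[k]) / rng
    data[[cols[k]]] <- pmin(1, pmax(0, v))
  }
  attr(data, "norm_stats") <- stats
  data
}

#' @rdname normalize_minmax
#' @export
norm_stats <- function(data) attr(data, "norm_stats")

#' Split a table into training and test sets
#'
#' Deterministic given `seed`. The training set has `floor(n * train_fraction)`
#' rows. With `stratified = TRUE` each class contributes
#' `floor(train_fraction * n_class)` training rows and remaining training slots
#' are filled from the classes with the largest fractional remainders, so the
#' train/test partition preserves class balance as closely as integer counts
#' allow. Stratification falls back to a simple random split (with a warning)
#' when some class has fewer than 2 members.
#'
#' @param data A data frame with a binary `y` column.
#' @param train_fraction Proportion of rows for training, in (0, 1).
#' @param seed Integer seed.
#' @param stratified Stratify on `y`? Default `TRUE`.
#' @return A list with tibbles `train` and `test`.
#' @examples
#' d <- tibble::tibble(x = 1:10, y = rep(0:1, 5))
#' sp <- split_train_test(d, 0.6, seed = 1)
#' nrow(sp$train)
#' @export
split_train_test <- function(data, train_fraction, seed = 1L,
                             stratified = TRUE) {
  data <- tibble::as_tibble(data)
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop("train_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  n <- nrow(data)
  if (n < 2L) stop("need at least 2 rows to split", call. = FALSE)
  n_train <- floor(n * train_fraction)
  if (n_train < 1L || n_train >= n) {
    stop("train_fraction leaves an empty train or test set", call. = FALSE)
  }
  set.seed(seed)
  if (stratified && "y" %in% names(data)) {
    cls <- split(seq_len(n), data$y)
    if (any(vapply(cls, length, 1L) < 2L)) {
      warning("stratification impossible (a class has < 2 members); ",
              "falling back to unstratified split", call. = FALSE)
      idx <- sample.int(n, n_train)
    } else {
      base <- vapply(cls, function(ix) floor(train_fraction * length(ix)), 0)
      rem <- vapply(cls, function(ix) train_fraction * length(ix), 0) - base
      short <- n_train - sum(base)
      if (short > 0) {
        top <- order(rem, decreasing = TRUE)[seq_len(short)]
        base[top] <- base[top] + 1
      }
      idx <- unlist(Map(function(ix, k) sample(ix, k), cls, base),
                    use.names = FALSE)
    }
  } else {
    idx <- sample.int(n, n_train)
  }
  list(train = data[sort(idx), , drop = FALSE],
       test = data[setdiff(seq_len(n), sort(idx)), , drop = FALSE])
}

#' Write a raw heart table to disk
#'
#' Writes a comma-separated file in the processed-Cleveland dialect, encoding
#' `NA` cells with `missing_marker`.
#'
#' @param data A data frame (last column the label).
#' @param path Output path.
#' @param missing_marker Token used for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_heart_csv <- function(data, path, missing_marker = "?") {
  m <- as.matrix(data)
  m[is.na(m)] <- missing_marker
  writeLines(apply(m, 1L, paste, collapse = ","), path)
  invisible(path)
}
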