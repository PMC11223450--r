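#' Summary statistics over repeated runs
#'
#' Mean, median, sample standard deviation (divisor `n - 1`), worst
#' (minimum) and best (maximum) of a vector of per-run accuracies.
#'
#' @param x Numeric vector, length >= 1 (`sd` is `NA` for a single value).
#' @return A one-row tibble with columns `mean`, `median`, `sd`, `worst`,
#'   `best`.
#' @examples
#' summarize_accuracy(c(0.8, 1.0))
#' @export
summarize_accuracy <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 1)
  tibble::tibble(mean = mean(x), median = median(x),
                 sd = if (length(x) >= 2) stats::sd(x) else NA_real_,
                 worst = min(x), best = max(x))
}

#' Run the four-stage prediction pipeline
#'
#' Orchestrates the full workflow on a raw clinical table, repeated
#' `n_repeats` times with derived seeds (`seed + k - 1` for repeat `k`):
#'
#' 1. preprocessing (missing-row and duplicate elimination, label
#'    binarization);
#' 2. stratified train/test split and min-max normalization (statistics from
#'    the training fold only, reused on the test fold);
#' 3. feature extraction ([assemble_features()]) and wrapper feature
#'    selection with the Self-Improved Aquila Optimizer, scored by a fast
#'    inner hybrid (reduced epochs, inner validation fold);
#' 4. training of the LSTM and QNN on the selected columns, SIAO tuning of
#'    the LSTM forget gate on the validation fold, and hybrid evaluation on
#'    the held-out test fold.
#'
#' A failed repeat is recorded and skipped; the run errors only if every
#' repeat fails.
#'
#' @param raw Raw table (e.g. from [read_heart_data()] or
#'   [generate_heart_data()]`$data`) with a `label` column.
#' @param train_fraction Training proportion (default 0.9).
#' @param n_repeats Number of repeated runs (default 5).
#' @param seed Base seed.
#' @param fs List of feature-selection settings: `n_pop`, `n_iter`,
#'   `weights`, `inner_epochs`, `inner_max_n`, `inner_fraction`.
#' @param lstm List: `hidden`, `epochs`, `lr`.
#' @param qnn List: `n_hidden`, `n_s`, `beta`, `epochs`, `lr`.
#' @param tune List: `n_pop`, `n_iter`, `scope`, `bound` (LSTM weight
#'   tuning; `n_iter = 0` disables).
#' @param threshold Decision threshold.
#' @param trim_p,winsor_p Passed to [assemble_features()].
#' @return An object of class `cvd_run`: list with
#'   * `metrics`: tibble, one row per successful repeat (all ten metric
#'     columns plus `repeat_id`);
#'   * `selected`: list of selected column-name vectors;
#'   * `convergence`: list of feature-selection fitness traces;
#'   * `summary`: [summarize_accuracy()] of the per-repeat accuracies;
#'   * `failures`: character vector of per-repeat error messages.
#' @export
cvd_pipeline <- function(raw, train_fraction = 0.9, n_repeats = 5L,
                         seed = 1L,
                         fs = list(), lstm = list(), qnn = list(),
                         tune = list(), threshold = 0.5,
                         trim_p = 0.1, winsor_p = 0.1) {
  fs <- utils::modifyList(list(n_pop = 10L, n_iter = 20L,
                               weights = c(err = 0.94, card = 0.05, su = 0.01),
                               inner_epochs = 10L, inner_max_n = 250L,
                               inner_fraction = 0.75), fs)
  lstm_cfg <- utils::modifyList(list(hidden = 8L, epochs = 120L, lr = 0.5), lstm)
  qnn_cfg <- utils::modifyList(list(n_hidden = 8L, n_s = 3L, beta = 1,
                                    epochs = 120L, lr = 0.5), qnn)
  tune_cfg <- utils::modifyList(list(n_pop = 8L, n_iter = 15L,
                                     scope = "forget_gate", bound = 2), tune)
  stopifnot(n_repeats >= 1)

  clean <- preprocess_heart(raw)
  metrics <- list(); selected <- list(); convergence <- list()
  failures <- character(0)

  for (k in seq_len(n_repeats)) {
    seed_k <- seed + k - 1L
    res <- tryCatch(
      run_one_repeat(clean, train_fraction, seed_k, fs, lstm_cfg, qnn_cfg,
                     tune_cfg, threshold, trim_p, winsor_p),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failures <- c(failures, paste0("repeat ", k, ": ", conditionMessage(res)))
      next
    }
    res$metrics$repeat_id <- k
    metrics[[length(metrics) + 1L]] <- res$metrics
    selected[[length(selected) + 1L]] <- res$selected
    convergence[[length(convergence) + 1L]] <- res$trace
  }
  if (length(metrics) == 0L) {
    stop("all repeats failed: ", paste(failures, collapse = "; "),
         call. = FALSE)
  }
  metrics <- dplyr::bind_rows(metrics)
  metrics <- dplyr::relocate(metrics, "repeat_id")
  structure(
    list(metrics = metrics, selected = selected, convergence = convergence,
         summary = summarize_accuracy(metrics$accuracy), failures = failures,
         config = list(train_fraction = train_fraction, seed = seed,
                       fs = fs, lstm = lstm_cfg, qnn = qnn_cfg,
                       tune = tune_cfg, threshold = threshold)),
    class = "cvd_run"
  )
}

run_one_repeat <- function(clean, train_fraction, seed_k, fs, lstm_cfg,
                           qnn_cfg, tune_cfg, threshold, trim_p, winsor_p) {
  sp <- split_train_test(clean, train_fraction, seed = seed_k)
  tr <- normalize_minmax(sp$train)
  te <- normalize_minmax(sp$test, stats = norm_stats(tr))
  feats_tr <- assemble_features(tr, trim_p = trim_p, winsor_p = winsor_p)
  feats_te <- assemble_features(te, trim_p = trim_p, winsor_p = winsor_p)

  # inner split of the training fold for the wrapper fitness and for tuning
  inner <- split_train_test(
    dplyr::mutate(feats_tr$features, y = feats_tr$y),
    fs$inner_fraction, seed = seed_k + 10000L)
  Xin <- as.matrix(dplyr::select(inner$train, -"y"))
  yin <- inner$train$y
  Xval <- as.matrix(dplyr::select(inner$test, -"y"))
  yval <- inner$test$y
  if (nrow(Xin) > fs$inner_max_n) {
    set.seed(seed_k + 20000L)
    keep <- sample.int(nrow(Xin), fs$inner_max_n)
    Xin <- Xin[keep, , drop = FALSE]; yin <- yin[keep]
  }

  eval_fn <- function(sel) {
    lw <- lstm_train(NULL, Xin[, sel, drop = FALSE], yin,
                     epochs = fs$inner_epochs, lr = lstm_cfg$lr,
                     seed = seed_k, hidden = lstm_cfg$hidden)
    qp <- qnn_train(NULL, Xin[, sel, drop = FALSE], yin,
                    epochs = fs$inner_epochs, lr = qnn_cfg$lr,
                    seed = seed_k, n_hidden = qnn_cfg$n_hidden,
                    n_s = qnn_cfg$n_s, beta = qnn_cfg$beta)
    p <- (lstm_forward_batch(lw, Xval[, sel, drop = FALSE]) +
            qnn_forward_batch(qp, Xval[, sel, drop = FALSE])) / 2
    mean((p >= threshold) != yval)
  }
  fsel <- select_features(feats_tr, eval_fn,
                          siao_params(dim = 1, n_pop = fs$n_pop,
                                      n_iter = fs$n_iter, seed = seed_k),
                          weights = fs$weights)
  sel <- fsel$selected
  if (length(sel) == 0L) {
    warning("empty feature subset selected; falling back to all original ",
            "attributes", call. = FALSE)
    sel <- which(feats_tr$family$family == "original")
  }

  Xtr <- as.matrix(feats_tr$features)[, sel, drop = FALSE]
  Xte <- as.matrix(feats_te$features)[, sel, drop = FALSE]
  lw <- lstm_train(NULL, Xtr, feats_tr$y, epochs = lstm_cfg$epochs,
                   lr = lstm_cfg$lr, seed = seed_k, hidden = lstm_cfg$hidden)
  if (tune_cfg$n_iter > 0L) {
    lw <- lstm_tune(lw, Xval[, sel, drop = FALSE], yval,
                    siao_params(dim = 1, n_pop = tune_cfg$n_pop,
                                n_iter = tune_cfg$n_iter,
                                seed = seed_k + 30000L),
                    scope = tune_cfg$scope, bound = tune_cfg$bound)
  }
  qp <- qnn_train(NULL, Xtr, feats_tr$y, epochs = qnn_cfg$epochs,
                  lr = qnn_cfg$lr, seed = seed_k, n_hidden = qnn_cfg$n_hidden,
                  n_s = qnn_cfg$n_s, beta = qnn_cfg$beta)
  model <- hybrid_model(lw, qp, threshold = threshold,
                        columns = names(feats_tr$features)[sel])
  pred <- predict(model, Xte)
  cm <- confusion_matrix(feats_te$y, pred$label)
  list(metrics = classification_metrics(cm),
       selected = names(feats_tr$features)[sel],
       trace = fsel$trace)
}

#' @export
print.cvd_run <- function(x, ...) {
  cat("<cvd_run>", nrow(x$metrics), "repeat(s)\n")
  print(x$summary)
  if (length(x$failures)) cat("failures:", paste(x$failures, collapse = "; "),
                              "\n")
  invisible(x)
}

#' @describeIn cvd_pipeline Per-repeat metric rows.
#' @param x A `cvd_run`.
#' @param ... Unused.
#' @method tidy cvd_run
#' @export
tidy.cvd_run <- function(x, ...) x$metrics

#' @describeIn cvd_pipeline One-row accuracy summary
#'   (mean/median/sd/worst/best).
#' @method glance cvd_run
#' @export
glance.cvd_run <- function(x, ...) x$summary

#' @describeIn cvd_pipeline Per-repeat metric bars.
#' @param object A `cvd_run`.
#' @method autoplot cvd_run
#' @export
autoplot.cvd_run <- function(object, ...) {
  long <- tidyr::pivot_longer(object$metrics, -"repeat_id",
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value,
                                     fill = factor(.data$repeat_id))) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "Value", fill = "Repeat") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
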