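#' Hybrid LSTM + QNN soft-voting classifier
#'
#' Combines a trained LSTM and a trained quantum neural network over the same
#' feature columns; the hybrid probability is the arithmetic mean of the two
#' submodel probabilities and the label is 1 when the probability meets the
#' decision threshold (ties go to the positive class).
#'
#' @param lstm Trained [lstm_init()] weights.
#' @param qnn Trained [qnn_init()] parameters.
#' @param threshold Decision threshold (default 0.5).
#' @param columns Optional character vector naming the feature columns the
#'   submodels expect, used to subset prediction input.
#' @return An object of class `hybrid_model`.
#' @export
hybrid_model <- function(lstm, qnn, threshold = 0.5, columns = NULL) {
  stopifnot(inherits(lstm, "lstm_weights"), inherits(qnn, "qnn_params"))
  structure(list(lstm = lstm, qnn = qnn, threshold = threshold,
                 columns = columns),
            class = "hybrid_model")
}

#' @export
print.hybrid_model <- function(x, ...) {
  cat("<hybrid_model> LSTM(h =", x$lstm$hidden, ") + QNN(", x$qnn$n_hidden,
      "units,", x$qnn$n_s, "levels ), threshold =", x$threshold, "\n")
  invisible(x)
}

#' Predict with the hybrid classifier
#'
#' @param object A [hybrid_model()].
#' @param newdata Data frame or matrix of samples in rows (feature columns
#'   only, or any superset when the model stores `columns`).
#' @param ... Unused.
#' @return A tibble with columns `p_lstm`, `p_qnn`, `probability`
#'   (their mean) and `label` (0/1).
#' @export
predict.hybrid_model <- function(object, newdata, ...) {
  X <- if (is.data.frame(newdata)) {
    if (!is.null(object$columns)) newdata <- newdata[object$columns]
    as.matrix(newdata)
  } else {
    as.matrix(newdata)
  }
  p_lstm <- lstm_forward_batch(object$lstm, X)
  p_qnn <- qnn_forward_batch(object$qnn, X)
  prob <- (p_lstm + p_qnn) / 2
  tibble::tibble(p_lstm = p_lstm, p_qnn = p_qnn, probability = prob,
                 label = as.integer(prob >= object$threshold))
}

#' @describeIn hybrid_model Component sizes as a tibble.
#' @param x A `hybrid_model`.
#' @param ... Unused.
#' @method tidy hybrid_model
#' @export
tidy.hybrid_model <- function(x, ...) {
  tibble::tibble(
    component = c("lstm", "qnn"),
    parameters = c(4 * x$lstm$hidden * (x$lstm$hidden + x$lstm$input_dim) +
                     5 * x$lstm$hidden + 1,
                   x$qnn$n_hidden * (x$qnn$input_dim + x$qnn$n_s + 1) + 1)
  )
}

#' @describeIn hybrid_model One-row model summary.
#' @method glance hybrid_model
#' @export
glance.hybrid_model <- function(x, ...) {
  tibble::tibble(lstm_hidden = x$lstm$hidden, qnn_hidden = x$qnn$n_hidden,
                 qnn_levels = x$qnn$n_s, threshold = x$threshold,
                 n_features = length(x$columns %||% NA_character_))
}

#' Save or load a hybrid model as JSON
#'
#' Serializes shapes, flattened weights and configuration to plain JSON so
#' models round-trip across sessions.
#'
#' @param model A [hybrid_model()].
#' @param path File path.
#' @return `save_hybrid_model()` returns `path` invisibly;
#'   `load_hybrid_model()` returns the restored `hybrid_model`.
#' @export
save_hybrid_model <- function(model, path) {
  enc <- function(m) if (is.matrix(m)) list(dim = dim(m), data = as.numeric(m))
                     else m
  payload <- list(
    lstm = lapply(unclass(model$lstm), enc),
    qnn = lapply(unclass(model$qnn), enc),
    threshold = model$threshold,
    columns = model$columns
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_hybrid_model
#' @export
load_hybrid_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  dec <- function(x) {
    if (is.list(x) && !is.null(x$dim)) matrix(x$data, x$dim[1], x$dim[2])
    else if (is.list(x)) unlist(x)
    else x
  }
  lstm <- lapply(payload$lstm, dec)
  qnn <- lapply(payload$qnn, dec)
  class(lstm) <- "lstm_weights"
  class(qnn) <- "qnn_params"
  hybrid_model(lstm, qnn, threshold = payload$threshold,
               columns = payload$columns)
}
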