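# CNN-LSTM saccade classifier with validation-recall model selection.
#
# Architecture (fixed order): conv1d -> ReLU -> maxpool(2) -> conv1d ->
# ReLU -> maxpool(2) -> LSTM -> dropout -> dense softmax(3). With the
# reference configuration (kernel 3, no implicit padding, pool 2) the
# sequence entering the LSTM has ((192 - 2) / 2 - 2) / 2 = 46 steps.
# Optimization details (Adam, learning rate, batch size, epochs) are not
# part of the method description and live in `training_config`.

#' CNN-LSTM architecture configuration
#'
#' Defaults are the reference architecture: two conv1d blocks of kernel 3
#' with 128 filters each (ReLU + max pool 2, valid padding), an LSTM with
#' 100 units, dropout 0.6 and a 3-unit softmax output.
#'
#' @param input_length samples per saccade window.
#' @param kernel_size conv kernel size.
#' @param conv_filters integer length-2, filters of the two conv blocks.
#' @param lstm_units LSTM hidden units.
#' @param dropout dropout rate applied after the LSTM (training only).
#' @param n_classes output classes.
#' @return object of class `model_config`, including the derived per-layer
#'   sequence lengths (`seq_lengths`).
#' @export
model_config <- function(input_length = 192L, kernel_size = 3L,
                         conv_filters = c(128L, 128L), lstm_units = 100L,
                         dropout = 0.6, n_classes = 3L) {
  stopifnot(kernel_size >= 1L, length(conv_filters) == 2L,
            all(conv_filters >= 1L), lstm_units >= 1L,
            dropout >= 0, dropout < 1)
  l1 <- input_length - kernel_size + 1L
  l2 <- l1 %/% 2L
  l3 <- l2 - kernel_size + 1L
  l4 <- l3 %/% 2L
  if (l4 < 1L) stop("input too short for the conv/pool stack", call. = FALSE)
  structure(list(input_length = as.integer(input_length),
                 kernel_size = as.integer(kernel_size),
                 conv_filters = as.integer(conv_filters),
                 lstm_units = as.integer(lstm_units),
                 dropout = dropout, n_classes = as.integer(n_classes),
                 seq_lengths = c(input = input_length, conv1 = l1,
                                 pool1 = l2, conv2 = l3, pool2 = l4)),
            class = "model_config")
}

#' Build an untrained CNN-LSTM model
#'
#' Parameters are initialized under `seed` (He-normal for convolutions,
#' uniform +-1/sqrt(H) for the LSTM with forget-gate bias 1, Glorot-uniform
#' for the dense layer); two models built with the same seed are identical.
#'
#' @param config a [model_config()].
#' @param seed integer seed.
#' @return object of class `cnn_lstm` with `params` and `config`.
#' @export
build_model <- function(config = model_config(), seed = 1L) {
  k <- config$kernel_size
  f1 <- config$conv_filters[1L]; f2 <- config$conv_filters[2L]
  h <- config$lstm_units; nc <- config$n_classes
  params <- with_seed(seed, {
    s <- 1 / sqrt(h)
    bl <- stats::runif(4L * h, -s, s)
    bl[(h + 1L):(2L * h)] <- 1  # forget gate bias
    list(W1 = matrix(stats::rnorm(k * f1, 0, sqrt(2 / k)), k, f1),
         b1 = numeric(f1),
         W2 = matrix(stats::rnorm(k * f1 * f2, 0, sqrt(2 / (k * f1))),
                     k * f1, f2),
         b2 = numeric(f2),
         Wx = matrix(stats::runif(f2 * 4L * h, -s, s), f2, 4L * h),
         Wh = matrix(stats::runif(h * 4L * h, -s, s), h, 4L * h),
         bl = bl,
         Wd = matrix(stats::runif(h * nc, -sqrt(6 / (h + nc)),
                                  sqrt(6 / (h + nc))), h, nc),
         bd = numeric(nc))
  })
  structure(list(params = params, config = config, seed = as.integer(seed)),
            class = "cnn_lstm")
}

#' Training configuration
#'
#' @param max_epochs maximum training epochs (>= 1).
#' @param batch_size mini-batch size.
#' @param learning_rate Adam learning rate.
#' @param seed integer seed driving shuffling, dropout and any other
#'   training-time randomness.
#' @param selection `"recall_compromise"` (checkpoint on the best
#'   min(recall C, recall P) over validation registers) or `"accuracy"`.
#' @return object of class `training_config`.
#' @export
training_config <- function(max_epochs = 100L, batch_size = 64L,
                            learning_rate = 1e-3, seed = 1L,
                            selection = c("recall_compromise", "accuracy")) {
  stopifnot(max_epochs >= 1L, batch_size >= 1L, learning_rate > 0)
  structure(list(max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 selection = match.arg(selection)),
            class = "training_config")
}

#' Class probabilities for saccade windows
#'
#' @param model a `cnn_lstm` or `trained_cnn_lstm`.
#' @param X numeric matrix of windows (rows), or a [saccade_dataset()].
#' @param batch_size forward-pass batch size.
#' @return N x 3 matrix of softmax probabilities (columns C, P, S).
#' @export
predict_saccade_probs <- function(model, X, batch_size = 512L) {
  X <- as_sample_matrix(X)
  if (ncol(X) != model$config$input_length) {
    stop("windows have ", ncol(X), " samples; model expects ",
         model$config$input_length, call. = FALSE)
  }
  n <- nrow(X)
  out <- matrix(NA_real_, n, model$config$n_classes,
                dimnames = list(NULL, diagnosis_levels))
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    out[i:j, ] <- nn_forward(model$params, X[i:j, , drop = FALSE],
                             model$config, train = FALSE)$probs
    i <- j + 1L
  }
  out
}

#' Predicted labels for saccade windows
#'
#' Argmax of the softmax output; exact probability ties are broken by the
#' severity order S > P > C.
#'
#' @inheritParams predict_saccade_probs
#' @return character vector of labels.
#' @export
predict_saccade_labels <- function(model, X, batch_size = 512L) {
  X <- as_sample_matrix(X)
  if (nrow(X) == 0L) return(character(0))
  probs <- predict_saccade_probs(model, X, batch_size)
  apply(probs, 1L, function(p) {
    cand <- diagnosis_levels[p >= max(p)]
    severity_tiebreak(cand)
  })
}

#' Recall compromise between control and presymptomatic
#'
#' The model-selection score: `min(recall_C, recall_P)`. It is 0 whenever
#' the classifier sacrifices either of the two confusable classes -- in
#' particular for the failure mode where no presymptomatic register is
#' recovered. Ties between checkpoints are resolved by higher macro recall,
#' then by the earlier epoch (handled in [train_with_selection()]).
#'
#' @param recalls named numeric vector with at least entries `C` and `P`,
#'   each in `[0, 1]`.
#' @return scalar score in `[0, 1]`.
#' @export
compromise_score <- function(recalls) {
  if (!all(c("C", "P") %in% names(recalls))) {
    stop("recalls must contain entries for classes C and P", call. = FALSE)
  }
  r <- recalls[c("C", "P")]
  if (any(is.na(r)) || any(r < 0) || any(r > 1)) {
    stop("recalls must lie in [0, 1]", call. = FALSE)
  }
  unname(min(r))
}

#' Train the classifier with register-recall model selection
#'
#' Trains by mini-batch Adam on cross-entropy over the training saccades'
#' `working_label` (which may have been relabeled). After every epoch the
#' validation saccades are predicted, aggregated to registers by majority
#' vote, and register-level per-class recall is computed against the
#' registers' ORIGINAL diagnoses (validation labels are never relabeled).
#' Parameters are checkpointed whenever the selection score improves; the
#' best checkpoint and the full history are returned.
#'
#' @param model an untrained `cnn_lstm` from [build_model()].
#' @param train_ds training [saccade_dataset()] (uses `working_label`).
#' @param val_ds validation [saccade_dataset()]; must contain registers of
#'   all three classes, otherwise a recall is undefined and an error is
#'   raised.
#' @param t_config a [training_config()].
#' @return object of class `trained_cnn_lstm`: `params` (best checkpoint),
#'   `selected_epoch`, `history` (per-epoch loss and validation register
#'   recalls), `config`, `t_config`.
#' @export
train_with_selection <- function(model, train_ds, val_ds,
                                 t_config = training_config()) {
  stopifnot(inherits(model, "cnn_lstm"),
            inherits(train_ds, "saccade_dataset"),
            inherits(val_ds, "saccade_dataset"))
  X <- train_ds$samples
  y <- match(as_diagnosis(train_ds$meta$working_label), diagnosis_levels)
  present <- sort(unique(val_ds$registers$diagnosis))
  if (!identical(present, diagnosis_levels)) {
    stop("validation registers must cover all classes C, P, S; found: ",
         paste(present, collapse = ", "), call. = FALSE)
  }
  n <- nrow(X)
  cfg <- model$config
  params <- model$params
  state <- nn_adam_init(params)
  best <- list(params = params, score = -Inf, macro = -Inf, epoch = 0L)
  hist <- vector("list", t_config$max_epochs)
  with_seed(t_config$seed, {
    for (epoch in seq_len(t_config$max_epochs)) {
      idx <- sample.int(n)
      loss_sum <- 0
      nb <- 0L
      i <- 1L
      while (i <= n) {
        j <- min(i + t_config$batch_size - 1L, n)
        bi <- idx[i:j]
        fwd <- nn_forward(params, X[bi, , drop = FALSE], cfg, train = TRUE)
        loss_sum <- loss_sum + nn_loss(fwd$probs, y[bi])
        grads <- nn_backward(params, fwd, y[bi])
        upd <- nn_adam_step(params, grads, state,
                            lr = t_config$learning_rate)
        params <- upd$params
        state <- upd$state
        nb <- nb + 1L
        i <- j + 1L
      }
      eval_model <- structure(list(params = params, config = cfg),
                              class = "cnn_lstm")
      if (t_config$selection == "recall_compromise") {
        pred <- predict_saccade_labels(eval_model, val_ds$samples)
        reg_pred <- vote_registers(val_ds, pred)
        cm <- confusion_matrix(reg_pred$diagnosis, reg_pred$predicted,
                               level = "register")
        recalls <- class_metrics(cm)$per_class$recall
        names(recalls) <- diagnosis_levels
        score <- compromise_score(recalls)
        macro <- mean(recalls)
      } else {
        pred <- predict_saccade_labels(eval_model, val_ds$samples)
        score <- mean(pred == val_ds$meta$given_label)
        macro <- score
        recalls <- c(C = NA_real_, P = NA_real_, S = NA_real_)
      }
      if (score > best$score ||
          (score == best$score && macro > best$macro)) {
        best <- list(params = params, score = score, macro = macro,
                     epoch = epoch)
      }
      hist[[epoch]] <- data.frame(epoch = epoch,
                                  train_loss = loss_sum / nb,
                                  recall_C = recalls[["C"]],
                                  recall_P = recalls[["P"]],
                                  recall_S = recalls[["S"]],
                                  score = score)
    }
  })
  structure(list(params = best$params, config = cfg, t_config = t_config,
                 selected_epoch = best$epoch, selected_score = best$score,
                 history = do.call(rbind, hist), seed = model$seed),
            class = c("trained_cnn_lstm", "cnn_lstm"))
}

#' @export
print.cnn_lstm <- function(x, ...) {
  cfg <- x$config
  cat("<", class(x)[1L], "> conv(", cfg$kernel_size, ",",
      cfg$conv_filters[1L], ") -> pool2 -> conv(", cfg$kernel_size, ",",
      cfg$conv_filters[2L], ") -> pool2 -> lstm(", cfg$lstm_units,
      ") -> dropout(", cfg$dropout, ") -> dense(", cfg$n_classes,
      ", softmax); ", cfg$seq_lengths[["pool2"]],
      " steps enter the LSTM\n", sep = "")
  if (!is.null(x$selected_epoch)) {
    cat("  selected epoch ", x$selected_epoch, " (score ",
        signif(x$selected_score, 3), ")\n", sep = "")
  }
  invisible(x)
}

#' Persist a trained model as plain text
#'
#' Weights are written as one CSV per parameter tensor under `dir`, with a
#' JSON manifest (`model.json`) holding the architecture, seeds, selected
#' epoch and history.
#'
#' @param model a `cnn_lstm` / `trained_cnn_lstm`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(model$params)) {
    data.table::fwrite(as.data.frame(as.matrix(model$params[[nm]])),
                       file.path(dir, paste0(nm, ".csv")))
  }
  manifest <- list(config = unclass(model$config),
                   t_config = if (!is.null(model$t_config))
                     unclass(model$t_config),
                   selected_epoch = model$selected_epoch,
                   history = model$history, seed = model$seed)
  jsonlite::write_json(manifest, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname save_model
#' @param dir directory written by `save_model`.
#' @export
load_model <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "model.json"),
                                  simplifyVector = TRUE)
  cfg <- do.call(model_config,
                 manifest$config[c("input_length", "kernel_size",
                                   "conv_filters", "lstm_units", "dropout",
                                   "n_classes")])
  params <- list()
  for (nm in c("W1", "b1", "W2", "b2", "Wx", "Wh", "bl", "Wd", "bd")) {
    m <- as.matrix(data.table::fread(file.path(dir, paste0(nm, ".csv"))))
    dimnames(m) <- NULL
    params[[nm]] <- if (ncol(m) == 1L) as.numeric(m) else m
  }
  structure(list(params = params, config = cfg,
                 selected_epoch = manifest$selected_epoch,
                 history = manifest$history, seed = manifest$seed),
            class = c("trained_cnn_lstm", "cnn_lstm"))
}
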