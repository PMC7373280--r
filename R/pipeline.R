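# End-to-end orchestration: split -> SOM relabeling (threshold sweep) ->
# CNN-LSTM training with validation selection -> register voting ->
# aggregated reports and automated threshold selection.
#
# Seed scheme: the dataset (if synthetic) is a pure function of its
# generator seed; the register split uses `split_seed` and is shared by
# every configuration; run r of every threshold uses
# derive_seed(seed, 1000 + r), so the theta = 0 baseline and each relabeled
# configuration are paired at matched seeds. Within a run the SOM, model
# initialization and training draw from derived sub-seeds.

#' Pipeline configuration
#'
#' @param data a [saccade_dataset()], a [generator_config()] (the dataset is
#'   generated on first use), or a path to a saccade-table CSV.
#' @param split_fractions train/validation/test fractions.
#' @param split_seed seed of the register split (shared across all
#'   configurations so every threshold sees the same division).
#' @param som list of arguments for [train_som()] (width, height, epochs,
#'   learning_rate, radius).
#' @param sweep_values relabeling thresholds to try; the no-relabel baseline
#'   (theta = 0) is always run in addition.
#' @param model a [model_config()].
#' @param training a [training_config()] (its seed is overridden by the
#'   per-run derived seed).
#' @param repeats repeated runs per configuration (>= 1).
#' @param seed root seed for the per-run streams.
#' @param out_dir optional artifact directory.
#' @param verbose print progress.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(data,
                            split_fractions = c(0.4, 0.4, 0.2),
                            split_seed = 1L,
                            som = list(width = 10L, height = 10L,
                                       epochs = 10L, learning_rate = 0.5),
                            sweep_values = c(2, 3, 4, 4.5),
                            model = model_config(),
                            training = training_config(),
                            repeats = 10L,
                            seed = 1L,
                            out_dir = NULL,
                            verbose = FALSE) {
  stopifnot(repeats >= 1L, all(sweep_values > 0))
  structure(list(data = data, split_fractions = split_fractions,
                 split_seed = as.integer(split_seed), som = som,
                 sweep_values = sweep_values, model = model,
                 training = training, repeats = as.integer(repeats),
                 seed = as.integer(seed), out_dir = out_dir,
                 verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

resolve_dataset <- function(config) {
  d <- config$data
  if (inherits(d, "saccade_dataset")) return(d)
  if (inherits(d, "generator_config")) return(generate_dataset(d))
  if (is.character(d)) return(read_saccade_table(d))
  stop("pipeline data must be a dataset, generator_config or CSV path",
       call. = FALSE)
}

#' Execute one run of the relabel-train-evaluate pipeline
#'
#' Splits the registers, optionally trains a SOM on the training saccades
#' and relabels them at `threshold` (`threshold = 0` skips relabeling),
#' trains the CNN-LSTM with validation-register recall selection, predicts
#' the test saccades and votes the test registers. Validation and test
#' labels are never touched by relabeling (asserted internally).
#'
#' @param config a [pipeline_config()].
#' @param threshold relabeling threshold (>= 0; 0 = no relabeling).
#' @param run_seed integer seed for this run's SOM / initialization /
#'   training streams.
#' @param dataset optionally the pre-resolved dataset (avoids regenerating
#'   it on every run of a sweep).
#' @return list with `val` and `test` (each a list of `register` and
#'   `saccade` [evaluation_report()]s), `relabel` (summary or `NULL`),
#'   `selected_epoch`, `threshold`, `run_seed`.
#' @export
run_single <- function(config, threshold, run_seed,
                       dataset = NULL) {
  stopifnot(threshold >= 0)
  ds <- dataset %||% resolve_dataset(config)
  split <- split_registers(ds, config$split_fractions, config$split_seed)
  parts <- apply_split(ds, split)
  guard_val <- paste(parts$val$meta$given_label, collapse = "")
  guard_test <- paste(parts$test$meta$given_label, collapse = "")
  relabel_summary <- NULL
  train_ds <- parts$train
  if (threshold > 0) {
    grid <- do.call(train_som,
                    c(list(x = train_ds, seed = derive_seed(run_seed, 1L)),
                      config$som))
    rl <- relabel_training_set(grid, train_ds, threshold)
    train_ds <- rl$dataset
    relabel_summary <- rl$summary
  }
  tcfg <- config$training
  tcfg$seed <- derive_seed(run_seed, 3L)
  model <- build_model(config$model, seed = derive_seed(run_seed, 2L))
  trained <- train_with_selection(model, train_ds, parts$val, tcfg)
  reports <- lapply(list(val = parts$val, test = parts$test), function(p) {
    pred <- predict_saccade_labels(trained, p$samples)
    reg <- vote_registers(p, pred)
    list(register = evaluation_report(
           confusion_matrix(reg$diagnosis, reg$predicted, "register"),
           level = "register", threshold = threshold, n_runs = 1L,
           seeds = run_seed),
         saccade = evaluation_report(
           confusion_matrix(p$meta$given_label, pred, "saccade"),
           level = "saccade", threshold = threshold, n_runs = 1L,
           seeds = run_seed))
  })
  stopifnot(identical(guard_val,
                      paste(parts$val$meta$given_label, collapse = "")),
            identical(guard_test,
                      paste(parts$test$meta$given_label, collapse = "")))
  list(val = reports$val, test = reports$test,
       relabel = relabel_summary, selected_epoch = trained$selected_epoch,
       threshold = threshold, run_seed = run_seed)
}

#' Run the full threshold sweep
#'
#' For every threshold in `{0} U sweep_values`, performs `repeats` runs on
#' the same register split (run r of every threshold shares the same
#' derived seed, pairing the baseline with each configuration) and
#' aggregates the reports by mean confusion matrix.
#'
#' @param config a [pipeline_config()].
#' @return object of class `sweep_result`: `entries` (one per threshold,
#'   each with aggregated `val_register`, `val_saccade`, `test_register`,
#'   `test_saccade` reports and per-run `relabel` summaries), `config`.
#' @export
run_threshold_sweep <- function(config) {
  ds <- resolve_dataset(config)
  thetas <- c(0, sort(unique(config$sweep_values)))
  run_seeds <- vapply(seq_len(config$repeats),
                      function(r) derive_seed(config$seed, 1000L + r),
                      integer(1))
  entries <- lapply(thetas, function(th) {
    runs <- lapply(run_seeds, function(s) {
      tandem_log("theta %.1f, run seed %d", th, s,
                 verbose = config$verbose)
      run_single(config, th, s, dataset = ds)
    })
    agg <- function(field, lvl) {
      aggregate_runs(lapply(runs, function(r) r[[field]][[lvl]]))
    }
    list(threshold = th,
         val_register = agg("val", "register"),
         val_saccade = agg("val", "saccade"),
         test_register = agg("test", "register"),
         test_saccade = agg("test", "saccade"),
         relabel = lapply(runs, `[[`, "relabel"),
         selected_epochs = vapply(runs, `[[`, integer(1),
                                  "selected_epoch"))
  })
  names(entries) <- paste0("theta_", thetas)
  structure(list(entries = entries, thresholds = thetas,
                 run_seeds = run_seeds, config = config),
            class = "sweep_result")
}

#' Select the relabeling threshold from a sweep
#'
#' Maximizes the recall compromise (min of validation register recall for C
#' and P) over the aggregated validation reports of the non-baseline
#' entries; ties go to the higher macro recall, then to the smaller
#' threshold. This automates the inspection-based choice of the original
#' study and recovers its reasoning pattern (a threshold whose P gain does
#' not sacrifice C).
#'
#' @param sweep a `sweep_result`.
#' @return the selected threshold (numeric scalar).
#' @export
select_threshold <- function(sweep) {
  entries <- Filter(function(e) e$threshold > 0, sweep$entries)
  if (!length(entries)) stop("sweep has no non-baseline entries",
                             call. = FALSE)
  stats_ <- lapply(entries, function(e) {
    rec <- e$val_register$metrics$per_class$recall
    names(rec) <- diagnosis_levels
    c(theta = e$threshold, score = compromise_score(rec),
      macro = mean(rec))
  })
  tab <- do.call(rbind, stats_)
  ord <- order(-tab[, "score"], -tab[, "macro"], tab[, "theta"])
  unname(tab[ord[1L], "theta"])
}

#' Run the complete experiment
#'
#' Threshold sweep, automated threshold selection, and the selected
#' configuration's aggregated test evaluation. If `config$out_dir` is set,
#' writes a run directory: configuration snapshot, per-threshold aggregated
#' reports (JSON), relabel summaries (CSV), sweep metrics table (CSV) and a
#' text log.
#'
#' @param config a [pipeline_config()].
#' @return list with `selected_threshold`, `final_test` (list of `register`
#'   and `saccade` aggregated reports at the selected threshold), `sweep`.
#' @export
run_full_pipeline <- function(config) {
  out_dir <- config$out_dir
  log_file <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    log_file <- file.path(out_dir, "pipeline.log")
  }
  tandem_log("starting sweep over thresholds {%s} + baseline, %d repeats",
             paste(config$sweep_values, collapse = ", "), config$repeats,
             verbose = config$verbose, log_file = log_file)
  sweep <- run_threshold_sweep(config)
  theta <- select_threshold(sweep)
  entry <- sweep$entries[[paste0("theta_", theta)]]
  tandem_log("selected theta = %.1f (val register recall compromise)",
             theta, verbose = config$verbose, log_file = log_file)
  if (!is.null(out_dir)) {
    cfg_snapshot <- list(split_fractions = config$split_fractions,
                         split_seed = config$split_seed, som = config$som,
                         sweep_values = config$sweep_values,
                         model = unclass(config$model),
                         training = unclass(config$training),
                         repeats = config$repeats, seed = config$seed,
                         run_seeds = sweep$run_seeds,
                         selected_threshold = theta)
    jsonlite::write_json(cfg_snapshot, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    rows <- lapply(sweep$entries, function(e) {
      data.frame(threshold = e$threshold,
                 val_register_accuracy = e$val_register$accuracy,
                 test_register_accuracy = e$test_register$accuracy,
                 test_saccade_accuracy = e$test_saccade$accuracy,
                 val_recall_C = e$val_register$metrics$per_class$recall[1L],
                 val_recall_P = e$val_register$metrics$per_class$recall[2L],
                 val_recall_S = e$val_register$metrics$per_class$recall[3L])
    })
    utils::write.csv(do.call(rbind, rows),
                     file.path(out_dir, "sweep_metrics.csv"),
                     row.names = FALSE)
    for (nm in names(sweep$entries)) {
      e <- sweep$entries[[nm]]
      for (lvl in c("val_register", "val_saccade", "test_register",
                    "test_saccade")) {
        write_report_json(e[[lvl]],
                          file.path(out_dir, paste0(nm, "_", lvl,
                                                    ".json")))
      }
      summaries <- Filter(Negate(is.null), e$relabel)
      if (length(summaries)) {
        utils::write.csv(relabel_summary_table(summaries),
                         file.path(out_dir, paste0(nm,
                                                   "_relabel.csv")),
                         row.names = FALSE)
      }
    }
    tandem_log("artifacts written to %s", out_dir,
               verbose = config$verbose, log_file = log_file)
  }
  list(selected_threshold = theta,
       final_test = list(register = entry$test_register,
                         saccade = entry$test_saccade),
       sweep = sweep)
}
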