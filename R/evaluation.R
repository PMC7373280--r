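# Register-level voting, confusion matrices, per-class metrics, run
# aggregation.

#' Majority-vote classification of a register
#'
#' The most frequent predicted saccade label; ties are broken by the
#' severity order S > P > C (the clinically conservative choice).
#'
#' @param saccade_labels non-empty character vector of predicted labels.
#' @return a single label.
#' @export
classify_register <- function(saccade_labels) {
  if (!length(saccade_labels)) stop("empty register", call. = FALSE)
  counts <- table(factor(as_diagnosis(saccade_labels),
                         levels = diagnosis_levels))
  cand <- diagnosis_levels[counts == max(counts)]
  severity_tiebreak(cand)
}

#' Vote every register of a dataset from per-saccade predictions
#'
#' @param ds a [saccade_dataset()].
#' @param predicted character vector aligned with the dataset's saccades.
#' @return data.frame with `register_id`, `diagnosis` (true) and
#'   `predicted` (voted label).
#' @export
vote_registers <- function(ds, predicted) {
  stopifnot(length(predicted) == n_saccades(ds))
  voted <- vapply(split(predicted, ds$meta$register_id), classify_register,
                  character(1))
  out <- ds$registers
  out$predicted <- unname(voted[out$register_id])
  out
}

#' Confusion matrix over the three diagnosis classes
#'
#' @param true,predicted equal-length label vectors.
#' @param level `"register"` or `"saccade"` (bookkeeping attribute).
#' @return 3x3 matrix (rows = true C/P/S, columns = predicted), class
#'   `confusion_matrix`.
#' @export
confusion_matrix <- function(true, predicted,
                             level = c("register", "saccade")) {
  level <- match.arg(level)
  if (length(true) != length(predicted)) {
    stop("true and predicted labels differ in length", call. = FALSE)
  }
  m <- table(true = factor(as_diagnosis(true), levels = diagnosis_levels),
             predicted = factor(as_diagnosis(predicted),
                                levels = diagnosis_levels))
  m <- unclass(m)
  structure(m, level = level, class = c("confusion_matrix", "matrix"))
}

#' Per-class and macro precision / recall / F1 from a confusion matrix
#'
#' `recall_i = M[i,i] / rowsum_i`, `precision_j = M[j,j] / colsum_j`,
#' `F1 = 2PR / (P + R)`; zero denominators yield 0 so macro averages stay
#' defined. Accuracy is trace / total.
#'
#' @param m a 3x3 confusion matrix (entries may be run-means).
#' @return list with `per_class` (data.frame class/precision/recall/f1),
#'   `macro` (named vector), `accuracy`.
#' @export
class_metrics <- function(m) {
  m <- unclass(as.matrix(m))
  stopifnot(nrow(m) == 3L, ncol(m) == 3L)
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  recall <- safe_div(diag(m), rowSums(m))
  precision <- safe_div(diag(m), colSums(m))
  f1 <- safe_div(2 * precision * recall, precision + recall)
  per_class <- data.frame(class = diagnosis_levels,
                          precision = unname(precision),
                          recall = unname(recall), f1 = unname(f1),
                          stringsAsFactors = FALSE)
  list(per_class = per_class,
       macro = c(precision = mean(precision), recall = mean(recall),
                 f1 = mean(f1)),
       accuracy = safe_div(sum(diag(m)), sum(m)))
}

#' Bundle a confusion matrix into an evaluation report
#'
#' @param confusion a [confusion_matrix()] (or plain 3x3 matrix).
#' @param level `"register"` or `"saccade"`.
#' @param threshold relabeling threshold the run used (0 = no relabeling).
#' @param n_runs number of runs the matrix aggregates.
#' @param seeds integer seeds of those runs.
#' @return object of class `evaluation_report`.
#' @export
evaluation_report <- function(confusion, level = c("register", "saccade"),
                              threshold = NA_real_, n_runs = 1L,
                              seeds = integer(0)) {
  level <- if (inherits(confusion, "confusion_matrix") &&
               missing(level)) attr(confusion, "level")
           else match.arg(level)
  m <- unclass(as.matrix(confusion))
  attr(m, "level") <- NULL
  met <- class_metrics(m)
  structure(list(confusion = m, level = level, metrics = met,
                 accuracy = met$accuracy, threshold = threshold,
                 n_runs = as.integer(n_runs), seeds = seeds),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> level = ", x$level,
      if (!is.na(x$threshold)) paste0(", theta = ", x$threshold),
      ", runs = ", x$n_runs, "\n", sep = "")
  print(round(x$confusion, 2))
  cat(sprintf("  accuracy %.2f%%; recalls C %.3f / P %.3f / S %.3f\n",
              100 * x$accuracy,
              x$metrics$per_class$recall[1L],
              x$metrics$per_class$recall[2L],
              x$metrics$per_class$recall[3L]))
  invisible(x)
}

#' Aggregate evaluation reports over repeated runs
#'
#' Element-wise mean of the confusion matrices; metrics are recomputed from
#' the mean matrix (so fractional entries such as a 0.7 run-mean
#' misclassification behave exactly like the printed run-mean matrices).
#'
#' @param reports non-empty list of `evaluation_report`s with matching
#'   level and threshold.
#' @return a single `evaluation_report`.
#' @export
aggregate_runs <- function(reports) {
  stopifnot(length(reports) >= 1L)
  lv <- unique(vapply(reports, `[[`, character(1), "level"))
  th <- unique(vapply(reports, `[[`, numeric(1), "threshold"))
  if (length(lv) != 1L || length(th) != 1L) {
    stop("cannot aggregate reports with mixed levels or thresholds",
         call. = FALSE)
  }
  mats <- lapply(reports, `[[`, "confusion")
  mean_m <- Reduce(`+`, mats) / length(mats)
  evaluation_report(mean_m, level = lv, threshold = th,
                    n_runs = sum(vapply(reports, `[[`, integer(1),
                                        "n_runs")),
                    seeds = unlist(lapply(reports, `[[`, "seeds")))
}

#' Serialize an evaluation report to JSON
#'
#' @param report an `evaluation_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(
    list(level = report$level, threshold = report$threshold,
         n_runs = report$n_runs, seeds = report$seeds,
         confusion = report$confusion,
         per_class = report$metrics$per_class,
         macro = as.list(report$metrics$macro),
         accuracy = report$accuracy),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
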