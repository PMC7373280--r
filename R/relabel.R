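# Cell-wise relabeling of training saccades (the label-noise correction).
#
# Decision rule per SOM cell, given its label counts (nC, nP, nS) and the
# ratio threshold theta:
#   1. strict S plurality (nS > nC and nS > nP)        -> S
#   2. no presymptomatic saccades in the cell (nP = 0) -> C
#   3. nC / nP < theta                                 -> P
#   4. otherwise                                       -> C
# A theta of 2 means the control count must be at least double the
# presymptomatic count for the cell to stay control; larger theta shifts
# more cells (hence saccades) to P. The S branch never involves theta, so
# the number of saccades relabeled to S is theta-invariant.

#' Relabeling configuration
#'
#' @param threshold ratio threshold theta (> 0).
#' @param sweep_values candidate thresholds for the experiment sweep.
#' @return object of class `relabel_config`.
#' @export
relabel_config <- function(threshold = 4, sweep_values = c(2, 3, 4, 4.5)) {
  stopifnot(threshold > 0, all(sweep_values > 0))
  structure(list(threshold = threshold, sweep_values = sweep_values),
            class = "relabel_config")
}

#' Relabel one cell's saccades from its label counts
#'
#' @param counts numeric length-3 `(nC, nP, nS)` with at least one positive
#'   entry.
#' @param threshold ratio threshold theta (> 0).
#' @return a single label `"C"`, `"P"` or `"S"`.
#' @export
relabel_saccade <- function(counts, threshold) {
  stopifnot(length(counts) == 3L, threshold > 0)
  if (any(counts < 0) || sum(counts) < 1) {
    stop("counts must be non-negative with at least one saccade",
         call. = FALSE)
  }
  nC <- counts[[1L]]; nP <- counts[[2L]]; nS <- counts[[3L]]
  if (nS > max(nC, nP)) return("S")
  if (nP == 0) return("C")
  if (nC / nP < threshold) return("P")
  "C"
}

#' Relabel a training collection through a trained map
#'
#' Sets every saccade's `working_label` to the decision of its BMU cell
#' (computed from the collection's own `given_label` counts); `given_label`
#' is never touched.
#'
#' @param grid a trained `som_grid`.
#' @param ds the training [saccade_dataset()].
#' @param threshold ratio threshold theta (> 0).
#' @param counts optional precomputed [compute_cell_counts()] for `ds`
#'   (reused across a threshold sweep).
#' @return list with `dataset` (relabeled copy) and `summary`
#'   (a `relabel_summary`).
#' @export
relabel_training_set <- function(grid, ds, threshold, counts = NULL) {
  stopifnot(inherits(ds, "saccade_dataset"))
  if (is.null(counts)) counts <- compute_cell_counts(grid, ds)
  bmu <- attr(counts, "bmu")
  stopifnot(length(bmu) == n_saccades(ds))
  used <- sort(unique(bmu))
  cell_label <- vapply(used, function(k) relabel_saccade(counts[k, ],
                                                         threshold),
                       character(1))
  new_label <- cell_label[match(bmu, used)]
  out <- ds
  out$meta$working_label <- new_label
  trans <- table(factor(ds$meta$given_label, levels = diagnosis_levels),
                 factor(new_label, levels = diagnosis_levels))
  summary <- structure(list(threshold = threshold,
                            transitions = unclass(trans),
                            n_changed = sum(trans) - sum(diag(trans))),
                       class = "relabel_summary")
  list(dataset = out, summary = summary)
}

#' @export
print.relabel_summary <- function(x, ...) {
  cat("<relabel_summary> theta = ", x$threshold, ", ", x$n_changed,
      " saccades changed\n", sep = "")
  print(x$transitions)
  invisible(x)
}

#' Tabulate relabel summaries across thresholds
#'
#' One row per (threshold, from, to) transition pair; the Fig-6-style
#' bookkeeping of how many saccades move between classes as theta varies.
#'
#' @param summaries list of `relabel_summary` objects.
#' @return data.frame with columns `threshold`, `from`, `to`, `n`.
#' @export
relabel_summary_table <- function(summaries) {
  do.call(rbind, lapply(summaries, function(s) {
    tr <- as.data.frame(as.table(s$transitions), stringsAsFactors = FALSE)
    names(tr) <- c("from", "to", "n")
    cbind(threshold = s$threshold, tr)
  }))
}
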