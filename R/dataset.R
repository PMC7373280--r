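# Core container: a set of saccade registers with per-saccade sample windows.

#' Construct a saccade dataset
#'
#' The central container of the package. A *register* is the set of all
#' saccades recorded from one patient; every saccade inherits the register's
#' diagnosis as its `given_label`. `working_label` starts equal to
#' `given_label` and is the only field the relabeling stage may change.
#'
#' @param samples numeric matrix, one row per saccade, `window_length`
#'   (default 192) columns of angular position in degrees.
#' @param meta data.frame aligned with `samples` rows, with columns
#'   `saccade_id`, `register_id`, `angle`, `given_label`, `working_label`
#'   and optionally `true_shape_label` (synthetic data only).
#' @param registers data.frame with columns `register_id`, `diagnosis`.
#'   If `NULL`, derived from `meta` (diagnosis = the register's given label).
#' @param provenance free-text note on where the data came from.
#' @return An object of class `saccade_dataset`.
#' @export
saccade_dataset <- function(samples, meta, registers = NULL,
                            provenance = "constructed") {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (is.null(registers)) {
    first <- !duplicated(meta$register_id)
    registers <- data.frame(register_id = meta$register_id[first],
                            diagnosis = meta$given_label[first],
                            stringsAsFactors = FALSE)
  }
  registers <- as.data.frame(registers, stringsAsFactors = FALSE)
  ds <- structure(list(samples = samples, meta = meta, registers = registers,
                       provenance = provenance),
                  class = "saccade_dataset")
  validate_saccade_dataset(ds)
}

#' Validate a saccade dataset's invariants
#'
#' Checks the window length (192 samples), angle domain, label validity,
#' that registers are non-empty, that saccades partition exactly onto the
#' register table (no orphans in either direction), and that every saccade's
#' `given_label` equals its register's diagnosis.
#'
#' @param ds a `saccade_dataset`.
#' @return `ds`, invisibly unchanged, or an error.
#' @export
validate_saccade_dataset <- function(ds) {
  samples <- ds$samples
  meta <- ds$meta
  registers <- ds$registers
  if (nrow(samples) != nrow(meta)) {
    stop("samples and meta disagree on the number of saccades", call. = FALSE)
  }
  if (nrow(meta) == 0L) stop("dataset contains no saccades", call. = FALSE)
  if (ncol(samples) != 192L) {
    stop("saccade windows must have 192 samples, found ", ncol(samples),
         call. = FALSE)
  }
  need <- c("saccade_id", "register_id", "angle", "given_label",
            "working_label")
  miss <- setdiff(need, names(meta))
  if (length(miss)) {
    stop("meta is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(meta$saccade_id)) {
    stop("duplicate saccade ids", call. = FALSE)
  }
  if (anyDuplicated(registers$register_id)) {
    stop("duplicate register ids", call. = FALSE)
  }
  bad_angle <- !(meta$angle %in% c(10, 20, 30, 60))
  if (any(bad_angle)) {
    stop("stimulus angle must be one of 10, 20, 30, 60; offending row(s): ",
         paste(utils::head(which(bad_angle), 5L), collapse = ", "),
         call. = FALSE)
  }
  as_diagnosis(meta$given_label)
  as_diagnosis(meta$working_label)
  as_diagnosis(registers$diagnosis)
  if (!is.null(meta$true_shape_label)) {
    as_diagnosis(meta$true_shape_label, allow_na = TRUE)
  }
  orphan <- setdiff(meta$register_id, registers$register_id)
  if (length(orphan)) {
    stop("saccades reference unknown register(s): ",
         paste(utils::head(orphan, 5L), collapse = ", "), call. = FALSE)
  }
  empty <- setdiff(registers$register_id, meta$register_id)
  if (length(empty)) {
    stop("register(s) with no saccades: ",
         paste(utils::head(empty, 5L), collapse = ", "), call. = FALSE)
  }
  diag_of <- stats::setNames(registers$diagnosis, registers$register_id)
  mism <- meta$given_label != diag_of[meta$register_id]
  if (any(mism)) {
    stop("given_label disagrees with register diagnosis for saccade(s): ",
         paste(utils::head(meta$saccade_id[mism], 5L), collapse = ", "),
         call. = FALSE)
  }
  invisible(ds)
}

#' @export
print.saccade_dataset <- function(x, ...) {
  tab <- table(factor(x$registers$diagnosis, levels = diagnosis_levels))
  stab <- table(factor(x$meta$given_label, levels = diagnosis_levels))
  cat("<saccade_dataset> ", nrow(x$registers), " registers, ",
      nrow(x$meta), " saccades (", ncol(x$samples), " samples each)\n",
      sep = "")
  cat("  registers C/P/S: ", paste(tab, collapse = "/"),
      "; saccades C/P/S: ", paste(stab, collapse = "/"), "\n", sep = "")
  cat("  provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Number of saccades / registers in a dataset
#' @param ds a `saccade_dataset`.
#' @return integer count.
#' @export
n_saccades <- function(ds) nrow(ds$meta)

#' @rdname n_saccades
#' @export
n_registers <- function(ds) nrow(ds$registers)

#' Subset a dataset by register ids
#'
#' @param ds a `saccade_dataset`.
#' @param register_ids character vector of register ids to keep.
#' @return a `saccade_dataset` restricted to those registers.
#' @export
subset_registers <- function(ds, register_ids) {
  unknown <- setdiff(register_ids, ds$registers$register_id)
  if (length(unknown)) {
    stop("unknown register id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  keep <- ds$meta$register_id %in% register_ids
  saccade_dataset(ds$samples[keep, , drop = FALSE],
                  ds$meta[keep, , drop = FALSE],
                  ds$registers[ds$registers$register_id %in% register_ids, ,
                               drop = FALSE],
                  provenance = ds$provenance)
}
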