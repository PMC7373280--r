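# Reading and writing saccade tables.
#
# Canonical on-disk form: one CSV with columns
#   saccade_id, register_id, angle, given_label, working_label,
#   [true_shape_label,] s000..s191
# Labels are the single characters C/P/S; samples are degrees
# (post-normalization unless the caller says otherwise).
# A second "matrix" layout accepts a headerless numeric matrix with 192
# columns plus a row-aligned metadata CSV, matching the deposited form of
# public saccade datasets (a (n, 192) matrix + per-row annotations).

sample_cols <- function() sprintf("s%03d", 0:191)

#' Read a saccade table
#'
#' @param path path to the CSV file (canonical layout), or to the headerless
#'   numeric matrix file when `format = "matrix"`.
#' @param format `"csv"` (canonical single file) or `"matrix"`
#'   (matrix + sidecar metadata).
#' @param metadata for `format = "matrix"`: path to a row-aligned metadata
#'   CSV with columns `register_id`, `angle` and a label column named
#'   `given_label` (or `label`); optional `saccade_id`, `working_label`.
#' @return a [saccade_dataset()].
#' @export
read_saccade_table <- function(path, format = c("csv", "matrix"),
                               metadata = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "csv") {
    dt <- data.table::fread(path, header = TRUE, sep = ",",
                            colClasses = list(character = c("saccade_id",
                                                            "register_id")))
    dt <- as.data.frame(dt, stringsAsFactors = FALSE)
    scol <- grep("^s[0-9]{3}$", names(dt), value = TRUE)
    if (length(scol) != 192L) {
      stop("expected 192 sample columns s000..s191, found ", length(scol),
           " in ", path, call. = FALSE)
    }
    scol <- sort(scol)
    samples <- as.matrix(dt[, scol])
    nonnum <- which(!vapply(dt[scol], is.numeric, logical(1)))
    if (length(nonnum)) {
      # locate the first offending cell so the error names the row
      col <- scol[nonnum[1L]]
      row <- which(is.na(suppressWarnings(as.numeric(dt[[col]]))))[1L]
      stop("non-numeric sample value in column ", col, ", row ", row,
           call. = FALSE)
    }
    meta_cols <- setdiff(names(dt), scol)
    meta <- dt[, meta_cols, drop = FALSE]
  } else {
    if (is.null(metadata)) {
      stop("format = 'matrix' needs a `metadata` sidecar path", call. = FALSE)
    }
    if (!file.exists(metadata)) {
      stop("file not found: ", metadata, call. = FALSE)
    }
    samples <- as.matrix(data.table::fread(path, header = FALSE))
    if (ncol(samples) != 192L) {
      stop("matrix file must have 192 columns, found ", ncol(samples),
           call. = FALSE)
    }
    meta <- as.data.frame(data.table::fread(metadata, header = TRUE),
                          stringsAsFactors = FALSE)
    if (nrow(meta) != nrow(samples)) {
      stop("metadata rows (", nrow(meta), ") do not match matrix rows (",
           nrow(samples), ")", call. = FALSE)
    }
    if (is.null(meta$given_label) && !is.null(meta$label)) {
      meta$given_label <- meta$label
      meta$label <- NULL
    }
  }
  if (is.null(meta$saccade_id)) {
    meta$saccade_id <- sprintf("sac%05d", seq_len(nrow(meta)))
  }
  meta$saccade_id <- as.character(meta$saccade_id)
  meta$register_id <- as.character(meta$register_id)
  if (is.null(meta$working_label)) meta$working_label <- meta$given_label
  keep <- intersect(c("saccade_id", "register_id", "angle", "given_label",
                      "working_label", "true_shape_label"), names(meta))
  saccade_dataset(samples, meta[, keep, drop = FALSE],
                  provenance = paste0("read from ", path))
}

#' Write a saccade table to CSV
#'
#' Canonical layout; `working_label` is persisted separately from
#' `given_label`, so a relabeled training table survives a round-trip.
#'
#' @param ds a [saccade_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_saccade_table <- function(ds, path) {
  validate_saccade_dataset(ds)
  samples <- as.data.frame(ds$samples)
  names(samples) <- sample_cols()
  out <- cbind(ds$meta, samples)
  data.table::fwrite(out, path)
  invisible(path)
}
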