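# Saccade segmentation and window normalization.
#
# Raw horizontal EOG traces (degrees, 200 Hz) are segmented into saccades by
# 2-cluster KMeans on absolute sample-to-sample velocity: the cluster with
# the larger centroid marks saccadic samples, maximal saccadic runs are
# merged across short dips and short runs are dropped. A 192-sample window
# centered on each detected saccade is then scaled by the stimulus angle to
# a common 30-degree amplitude, and right-to-left saccades are mirrored.

#' Preprocessing configuration
#'
#' @param window_length window length in samples (default 192).
#' @param target_amplitude common amplitude after angle scaling, degrees.
#' @param sampling_rate Hz.
#' @param min_saccade_duration drop detected runs shorter than this
#'   (samples).
#' @param merge_gap merge saccadic runs separated by at most this many
#'   non-saccadic samples.
#' @param kmeans_seed seed for the KMeans initialization.
#' @return object of class `preprocess_config`.
#' @export
preprocess_config <- function(window_length = 192L, target_amplitude = 30,
                              sampling_rate = 200, min_saccade_duration = 5L,
                              merge_gap = 3L, kmeans_seed = 1L) {
  stopifnot(window_length >= 2L, target_amplitude > 0, sampling_rate > 0)
  structure(list(window_length = as.integer(window_length),
                 target_amplitude = target_amplitude,
                 sampling_rate = sampling_rate,
                 min_saccade_duration = as.integer(min_saccade_duration),
                 merge_gap = as.integer(merge_gap),
                 kmeans_seed = as.integer(kmeans_seed)),
            class = "preprocess_config")
}

#' First-difference velocity of a trace
#'
#' @param trace numeric vector, degrees.
#' @param sampling_rate Hz.
#' @return numeric vector of length `length(trace) - 1`, degrees/second.
#' @export
compute_velocity <- function(trace, sampling_rate = 200) {
  if (length(trace) < 2L) stop("trace must have at least 2 samples",
                               call. = FALSE)
  diff(trace) * sampling_rate
}

#' Segment saccades from a raw trace
#'
#' @param trace numeric vector, degrees.
#' @param config a [preprocess_config()].
#' @return integer matrix with columns `onset`, `offset`: 0-based half-open
#'   intervals in trace samples, ascending. Empty (0-row) for degenerate
#'   (constant) traces, with a warning.
#' @export
segment_saccades <- function(trace, config = preprocess_config()) {
  if (length(trace) <= config$window_length) {
    stop("trace must be longer than the window length", call. = FALSE)
  }
  absv <- abs(diff(trace))
  empty <- cbind(onset = integer(0), offset = integer(0))
  if (diff(range(absv)) < 1e-12) {
    warning("constant trace: no velocity contrast, returning no saccades",
            call. = FALSE)
    return(empty)
  }
  km <- with_seed(config$kmeans_seed,
                  tryCatch(stats::kmeans(absv, centers = 2L, nstart = 5L,
                                         iter.max = 100L),
                           error = function(e) NULL))
  if (is.null(km)) {
    warning("degenerate velocity clustering, returning no saccades",
            call. = FALSE)
    return(empty)
  }
  sacc <- km$cluster == which.max(km$centers)
  r <- rle(sacc)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])  # 1-based velocity indices
  if (nrow(runs) == 0L) return(empty)
  # merge runs separated by small gaps
  merged <- runs[1L, , drop = FALSE]
  if (nrow(runs) > 1L) {
    for (i in 2:nrow(runs)) {
      gap <- runs[i, 1L] - merged[nrow(merged), 2L] - 1L
      if (gap <= config$merge_gap) {
        merged[nrow(merged), 2L] <- runs[i, 2L]
      } else {
        merged <- rbind(merged, runs[i, , drop = FALSE])
      }
    }
  }
  # velocity index v (1-based) spans trace samples v-1 .. v (0-based)
  onset <- merged[, 1L] - 1L
  offset <- merged[, 2L] + 1L
  keep <- (offset - onset) >= config$min_saccade_duration
  cbind(onset = as.integer(onset[keep]), offset = as.integer(offset[keep]))
}

#' Extract a centered window around a saccade interval
#'
#' The window of `window_length` samples is centered at
#' `floor((onset + offset) / 2)` (interval midpoint; the center lands at
#' window index `window_length / 2`). Windows that would cross the trace
#' bounds are discarded (`NULL`), not padded.
#'
#' @param trace numeric vector.
#' @param interval length-2 numeric `(onset, offset)`, 0-based half-open.
#' @param config a [preprocess_config()].
#' @return numeric vector of `window_length` samples, or `NULL`.
#' @export
extract_window <- function(trace, interval, config = preprocess_config()) {
  onset <- interval[[1L]]
  offset <- interval[[2L]]
  if (onset < 0 || offset > length(trace) || offset <= onset) {
    stop("invalid interval for this trace", call. = FALSE)
  }
  center <- floor((onset + offset) / 2)
  start <- center - floor(config$window_length / 2)
  end <- start + config$window_length  # half-open
  if (start < 0 || end > length(trace)) {
    message("window around sample ", center,
            " exceeds trace bounds; discarded")
    return(NULL)
  }
  trace[(start + 1L):end]
}

#' Scale a window to the common target amplitude
#'
#' Every sample is multiplied by `target_amplitude / angle`, so saccades
#' elicited by different stimulus angles share an amplitude of about 30
#' degrees.
#'
#' @param samples numeric vector (or matrix, rows = saccades).
#' @param angle stimulus angle in degrees (> 0); recycled over matrix rows
#'   if length 1, else one angle per row.
#' @param config a [preprocess_config()].
#' @return scaled samples, same shape as the input.
#' @export
normalize_amplitude <- function(samples, angle, config = preprocess_config()) {
  if (any(angle <= 0)) stop("angle must be > 0", call. = FALSE)
  if (is.matrix(samples)) {
    samples * (config$target_amplitude / angle)
  } else {
    samples * (config$target_amplitude / angle[1L])
  }
}

#' Mirror right-to-left saccades
#'
#' Direction is detected from quarter means: with
#' `d = mean(last quarter) - mean(first quarter)`, a negative `d` flags a
#' right-to-left saccade and the window is negated; `d >= 0` (including the
#' exact-zero tie) leaves the window unchanged. Idempotent.
#'
#' @param samples numeric vector of at least 8 samples.
#' @return numeric vector, left-to-right oriented.
#' @export
normalize_direction <- function(samples) {
  n <- length(samples)
  if (n < 8L) stop("need at least 8 samples to detect direction",
                   call. = FALSE)
  q <- floor(n / 4)
  d <- mean(samples[(n - q + 1L):n]) - mean(samples[1:q])
  if (d < 0) -samples else samples
}

#' Segment and normalize a raw trace into a saccade dataset
#'
#' Convenience composition of [segment_saccades()], [extract_window()],
#' [normalize_amplitude()] and [normalize_direction()] for a single-register
#' trace recorded at one stimulus angle.
#'
#' @param trace numeric vector, degrees.
#' @param angle stimulus angle of the test, degrees.
#' @param register_id register (patient) identifier.
#' @param diagnosis register diagnosis (`"C"`, `"P"` or `"S"`).
#' @param config a [preprocess_config()].
#' @return a [saccade_dataset()], or `NULL` if no usable window was found.
#' @export
preprocess_trace <- function(trace, angle, register_id = "R001",
                             diagnosis = "C",
                             config = preprocess_config()) {
  iv <- segment_saccades(trace, config)
  wins <- list()
  for (i in seq_len(nrow(iv))) {
    w <- extract_window(trace, iv[i, ], config)
    if (!is.null(w)) {
      wins[[length(wins) + 1L]] <-
        normalize_direction(normalize_amplitude(w, angle, config))
    }
  }
  if (!length(wins)) return(NULL)
  samples <- do.call(rbind, wins)
  meta <- data.frame(
    saccade_id = sprintf("%s_s%03d", register_id, seq_along(wins)),
    register_id = register_id, angle = angle,
    given_label = diagnosis, working_label = diagnosis,
    stringsAsFactors = FALSE)
  saccade_dataset(samples, meta, provenance = "segmented from raw trace")
}
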