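# Synthetic saccade-register generator.
#
# Emulates the structure the relabeling method assumes: control (C) and sick
# (S) registers are shape-homogeneous, while each presymptomatic (P) register
# contains a majority of control-shaped saccades and a minority of genuinely
# slowed ones -- yet every saccade inherits the register's diagnosis. The
# per-saccade shape actually drawn is kept in `true_shape_label`.
#
# Shape family: a logistic (sigmoid) position step of amplitude equal to the
# stimulus angle, with rise time constant tau (samples); slowed saccades get
# a larger tau, and sick saccades optionally a delayed secondary step
# (dysmetric overshoot correction).

#' Shape parameters for one diagnosis class
#'
#' @param tau logistic rise time constant, in samples (> 0). At 200 Hz,
#'   tau = 2.5 samples corresponds to a fast, healthy saccade; larger tau
#'   means a slowed saccade.
#' @param dysmetria_fraction amplitude of a secondary delayed step as a
#'   fraction of the main amplitude, in [0, 1); models dysmetric saccades.
#' @param noise_sd per-sample Gaussian noise SD, degrees (>= 0).
#' @param baseline_sd SD of the per-saccade random baseline offset, degrees.
#' @return object of class `shape_params`.
#' @export
shape_params <- function(tau, dysmetria_fraction = 0, noise_sd = 0.5,
                         baseline_sd = 0.2) {
  if (!is.numeric(tau) || tau <= 0) {
    stop("tau must be a positive number of samples", call. = FALSE)
  }
  if (dysmetria_fraction < 0 || dysmetria_fraction >= 1) {
    stop("dysmetria_fraction must lie in [0, 1)", call. = FALSE)
  }
  if (noise_sd < 0 || baseline_sd < 0) {
    stop("noise_sd and baseline_sd must be >= 0", call. = FALSE)
  }
  structure(list(tau = tau, dysmetria_fraction = dysmetria_fraction,
                 noise_sd = noise_sd, baseline_sd = baseline_sd),
            class = "shape_params")
}

#' Default per-class shape parameters
#'
#' Control saccades are fast (tau 2.5 samples), presymptomatic ones slowed
#' (tau 5), sick ones strongly slowed (tau 10) with a 15% dysmetric
#' secondary step. Chosen so the C/P overlap is non-trivial but resolvable.
#'
#' @return named list of [shape_params()] for C, P, S.
#' @export
default_class_shapes <- function() {
  list(C = shape_params(tau = 2.5),
       P = shape_params(tau = 5),
       S = shape_params(tau = 10, dysmetria_fraction = 0.15))
}

#' Generator configuration
#'
#' Defaults mirror the structure of the study cohort: 38/18/29 registers for
#' C/P/S, about 70 saccades per register (uniform 60..80), all four stimulus
#' angles equally likely, half of the saccades right-to-left, and a
#' contamination of 0.6 (60% of the saccades inside each presymptomatic
#' register are control-shaped).
#'
#' @param registers_per_class positive integer length-3 (C, P, S).
#' @param saccades_per_register integer range `c(min, max)` (inclusive).
#' @param contamination fraction in [0, 1] of control-shaped saccades inside
#'   each P register (bag-level label noise). Counts are rounded to the
#'   nearest integer but every P register keeps at least one P-shaped
#'   saccade.
#' @param class_shapes named list of [shape_params()] for C, P, S.
#' @param angles subset of c(10, 20, 30, 60).
#' @param angle_weights sampling weights for `angles`.
#' @param rtl_probability probability that a saccade is right-to-left
#'   (direction -1) before direction normalization.
#' @param seed root integer seed; each register draws from a derived
#'   substream (see [derive_seed()]), so the dataset is a pure function of
#'   the configuration.
#' @param normalize apply amplitude scaling (to 30 degrees) and direction
#'   normalization to the stored windows, i.e. emit the canonical
#'   preprocessed representation. Set `FALSE` to keep raw amplitudes.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(registers_per_class = c(C = 38, P = 18, S = 29),
                             saccades_per_register = c(60, 80),
                             contamination = 0.6,
                             class_shapes = default_class_shapes(),
                             angles = c(10, 20, 30, 60),
                             angle_weights = NULL,
                             rtl_probability = 0.5,
                             seed = 1L,
                             normalize = TRUE) {
  registers_per_class <- as.integer(registers_per_class)
  if (length(registers_per_class) != 3L || any(registers_per_class < 1L)) {
    stop("registers_per_class must be three positive integers (C, P, S)",
         call. = FALSE)
  }
  names(registers_per_class) <- diagnosis_levels
  if (length(saccades_per_register) == 1L) {
    saccades_per_register <- rep(saccades_per_register, 2L)
  }
  saccades_per_register <- as.integer(saccades_per_register)
  if (any(saccades_per_register < 1L) ||
      saccades_per_register[2L] < saccades_per_register[1L]) {
    stop("saccades_per_register must be a valid positive range",
         call. = FALSE)
  }
  if (contamination < 0 || contamination > 1) {
    stop("contamination must lie in [0, 1]", call. = FALSE)
  }
  if (length(angles) < 1L || !all(angles %in% c(10, 20, 30, 60))) {
    stop("angles must be a non-empty subset of {10, 20, 30, 60}",
         call. = FALSE)
  }
  if (is.null(angle_weights)) angle_weights <- rep(1, length(angles))
  stopifnot(length(angle_weights) == length(angles), all(angle_weights >= 0))
  stopifnot(all(diagnosis_levels %in% names(class_shapes)))
  structure(list(registers_per_class = registers_per_class,
                 saccades_per_register = saccades_per_register,
                 contamination = contamination,
                 class_shapes = class_shapes,
                 angles = angles, angle_weights = angle_weights,
                 rtl_probability = rtl_probability,
                 seed = as.integer(seed), normalize = isTRUE(normalize)),
            class = "generator_config")
}

#' Generate one synthetic saccade window
#'
#' Closed form: `s(t) = direction * (A * logistic((t - t0)/tau) +
#' dysmetria_fraction * A * logistic((t - t0 - delay)/tau) + eps(t)) + b`,
#' with `A = angle`, `eps(t)` i.i.d. Normal(0, noise_sd) and
#' `b ~ Normal(0, baseline_sd)`. The noise term is scaled by `direction`
#' together with the signal, so a right-to-left saccade generated under the
#' same seed is the exact mirror of its left-to-right twin (up to the
#' unsigned baseline).
#'
#' @param shape a [shape_params()].
#' @param angle stimulus angle (degrees); also the target amplitude A.
#' @param direction +1 (left-to-right) or -1.
#' @param t0 onset center, sample index in [0, length).
#' @param length window length in samples.
#' @param seed optional integer seed; if `NULL`, draws from the current RNG
#'   stream (used by [generate_dataset()]).
#' @param delay delay of the dysmetric secondary step, samples.
#' @return numeric vector of `length` samples, degrees.
#' @export
generate_saccade_waveform <- function(shape, angle, direction = 1L, t0 = 96,
                                      length = 192L, seed = NULL,
                                      delay = 20) {
  stopifnot(inherits(shape, "shape_params"))
  if (length < 1L) stop("length must be >= 1", call. = FALSE)
  if (t0 < 0 || t0 >= length) stop("t0 must lie in [0, length)",
                                   call. = FALSE)
  if (!direction %in% c(-1, 1)) stop("direction must be +1 or -1",
                                     call. = FALSE)
  gen <- function() {
    t <- seq_len(length) - 1
    a <- angle
    sig <- a * stats::plogis((t - t0) / shape$tau)
    if (shape$dysmetria_fraction > 0) {
      sig <- sig + shape$dysmetria_fraction * a *
        stats::plogis((t - t0 - delay) / shape$tau)
    }
    eps <- if (shape$noise_sd > 0) stats::rnorm(length, 0, shape$noise_sd)
           else numeric(length)
    b <- if (shape$baseline_sd > 0) stats::rnorm(1, 0, shape$baseline_sd)
         else 0
    direction * (sig + eps) + b
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Generate a synthetic saccade dataset
#'
#' C and S registers contain only saccades of their own shape class; each P
#' register contains `round(contamination * n)` control-shaped saccades
#' (capped so at least one P-shaped saccade remains) and the rest P-shaped.
#' All saccades carry the register's diagnosis as `given_label`;
#' `true_shape_label` records the shape actually drawn.
#'
#' @param config a [generator_config()].
#' @return a [saccade_dataset()] with a `true_shape_label` column.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  ppc <- config$preprocess %||% preprocess_config()
  meta_list <- list()
  sample_list <- list()
  reg_list <- list()
  for (ci in seq_along(diagnosis_levels)) {
    cls <- diagnosis_levels[ci]
    n_reg <- config$registers_per_class[[cls]]
    for (ri in seq_len(n_reg)) {
      reg_id <- sprintf("%s%03d", cls, ri)
      reg_seed <- derive_seed(config$seed, ci, ri)
      reg <- with_seed(reg_seed, {
        n_sac <- sample(seq(config$saccades_per_register[1L],
                            config$saccades_per_register[2L]), 1L)
        shape_lab <- rep(cls, n_sac)
        if (cls == "P") {
          n_c <- min(round_half_up(config$contamination * n_sac), n_sac - 1L)
          shape_lab[sample.int(n_sac, n_c)] <- "C"
        }
        angle <- sample(config$angles, n_sac, replace = TRUE,
                        prob = config$angle_weights)
        dir <- ifelse(stats::runif(n_sac) < config$rtl_probability, -1L, 1L)
        sm <- matrix(0, n_sac, 192L)
        for (si in seq_len(n_sac)) {
          w <- generate_saccade_waveform(config$class_shapes[[shape_lab[si]]],
                                         angle = angle[si],
                                         direction = dir[si])
          if (config$normalize) {
            w <- normalize_direction(normalize_amplitude(w, angle[si], ppc))
          }
          sm[si, ] <- w
        }
        list(n = n_sac, shape = shape_lab, angle = angle, samples = sm)
      })
      meta_list[[reg_id]] <- data.frame(
        saccade_id = sprintf("%s_s%03d", reg_id, seq_len(reg$n)),
        register_id = reg_id, angle = reg$angle,
        given_label = cls, working_label = cls,
        true_shape_label = reg$shape, stringsAsFactors = FALSE)
      sample_list[[reg_id]] <- reg$samples
      reg_list[[reg_id]] <- data.frame(register_id = reg_id, diagnosis = cls,
                                       stringsAsFactors = FALSE)
    }
  }
  saccade_dataset(do.call(rbind, sample_list),
                  do.call(rbind, meta_list),
                  do.call(rbind, reg_list),
                  provenance = sprintf(
                    "synthetic (seed %d, contamination %.2f)",
                    config$seed, config$contamination))
}

#' Generate a raw horizontal EOG trace with planted saccades
#'
#' Builds a trace by concatenating fixations and logistic saccade
#' transitions, and returns the ground-truth saccade intervals for testing
#' segmentation. An interval is the half-peak-velocity region of its
#' transition (0-based, half-open, in trace samples).
#'
#' @param plan list of entries; each entry is either
#'   `list(fixation = duration_samples)` or
#'   `list(angle = degrees, tau = samples, direction = +1/-1,
#'   duration = samples)` (`direction` defaults to +1, `duration` to
#'   `ceiling(12 * tau)`).
#' @param sampling_rate Hz (kept as an attribute; default 200).
#' @param noise_sd Gaussian noise SD added to the whole trace, degrees.
#' @param seed integer seed for the noise.
#' @return list with `trace` (numeric vector), `intervals` (matrix with
#'   columns `onset`, `offset`) and `sampling_rate`.
#' @export
generate_raw_trace <- function(plan, sampling_rate = 200, noise_sd = 0,
                               seed = 1L) {
  if (!length(plan)) stop("plan must be non-empty", call. = FALSE)
  pieces <- list()
  onsets <- integer(0)
  offsets <- integer(0)
  level <- 0
  pos <- 0L  # samples emitted so far
  for (entry in plan) {
    if (!is.null(entry$fixation)) {
      d <- as.integer(entry$fixation)
      if (d < 1L) stop("fixation duration must be >= 1 sample",
                       call. = FALSE)
      pieces[[length(pieces) + 1L]] <- rep(level, d)
      pos <- pos + d
    } else {
      if (is.null(entry$angle) || is.null(entry$tau)) {
        stop("saccade plan entry needs `angle` and `tau`", call. = FALSE)
      }
      dir <- entry$direction %||% 1
      d <- as.integer(entry$duration %||% ceiling(12 * entry$tau))
      if (d < 2L) stop("saccade duration must be >= 2 samples",
                       call. = FALSE)
      t <- seq_len(d) - 1
      lo <- stats::plogis((0 - d / 2) / entry$tau)
      hi <- stats::plogis((d - 1 - d / 2) / entry$tau)
      step <- (stats::plogis((t - d / 2) / entry$tau) - lo) / (hi - lo)
      seg <- level + dir * entry$angle * step
      # ground truth: half-peak region of the within-segment velocity
      v <- abs(diff(seg))
      act <- which(v >= 0.5 * max(v))
      onsets <- c(onsets, pos + min(act) - 1L)
      offsets <- c(offsets, pos + max(act) + 1L)
      pieces[[length(pieces) + 1L]] <- seg
      level <- level + dir * entry$angle
      pos <- pos + d
    }
  }
  trace <- unlist(pieces, use.names = FALSE)
  if (noise_sd > 0) {
    trace <- trace + with_seed(seed, stats::rnorm(length(trace), 0,
                                                  noise_sd))
  }
  list(trace = trace,
       intervals = cbind(onset = onsets, offset = offsets),
       sampling_rate = sampling_rate)
}
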