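# Shared fixtures. Everything is generated in code; no data files.

# A tiny handmade dataset: 2 registers, 3 saccades, deterministic samples.
tiny_dataset <- function() {
  samples <- rbind(seq(0, 30, length.out = 192),
                   30 * plogis((0:191 - 96) / 4),
                   rep(15, 192))
  meta <- data.frame(
    saccade_id = c("a1", "a2", "b1"),
    register_id = c("R1", "R1", "R2"),
    angle = c(30, 30, 60),
    given_label = c("C", "C", "P"),
    working_label = c("C", "C", "P"),
    stringsAsFactors = FALSE)
  saccade_dataset(samples, meta)
}

# Small, fast generator config (class-imbalanced like a real cohort).
small_gen_config <- function(seed = 42, contamination = 0.6,
                             registers = c(6, 5, 5)) {
  generator_config(registers_per_class = registers,
                   saccades_per_register = c(10, 14),
                   contamination = contamination, seed = seed)
}

# Frozen end-to-end fixture: 30 registers with the cohort's ~2:1 training
# C:P saccade imbalance (the threshold sweep range is calibrated to that
# imbalance), scaled-down saccade counts, a 6x6 map (~7 saccades/cell) and
# a small CNN-LSTM. Used by the pipeline and acceptance tests.
e2e_generator_config <- function(seed = 101) {
  generator_config(registers_per_class = c(14, 7, 9),
                   saccades_per_register = c(15, 25),
                   contamination = 0.6, seed = seed)
}

e2e_pipeline_config <- function(ds, repeats = 2, seed = 7) {
  pipeline_config(
    ds, split_seed = 11,
    som = list(width = 6, height = 6, epochs = 10, learning_rate = 0.5),
    model = model_config(conv_filters = c(16L, 16L), lstm_units = 24L,
                         dropout = 0.2),
    training = training_config(max_epochs = 12L, batch_size = 32L),
    repeats = repeats, seed = seed)
}

small_model_config <- function() {
  model_config(conv_filters = c(4L, 4L), lstm_units = 6L, dropout = 0)
}

# Independent brute-force oracle for the cell relabeling decision tree,
# written directly from the algorithm listing (plain nested ifs, no reuse
# of package code).
oracle_relabel <- function(nC, nP, nS, threshold) {
  majority_is_S <- (nS > nC) && (nS > nP)
  if (majority_is_S) {
    "S"
  } else if (nP == 0) {
    "C"
  } else if (nC / nP < threshold) {
    "P"
  } else {
    "C"
  }
}
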