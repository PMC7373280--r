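# Register-stratified train / validation / test splitting.

#' Split registers into train / validation / test sets
#'
#' Stratified by diagnosis class. Within each class of size `n_c`, the train
#' and validation sets receive `round(f * n_c)` registers (nearest integer,
#' halves up) and the test set the remainder; membership is a seeded random
#' permutation. The per-class counts therefore depend only on the class sizes
#' and fractions, never on the seed, and with the study's class sizes
#' (38, 18, 29) and fractions (0.4, 0.4, 0.2) the rule reproduces the printed
#' 15-15-8 / 7-7-4 / 12-12-5 register split.
#'
#' @param ds a [saccade_dataset()].
#' @param fractions numeric length-3 (train, validation, test), non-negative,
#'   summing to 1. Default `c(0.4, 0.4, 0.2)`.
#' @param seed integer seed for the within-class permutations.
#' @return An object of class `dataset_split`: list with
#'   `train_register_ids`, `val_register_ids`, `test_register_ids`,
#'   `fractions`, `seed`.
#' @export
split_registers <- function(ds, fractions = c(0.4, 0.4, 0.2), seed = 1L) {
  stopifnot(length(fractions) == 3L)
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must be non-negative and sum to 1", call. = FALSE)
  }
  regs <- ds$registers
  out <- list(train = character(0), val = character(0), test = character(0))
  with_seed(seed, {
    for (cls in diagnosis_levels) {
      ids <- sort(regs$register_id[regs$diagnosis == cls])
      n_c <- length(ids)
      if (n_c == 0L) {
        stop("class ", cls, " has no registers; cannot stratify",
             call. = FALSE)
      }
      n_train <- round_half_up(fractions[1L] * n_c)
      n_val <- round_half_up(fractions[2L] * n_c)
      n_test <- n_c - n_train - n_val
      if (n_test < 1L) {
        stop("class ", cls, " would receive ", n_test, " test register(s) ",
             "under the remainder rule; adjust the fractions", call. = FALSE)
      }
      perm <- sample(ids)
      out$train <- c(out$train, perm[seq_len(n_train)])
      out$val <- c(out$val, perm[n_train + seq_len(n_val)])
      out$test <- c(out$test, perm[n_train + n_val + seq_len(n_test)])
    }
  })
  structure(list(train_register_ids = out$train,
                 val_register_ids = out$val,
                 test_register_ids = out$test,
                 fractions = fractions, seed = as.integer(seed)),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat("<dataset_split> train/val/test registers: ",
      length(x$train_register_ids), "/", length(x$val_register_ids), "/",
      length(x$test_register_ids), " (fractions ",
      paste(x$fractions, collapse = "/"), ", seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Materialize the three subsets of a split
#'
#' @param ds a [saccade_dataset()].
#' @param split a `dataset_split` from [split_registers()].
#' @return list with `train`, `val`, `test` saccade datasets.
#' @export
apply_split <- function(ds, split) {
  list(train = subset_registers(ds, split$train_register_ids),
       val = subset_registers(ds, split$val_register_ids),
       test = subset_registers(ds, split$test_register_ids))
}
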