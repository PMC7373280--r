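# Internal helpers: seeded evaluation, seed derivation, logging.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the current RNG state, sets `seed`, evaluates `expr`, and restores
#' the previous state, so library code never clobbers the caller's stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a root seed and a stream index
#'
#' Deterministic integer hash (multiplicative congruential fold, modulus
#' 2147483563 < 2^31 so results are valid R integer seeds). Used to give each
#' register, run and stage its own reproducible substream.
#'
#' @param seed root integer seed.
#' @param ... one or more integer stream indices.
#' @return integer seed in [1, 2147483562].
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483563
  h <- as.numeric(seed) %% m
  for (k in c(...)) {
    h <- (h * 69069 + as.numeric(k) + 1) %% m
  }
  as.integer(h + 1)
}

tandem_log <- function(..., verbose = TRUE, log_file = NULL) {
  if (!isTRUE(verbose) && is.null(log_file)) return(invisible(NULL))
  line <- paste0("[", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "] ",
                 sprintf(...))
  if (isTRUE(verbose)) message(line)
  if (!is.null(log_file)) cat(line, "\n", file = log_file, append = TRUE)
  invisible(NULL)
}

round_half_up <- function(x) floor(x + 0.5)
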