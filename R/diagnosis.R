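#' Diagnosis classes
#'
#' The three diagnosis classes used throughout: `"C"` (control), `"P"`
#' (presymptomatic) and `"S"` (sick / overt ataxia). Ties anywhere in the
#' package (register votes, equal softmax probabilities) are broken by the
#' severity order S > P > C: when in doubt, the clinically conservative call
#' is the severer class.
#'
#' @format `diagnosis_levels` is a character vector of length 3.
#' @export
diagnosis_levels <- c("C", "P", "S")

# severity rank: higher = severer (S > P > C)
severity_rank <- c(C = 1L, P = 2L, S = 3L)

#' Validate and canonicalize diagnosis labels
#'
#' @param x character vector (or factor) of labels.
#' @param allow_na accept missing values (used for the optional synthetic
#'   ground-truth column).
#' @return character vector with entries in `diagnosis_levels`.
#' @export
as_diagnosis <- function(x, allow_na = FALSE) {
  x <- as.character(x)
  bad <- !(x %in% diagnosis_levels)
  if (allow_na) bad <- bad & !is.na(x)
  if (any(bad)) {
    stop("unknown diagnosis label(s): ",
         paste(unique(x[bad]), collapse = ", "),
         " (expected C, P or S)", call. = FALSE)
  }
  x
}

# Among a set of candidate labels, return the severest (S > P > C).
severity_tiebreak <- function(labels) {
  labels[which.max(severity_rank[labels])]
}
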