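# Self-organizing map over saccade windows.
#
# Standard sequential (Kohonen) training: for every presented sample the
# Euclidean-nearest cell wins, and every cell moves toward the sample by
# learning_rate * Gaussian(grid distance to winner). Learning rate and
# neighborhood radius decay linearly to 1% of their initial values over the
# full run. Weights are initialized as randomly drawn training samples.
# The map size is not prescribed by the method; the 10 x 10 default keeps
# roughly 20+ saccades per cell for a cohort-sized training set.

as_sample_matrix <- function(x) {
  if (inherits(x, "saccade_dataset")) x$samples else as.matrix(x)
}

#' Train a self-organizing map
#'
#' @param x a [saccade_dataset()] or numeric matrix (rows = saccades).
#' @param width,height grid dimensions (positive integers).
#' @param epochs full passes over the data.
#' @param learning_rate initial learning rate (decays linearly to 1%).
#' @param radius initial Gaussian neighborhood radius in grid units;
#'   default `max(width, height) / 2`.
#' @param seed integer seed (initialization and presentation order).
#' @return object of class `som_grid`: `weights` (ncell x 192, row-major
#'   cell order), `width`, `height`, `coords`, `hyperparams`.
#' @export
train_som <- function(x, width = 10L, height = 10L, epochs = 10L,
                      learning_rate = 0.5, radius = NULL, seed = 1L) {
  X <- as_sample_matrix(x)
  n <- nrow(X)
  if (n < 1L) stop("need at least one saccade", call. = FALSE)
  if (width < 1L || height < 1L || epochs < 1L || learning_rate <= 0) {
    stop("grid dimensions, epochs and learning rate must be positive",
         call. = FALSE)
  }
  if (is.null(radius)) radius <- max(width, height) / 2
  ncell <- as.integer(width * height)
  # cell k (1-based) sits at grid row (k-1) %/% width, col (k-1) %% width
  gr <- (seq_len(ncell) - 1L) %/% width
  gc <- (seq_len(ncell) - 1L) %% width
  init <- with_seed(seed, {
    idx <- sample.int(n, ncell, replace = ncell > n)
    orders <- vapply(seq_len(epochs), function(e) sample.int(n),
                     integer(n))
    list(W = X[idx, , drop = FALSE], orders = orders)
  })
  Wt <- .som_train_cpp(t(X), t(init$W), as.integer(gr), as.integer(gc),
                       init$orders,
                       learning_rate, 0.01 * learning_rate,
                       radius, max(0.01 * radius, 1e-3))
  W <- t(Wt)
  structure(list(weights = W, width = as.integer(width),
                 height = as.integer(height),
                 coords = cbind(row = gr, col = gc),
                 hyperparams = list(epochs = as.integer(epochs),
                                    learning_rate = learning_rate,
                                    radius = radius,
                                    seed = as.integer(seed))),
            class = "som_grid")
}

#' @export
print.som_grid <- function(x, ...) {
  cat("<som_grid> ", x$height, "x", x$width, " map, ",
      ncol(x$weights), "-dim weights (epochs ", x$hyperparams$epochs,
      ", seed ", x$hyperparams$seed, ")\n", sep = "")
  invisible(x)
}

# 1-based row-major BMU cell indices for a sample matrix; ties resolve to
# the smallest index via max.col on the negated distance is unsafe -- use
# explicit first-minimum.
bmu_index <- function(grid, X) {
  X <- as_sample_matrix(X)
  if (ncol(X) != ncol(grid$weights)) {
    stop("sample length ", ncol(X), " does not match the map's ",
         ncol(grid$weights), "-dim weights", call. = FALSE)
  }
  W <- grid$weights
  # squared distances: ||w||^2 - 2 x.w (the ||x||^2 term is constant per row)
  d2 <- matrix(rowSums(W^2), nrow(X), nrow(W), byrow = TRUE) -
    2 * tcrossprod(X, W)
  apply(d2, 1L, which.min)
}

#' Best matching unit of one saccade window
#'
#' @param grid a trained `som_grid`.
#' @param samples numeric vector of length 192.
#' @return integer `(row, col)`, 0-based grid coordinates; distance ties are
#'   broken toward the smallest row-major index.
#' @export
assign_bmu <- function(grid, samples) {
  k <- bmu_index(grid, matrix(samples, nrow = 1L))
  c(row = grid$coords[k, 1L], col = grid$coords[k, 2L])
}

#' Per-cell diagnosis label counts
#'
#' Counts, for every map cell, the training saccades whose BMU it is, split
#' by their `given_label` (the |C|, |P|, |S| of the relabeling rule). Each
#' saccade contributes to exactly one cell and is included in its own cell's
#' counts.
#'
#' @param grid a trained `som_grid`.
#' @param x a [saccade_dataset()], or a numeric matrix if `labels` is given.
#' @param labels optional character vector of labels aligned with the rows
#'   of `x` (defaults to the dataset's `given_label`).
#' @return object of class `cell_counts`: integer matrix (ncell x 3, columns
#'   C/P/S) with the BMU index vector as attribute `bmu`.
#' @export
compute_cell_counts <- function(grid, x, labels = NULL) {
  if (is.null(labels)) {
    stopifnot(inherits(x, "saccade_dataset"))
    labels <- x$meta$given_label
  }
  labels <- as_diagnosis(labels)
  X <- as_sample_matrix(x)
  stopifnot(length(labels) == nrow(X))
  counts <- matrix(0L, nrow(grid$weights), 3L,
                   dimnames = list(NULL, diagnosis_levels))
  if (nrow(X)) {
    bmu <- bmu_index(grid, X)
    tab <- table(factor(bmu, levels = seq_len(nrow(grid$weights))),
                 factor(labels, levels = diagnosis_levels))
    counts[] <- as.integer(tab)
    attr(counts, "bmu") <- bmu
  } else {
    attr(counts, "bmu") <- integer(0)
  }
  class(counts) <- c("cell_counts", class(counts))
  counts
}

#' Quantization error of a map on a sample set
#'
#' Mean Euclidean distance from each sample to its BMU weight vector; the
#' standard SOM fit diagnostic (lower is better).
#'
#' @param grid a trained `som_grid`.
#' @param x a [saccade_dataset()] or numeric matrix.
#' @return non-negative scalar.
#' @export
quantization_error <- function(grid, x) {
  X <- as_sample_matrix(x)
  if (!nrow(X)) stop("empty collection", call. = FALSE)
  bmu <- bmu_index(grid, X)
  mean(sqrt(rowSums((X - grid$weights[bmu, , drop = FALSE])^2)))
}

#' Persist / restore a trained map as plain text
#'
#' Weights go to a CSV, dimensions and hyperparameters to a JSON sidecar
#' (`<path>.json`).
#'
#' @param grid a `som_grid`.
#' @param path CSV path for the weights.
#' @return `save_som`: `path` invisibly; `load_som`: a `som_grid`.
#' @export
save_som <- function(grid, path) {
  data.table::fwrite(as.data.frame(grid$weights), path)
  jsonlite::write_json(list(width = grid$width, height = grid$height,
                            hyperparams = grid$hyperparams),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_som
#' @export
load_som <- function(path) {
  W <- as.matrix(data.table::fread(path))
  dimnames(W) <- NULL
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ncell <- hdr$width * hdr$height
  stopifnot(nrow(W) == ncell)
  gr <- (seq_len(ncell) - 1L) %/% hdr$width
  gc <- (seq_len(ncell) - 1L) %% hdr$width
  structure(list(weights = W, width = as.integer(hdr$width),
                 height = as.integer(hdr$height),
                 coords = cbind(row = gr, col = gc),
                 hyperparams = hdr$hyperparams),
            class = "som_grid")
}
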