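# Basic diagnostics plots (base graphics).

#' Plot the majority class of each SOM cell
#'
#' Cells are colored by the majority given label of the saccades mapped to
#' them (ties toward the severer class); empty cells stay white.
#'
#' @param grid a trained `som_grid`.
#' @param counts a [compute_cell_counts()] result for the grid.
#' @param ... passed to [graphics::image()].
#' @return invisibly, the matrix of majority labels.
#' @export
plot_som_map <- function(grid, counts, ...) {
  lab <- apply(unclass(counts), 1L, function(cnt) {
    if (sum(cnt) == 0) return(NA_character_)
    cand <- diagnosis_levels[cnt == max(cnt)]
    severity_tiebreak(cand)
  })
  z <- matrix(match(lab, diagnosis_levels), grid$height, grid$width,
              byrow = TRUE)
  graphics::image(x = seq_len(grid$width), y = seq_len(grid$height),
                  z = t(z)[, rev(seq_len(grid$height)), drop = FALSE],
                  zlim = c(1, 3), col = c("#d73027", "#1a9850", "#4575b4"),
                  xlab = "map column", ylab = "map row", axes = FALSE, ...)
  graphics::box()
  graphics::legend("topright", legend = diagnosis_levels, fill =
                     c("#d73027", "#1a9850", "#4575b4"), bty = "n")
  invisible(matrix(lab, grid$height, grid$width, byrow = TRUE))
}

#' Heatmap of a confusion matrix
#'
#' @param report an [evaluation_report()] (or 3x3 matrix).
#' @param ... passed to [graphics::image()].
#' @return invisibly, the matrix plotted.
#' @export
plot_confusion <- function(report, ...) {
  m <- if (inherits(report, "evaluation_report")) report$confusion
       else unclass(as.matrix(report))
  graphics::image(1:3, 1:3, t(m)[, 3:1, drop = FALSE],
                  col = grDevices::hcl.colors(25, "Blues", rev = TRUE),
                  xlab = "predicted", ylab = "true", axes = FALSE, ...)
  graphics::axis(1, at = 1:3, labels = diagnosis_levels)
  graphics::axis(2, at = 3:1, labels = diagnosis_levels)
  for (i in 1:3) for (j in 1:3) {
    graphics::text(j, 4 - i, format(round(m[i, j], 2)))
  }
  graphics::box()
  invisible(m)
}

#' Metric-versus-threshold lines for a sweep
#'
#' Per-class validation or test register recall against the relabeling
#' threshold (0 = no relabeling).
#'
#' @param sweep a `sweep_result`.
#' @param which one of `"val_register"`, `"val_saccade"`,
#'   `"test_register"`, `"test_saccade"`.
#' @param metric `"recall"`, `"precision"` or `"f1"`.
#' @return invisibly, the plotted data.frame.
#' @export
plot_threshold_metrics <- function(sweep, which = "val_register",
                                   metric = "recall") {
  rows <- do.call(rbind, lapply(sweep$entries, function(e) {
    pc <- e[[which]]$metrics$per_class
    data.frame(threshold = e$threshold, class = pc$class,
               value = pc[[metric]])
  }))
  graphics::matplot(unique(rows$threshold),
                    matrix(rows$value, ncol = 3L, byrow = TRUE),
                    type = "b", pch = 1:3, lty = 1, xlab = "threshold",
                    ylab = metric,
                    col = c("#d73027", "#1a9850", "#4575b4"))
  graphics::legend("bottomleft", legend = diagnosis_levels, col =
                     c("#d73027", "#1a9850", "#4575b4"), lty = 1,
                   pch = 1:3, bty = "n")
  invisible(rows)
}
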