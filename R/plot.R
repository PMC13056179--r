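#' Plot a fitted k-mer spectrum model
#'
#' Overlays the normalized count histogram with the fitted mixture F(x) and
#' its weighted components.
#'
#' @param x A `kmix` fit.
#' @param log `""` (linear) or `"y"` for a log-scaled density axis.
#' @param xlim Optional count range to display.
#' @param main Plot title.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.kmix <- function(x, log = "", xlim = NULL, main = "k-mer count spectrum",
                      ...) {
  hist <- x$hist
  xs <- seq_len(hist$c)
  hn <- hist$h / sum(hist$h)
  mat <- mixture_matrix(x$model, hist$c)
  f <- rowSums(mat)
  floorv <- if (log == "y") max(min(hn[hn > 0]) * 1e-3, 1e-12) else 0
  clip <- function(v) pmax(v, floorv)
  if (is.null(xlim)) xlim <- c(1, hist$c)
  cols <- c("firebrick", "goldenrod3", "steelblue", "darkgreen")
  graphics::plot(xs, clip(hn), type = "h", col = "grey70", lwd = 2,
                 log = log, xlim = xlim, xlab = "k-mer count x",
                 ylab = "fraction of distinct k-mers", main = main, ...)
  graphics::lines(xs, clip(f), lwd = 2)
  for (j in seq_len(ncol(mat)))
    graphics::lines(xs, clip(mat[, j]), lty = 2, col = cols[(j - 1) %% 4 + 1])
  graphics::legend("topright", bty = "n", lwd = c(2, rep(1, ncol(mat))),
                   lty = c(1, rep(2, ncol(mat))),
                   col = c("black", cols[seq_len(ncol(mat))]),
                   legend = c("mixture F(x)", colnames(mat)))
  invisible(x)
}

#' Per-generation animation frames of the optimization
#'
#' Writes one PNG per recorded generation, showing the best model of that
#' generation over the histogram — an animation of the evolutionary search.
#'
#' @param fit A `kmix` fit (its per-generation best solutions are retained).
#' @param dir Output directory (created if needed).
#' @param width,height Frame size in pixels.
#' @return Character vector of frame paths (one per generation), invisibly.
#' @export
plot_fit_frames <- function(fit, dir, width = 720, height = 480) {
  stopifnot(inherits(fit, "kmix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gens <- nrow(fit$trace_genomes)
  hist <- fit$hist
  xs <- seq_len(hist$c)
  hn <- hist$h / sum(hist$h)
  paths <- character(gens)
  for (g in seq_len(gens)) {
    model <- decode_genome(fit$trace_genomes[g, ], fit$layout, hist$c)
    paths[g] <- file.path(dir, sprintf("frame%04d.png", g))
    grDevices::png(paths[g], width = width, height = height)
    graphics::plot(xs, hn, type = "h", col = "grey70", lwd = 2,
                   xlab = "k-mer count x", ylab = "fraction of distinct k-mers",
                   main = sprintf("generation %d (Err = %.4g)", g,
                                  fit$trace[g]))
    graphics::lines(xs, mixture_pmf(model, hist$c), lwd = 2)
    grDevices::dev.off()
  }
  invisible(paths)
}
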