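# Base-graphics rendering of splicing maps.

#' Plot a splicing map
#'
#' Draws per-condition mean curves with optional confidence envelopes and
#' dashed separators at window boundaries. When `file` ends in `.png` or
#' `.svg` the plot is written to that device; otherwise it is drawn on the
#' active device.
#'
#' @param x a `splicing_map`.
#' @param bounds optional `permutation_bounds` drawn as a grey envelope.
#' @param file optional output path (`.png` or `.svg`).
#' @param main plot title.
#' @param ... further arguments passed to [graphics::matplot()].
#' @return Invisibly, `x`.
#' @export
plot_splicing_map <- function(x, bounds = NULL, file = NULL,
                              main = "splicing map", ...) {
  stopifnot(inherits(x, "splicing_map"))
  draw <- function() {
    curves <- do.call(cbind, lapply(x$conditions, `[[`, "mean_curve"))
    ylim <- range(c(curves, bounds$lower, bounds$upper), na.rm = TRUE)
    graphics::matplot(seq_len(x$L) - 1L, curves, type = "l", lty = 1,
                      col = seq_len(ncol(curves)) + 1L, xlab = "meta-event position",
                      ylab = "mean signal", main = main, ylim = ylim, ...)
    if (!is.null(bounds)) {
      ok <- !is.na(bounds$lower) & !is.na(bounds$upper)
      xs <- (seq_len(x$L) - 1L)[ok]
      graphics::polygon(c(xs, rev(xs)),
                        c(bounds$lower[ok], rev(bounds$upper[ok])),
                        col = grDevices::adjustcolor("grey", 0.5), border = NA)
    }
    graphics::abline(v = x$window_size * seq_len(x$n_windows - 1L), lty = 2,
                     col = "grey40")
    graphics::legend("topright", legend = names(x$conditions), lty = 1,
                     col = seq_along(x$conditions) + 1L, bty = "n", cex = 0.8)
  }
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    if (ext == "png") {
      grDevices::png(file, width = 1000, height = 500)
    } else if (ext == "svg") {
      grDevices::svg(file, width = 10, height = 5)
    } else {
      stop("unsupported plot format: ", ext, call. = FALSE)
    }
    on.exit(grDevices::dev.off())
    draw()
  } else {
    draw()
  }
  invisible(x)
}
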