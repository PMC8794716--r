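# Diagnostic plot for correlograms.

#' Plot a correlogram
#'
#' Draws per-class autocorrelation r against distance-class midpoints with
#' bootstrap error bars and the permutation-null band (dashed), the
#' conventional way spatial genetic structure is displayed.
#'
#' @param x A `correlogram` from [correlogram()].
#' @param ... Passed to [plot()].
#' @export
plot.correlogram <- function(x, ...) {
  mid <- (x$class_lo + x$class_hi) / 2
  ok <- !is.na(x$r)
  ylim <- range(c(x$r, x$boot_lo, x$boot_hi, x$null_lo, x$null_hi),
                na.rm = TRUE)
  plot(mid[ok], x$r[ok], type = "b", pch = 16, ylim = ylim,
       xlab = "distance class midpoint (m)", ylab = "autocorrelation r",
       ...)
  graphics::abline(h = 0, col = "grey60")
  graphics::arrows(mid[ok], x$boot_lo[ok], mid[ok], x$boot_hi[ok],
                   angle = 90, code = 3, length = 0.03)
  if (!is.null(x$null_lo)) {
    graphics::lines(mid[ok], x$null_lo[ok], lty = 2, col = "red")
    graphics::lines(mid[ok], x$null_hi[ok], lty = 2, col = "red")
  }
  invisible(x)
}
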