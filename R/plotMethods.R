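#' Plot a fraction series, optionally with a fitted model overlay
#'
#' Base-graphics time course of the four observed class fractions with
#' +/- 1 sigma error bars; when `fit` is supplied, the delay-corrected
#' model prediction is drawn through the data.
#'
#' @param x a [FractionSeries-class].
#' @param fit optional [AllelicFit-class].
#' @param y ignored.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
setMethod("plot", signature(x = "FractionSeries", y = "missing"),
          function(x, y, fit = NULL, ...) {
  d <- x@data
  cols <- c(none = "grey40", monoY = "goldenrod2", monoR = "firebrick3",
            bi = "forestgreen")
  graphics::plot(range(d$bin_center_h), c(0, 1), type = "n",
                 xlab = "time (h)", ylab = "population fraction", ...)
  for (cl in OBSERVED_CLASSES) {
    f <- d[[paste0("f_", cl)]]
    df <- d[[paste0("df_", cl)]]
    graphics::points(d$bin_center_h, f, col = cols[cl], pch = 16)
    graphics::arrows(d$bin_center_h, f - df, d$bin_center_h, f + df,
                     angle = 90, code = 3, length = 0.02, col = cols[cl])
  }
  if (!is.null(fit)) {
    tt <- seq(min(d$bin_center_h), max(d$bin_center_h), length.out = 200)
    pred <- delayedModelSeries(fit@model, fit@delays, tt)
    for (cl in OBSERVED_CLASSES)
      graphics::lines(tt, pred[[paste0("f_", cl)]], col = cols[cl])
  }
  graphics::legend("topright", legend = OBSERVED_CLASSES, col = cols,
                   pch = 16, bty = "n")
  invisible(x)
})
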