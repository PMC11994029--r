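#' Plot stability calls
#'
#' Treatment mean relative invader growth rates with the RGR = 1 stability
#' threshold; filled points are groups called stable.
#'
#' @param x A [classify_stability()] result.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.stability_calls <- function(x, ...) {
  sp <- factor(x$focal)
  jitter_x <- as.integer(sp) + stats::runif(nrow(x), -0.18, 0.18)
  graphics::plot(jitter_x, x$mean_rgr, xaxt = "n",
                 pch = ifelse(x$stable, 19, 1),
                 xlab = "focal species", ylab = "mean relative invader growth rate",
                 ...)
  graphics::axis(1, at = seq_len(nlevels(sp)), labels = levels(sp))
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}

#' Plot the single- vs co-invasion comparison
#'
#' Scatter of paired treatment means by species with the 1-1 line (dashed)
#' and the fitted common-slope lines from the additive model.
#'
#' @param x A [fit_rgr_comparison()] result.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.rgr_comparison <- function(x, ...) {
  d <- x$data
  graphics::plot(d$x, d$y, col = as.integer(d$species), pch = 19,
                 xlab = "mean RGR, single invasion",
                 ylab = "mean RGR, co-invasion", ...)
  graphics::abline(0, 1, lty = 2)
  for (i in seq_along(x$intercepts)) {
    graphics::abline(x$intercepts[i], x$common_slope, col = i)
  }
  graphics::legend("topleft", legend = levels(d$species),
                   col = seq_along(x$intercepts), pch = 19, bty = "n")
  invisible(x)
}
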