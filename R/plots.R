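#' Diagnostic plots for a fitted additive hazard model
#'
#' Plots the fitted arm-specific hazard, survival or density over the
#' observed follow-up with pointwise 95% bands, overlaying the
#' nonparametric observed quantity where one exists: actuarial
#' life-table hazards (points with error bars) on the hazard panel and
#' Kaplan-Meier curves (dotted steps) on the survival panel.  Control
#' arm in red, treated arm in blue, following the usual two-arm
#' convention.
#'
#' @param x An [ahaz_fit()].
#' @param ds The [survival_dataset()] the model was fitted to (needed
#'   for the observed overlays; omit to plot fitted curves only).
#' @param which One of `"hazard"`, `"survival"`, `"density"`, or
#'   `"all"` for a 1x3 panel.
#' @param lt_width Life-table interval width for the hazard overlay.
#' @param n_grid Number of grid points for the fitted curves.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.ahaz_fit <- function(x, ds = NULL,
                          which = c("hazard", "survival", "density",
                                    "all"),
                          lt_width = 0.25, n_grid = 101L, ...) {
  which <- match.arg(which)
  if (which == "all") {
    op <- graphics::par(mfrow = c(1, 3))
    on.exit(graphics::par(op))
    for (w in c("hazard", "survival", "density"))
      plot(x, ds = ds, which = w, lt_width = lt_width,
           n_grid = n_grid, ...)
    return(invisible(x))
  }
  tg <- seq(0, x$max_time, length.out = n_grid)
  pr <- lapply(c(0L, 1L), function(a)
    predict(x, tg, arm = a, quantity = which))
  cols <- c("red", "blue")
  ylim <- range(unlist(lapply(pr, function(p) c(p$lower, p$upper))),
                0, na.rm = TRUE)
  graphics::plot(NA, xlim = c(0, x$max_time), ylim = ylim,
                 xlab = "years", ylab = which,
                 main = sprintf("%s baseline", x$family_name), ...)
  for (a in 1:2) {
    p <- pr[[a]]
    graphics::polygon(c(p$time, rev(p$time)), c(p$lower, rev(p$upper)),
                      col = grDevices::adjustcolor(cols[a], 0.15),
                      border = NA)
    graphics::lines(p$time, p$estimate, col = cols[a], lwd = 2)
  }
  if (!is.null(ds)) {
    if (which == "hazard") {
      for (a in 1:2) {
        lt <- life_table(ds, a - 1L, width = lt_width)
        mid <- (lt$start + lt$end) / 2
        graphics::points(mid, lt$hazard, col = cols[a], pch = 16,
                         cex = 0.6)
        graphics::segments(mid, lt$lower, mid, lt$upper, col = cols[a])
      }
    } else if (which == "survival") {
      for (a in 1:2) {
        k <- km(ds, a - 1L)
        graphics::lines(c(0, k$time), c(1, k$surv), type = "s",
                        lty = 3, col = cols[a])
      }
    }
  }
  graphics::legend("topright", legend = c("control", "treated"),
                   col = cols, lwd = 2, bty = "n", cex = 0.8)
  invisible(x)
}
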