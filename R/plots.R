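#' Plot a thermal field
#'
#' Temperature evolution at a selection of depths, on a logarithmic time
#' axis, with the melting point of water marked.
#'
#' @param x A \code{thermal_field}.
#' @param radii_km Radii to draw; defaults to six depths spanning the body.
#' @param ... Passed to \code{matplot}.
#' @export
plot.thermal_field <- function(x, radii_km = NULL, ...) {
  R <- x$config$radius_km
  if (is.null(radii_km))
    radii_km <- signif(R * c(0, 0.3, 0.5, 0.7, 0.85, 0.95), 3)
  tt <- x$times_yr
  sel <- tt > 0
  Tsel <- vapply(radii_km, function(r) temperature_at(x, r)[sel],
                 numeric(sum(sel)))
  graphics::matplot(tt[sel], Tsel, type = "l", log = "x", lty = 1,
                    xlab = "time after formation [yr]",
                    ylab = "temperature [K]",
                    main = sprintf("R = %g km, formed %g Myr after CAI",
                                   R, x$config$t_form_myr), ...)
  graphics::abline(h = 273.15, lty = 3)
  graphics::legend("topleft", bty = "n", lty = 1,
                   col = seq_along(radii_km),
                   legend = sprintf("r = %g km", radii_km), cex = 0.8)
  invisible(x)
}

#' Plot an abundance profile
#'
#' Ribose abundance (left axis, log scale) against radius or time, with
#' the driving temperature on the right axis and the measured meteoritic
#' range shaded.
#'
#' @param x An \code{abundance_profile}.
#' @param range Measured range to shade, ppb.
#' @param ... Passed to \code{plot}.
#' @export
plot.abundance_profile <- function(x, range = meteoritic_range(), ...) {
  axis_time <- attr(x, "axis") == "time"
  xs <- if (axis_time) x$time_yr else x$radius_km
  xlab <- if (axis_time) "time after formation [yr]" else "radius [km]"
  temp <- if (axis_time) x$temperature_K else x$t_max_K
  ppb <- pmax(x$ribose_ppb, 1e-4)

  op <- graphics::par(mar = c(5, 4, 3, 4))
  on.exit(graphics::par(op))
  ylim <- c(1e-1, max(c(ppb, range[["high"]] * 4)))
  graphics::plot(xs, ppb, type = "s", log = if (axis_time) "xy" else "y",
                 col = "firebrick", lwd = 2, xlab = xlab,
                 ylab = "ribose [ppb, bulk mass]", ylim = ylim,
                 main = sprintf("catalyst %s (%s scenario)",
                                attr(x, "catalyst"), attr(x, "scenario")),
                 ...)
  graphics::rect(min(xs[xs > 0]), range[["low"]], max(xs), range[["high"]],
                 col = grDevices::adjustcolor("steelblue", 0.2), border = NA)
  graphics::par(new = TRUE)
  graphics::plot(xs, temp, type = "l", log = if (axis_time) "x" else "",
                 axes = FALSE, xlab = "", ylab = "", col = "grey30", lty = 2)
  graphics::axis(4)
  graphics::mtext("temperature [K]", side = 4, line = 2.5)
  graphics::abline(h = 273.15, lty = 3, col = "grey60")
  invisible(x)
}
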