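# Static report figures drawn with base graphics.

#' Plot the probe trail over the phantom
#'
#' Inclusion footprints, the probe trail, and the recorded key presses.
#'
#' @param log a `telepalp_session`.
#' @param phantom the `telepalp_phantom` the session explored.
#' @export
plot_session_trail <- function(log, phantom) {
  plot(NA, xlim = c(0, phantom$size_xyz[1]), ylim = c(0, phantom$size_xyz[2]),
       asp = 1, xlab = "x (mm)", ylab = "y (mm)",
       main = "Probe trail and responses")
  inc <- phantom$inclusions
  if (nrow(inc)) {
    th <- seq(0, 2 * pi, length.out = 60)
    pal <- grDevices::hcl.colors(length(unique(inc$material)), "Dark 3")
    col_of <- setNames(pal, sort(unique(inc$material)))
    for (i in seq_len(nrow(inc)))
      graphics::polygon(inc$x[i] + inc$radius[i] * cos(th),
                        inc$y[i] + inc$radius[i] * sin(th),
                        border = col_of[inc$material[i]], lwd = 2)
    graphics::legend("topright", legend = names(col_of), col = col_of,
                     lwd = 2, cex = 0.7, bg = "white")
  }
  graphics::lines(log$stage$x_mm, log$stage$y_mm, col = "lightblue3")
  if (!is.null(log$responses) && nrow(log$responses))
    graphics::points(log$responses$x_mm, log$responses$y_mm, pch = 21,
                     bg = "black")
  invisible(NULL)
}

#' Plot the tolerance curve
#'
#' Mean TP, FP and accuracy against the classification tolerance.
#'
#' @param curve the data.frame returned by [tolerance_sweep()].
#' @export
plot_tolerance_curve <- function(curve) {
  old <- graphics::par(mar = c(4, 4, 2, 4))
  on.exit(graphics::par(old))
  ylim <- c(0, max(curve$mean_tp, curve$mean_fp) * 1.1)
  plot(curve$tolerance_mm, curve$mean_tp, type = "b", col = "goldenrod2",
       pch = 16, ylim = ylim, xlab = "tolerance (mm)", ylab = "mean count",
       main = "Classification vs tolerance")
  graphics::lines(curve$tolerance_mm, curve$mean_fp, type = "b",
                  col = "firebrick", pch = 16)
  graphics::par(new = TRUE)
  plot(curve$tolerance_mm, curve$mean_accuracy, type = "b", col = "steelblue",
       pch = 17, axes = FALSE, xlab = "", ylab = "", ylim = c(0, 1))
  graphics::axis(4)
  graphics::mtext("accuracy", side = 4, line = 2.5)
  graphics::legend("topleft", c("TP", "FP", "accuracy"),
                   col = c("goldenrod2", "firebrick", "steelblue"),
                   pch = c(16, 16, 17), cex = 0.8)
  invisible(NULL)
}

#' Plot identification rates with the psychometric fit
#'
#' @param rates the data.frame from [identification_rate_by_material()].
#' @param fit a `telepalp_psychfit` from [fit_cdf()].
#' @export
plot_psychometric <- function(rates, fit = NULL) {
  plot(rates$stiffness_k, rates$mean_rate, pch = 18, cex = 1.4,
       ylim = c(0, 1), xlab = "stiffness (N/mm)",
       ylab = "identification rate", main = "Psychometric curve")
  spread <- rates$iqr > 0
  if (any(spread))
    graphics::arrows(rates$stiffness_k[spread],
                     pmax(0, rates$mean_rate - rates$iqr / 2)[spread],
                     rates$stiffness_k[spread],
                     pmin(1, rates$mean_rate + rates$iqr / 2)[spread],
                     angle = 90, code = 3, length = 0.04)
  if (!is.null(fit) && !is.na(fit$a_thr)) {
    xs <- seq(min(rates$stiffness_k) - 0.5, max(rates$stiffness_k) + 0.5,
              length.out = 200)
    graphics::lines(xs, plogis((xs - fit$a_thr) / fit$b_scale),
                    col = "red", lty = 2)
    graphics::abline(v = fit$a_thr, col = "grey60", lty = 3)
  }
  invisible(NULL)
}

#' Render the standard report figures to files
#'
#' Writes the trail plot, tolerance curve and psychometric plot as PNGs.
#'
#' @param log a `telepalp_session`.
#' @param phantom the explored phantom.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
render_report <- function(log, phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grDevices::png(file.path(dir, "trail.png"), 700, 700)
  plot_session_trail(log, phantom)
  grDevices::dev.off()
  if (!is.null(log$responses) && nrow(log$responses)) {
    an <- analyze_sessions(log$responses, phantom)
    grDevices::png(file.path(dir, "tolerance.png"), 700, 500)
    plot_tolerance_curve(an$tolerance_curve)
    grDevices::dev.off()
    grDevices::png(file.path(dir, "psychometric.png"), 700, 500)
    plot_psychometric(an$material_rates,
                      structure(an$fit, class = "telepalp_psychfit"))
    grDevices::dev.off()
  }
  invisible(dir)
}
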