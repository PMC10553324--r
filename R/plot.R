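state_colors <- c(OFF = "#d62728", ON = "#2ca02c",
                  ON_NON_TROUBLESOME_DYSK = "#9edf64",
                  ON_TROUBLESOME_DYSK = "#ff7f0e",
                  DAYTIME_INACTIVITY = "#aec7e8",
                  NIGHTTIME_INACTIVITY = "#1f77b4",
                  NOT_WORN = "#7f7f7f", NOT_DETECTABLE = "#c7c7c7")

#' Plot a motor-state timeline
#'
#' `which = "timeline"` draws the temporal panel: a state ribbon over the
#' dyskinesia, tremor and bradykinesia intensity traces; `"pie"` the
#' percentage-duration pie chart; `"bars"` stacked per-day state hours.
#'
#' @param x a `"motor_timeline"`.
#' @param which `"timeline"`, `"pie"` or `"bars"`.
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.motor_timeline <- function(x, which = c("timeline", "pie", "bars"),
                                ...) {
  which <- match.arg(which)
  iv <- x$intervals
  if (which == "pie") {
    d <- summarize_durations(x)
    d <- d[d$hours > 0, ]
    graphics::pie(d$hours, labels = sprintf("%s (%.0f%%)", d$state,
                                            d$percent),
                  col = state_colors[d$state],
                  main = "Motor-state share of recording")
    return(invisible(x))
  }
  if (which == "bars") {
    day <- format(iv$start, "%Y-%m-%d")
    tab <- table(iv$state, day) * x$interval_s / 3600
    graphics::barplot(as.matrix(tab), col = state_colors[rownames(tab)],
                      ylab = "hours", main = "Daily motor-state hours",
                      legend.text = rownames(tab),
                      args.legend = list(cex = 0.6, x = "topright"))
    return(invisible(x))
  }
  has_tr <- !is.null(x$epochs)
  old <- graphics::par(mfrow = c(if (has_tr) 3 else 1, 1),
                       mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(old))
  th <- as.numeric(difftime(iv$start, x$start_time, units = "hours"))
  graphics::plot(NA, xlim = range(c(th, th + x$interval_s / 3600)),
                 ylim = c(0, 1), yaxt = "n", ylab = "state", xlab = "",
                 main = paste("Motor states:", x$subject_id))
  graphics::rect(th, 0, th + x$interval_s / 3600, 1,
                 col = state_colors[as.character(iv$state)], border = NA)
  if (has_tr) {
    eh <- x$epochs$t0 / 3600
    graphics::plot(eh, x$epochs$dysk_intensity, type = "h", col = "#ff7f0e",
                   ylim = c(0, 4), ylab = "dyskinesia", xlab = "")
    graphics::abline(h = c(0.5, 2.5), lty = 3)
    graphics::plot(eh, x$epochs$tremor_intensity, type = "h",
                   col = "#d62728", ylim = c(0, 4),
                   ylab = "tremor / brady", xlab = "hours")
    graphics::points(eh, x$epochs$brady_intensity, type = "h",
                     col = "#1f77b4")
  }
  invisible(x)
}

#' Plot a spectrogram matrix
#'
#' @param m matrix from [spectrogram_matrix()].
#' @param log_power image `log10(power + eps)` instead of raw power.
#' @param ... passed to [graphics::image()].
#' @return `m`, invisibly.
#' @export
plot_spectrogram <- function(m, log_power = TRUE, ...) {
  fr <- attr(m, "freqs"); t0 <- attr(m, "t0")
  z <- if (log_power) log10(t(m) + 1e-12) else t(m)
  graphics::image(t0 / 3600, fr, z, xlab = "hours", ylab = "Hz",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(m)
}
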