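## Base-graphics summaries: per-channel corrected piece means and
## cross-concert ROI trajectories.

#' Bar plot of SSC-corrected channel means
#'
#' One bar per long channel: the mean (across pieces, and concerts if
#' present) of the SSC-corrected piece means; zeroed-fraction shown as
#' bar shading.
#'
#' @param ssc_report an `ssc_report` (optionally with `concert` /
#'   `performer` columns from the pipeline).
#' @param main plot title.
#' @export
plot_ssc_report <- function(ssc_report, main = "SSC-corrected channel means") {
  agg <- stats::aggregate(corrected ~ pair, data = ssc_report, FUN = mean)
  zf <- stats::aggregate(zeroed ~ pair, data = ssc_report, FUN = mean)
  cols <- grDevices::gray(1 - 0.8 * zf$zeroed[match(agg$pair, zf$pair)])
  graphics::barplot(agg$corrected, names.arg = agg$pair, las = 2,
                    col = cols, main = main,
                    ylab = sprintf("corrected mean [%s]",
                                   attr(ssc_report, "units") %||% "Molar mm"),
                    cex.names = 0.7)
  graphics::mtext("darker = more often zeroed (low trust)", cex = 0.8)
}

#' Cross-concert ROI trajectory plot
#'
#' Per-concert ROI means with confidence-interval whiskers, one panel
#' line per performer; gap concerts are left blank (never
#' interpolated).
#'
#' @param tt a [trend_table()].
#' @param scout scout name to plot.
#' @param chromophore `"HbO"`, `"HbR"` or `"HbT"`.
#' @export
plot_trend <- function(tt, scout, chromophore = "HbT") {
  sub <- tt[tt$scout == scout & tt$chromophore == chromophore, ]
  if (nrow(sub) == 0L) stop_("no rows for scout %s / %s", scout, chromophore)
  perfs <- unique(sub$performer)
  ylim <- range(c(sub$ci_low, sub$ci_high), na.rm = TRUE)
  graphics::plot(NA, xlim = range(sub$concert_index), ylim = ylim,
                 xlab = "concert", ylab = sprintf("%s [Molar mm]", chromophore),
                 main = sprintf("%s across concerts", scout))
  graphics::abline(h = 0, lty = 3)
  for (i in seq_along(perfs)) {
    d <- sub[sub$performer == perfs[i] & !sub$gap, ]
    off <- (i - mean(seq_along(perfs))) * 0.08
    graphics::points(d$concert_index + off, d$mean, pch = 19, col = i)
    graphics::lines(d$concert_index + off, d$mean, col = i, lty = 2)
    graphics::arrows(d$concert_index + off, d$ci_low,
                     d$concert_index + off, d$ci_high,
                     angle = 90, code = 3, length = 0.04, col = i)
  }
  graphics::legend("topright", legend = perfs, col = seq_along(perfs),
                   pch = 19, bty = "n")
}
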