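## Base-graphics summaries of the two key visualizations: the scoring
## feature scatter and the sound-locked normalized power time courses.

#' Plot the sleep-scoring feature scatter
#'
#' Theta/delta power ratio (log scale) against peak-to-peak SD, one point
#' per scoring window, coloured by state when a `state` column is present.
#'
#' @param features `data.frame` from [computeFeatures()], optionally with
#'   a `state` column.
#' @return Invisibly, `NULL`. Called for its side effect.
#' @export
plotFeatureScatter <- function(features) {
  cols <- if ("state" %in% names(features)) {
    c(NREM = "darkorange2", REM = "purple3", WAKE = "grey40",
      UNKNOWN = "grey80")[features$state]
  } else "grey30"
  graphics::plot(features$p2p_sd, features$theta_delta_ratio, log = "y",
                 pch = 16, col = cols, cex = 0.6,
                 xlab = "peak-to-peak SD (uV)",
                 ylab = "theta/delta power ratio")
  if ("state" %in% names(features))
    graphics::legend("topright", legend = c("NREM", "REM"), pch = 16,
                     col = c("darkorange2", "purple3"), bty = "n")
  invisible(NULL)
}

#' Plot aggregated normalized power time courses
#'
#' Mean normalized band power over the 24 s around sound onset, one line
#' per sound type, with the 8-s sound window shaded.
#'
#' @param agg Output of [aggregateEpochs()] (optionally filtered to one
#'   sleep state).
#' @return Invisibly, `NULL`.
#' @export
plotPowerTimecourse <- function(agg) {
  stopifnot(all(c("time_s", "mean_normalized", "sound_type") %in% names(agg)))
  phases <- if ("phase" %in% names(agg)) unique(agg$phase) else "all"
  for (ph in phases) {
    d <- if ("phase" %in% names(agg)) agg[agg$phase == ph, ] else agg
    sounds <- unique(d$sound_type)
    cols <- stats::setNames(
      grDevices::hcl.colors(max(3L, length(sounds)), "Dark 3")[
        seq_along(sounds)], sounds)
    graphics::plot(NA, xlim = c(-8, 16), ylim = range(0, 1.3,
                                                      d$mean_normalized),
                   xlab = "time from sound onset (s)",
                   ylab = "normalized band power",
                   main = if (ph == "all") "" else paste0(ph, " sleep"))
    graphics::rect(0, 0, 8, 1.3, col = grDevices::adjustcolor("gold", 0.2),
                   border = NA)
    graphics::abline(h = 1, lty = 3)
    for (s in sounds) {
      ds <- d[d$sound_type == s, ]
      graphics::lines(ds$time_s - 8.5, ds$mean_normalized, col = cols[s],
                      lwd = 2)
    }
    graphics::legend("bottomleft", legend = sounds, col = cols[sounds],
                     lwd = 2, bty = "n", cex = 0.8)
  }
  invisible(NULL)
}
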