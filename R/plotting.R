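#' Diagnostic plot of a Jaccard series with pause markers
#'
#' Two stacked panels: the Jaccard coefficient versus frame number with
#' detected pauses shaded (yellow) and, when available, expert-annotated
#' pauses marked (green), and the derivative of the Jaccard curve with the
#' detection threshold band. This is the standard per-video inspection
#' figure for judging whether predicted plateaus line up with annotation.
#'
#' @param jaccard A [JaccardSeries-class].
#' @param deriv The matching [DerivativeSeries-class] (computed when
#'   missing).
#' @param events Detected [PauseEvents-class] (optional).
#' @param truth Annotated [PauseEvents-class] (optional).
#' @param threshold Optional numeric threshold to draw on the derivative
#'   panel.
#' @param main Plot title.
#' @return Invisibly, `NULL`. Called for its side effect on the active
#'   graphics device.
#' @export
plotPauseDiagnostics <- function(jaccard, deriv = NULL, events = NULL,
                                 truth = NULL, threshold = NULL,
                                 main = "Jaccard coefficient and detected pauses") {
  stopifnot(is(jaccard, "JaccardSeries"))
  if (is.null(deriv)) deriv <- finiteDifference(jaccard)
  op <- graphics::par(mfrow = c(2, 1), mar = c(2.5, 4, 2, 1), mgp = c(2, 0.7, 0))
  on.exit(graphics::par(op))
  f <- frameIndex(jaccard)
  graphics::plot(f, signalValues(jaccard), type = "l", col = "grey25",
                 xlab = "", ylab = "Jaccard coefficient", ylim = c(0, 1),
                 main = main)
  shadeEvents <- function(ev, col) {
    for (k in seq_len(length(ev)))
      graphics::rect(startFrame(ev)[k], graphics::par("usr")[3],
                     endFrame(ev)[k], graphics::par("usr")[4],
                     col = col, border = NA)
  }
  if (!is.null(events) && length(events)) {
    shadeEvents(events, grDevices::adjustcolor("gold", 0.4))
    graphics::lines(f, signalValues(jaccard), col = "grey25")
  }
  if (!is.null(truth) && length(truth))
    graphics::abline(v = c(startFrame(truth), endFrame(truth)),
                     col = "forestgreen", lty = 2)
  graphics::legend("bottomleft", bty = "n", cex = 0.8,
                   fill = c("gold", NA), border = NA,
                   lty = c(NA, 2), col = c(NA, "forestgreen"),
                   legend = c("detected pause", "annotated pause"))
  graphics::plot(frameIndex(deriv), signalValues(deriv), type = "l",
                 col = "grey25", xlab = "frame", ylab = "dJ / dframe")
  graphics::abline(h = 0, col = "grey70")
  if (!is.null(threshold))
    graphics::abline(h = c(-threshold, threshold), col = "firebrick",
                     lty = 3)
  invisible(NULL)
}
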