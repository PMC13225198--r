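#' End-to-end pause detection
#'
#' Runs the full pipeline on raw frames: per-frame detection (background
#' subtraction by default), IoU tracking, primary-track selection, and
#' plateau segmentation of the Jaccard series. When the input is already a
#' track (or a box CSV read via [readBoxCSV()]) the detection and tracking
#' stages are skipped.
#'
#' @param input A [FrameSequence-class], a [BirdTrack-class], or a list of
#'   tracks (the primary one is selected).
#' @param detector Optional detector function (see [frameDetector()]); by
#'   default a median-background model is estimated from the input frames.
#' @param trackerParam A [TrackerParam-class].
#' @param pauseParam A [PauseDetectorParam-class].
#' @return A list with elements `track` (the analysed [BirdTrack-class]),
#'   `jaccard` ([JaccardSeries-class]), `derivative`
#'   ([DerivativeSeries-class]), `threshold` (numeric) and `events`
#'   ([PauseEvents-class]).
#' @examples
#' sc <- generateBoxSequence(SceneParam(durationS = 1))
#' res <- runPauseDetection(sceneTrack(sc))
#' res$events
#' @export
runPauseDetection <- function(input, detector = NULL,
                              trackerParam = TrackerParam(),
                              pauseParam = PauseDetectorParam()) {
  track <- if (is(input, "FrameSequence")) {
    dets <- detectAllFrames(input, detector)
    if (is.null(dets) || !nrow(dets))
      stop("no subject: the detector found nothing in any frame",
           call. = FALSE)
    selectPrimaryTrack(trackDetections(dets, frameRate = frameRate(input),
                                       param = trackerParam))
  } else if (is(input, "BirdTrack")) input
  else if (is.list(input) && length(input) && is(input[[1]], "BirdTrack"))
    selectPrimaryTrack(input)
  else stop("unsupported input type", call. = FALSE)
  js <- jaccardSeries(track)
  ds <- finiteDifference(js)
  thr <- if (pauseParam@thresholdReference == "derivative")
    pauseThreshold(ds, fraction = pauseParam@thresholdFraction,
                   window = pauseParam@meanWindow)
  else pauseThreshold(js, fraction = pauseParam@thresholdFraction,
                      window = pauseParam@meanWindow)
  events <- detectPauses(track, pauseParam)
  list(track = track, jaccard = js, derivative = ds, threshold = thr,
       events = events)
}
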