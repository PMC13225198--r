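#' Box-sequence CSV (MOT-like dialect)
#'
#' One row per detection, comma-separated with a header, columns
#' `frame,track_id,x_min,y_min,x_max,y_max,score`. Frames are 0-based;
#' coordinates follow the package-wide half-open pixel convention.
#'
#' @param path File path.
#' @param x A [BirdTrack-class], a list of them, or a detection data frame
#'   with a `track_id` column.
#' @param frameRate Frame rate to attach to the tracks read back (the CSV
#'   itself does not store one).
#' @return `readBoxCSV` returns a named list of [BirdTrack-class] objects
#'   (names are track ids); `writeBoxCSV` returns `path` invisibly.
#' @name boxCSV
NULL

#' @rdname boxCSV
#' @export
writeBoxCSV <- function(x, path) {
  if (is(x, "BirdTrack")) x <- list(x)
  if (is.list(x)) {
    x <- do.call(rbind, lapply(x, function(tr) {
      d <- detections(tr)
      data.frame(frame = d$frame, track_id = trackId(tr), d[, -1])
    }))
  }
  cols <- c("frame", "track_id", "x_min", "y_min", "x_max", "y_max", "score")
  utils::write.csv(x[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname boxCSV
#' @export
readBoxCSV <- function(path, frameRate) {
  d <- utils::read.csv(path)
  need <- c("frame", "track_id", "x_min", "y_min", "x_max", "y_max")
  if (!all(need %in% names(d)))
    stop("malformed box CSV ", path, ": need columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (is.null(d$score)) d$score <- 1
  out <- lapply(split(d, d$track_id), function(dd) {
    dd <- dd[order(dd$frame), ]
    BirdTrack(dd[, setdiff(names(dd), "track_id")], frameRate = frameRate,
              trackId = dd$track_id[1])
  })
  out[order(as.integer(names(out)))]
}

#' Pause-event CSV
#'
#' Comma-separated with a header, columns
#' `start_frame,end_frame,duration_frames,duration_ms`; frame intervals are
#' 0-based and inclusive. The same dialect is used for detected pauses and
#' for expert ground-truth annotations.
#'
#' @param x A [PauseEvents-class].
#' @param path File path.
#' @param frameRate Frame rate attached to the events read back.
#' @return `readPauseCSV` returns a [PauseEvents-class]; `writePauseCSV`
#'   returns `path` invisibly.
#' @name pauseCSV
NULL

#' @rdname pauseCSV
#' @export
writePauseCSV <- function(x, path) {
  stopifnot(is(x, "PauseEvents"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname pauseCSV
#' @export
readPauseCSV <- function(path, frameRate) {
  d <- utils::read.csv(path)
  if (!all(c("start_frame", "end_frame") %in% names(d)))
    stop("malformed pause CSV ", path,
         ": need columns start_frame, end_frame", call. = FALSE)
  PauseEvents(start = d$start_frame, end = d$end_frame,
              frameRate = frameRate)
}

#' Jaccard-signal CSV
#'
#' Columns `frame,jaccard,derivative`; the derivative is `NA` on the last
#' sample of each contiguous segment (no forward difference exists there).
#'
#' @param jaccard A [JaccardSeries-class].
#' @param deriv The matching [DerivativeSeries-class] (computed when
#'   missing).
#' @param path File path.
#' @param frameRate Frame rate attached on reading.
#' @return `readSignalCSV` returns a list with elements `jaccard` and
#'   `derivative`; `writeSignalCSV` returns `path` invisibly.
#' @name signalCSV
NULL

#' @rdname signalCSV
#' @export
writeSignalCSV <- function(jaccard, path, deriv = NULL) {
  stopifnot(is(jaccard, "JaccardSeries"))
  if (is.null(deriv)) deriv <- finiteDifference(jaccard)
  d <- data.frame(frame = frameIndex(jaccard), jaccard = signalValues(jaccard),
                  derivative = signalValues(deriv)[
                    match(frameIndex(jaccard), frameIndex(deriv))])
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname signalCSV
#' @export
readSignalCSV <- function(path, frameRate) {
  d <- utils::read.csv(path)
  if (!all(c("frame", "jaccard") %in% names(d)))
    stop("malformed signal CSV ", path, ": need columns frame, jaccard",
         call. = FALSE)
  js <- new("JaccardSeries", frame = as.integer(d$frame),
            values = d$jaccard, frameRate = as.numeric(frameRate))
  ds <- NULL
  if ("derivative" %in% names(d) && any(!is.na(d$derivative))) {
    keep <- !is.na(d$derivative)
    ds <- new("DerivativeSeries", frame = as.integer(d$frame[keep]),
              values = d$derivative[keep], frameRate = as.numeric(frameRate))
  }
  list(jaccard = js, derivative = ds)
}

#' Read a directory of numbered still frames
#'
#' Accepts PNG (and TIFF, when the tiff package is installed) stills whose
#' file names sort into frame order; RGB images are converted to grayscale
#' with luma weights. The frame rate must be supplied — still directories
#' do not carry one.
#'
#' @param dir Directory of image files.
#' @param frameRate Frames per second of the original recording.
#' @param pattern Regular expression selecting image files.
#' @return A [FrameSequence-class].
#' @export
readFrameDirectory <- function(dir, frameRate,
                               pattern = "\\.(png|tif|tiff)$") {
  files <- sort(list.files(dir, pattern = pattern, ignore.case = TRUE,
                           full.names = TRUE))
  if (!length(files)) stop("no image files found in ", dir, call. = FALSE)
  readOne <- function(f) {
    if (grepl("\\.png$", f, ignore.case = TRUE)) img <- png::readPNG(f)
    else {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("the tiff package is required for TIFF input", call. = FALSE)
      img <- tiff::readTIFF(f)
    }
    rgbToGray(img)
  }
  FrameSequence(lapply(files, readOne), frameRate = frameRate)
}

#' Write a frame sequence as numbered PNG stills
#'
#' @param frames A [FrameSequence-class].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return The directory path, invisibly.
#' @export
writeFrameDirectory <- function(frames, dir, prefix = "frame") {
  stopifnot(is(frames, "FrameSequence"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(length(frames)))
    png::writePNG(getFrame(frames, i),
                  file.path(dir, sprintf("%s_%06d.png", prefix,
                                         frames@frame[i])))
  invisible(dir)
}

#' Write an evaluation report as JSON
#'
#' Pooled confusion counts and metrics, with an optional per-video
#' breakdown, in a stable machine-readable layout.
#'
#' @param evaluation A list as returned by [evaluatePauses()], or a
#'   [ConfusionCounts-class].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeMetricsJSON <- function(evaluation, path) {
  if (is(evaluation, "ConfusionCounts"))
    evaluation <- list(perVideo = NULL, pooled = evaluation)
  cc <- evaluation$pooled
  out <- list(tp = tp(cc), fp = fp(cc), fn = fn(cc),
              precision = suppressWarnings(precision(cc)),
              recall = suppressWarnings(recall(cc)),
              f1 = suppressWarnings(f1Score(cc)))
  if (!is.null(evaluation$perVideo)) out$per_video <- evaluation$perVideo
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read and write scene parameters as YAML
#'
#' A plain-text echo of every simulator parameter, so a synthetic dataset
#' can be regenerated exactly from its config file.
#'
#' @param param A [SceneParam-class].
#' @param path File path (YAML).
#' @return `readSceneParam` returns a [SceneParam-class]; `writeSceneParam`
#'   returns `path` invisibly.
#' @name sceneParamIO
NULL

#' @rdname sceneParamIO
#' @export
writeSceneParam <- function(param, path) {
  stopifnot(is(param, "SceneParam"))
  slots <- slotNames(param)
  x <- lapply(slots, function(s) {
    v <- slot(param, s)
    if (is.matrix(v)) apply(v, 1, as.list) else v
  })
  names(x) <- slots
  x <- x[!vapply(x, is.null, logical(1))]
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname sceneParamIO
#' @export
readSceneParam <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$pauseIntervals))
    x$pauseIntervals <- do.call(rbind, lapply(x$pauseIntervals, unlist))
  if (!is.null(x$bodyCenter)) x$bodyCenter <- unlist(x$bodyCenter)
  if (!is.null(x$pauseDurationRangeMs))
    x$pauseDurationRangeMs <- unlist(x$pauseDurationRangeMs)
  do.call(SceneParam, x)
}

#' Write a synthetic scene to disk
#'
#' Ground-truth box CSV, pause-annotation CSV, the echoed configuration as
#' YAML, and (for rendered scenes) numbered PNG frames.
#'
#' @param scene A [SyntheticScene-class].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
writeScene <- function(scene, dir) {
  stopifnot(is(scene, "SyntheticScene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    boxes = writeBoxCSV(sceneTrack(scene), file.path(dir, "boxes.csv")),
    pauses = writePauseCSV(scenePauses(scene), file.path(dir, "pauses.csv")),
    config = writeSceneParam(sceneParam(scene), file.path(dir, "scene.yaml")))
  if (!is.null(sceneFrames(scene)))
    files <- c(files,
               frames = writeFrameDirectory(sceneFrames(scene),
                                            file.path(dir, "frames")))
  invisible(files)
}
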