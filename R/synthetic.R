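#' @rdname SceneParam-class
#' @param frameWidth,frameHeight,frameRate,durationS,wingbeatHz,baseHalfWidth,baseHalfHeight,wingAmplitude,heightAmplitude,pausePostureFraction,bodyCenter,jitterSd,pixelNoiseSd,pauseIntervals,pauseRatePerS,pauseDurationRangeMs,seed
#'   See the class slots.
#' @return `SceneParam()` returns a validated parameter object.
#' @examples
#' SceneParam(durationS = 1, pauseIntervals = cbind(200, 229))
#' @export
SceneParam <- function(frameWidth = 800, frameHeight = 600, frameRate = 500,
                       durationS = 2, wingbeatHz = 40,
                       baseHalfWidth = 40, baseHalfHeight = 30,
                       wingAmplitude = 160, heightAmplitude = 50,
                       pausePostureFraction = 0.6,
                       bodyCenter = c(frameWidth / 2, frameHeight / 2),
                       jitterSd = 1, pixelNoiseSd = 0.02,
                       pauseIntervals = NULL, pauseRatePerS = 1,
                       pauseDurationRangeMs = c(20, 80), seed = 1L) {
  if (!is.null(pauseIntervals)) {
    pauseIntervals <- as.matrix(pauseIntervals)
    storage.mode(pauseIntervals) <- "integer"
  }
  p <- new("SceneParam", frameWidth = frameWidth, frameHeight = frameHeight,
           frameRate = frameRate, durationS = durationS,
           wingbeatHz = wingbeatHz, baseHalfWidth = baseHalfWidth,
           baseHalfHeight = baseHalfHeight, wingAmplitude = wingAmplitude,
           heightAmplitude = heightAmplitude,
           pausePostureFraction = pausePostureFraction,
           bodyCenter = bodyCenter, jitterSd = jitterSd,
           pixelNoiseSd = pixelNoiseSd, pauseIntervals = pauseIntervals,
           pauseRatePerS = pauseRatePerS,
           pauseDurationRangeMs = pauseDurationRangeMs,
           seed = as.integer(seed))
  maxHW <- p@baseHalfWidth + p@wingAmplitude
  maxHH <- p@baseHalfHeight + p@heightAmplitude
  if (p@bodyCenter[1] - maxHW < 0 || p@bodyCenter[1] + maxHW > p@frameWidth ||
      p@bodyCenter[2] - maxHH < 0 || p@bodyCenter[2] + maxHH > p@frameHeight)
    stop("scene larger than frame: the bird's maximal extent does not fit",
         call. = FALSE)
  p
}

setMethod("show", "SceneParam", function(object) {
  cat(sprintf(paste0("SceneParam: %g x %g px @ %g fps, %.3g s, wingbeat %g Hz\n",
                     "  body half-extents (%g, %g) px + wing modulation (%g, %g) px\n",
                     "  jitterSd=%g px, pixelNoiseSd=%g, seed=%d\n"),
              object@frameWidth, object@frameHeight, object@frameRate,
              object@durationS, object@wingbeatHz, object@baseHalfWidth,
              object@baseHalfHeight, object@wingAmplitude,
              object@heightAmplitude, object@jitterSd, object@pixelNoiseSd,
              object@seed))
  if (!is.null(object@pauseIntervals))
    cat(sprintf("  %d explicit pause interval(s)\n", nrow(object@pauseIntervals)))
  else
    cat(sprintf("  random pauses: rate %g/s, durations %g-%g ms\n",
                object@pauseRatePerS, object@pauseDurationRangeMs[1],
                object@pauseDurationRangeMs[2]))
})

## Evaluate fn() with the RNG seeded to `seed`, restoring global RNG state.
withSeed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv())
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  fn()
}

#' Sample a random pause schedule
#'
#' Pause onsets follow a homogeneous Poisson process of the given rate,
#' with durations drawn uniformly from the stated range. Pauses are
#' truncated at the end of the recording, and any pause starting before the
#' previous one ends is dropped (de-overlapping). Reproducible from the
#' seed.
#'
#' @param ratePerS Expected pauses per second (>= 0).
#' @param durationRangeMs Numeric length 2, uniform duration range in ms.
#' @param totalS Total recording time in seconds.
#' @param seed Optional integer seed (when `NULL` the current RNG stream is
#'   used).
#' @return A 2-column matrix of `[start_s, end_s)` intervals in seconds,
#'   sorted, non-overlapping (0 rows when no pause is drawn).
#' @export
samplePauseSchedule <- function(ratePerS, durationRangeMs, totalS,
                                seed = NULL) {
  if (ratePerS < 0) stop("'ratePerS' must be >= 0", call. = FALSE)
  if (length(durationRangeMs) != 2 || any(durationRangeMs <= 0) ||
      diff(durationRangeMs) < 0)
    stop("'durationRangeMs' must be an increasing positive pair",
         call. = FALSE)
  expPauseS <- ratePerS * totalS * mean(durationRangeMs) / 1000
  if (expPauseS > totalS)
    stop("infeasible pause density: expected pause time exceeds the total",
         call. = FALSE)
  draw <- function() {
    k <- stats::rpois(1, ratePerS * totalS)
    if (k == 0) return(matrix(numeric(), ncol = 2))
    onset <- sort(stats::runif(k, 0, totalS))
    dur <- stats::runif(k, durationRangeMs[1], durationRangeMs[2]) / 1000
    end <- pmin(onset + dur, totalS)
    keep <- logical(k)
    lastEnd <- -Inf
    for (i in seq_len(k)) {
      if (onset[i] > lastEnd) {
        keep[i] <- TRUE
        lastEnd <- end[i]
      }
    }
    cbind(onset[keep], end[keep])
  }
  if (is.null(seed)) draw() else withSeed(seed, draw)
}

## Shared kinematic core of both generator tiers: per-frame pause state,
## wing phase, half-extents and jittered body centre. Assumes the RNG is
## already seeded by the caller.
sceneKinematics <- function(param) {
  n <- round(param@frameRate * param@durationS)
  if (n < 2) stop("invalid schedule: scene must span >= 2 frames",
                  call. = FALSE)
  if (!is.null(param@pauseIntervals)) {
    iv <- param@pauseIntervals
  } else {
    sec <- samplePauseSchedule(param@pauseRatePerS,
                               param@pauseDurationRangeMs,
                               param@durationS)
    iv <- cbind(floor(sec[, 1] * param@frameRate),
                pmin(n - 1, ceiling(sec[, 2] * param@frameRate) - 1))
    iv <- iv[iv[, 2] >= iv[, 1], , drop = FALSE]
    storage.mode(iv) <- "integer"
  }
  paused <- rep(FALSE, n)
  for (k in seq_len(nrow(iv))) paused[(iv[k, 1]:iv[k, 2]) + 1L] <- TRUE
  inc <- ifelse(paused, 0, 2 * pi * param@wingbeatHz / param@frameRate)
  phase <- cumsum(inc) - inc  # phase 0 at the first frame
  s <- abs(sin(phase))
  s[paused] <- param@pausePostureFraction
  hw <- param@baseHalfWidth + param@wingAmplitude * s
  hh <- param@baseHalfHeight + param@heightAmplitude * s
  jx <- as.numeric(stats::filter(stats::rnorm(n, 0, param@jitterSd), 0.9,
                                 method = "recursive"))
  jy <- as.numeric(stats::filter(stats::rnorm(n, 0, param@jitterSd), 0.9,
                                 method = "recursive"))
  cx <- pmin(pmax(param@bodyCenter[1] + jx, hw), param@frameWidth - hw)
  cy <- pmin(pmax(param@bodyCenter[2] + jy, hh), param@frameHeight - hh)
  active <- (n - sum(paused)) / param@frameRate
  list(n = n, paused = paused, intervals = iv, phase = phase,
       hw = hw, hh = hh, cx = cx, cy = cy,
       wingbeatCount = as.integer(round(param@wingbeatHz * active)))
}

sceneFromKinematics <- function(param, kin, frames = NULL) {
  d <- data.frame(frame = seq_len(kin$n) - 1L,
                  x_min = kin$cx - kin$hw, y_min = kin$cy - kin$hh,
                  x_max = kin$cx + kin$hw, y_max = kin$cy + kin$hh)
  iv <- kin$intervals
  o <- order(iv[, 1])
  new("SyntheticScene",
      track = BirdTrack(d, frameRate = param@frameRate),
      pauseEvents = PauseEvents(start = iv[o, 1], end = iv[o, 2],
                                frameRate = param@frameRate),
      wingbeatCount = kin$wingbeatCount, param = param, frames = frames)
}

#' Generate a ground-truthed synthetic box sequence
#'
#' The fast simulator tier: per-frame ground-truth bounding boxes of a
#' single hovering bird, with no pixels rendered. While flapping, the box
#' half-width oscillates as `baseHalfWidth + wingAmplitude * |sin(phase)|`
#' (widest at both stroke extremes, approximating the projected wing
#' envelope) and the half-height analogously; during a scheduled pause the
#' wing phase freezes and the box is held at the pause posture (wings
#' extended backwards near mid-pronation), moved only by body jitter. Fully
#' reproducible from the seed in the parameters.
#'
#' @param param A [SceneParam-class].
#' @return A [SyntheticScene-class] (with no frames).
#' @examples
#' sc <- generateBoxSequence(SceneParam(durationS = 1, seed = 7))
#' sceneWingbeatCount(sc)
#' scenePauses(sc)
#' @export
generateBoxSequence <- function(param) {
  stopifnot(is(param, "SceneParam"))
  withSeed(param@seed, function() sceneFromKinematics(param,
                                                      sceneKinematics(param)))
}

#' Render a ground-truthed synthetic frame sequence
#'
#' The pixel tier: rasterises a dark body ellipse plus two wing ellipses
#' whose horizontal extent follows the wing phase (held at the pause
#' posture during pauses) on a light background, then adds Gaussian pixel
#' noise. The ground-truth bounding box of each frame is the tight box of
#' all bird pixels, so detector and tracker can be scored pixel-up.
#'
#' @param param A [SceneParam-class]. Rendering cost scales with
#'   `frameWidth * frameHeight * frames`, so keep scenes small (e.g.
#'   200 x 150 px for a fraction of a second) in interactive use.
#' @return A [SyntheticScene-class] whose `frames` slot is a
#'   [FrameSequence-class].
#' @export
renderFrames <- function(param) {
  stopifnot(is(param, "SceneParam"))
  withSeed(param@seed, function() {
    kin <- sceneKinematics(param)
    w <- as.integer(param@frameWidth); h <- as.integer(param@frameHeight)
    px <- matrix(rep(seq_len(w) - 0.5, each = h), nrow = h)  # pixel centres, x
    py <- matrix(rep(seq_len(h) - 0.5, times = w), nrow = h) # pixel centres, y
    arr <- array(0, dim = c(h, w, kin$n))
    boxes <- matrix(0, kin$n, 4)
    bhw <- param@baseHalfWidth; bhh <- param@baseHalfHeight
    for (i in seq_len(kin$n)) {
      cx <- kin$cx[i]; cy <- kin$cy[i]
      body <- ((px - cx) / bhw)^2 + ((py - cy) / bhh)^2 <= 1
      wext <- kin$hw[i] - bhw
      wingV <- max(2, 0.4 * kin$hh[i])
      mask <- body
      img <- matrix(0.75, h, w)
      if (wext >= 1) {
        aW <- (bhw + wext) / 2
        for (sgn in c(-1, 1)) {
          wing <- ((px - (cx + sgn * aW)) / aW)^2 +
            ((py - cy) / wingV)^2 <= 1
          img[wing] <- 0.35
          mask <- mask | wing
        }
      }
      img[body] <- 0.15
      cols <- range(which(colSums(mask) > 0))
      rows <- range(which(rowSums(mask) > 0))
      boxes[i, ] <- c(cols[1] - 1, rows[1] - 1, cols[2], rows[2])
      if (param@pixelNoiseSd > 0)
        img <- img + stats::rnorm(h * w, 0, param@pixelNoiseSd)
      arr[, , i] <- pmin(pmax(img, 0), 1)
    }
    kin$cx <- (boxes[, 1] + boxes[, 3]) / 2
    kin$cy <- (boxes[, 2] + boxes[, 4]) / 2
    kin$hw <- (boxes[, 3] - boxes[, 1]) / 2
    kin$hh <- (boxes[, 4] - boxes[, 2]) / 2
    sceneFromKinematics(param, kin,
                        frames = FrameSequence(arr, param@frameRate))
  })
}

#' Render the bird-free background plate
#'
#' The clean background image of the synthetic scene (uniform illumination,
#' no bird, no noise), as a fixed camera would record before the bird
#' arrives at the feeder. Useful as the reference image of a
#' [BackgroundModel-class]: estimating the background from the video itself
#' (per-pixel median) leaves a ghost of a perfectly stationary subject,
#' whereas a bird-free plate does not.
#'
#' @param param A [SceneParam-class].
#' @return Numeric matrix (`frameHeight x frameWidth`).
#' @export
renderBackground <- function(param) {
  stopifnot(is(param, "SceneParam"))
  matrix(0.75, as.integer(param@frameHeight), as.integer(param@frameWidth))
}

#' Synthetic-scene accessors
#'
#' @param x A [SyntheticScene-class].
#' @return `sceneTrack`: the ground-truth [BirdTrack-class]; `scenePauses`:
#'   the injected [PauseEvents-class]; `sceneWingbeatCount`: integer count
#'   of full wingbeats while flapping; `sceneParam`: the generating
#'   [SceneParam-class]; `sceneFrames`: the rendered
#'   [FrameSequence-class] or `NULL`.
#' @name sceneAccessors
NULL

#' @rdname sceneAccessors
#' @export
sceneTrack <- function(x) { stopifnot(is(x, "SyntheticScene")); x@track }
#' @rdname sceneAccessors
#' @export
scenePauses <- function(x) { stopifnot(is(x, "SyntheticScene")); x@pauseEvents }
#' @rdname sceneAccessors
#' @export
sceneWingbeatCount <- function(x) {
  stopifnot(is(x, "SyntheticScene")); x@wingbeatCount
}
#' @rdname sceneAccessors
#' @export
sceneParam <- function(x) { stopifnot(is(x, "SyntheticScene")); x@param }
#' @rdname sceneAccessors
#' @export
sceneFrames <- function(x) { stopifnot(is(x, "SyntheticScene")); x@frames }

setMethod("show", "SyntheticScene", function(object) {
  cat(sprintf("SyntheticScene: %d frames, %d pause(s), %d wingbeats%s\n",
              length(object@track), length(object@pauseEvents),
              object@wingbeatCount,
              if (is.null(object@frames)) " (boxes only)" else " (rendered)"))
})
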