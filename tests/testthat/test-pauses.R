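test_that("pauseThreshold is the stated fraction of the reference mean", {
  js <- new("JaccardSeries", frame = 0:3, values = rep(0.8, 4), frameRate = 500)
  expect_equal(pauseThreshold(js, fraction = 0.9), 0.72)
  js2 <- new("JaccardSeries", frame = 0:1, values = c(0.6, 1.0), frameRate = 500)
  expect_equal(pauseThreshold(js2, fraction = 0.5), 0.4)
  # default fraction is 0.9
  expect_equal(pauseThreshold(js), 0.9 * 0.8)
  # derivative reference uses the mean absolute change
  ds <- new("DerivativeSeries", frame = 0:2, values = c(-0.2, 0.4, 0),
            frameRate = 500)
  expect_equal(pauseThreshold(ds, fraction = 0.9), 0.9 * 0.2)
  empty <- new("JaccardSeries", frame = integer(), values = numeric(),
               frameRate = 500)
  expect_error(pauseThreshold(empty), "insufficient")
  expect_error(pauseThreshold(js, fraction = 0), "fraction")
})

test_that("windowed pauseThreshold tracks local scale", {
  v <- c(rep(0.2, 10), rep(0.8, 10))
  js <- new("JaccardSeries", frame = 0:19, values = v, frameRate = 500)
  thr <- pauseThreshold(js, fraction = 1, window = 5)
  expect_length(thr, 20)
  expect_equal(thr[3], 0.2)   # fully inside the low block
  expect_equal(thr[18], 0.8)  # fully inside the high block
  expect_true(all(diff(thr) >= -1e-12))
})

test_that("flagPauseFrames thresholds the absolute derivative", {
  ds <- new("DerivativeSeries", frame = 0:2, values = c(0, 0.5, 0.01),
            frameRate = 500)
  expect_equal(flagPauseFrames(ds, 0.1), c(TRUE, FALSE, TRUE))
  # threshold 0 flags exactly-zero derivatives only
  expect_equal(flagPauseFrames(ds, 0), c(TRUE, FALSE, FALSE))
  expect_error(flagPauseFrames(ds, -1), ">= 0")
  # sign-agnostic
  ds2 <- new("DerivativeSeries", frame = 0:1, values = c(-0.05, 0.05),
             frameRate = 500)
  expect_equal(flagPauseFrames(ds2, 0.1), c(TRUE, TRUE))
})

test_that("extractPauseEvents merges across tolerated gaps and filters short runs", {
  p3 <- PauseDetectorParam(minPauseFrames = 3)
  ev <- extractPauseEvents(c(FALSE, TRUE, TRUE, TRUE, FALSE), param = p3,
                           frameRate = 500)
  expect_equal(length(ev), 1L)
  expect_equal(startFrame(ev), 1L); expect_equal(endFrame(ev), 3L)
  expect_equal(durationFrames(ev), 3L)
  expect_equal(durationMs(ev), 6)

  p2 <- PauseDetectorParam(minPauseFrames = 2)
  expect_equal(length(extractPauseEvents(c(TRUE, FALSE, TRUE), param = p2,
                                         frameRate = 500)), 0L)

  p41 <- PauseDetectorParam(minPauseFrames = 4, gapToleranceFrames = 1)
  ev2 <- extractPauseEvents(c(TRUE, TRUE, FALSE, TRUE, TRUE), param = p41,
                            frameRate = 500)
  expect_equal(length(ev2), 1L)
  expect_equal(c(startFrame(ev2), endFrame(ev2)), c(0L, 4L))

  # a tolerated gap at the mask edge is not bridged (no flanking run)
  ev3 <- extractPauseEvents(c(FALSE, TRUE, TRUE, TRUE, TRUE), param = p41,
                            frameRate = 500)
  expect_equal(c(startFrame(ev3), endFrame(ev3)), c(1L, 4L))

  expect_equal(length(extractPauseEvents(logical(), param = p3,
                                         frameRate = 500)), 0L)
})

test_that("extractPauseEvents never bridges detection gaps in frame indices", {
  p <- PauseDetectorParam(minPauseFrames = 3, gapToleranceFrames = 2)
  # frames 0,1,2 then 10,11,12: two separate runs despite all-true mask
  ev <- extractPauseEvents(rep(TRUE, 6), frame = c(0:2, 10:12), param = p,
                           frameRate = 500)
  expect_equal(startFrame(ev), c(0L, 10L))
  expect_equal(endFrame(ev), c(2L, 12L))
})

test_that("detectPauses recovers a frozen interval amid oscillation", {
  tr <- frozenBoxTrack(n = 400, freezeAt = 100:130)
  ev <- detectPauses(tr)
  expect_equal(length(ev), 1L)
  expect_lte(abs(startFrame(ev) - 100), 2)
  expect_lte(abs(endFrame(ev) - 130), 2)
})

test_that("detectPauses handles the degenerate all-still and no-pause cases", {
  # identical boxes throughout -> one event spanning (nearly) the series
  d <- data.frame(frame = 0:99, x_min = 0, y_min = 0, x_max = 10, y_max = 10)
  still <- BirdTrack(d, frameRate = 500)
  ev <- detectPauses(still)
  expect_equal(length(ev), 1L)
  expect_equal(startFrame(ev), 0L)
  expect_gte(endFrame(ev), 96L)
  # pure oscillation with no frozen interval -> no events
  osc <- frozenBoxTrack(n = 400, freezeAt = integer())
  expect_equal(length(detectPauses(osc)), 0L)
  expect_error(detectPauses(BirdTrack(d[1:2, ], frameRate = 500)),
               "insufficient")
})

test_that("detectPauses is deterministic and monotone in its parameters", {
  tr <- sceneTrack(generateBoxSequence(SceneParam(durationS = 2, seed = 5)))
  ev1 <- detectPauses(tr)
  ev2 <- detectPauses(tr)
  expect_identical(as.data.frame(ev1), as.data.frame(ev2))

  js <- jaccardSeries(tr); ds <- finiteDifference(js)
  nFlagged <- function(fr) sum(flagPauseFrames(ds, pauseThreshold(ds, fr)))
  flagged <- vapply(c(0.2, 0.5, 0.9, 1), nFlagged, numeric(1))
  expect_true(all(diff(flagged) >= 0))

  nEvents <- function(mp) length(detectPauses(tr,
    PauseDetectorParam(minPauseFrames = mp)))
  counts <- vapply(c(1L, 3L, 6L, 12L), nEvents, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("detected events are sorted, disjoint and inside the series range", {
  for (seed in 1:5) {
    sc <- generateBoxSequence(SceneParam(durationS = 2, seed = seed))
    tr <- sceneTrack(sc)
    ev <- detectPauses(tr)
    if (length(ev) > 1) {
      expect_true(all(diff(startFrame(ev)) > 0))
      expect_true(all(startFrame(ev)[-1] > endFrame(ev)[-length(ev)]))
    }
    if (length(ev)) {
      expect_gte(min(startFrame(ev)), min(frameIndex(tr)))
      expect_lte(max(endFrame(ev)), max(frameIndex(tr)))
    }
  }
})

test_that("the literal Jaccard-mean threshold rule is available as an option", {
  tr <- frozenBoxTrack(n = 200, freezeAt = 50:80)
  p <- PauseDetectorParam(thresholdReference = "jaccard")
  ev <- detectPauses(tr, p)
  # the permissive published wording flags the frozen stretch too: the
  # detected events must cover the injected pause
  expect_true(any(startFrame(ev) <= 52 & endFrame(ev) >= 76))
  js <- jaccardSeries(tr)
  expect_equal(pauseThreshold(js), 0.9 * mean(signalValues(js)))
})

test_that("pause event containers validate their invariants", {
  expect_error(PauseEvents(start = c(10, 5), end = c(20, 8), frameRate = 500),
               "sorted")
  expect_error(PauseEvents(start = c(0, 5), end = c(6, 10), frameRate = 500),
               "non-overlapping")
  ev <- PauseEvents(start = c(0, 10), end = c(4, 12), frameRate = 500)
  expect_equal(durationFrames(ev), c(5L, 3L))
  expect_equal(durationMs(ev), c(10, 6))
})
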