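test_that("box-sequence generation is reproducible and honours the schedule", {
  p <- SceneParam(durationS = 1, seed = 42)
  sc1 <- generateBoxSequence(p)
  sc2 <- generateBoxSequence(p)
  expect_identical(detections(sceneTrack(sc1)), detections(sceneTrack(sc2)))
  expect_identical(as.data.frame(scenePauses(sc1)),
                   as.data.frame(scenePauses(sc2)))
  # a different seed changes the realisation
  sc3 <- generateBoxSequence(SceneParam(durationS = 1, seed = 43))
  expect_false(identical(detections(sceneTrack(sc1)),
                         detections(sceneTrack(sc3))))
  # explicit empty schedule -> no pauses in the ground truth
  none <- generateBoxSequence(SceneParam(durationS = 0.5,
                                         pauseIntervals = matrix(integer(),
                                                                 ncol = 2)))
  expect_equal(length(scenePauses(none)), 0L)
  expect_equal(length(sceneTrack(none)), 250L)
})

test_that("generator bookkeeping: wingbeats and pause frames add up", {
  # 1 s at 40 Hz with one 60 ms pause: ~38 wingbeats, one 30-frame pause
  p <- SceneParam(durationS = 1, wingbeatHz = 40,
                  pauseIntervals = cbind(250, 279))
  sc <- generateBoxSequence(p)
  expect_equal(sceneWingbeatCount(sc), 38L)  # round(40 * 0.94)
  expect_equal(durationFrames(scenePauses(sc)), 30L)
  expect_equal(durationMs(scenePauses(sc)), 60)
  # during the pause the box is frozen up to jitter; with zero jitter the
  # held posture is exactly constant
  p0 <- SceneParam(durationS = 1, jitterSd = 0, pauseIntervals = cbind(250, 279))
  b <- trackBoxes(sceneTrack(generateBoxSequence(p0)))
  widths <- b[, 3] - b[, 1]
  expect_equal(unique(widths[251:280]),
               2 * (40 + 0.6 * 160))  # base + posture fraction of amplitude
  expect_gt(stats::sd(widths[1:250]), 10)  # flapping modulation
})

test_that("ground-truth wingbeat count is consistent with the spectral estimate", {
  p <- SceneParam(durationS = 1, jitterSd = 0,
                  pauseIntervals = matrix(integer(), ncol = 2))
  sc <- generateBoxSequence(p)
  js <- jaccardSeries(sceneTrack(sc))
  # the IoU dissimilarity pulses twice per wingbeat (once per stroke)
  fhat <- estimateWingbeatFrequency(js, peaksPerWingbeat = 2)
  expect_lte(abs(fhat * 1 - sceneWingbeatCount(sc)), 1)
})

test_that("pause schedules follow the Poisson process within sampling error", {
  expect_equal(nrow(samplePauseSchedule(0, c(20, 80), 10, seed = 1)), 0)
  s1 <- samplePauseSchedule(2, c(20, 80), 10, seed = 7)
  expect_identical(s1, samplePauseSchedule(2, c(20, 80), 10, seed = 7))
  expect_true(all(s1[, 2] > s1[, 1]))
  expect_true(all(s1 >= 0 & s1 <= 10))
  if (nrow(s1) > 1) expect_true(all(s1[-1, 1] > s1[-nrow(s1), 2]))
  # Monte-Carlo mean over 200 seeded replicates vs the Poisson expectation
  # of 20; de-overlapping drops ~10% of onsets (expected collision rate
  # rate * mean duration = 0.1), so allow that bias plus sampling error
  counts <- vapply(1:200, function(s)
    nrow(samplePauseSchedule(2, c(20, 80), 10, seed = s)), numeric(1))
  expect_gt(mean(counts), 20 * 0.85)
  expect_lt(mean(counts), 20 * 1.05)
  expect_error(samplePauseSchedule(10, c(900, 1100), 10, seed = 1),
               "infeasible")
})

test_that("scenes too large for the frame are rejected", {
  expect_error(SceneParam(frameWidth = 200, frameHeight = 150,
                          bodyCenter = c(100, 75)),
               "larger than frame")
  expect_error(SceneParam(durationS = 1,
                          pauseIntervals = cbind(c(0, 10), c(20, 30))),
               "non-overlapping")
  expect_error(SceneParam(durationS = 1, pauseIntervals = cbind(0, 600)),
               "start <= end < nFrames")
})

test_that("rendered frames have the configured geometry and ground truth", {
  p <- SceneParam(frameWidth = 160, frameHeight = 120, durationS = 0.04,
                  baseHalfWidth = 12, baseHalfHeight = 8, wingAmplitude = 40,
                  heightAmplitude = 12, jitterSd = 0.5, seed = 4)
  sc <- renderFrames(p)
  fr <- sceneFrames(sc)
  expect_s4_class(fr, "FrameSequence")
  expect_equal(dim(fr@frames), c(120, 160, 20))
  expect_true(all(fr@frames >= 0 & fr@frames <= 1))
  # ground-truth box contains the (jitter-centred) body-centre pixel
  b <- detections(sceneTrack(sc))
  expect_true(all(b$x_min < 80 & 80 < b$x_max))
  expect_true(all(b$y_min < 60 & 60 < b$y_max))
  expect_true(all(b$x_min >= 0 & b$x_max <= 160 &
                  b$y_min >= 0 & b$y_max <= 120))
  # same seed -> identical pixels
  sc2 <- renderFrames(p)
  expect_identical(fr@frames, sceneFrames(sc2)@frames)
})

test_that("simulator leaves the caller's RNG stream untouched", {
  set.seed(1); before <- .Random.seed
  invisible(generateBoxSequence(SceneParam(durationS = 0.1, seed = 99)))
  expect_identical(.Random.seed, before)
})
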