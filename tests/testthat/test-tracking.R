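detRow <- function(frame, box, score = 1) {
  data.frame(frame = frame, x_min = box[1], y_min = box[2], x_max = box[3],
             y_max = box[4], score = score, label = "hummingbird")
}

test_that("overlapping detections across frames form a single track", {
  dets <- do.call(rbind, lapply(0:19, function(f)
    detRow(f, c(100 + f, 100, 150 + f, 160))))
  tracks <- trackDetections(dets, frameRate = 500)
  expect_length(tracks, 1)
  expect_equal(frameIndex(tracks[[1]]), 0:19)
  expect_equal(trackId(tracks[[1]]), 1L)
})

test_that("two well-separated moving birds keep their identities", {
  sc1 <- generateBoxSequence(SceneParam(durationS = 0.4, seed = 1,
                                        bodyCenter = c(250, 300)))
  sc2 <- generateBoxSequence(SceneParam(durationS = 0.4, seed = 2,
                                        bodyCenter = c(550, 300)))
  d1 <- detections(sceneTrack(sc1)); d2 <- detections(sceneTrack(sc2))
  dets <- rbind(d1, d2)
  dets <- dets[order(dets$frame), ]
  tracks <- trackDetections(dets, frameRate = 500)
  expect_length(tracks, 2)
  # each recovered track reproduces one simulated bird exactly: no swaps
  centres <- vapply(tracks, function(tr) mean(trackBoxes(tr)[, 1]), numeric(1))
  left <- tracks[[which.min(centres)]]; right <- tracks[[which.max(centres)]]
  expect_equal(trackBoxes(left), trackBoxes(sceneTrack(sc1)))
  expect_equal(trackBoxes(right), trackBoxes(sceneTrack(sc2)))
})

test_that("a gap longer than maxMissedFrames closes the track", {
  box <- c(100, 100, 150, 160)
  dets <- rbind(detRow(0, box), detRow(1, box),
                detRow(10, box), detRow(11, box))
  tracks <- trackDetections(dets, frameRate = 500,
                            param = TrackerParam(maxMissedFrames = 5))
  expect_length(tracks, 2)
  expect_equal(frameIndex(tracks[[1]]), 0:1)
  expect_equal(frameIndex(tracks[[2]]), 10:11)
  expect_equal(vapply(tracks, trackId, integer(1)), 1:2)
  # within the tolerance the track survives the gap
  tracks2 <- trackDetections(dets, frameRate = 500,
                             param = TrackerParam(maxMissedFrames = 9))
  expect_length(tracks2, 1)
  expect_equal(frameIndex(tracks2[[1]]), c(0L, 1L, 10L, 11L))
})

test_that("association rejects pairs below minIoU and keeps frames increasing", {
  dets <- rbind(detRow(0, c(0, 0, 10, 10)), detRow(1, c(100, 100, 110, 110)))
  tracks <- trackDetections(dets, frameRate = 500)
  expect_length(tracks, 2)  # disjoint boxes never associate
  for (tr in tracks) expect_true(all(diff(frameIndex(tr)) > 0))

  state <- hoverpause:::newTrackerState(TrackerParam())
  state <- associateDetections(state, detRow(5, c(0, 0, 10, 10)))
  expect_error(associateDetections(state, detRow(5, c(0, 0, 10, 10))),
               "out-of-order")
  expect_error(associateDetections(state, detRow(4, c(0, 0, 10, 10))),
               "out-of-order")
})

test_that("each detection is assigned to exactly one track", {
  set.seed(77)
  frames <- rep(0:29, each = 2)
  wob <- function(base) base + cumsum(rnorm(30, 0, 2))
  x1 <- wob(100); x2 <- wob(300)
  dets <- do.call(rbind, lapply(seq_along(frames), function(i) {
    f <- frames[i]
    x <- if (i %% 2) x1[f + 1] else x2[f + 1]
    detRow(f, c(x, 100, x + 60, 180))
  }))
  tracks <- trackDetections(dets, frameRate = 500)
  total <- sum(vapply(tracks, length, integer(1)))
  expect_equal(total, nrow(dets))
})

test_that("appearance blending can rescue an ambiguous association", {
  p <- TrackerParam(useAppearance = TRUE, appearanceWeight = 0.5,
                    minIoU = 0.1)
  state <- hoverpause:::newTrackerState(p)
  d0 <- rbind(detRow(0, c(0, 0, 10, 10)), detRow(0, c(12, 0, 22, 10)))
  f0 <- rbind(c(1, 0), c(0, 1))
  state <- associateDetections(state, d0, features = f0)
  # by IoU alone track 1 would claim the box at x_min 4 (IoU 0.43 vs 0.25);
  # the appearance term overrides and assigns by feature identity
  d1 <- rbind(detRow(1, c(4, 0, 14, 10)), detRow(1, c(6, 0, 16, 10)))
  f1 <- rbind(c(0, 1), c(1, 0))
  state <- associateDetections(state, d1, features = f1)
  expect_length(state$active, 2)
  ids <- vapply(state$active, function(tr) tr$id, integer(1))
  lastx <- vapply(state$active, function(tr) tr$lastBox[1], numeric(1))
  expect_equal(lastx[ids == 1L], 6)
  expect_equal(lastx[ids == 2L], 4)
})

test_that("selectPrimaryTrack prefers coverage, then area, then id", {
  mk <- function(n, size, id) {
    d <- data.frame(frame = 0:(n - 1), x_min = 0, y_min = 0, x_max = size,
                    y_max = size)
    BirdTrack(d, frameRate = 500, trackId = id)
  }
  long <- mk(50, 10, 1); shortBig <- mk(10, 100, 2)
  expect_equal(trackId(selectPrimaryTrack(list(shortBig, long))), 1L)
  bigger <- mk(50, 30, 3)
  expect_equal(trackId(selectPrimaryTrack(list(long, bigger))), 3L)
  twin <- mk(50, 10, 9)
  expect_equal(trackId(selectPrimaryTrack(list(twin, long))), 1L)
  expect_equal(trackId(selectPrimaryTrack(list(long))), 1L)
  expect_error(selectPrimaryTrack(list()), "no subject")
})
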