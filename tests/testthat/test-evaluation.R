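ev <- function(starts, ends, fps = 500) PauseEvents(starts, ends, fps)

test_that("matchPauses covers containment, disjoint and ambiguous overlap", {
  cc <- matchPauses(ev(10, 20), ev(12, 18))
  expect_equal(c(tp(cc), fp(cc), fn(cc)), c(1L, 0L, 0L))
  cc2 <- matchPauses(ev(0, 5), ev(10, 15))
  expect_equal(c(tp(cc2), fp(cc2), fn(cc2)), c(0L, 1L, 1L))
  # two predictions both touching one annotation: one-to-one matching
  # (within-list overlap in the predictions is tolerated)
  p <- data.frame(start_frame = c(0L, 4L), end_frame = c(5L, 8L))
  cc3 <- matchPauses(p, ev(4, 6))
  expect_equal(c(tp(cc3), fp(cc3), fn(cc3)), c(1L, 1L, 0L))
  # empty lists
  cc4 <- matchPauses(ev(integer(), integer()), ev(0, 5))
  expect_equal(c(tp(cc4), fp(cc4), fn(cc4)), c(0L, 0L, 1L))
})

test_that("minimum-overlap criteria gate the matching", {
  # 2-frame overlap: enough at the default, not at minOverlapFrames = 3
  expect_equal(tp(matchPauses(ev(0, 11), ev(10, 20))), 1L)
  expect_equal(tp(matchPauses(ev(0, 11), ev(10, 20), minOverlapFrames = 3)), 0L)
  # fractional criterion: overlap must cover half the annotation
  expect_equal(tp(matchPauses(ev(0, 11), ev(10, 20),
                              minOverlapFraction = 0.5)), 0L)
  expect_equal(tp(matchPauses(ev(0, 16), ev(10, 20),
                              minOverlapFraction = 0.5)), 1L)
})

test_that("counts are conserved for arbitrary event lists", {
  set.seed(101)
  for (i in 1:100) {
    p <- randomEventList(); g <- randomEventList()
    cc <- matchPauses(PauseEvents(p$start_frame, p$end_frame, 500),
                      PauseEvents(g$start_frame, g$end_frame, 500))
    expect_identical(tp(cc) + fp(cc), nrow(p))
    expect_identical(tp(cc) + fn(cc), nrow(g))
  }
})

test_that("optimal matching agrees with the exhaustive oracle; greedy can lag", {
  set.seed(202)
  disagreements <- 0L
  for (i in 1:300) {
    p <- randomEventList(); g <- randomEventList()
    want <- bruteMatchTP(p, g)
    got <- tp(matchPauses(PauseEvents(p$start_frame, p$end_frame, 500),
                          PauseEvents(g$start_frame, g$end_frame, 500)))
    expect_identical(got, want)
    greedy <- tp(matchPauses(PauseEvents(p$start_frame, p$end_frame, 500),
                             PauseEvents(g$start_frame, g$end_frame, 500),
                             method = "greedy"))
    expect_lte(greedy, want)
    if (greedy < want) disagreements <- disagreements + 1L
  }
  # the hand-built case where greedy provably under-counts
  pred <- ev(c(0, 21), c(20, 30))
  truth <- ev(c(0, 12), c(4, 25))
  expect_equal(tp(matchPauses(pred, truth)), 2L)
  expect_equal(tp(matchPauses(pred, truth, method = "greedy")), 1L)
})

test_that("precision, recall and F1 reproduce the published worked example", {
  cc <- ConfusionCounts(tp = 55, fp = 19, fn = 19)
  expect_equal(precision(cc), 55 / 74)
  expect_equal(recall(cc), 55 / 74)
  expect_equal(f1Score(cc), 55 / 74)
  expect_equal(round(100 * precision(cc)), 74)
  expect_equal(round(f1Score(cc), 2), 0.74)
})

test_that("metrics handle boundary counts and warn on empty denominators", {
  expect_equal(precision(ConfusionCounts(0, 5, 0)), 0)
  expect_equal(precision(ConfusionCounts(10, 0, 3)), 1)
  expect_equal(recall(ConfusionCounts(0, 0, 3)), 0)
  expect_equal(recall(ConfusionCounts(7, 2, 0)), 1)
  expect_warning(p0 <- precision(ConfusionCounts(0, 0, 4)), "zero denominator")
  expect_equal(p0, 0)
  # F1 identities
  cc <- ConfusionCounts(19, 19, 0)
  expect_equal(f1Score(cc), 2 / 3)  # P = 0.5, R = 1
  ccEq <- ConfusionCounts(8, 2, 2)
  expect_equal(f1Score(ccEq), precision(ccEq))  # P == R -> F1 == P
  expect_equal(f1Score(ConfusionCounts(0, 3, 3)), 0)
})

test_that("metric values are bounded by min and max of precision and recall", {
  set.seed(303)
  for (i in 1:100) {
    cc <- ConfusionCounts(sample(0:20, 1), sample(0:20, 1), sample(0:20, 1))
    p <- suppressWarnings(precision(cc))
    r <- suppressWarnings(recall(cc))
    f <- suppressWarnings(f1Score(cc))
    expect_true(all(c(p, r, f) >= 0 & c(p, r, f) <= 1))
    expect_lte(f, max(p, r) + 1e-12)
    expect_gte(f, min(p, r) - 1e-12)
  }
})

test_that("wingbeat-frequency estimation finds the dominant spectral peak", {
  fs <- 500
  for (f in c(35, 40, 45)) {
    t <- (0:(fs - 1)) / fs
    js <- new("JaccardSeries", frame = 0:(fs - 1),
              values = 0.5 + 0.1 * sin(2 * pi * f * t), frameRate = fs)
    est <- estimateWingbeatFrequency(js)
    expect_lte(abs(est - f), fs / length(t))  # within one spectral bin
    expect_gte(est, 35); expect_lte(est, 45)
  }
  const <- new("JaccardSeries", frame = 0:99, values = rep(0.7, 100),
               frameRate = fs)
  expect_error(estimateWingbeatFrequency(const), "no spectral peak")
})

test_that("masking pause intervals removes their spectral distortion", {
  fs <- 500; t <- (0:999) / fs
  v <- 0.5 + 0.1 * sin(2 * pi * 40 * t)
  v[301:500] <- 0.98  # a long plateau
  js <- new("JaccardSeries", frame = 0:999, values = v, frameRate = fs)
  masked <- estimateWingbeatFrequency(
    js, excludeEvents = PauseEvents(300, 499, fs))
  expect_lte(abs(masked - 40), fs / length(t))
})

test_that("pauseStats computes pause frequency and mean duration", {
  s <- pauseStats(ev(c(0, 100), c(4, 104)), nWingbeats = 4)
  expect_equal(s$pause_frequency, 0.5)
  expect_equal(s$mean_pause_duration_ms, 10)
  # the published extreme case: 27 pauses in 48 wingbeats
  manyStarts <- seq(0, by = 50, length.out = 27)
  s2 <- pauseStats(ev(manyStarts, manyStarts + 9), nWingbeats = 48)
  expect_equal(s2$pause_frequency, 27 / 48)
  expect_equal(round(s2$pause_frequency, 4), 0.5625)
  s0 <- pauseStats(ev(integer(), integer()), nWingbeats = 10)
  expect_equal(s0$pause_frequency, 0)
  expect_true(is.na(s0$mean_pause_duration_ms))
  expect_error(pauseStats(ev(0, 4), nWingbeats = 0), "nWingbeats")
})

test_that("frames per wingbeat matches the recording arithmetic", {
  expect_equal(round(framesPerWingbeat(500, 35)), 14)
  expect_equal(framesPerWingbeat(500, 40), 12.5)
})

test_that("evaluatePauses pools counts across videos", {
  pred <- list(a = ev(10, 20), b = ev(c(0, 50), c(5, 60)))
  truth <- list(a = ev(12, 22), b = ev(100, 110))
  out <- evaluatePauses(pred, truth)
  expect_equal(tp(out$pooled), 1L)
  expect_equal(fp(out$pooled), 2L)
  expect_equal(fn(out$pooled), 1L)
  expect_equal(nrow(out$perVideo), 2)
  expect_equal(out$perVideo$tp[out$perVideo$video_id == "a"], 1L)
})
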