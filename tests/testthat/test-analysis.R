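# downstream analysis: alignment, binning, normalisation, contrasts, accuracy

mk_series <- function(counts, fps = 30) {
  data.frame(timestamp_s = (seq_along(counts) - 1) / fps,
             active_count = counts)
}

test_that("alignment puts differing-length series on a common grid", {
  # live acquisition gives different lengths for the same 20 s duration
  set.seed(1)
  t1 <- sort(runif(598, 0, 20 - 1e-3))
  t2 <- sort(runif(602, 0, 20 - 1e-3))
  s1 <- data.frame(timestamp_s = t1, active_count = rpois(598, 5))
  s2 <- data.frame(timestamp_s = t2, active_count = rpois(602, 5))
  al <- alignSeries(list(s1, s2), 30, durationS = 20)
  expect_equal(nrow(al[[1]]), 600L)
  expect_equal(nrow(al[[2]]), 600L)
  expect_equal(al[[1]]$timestamp_s, (0:599) / 30)
  expect_false(anyNA(al[[1]]$active_count))
  # an already-uniform series is unchanged
  u <- mk_series(rep(c(3L, 5L), 30))
  expect_equal(alignSeries(list(u), 30)[[1]]$active_count, u$active_count)
})

test_that("small timestamp jitter does not move the aligned means", {
  # a smooth activity trace sampled on a clean grid vs with +/-10 ms jitter
  set.seed(2)
  tt <- (0:599) / 30
  counts <- round(5 + 3 * sin(tt / 3))
  clean <- data.frame(timestamp_s = tt, active_count = counts)
  jit <- data.frame(timestamp_s = sort(tt + runif(600, -0.01, 0.01)),
                    active_count = counts)
  al <- alignSeries(list(clean, jit), 30, durationS = 20)
  expect_true(all(abs(al[[1]]$active_count - al[[2]]$active_count) <= 1))
})

test_that("binning means over half-open bins", {
  # constant series: every bin is the constant
  b <- binSeries(mk_series(rep(7L, 900)), 10)
  expect_equal(nrow(b), 3L)
  expect_true(all(b$mean_count == 7))
  expect_true(all(b$n_frames == 300L))
  # hand-computed: 5 s of 0 then 5 s of 10 at 30 Hz, one 10-s bin
  b2 <- binSeries(mk_series(c(rep(0L, 150), rep(10L, 150))), 10)
  expect_equal(b2$mean_count, 5.0)
  # re-binning 1 s -> 10 s equals direct 10-s binning (equal frames per bin)
  x <- mk_series(rpois(900, 4))
  expect_equal(binSeries(binSeries(x, 1), 10)$mean_count,
               binSeries(x, 10)$mean_count)
  # binning conserves the global mean when bins tile the series evenly
  expect_equal(mean(binSeries(x, 10)$mean_count), mean(x$active_count))
  expect_error(binSeries(mk_series(integer(0)), 10), "empty")
})

test_that("startle normalisation subtracts the post-onset window mean", {
  x <- mk_series(rep(6L, 2700))  # 90 s
  n <- normalizeToStartle(x, onsetS = 30)
  expect_true(all(n$active_count == 0))  # constant in, zero out
  y <- mk_series(rpois(2700, 5))
  ny <- normalizeToStartle(y, onsetS = 30)
  win <- ny$timestamp_s >= 30 & ny$timestamp_s < 60
  expect_equal(mean(ny$active_count[win]), 0)  # zero mean by construction
  # equivariance: normalise(x + c) == normalise(x)
  yc <- y
  yc$active_count <- yc$active_count + 11
  expect_equal(normalizeToStartle(yc, 30)$active_count, ny$active_count)
  expect_error(normalizeToStartle(y, onsetS = 200), "outside")
})

test_that("window contrasts compare event and baseline means", {
  x <- mk_series(c(rep(4, 90 * 30), rep(6, 90 * 30)), fps = 30)
  # event 120-150 s (mean 6) vs baseline 40-70 s (mean 4)
  expect_equal(windowContrast(x, c(120, 150), c(40, 70), "absolute"), 2)
  expect_equal(windowContrast(x, c(120, 150), c(40, 70), "percent"), 50)
  expect_equal(windowContrast(x, c(40, 70), c(40, 70)), 0)
  # absolute contrast scales with the series
  x2 <- x
  x2$active_count <- 3 * x2$active_count
  expect_equal(windowContrast(x2, c(120, 150), c(40, 70)), 6)
  z <- mk_series(c(rep(0, 90 * 30), rep(6, 90 * 30)))
  expect_error(windowContrast(z, c(120, 150), c(40, 70), "percent"),
               "baseline")
})

test_that("replicate averaging gives per-bin mean and SEM", {
  b1 <- binSeries(mk_series(rep(4L, 600)), 10)
  b2 <- binSeries(mk_series(rep(6L, 600)), 10)
  avg <- averageReplicates(list(b1, b2))
  expect_true(all(avg$mean_count == 5))
  expect_true(all(avg$sem_count == 1))  # sd = sqrt(2), / sqrt(2)
  # identical replicates: SEM 0
  same <- averageReplicates(list(b1, b1, b1))
  expect_true(all(same$sem_count == 0))
  expect_warning(averageReplicates(list(b1)), "SEM undefined")
  expect_error(averageReplicates(list(b1, binSeries(mk_series(rep(1L, 300)),
                                                    10))),
               "grid")
})

test_that("SEM shrinks like 1/sqrt(n) across synthetic replicates", {
  set.seed(7)
  reps <- lapply(1:12, function(i) binSeries(mk_series(rpois(600, 5)), 10))
  sem12 <- mean(averageReplicates(reps)$sem_count)
  sem3 <- mean(sapply(1:30, function(i)
    mean(averageReplicates(sample(reps, 3))$sem_count)))
  expect_lt(abs(sem12 / sem3 - sqrt(3 / 12)), 0.25)
})

test_that("tidy long-format export keeps every replicate and bin", {
  reps <- list(a = binSeries(mk_series(rep(1L, 600)), 10),
               b = binSeries(mk_series(rep(2L, 600)), 10))
  td <- tidyReplicates(reps, group = "ctrl")
  expect_equal(nrow(td), 4L)
  expect_equal(names(td), c("group", "replicate", "bin_start_s", "value"))
  expect_equal(unique(td$group), "ctrl")
})

test_that("accuracy metrics: exact-match percent and normalised error", {
  expect_s4_class(evaluateAccuracy(rep(5L, 100), rep(5L, 100), 10),
                  "AccuracyReport")
  perfect <- evaluateAccuracy(rep(5L, 100), rep(5L, 100), 10)
  expect_equal(perfect@accuracyPct, 100)
  expect_equal(perfect@meanErrorPct, 0)
  # 150 frames, truth 10 everywhere, 3 frames predicted 9:
  # accuracy 147/150 = 98.0%, mean error (3 x 10%) / 150 = 0.2%
  pred <- rep(10L, 150); pred[c(5, 80, 149)] <- 9L
  r <- evaluateAccuracy(pred, rep(10L, 150), 10)
  expect_equal(r@accuracyPct, 98.0)
  expect_equal(r@meanErrorPct, 0.2)
  expect_error(evaluateAccuracy(1:5, 1:6, 10), "aligned")
  expect_error(evaluateAccuracy(1:5, 1:5, 0), "groupSize")
})

test_that("accuracy 100% and mean error 0% coincide", {
  set.seed(3)
  for (i in 1:20) {
    tru <- rpois(50, 6)
    pred <- tru
    if (i %% 2 == 0) pred[sample(50, 1)] <- pred[sample(50, 1)] + 1L
    r <- evaluateAccuracy(pred, tru, 10)
    expect_equal(r@accuracyPct == 100, r@meanErrorPct == 0)
  }
})

test_that("pooling weights accuracy by frames and SEMs the clip errors", {
  r1 <- evaluateAccuracy(c(1L, 1L, 1L, 2L), c(1L, 1L, 1L, 1L), 10)
  r2 <- evaluateAccuracy(rep(3L, 8), rep(3L, 8), 10)
  p <- poolAccuracy(list(r1, r2))
  expect_equal(p@nFrames, 12L)
  expect_equal(p@accuracyPct, 100 * 11 / 12)
  expect_equal(p@meanErrorPct, mean(c(2.5, 0)))
  expect_equal(p@semErrorPct, sd(c(2.5, 0)) / sqrt(2))
})

test_that("the full optogenetic chain runs in the documented order", {
  # 1-s bins -> subtract startle mean -> 10-s bins
  set.seed(9)
  x <- mk_series(rpois(200 * 30, 5))
  out <- normalizeAndBin(x, onsetS = 120)
  fine <- normalizeToStartle(binSeries(x, 1), 120)
  expect_equal(out$mean_count, binSeries(fine, 10)$mean_count)
})
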