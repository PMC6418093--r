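# detection pipeline: segmentation, consolidation, counting

fast_params <- function(...) detectionParams(warmupFrames = 5L, ...)

test_that("a constant scene yields an empty mask once the model has seen it", {
  for (p in list(detectionParams(), detectionParams(knnThreshold = 100,
                                                    nSamples = 2L))) {
    model <- backgroundModel(60, 40, p)
    fr <- grayFrame()
    masks <- lapply(1:120, function(i) segmentForeground(fr, model))
    expect_true(all(!vapply(masks[-1], any, TRUE)))
  }
})

test_that("a translating blob is segmented and counted; a stopped one fades", {
  h <- 120; w <- 160; r <- 4
  mkframe <- function(cx) {
    f <- matrix(220L, h, w)
    f[discMask(h, w, cx, 60, r)] <- 40L
    f
  }
  centres <- c(seq(20, by = 3, length.out = 34), rep(20 + 3 * 33, 26))
  p <- fast_params()
  model <- backgroundModel(w, h, p)
  rs <- roiSet(circularROI("a", 80, 60, 55), w, h)
  counts <- integer(0); cover <- numeric(0)
  for (i in seq_along(centres)) {
    fr <- mkframe(centres[i])
    mask <- segmentForeground(fr, model)
    if (i > p@warmupFrames && i <= 34) {
      # moving phase: the newly-entered pixels of the blob are in the mask
      new_px <- discMask(h, w, centres[i], 60, r) &
        !discMask(h, w, centres[i - 1], 60, r)
      cover <- c(cover, sum(mask & new_px) / sum(new_px))
      cm <- consolidateMask(mask, p)
      counts <- c(counts, countComponents(cm, rs, p)$counts[["a"]])
    }
    if (i > 45) {
      # stopped: the blob leaves the foreground within historyFrames
      expect_lt(sum(mask), 3)
    }
  }
  expect_true(all(cover >= 0.8))
  expect_true(all(counts == 1L))
})

test_that("consolidation merges fragments and opening erases speckle", {
  p <- detectionParams(closeKernel = 3L, blurKernel = 1L)
  empty <- matrix(FALSE, 40, 60)
  expect_identical(consolidateMask(empty, p), empty)
  # two fragments of one fly, 2 px apart (< closeKernel): one component after
  frag <- empty
  frag[18:22, 20:23] <- TRUE
  frag[18:22, 26:29] <- TRUE
  expect_equal(nComponents(frag), 2L)
  expect_equal(nComponents(consolidateMask(frag, p)), 1L)
  # an isolated 1-px speckle is erased by a 3-px opening
  spk <- empty
  spk[10, 10] <- TRUE
  spk[25:29, 40:44] <- TRUE
  out <- consolidateMask(spk, detectionParams(blurKernel = 1L,
                                              closeKernel = 1L,
                                              openKernel = 3L))
  expect_false(out[10, 10])
  expect_true(any(out[25:29, 40:44]))
  # the default consolidation + min-area path also drops the speckle
  cc <- countComponents(consolidateMask(spk, detectionParams(closeKernel = 1L)),
                        roiSet(circularROI("a", 30, 20, 18), 60, 40),
                        detectionParams())
  expect_equal(unname(cc$counts), 1L)
})

test_that("components are counted per ROI with area bounds", {
  h <- 120; w <- 160
  rs <- roiSet(circularROI("arena1", 60, 60, 55), w, h)
  mask <- discMask(h, w, 40, 40, 4) | discMask(h, w, 80, 60, 4) |
    discMask(h, w, 50, 90, 4) | discMask(h, w, 140, 60, 4)  # last outside
  res <- countComponents(mask, rs, detectionParams())
  expect_equal(unname(res$counts), 3L)
  expect_equal(sum(is.na(res$components$roi)), 1L)
  # empty mask: zero everywhere
  expect_equal(unname(countComponents(matrix(FALSE, h, w), rs,
                                      detectionParams())$counts), 0L)
  # area caps: a big blob is excluded by maxArea, small ones by minArea
  res2 <- countComponents(mask, rs, detectionParams(maxArea = 10))
  expect_equal(unname(res2$counts), 0L)
  res3 <- countComponents(mask, rs, detectionParams(minArea = 200))
  expect_equal(unname(res3$counts), 0L)
})

test_that("two blobs closer than the closing kernel merge into one detection", {
  h <- 60; w <- 80
  mask <- discMask(h, w, 30, 30, 4) | discMask(h, w, 40, 30, 4)  # ~2 px gap
  p <- detectionParams(closeKernel = 3L)
  expect_equal(nComponents(consolidateMask(mask, p)), 1L)
})

test_that("detectStream is deterministic and flags warm-up", {
  cfg <- smallConfig(seed = 41, durationS = 3)
  sim <- simulateArena(cfg)
  stream <- renderFrames(sim)
  rs <- roiSet(cfg@arena, cfg@width, cfg@height)
  p <- detectionParams(warmupFrames = 20L)
  rec1 <- detectStream(stream, rs, p)
  rec2 <- detectStream(stream, rs, p)
  expect_identical(rec1, rec2)
  expect_equal(nrow(rec1), nFrames(stream))
  expect_true(all(is.na(rec1$arena1[rec1$warmup])))
  expect_true(all(!is.na(rec1$arena1[!rec1$warmup])))
  expect_true(all(rec1$arena1[!rec1$warmup] >= 0))
})

test_that("static-scene videos yield zero counts after warm-up", {
  cfg <- smallConfig(seed = 44, pStop = 1, pGo = 0, durationS = 3)
  stream <- renderFrames(simulateArena(cfg))
  rec <- detectStream(stream, roiSet(cfg@arena, cfg@width, cfg@height),
                      detectionParams(warmupFrames = 30L))
  expect_true(all(rec$arena1[!rec$warmup] == 0))
})

test_that("well-separated moving flies are counted at ground truth", {
  # straight ballistic walkers, never revisiting old ground
  w <- 320L; h <- 240L
  cfg <- arenaSimConfig(nFlies = 3L, width = w, height = h,
                        arena = circularROI("a", 160, 120, 110),
                        noiseSd = 0, seed = 1, durationS = 1.5)
  pos <- straightWalkers(45, ys = c(70, 120, 170), x0 = 65, speed = 4)
  sim <- scriptedSim(cfg, pos)
  stream <- renderFrames(sim)
  rec <- detectStream(stream, roiSet(cfg@arena, w, h),
                      detectionParams(warmupFrames = 5L))
  post <- !rec$warmup
  expect_true(mean(rec$a[post] == 3L) >= 0.95)
  # monotone occlusion: removing a fly never increases the count
  sim2 <- scriptedSim(cfg, pos[, 1:2, , drop = FALSE])
  rec2 <- detectStream(renderFrames(sim2), roiSet(cfg@arena, w, h),
                       detectionParams(warmupFrames = 5L))
  expect_true(all(rec2$a[post] <= rec$a[post]))
})

test_that("1-fly and 30-fly videos process without error", {
  for (n in c(1L, 30L)) {
    cfg <- smallConfig(seed = 50 + n, nFlies = n, durationS = 1)
    rec <- detectStream(renderFrames(simulateArena(cfg)),
                        roiSet(cfg@arena, cfg@width, cfg@height),
                        detectionParams(warmupFrames = 10L))
    expect_equal(nrow(rec), 30L)
    expect_true(all(rec$arena1[!rec$warmup] >= 0))
  }
})
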