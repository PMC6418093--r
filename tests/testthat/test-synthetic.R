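# the arena simulator: walkers, rendering, fixtures

test_that("degenerate transition probabilities freeze or saturate movement", {
  frozen <- simulateArena(smallConfig(seed = 1, pStop = 1, pGo = 0,
                                      durationS = 2))
  expect_true(all(!frozen@moving))
  expect_true(all(groundTruth(frozen)$moving_count == 0))
  # always-go with a tight, fast gait: every fly is in the move state and,
  # away from wall reflections (which can fold a step back onto itself),
  # displaces above the motion threshold every frame
  busy_cfg <- arenaSimConfig(seed = 2, pStop = 0, pGo = 1, speedSd = 0.2,
                             durationS = 2)  # full-size arena, no rendering
  busy <- simulateArena(busy_cfg)
  expect_true(all(busy@walkState[-1, ]))
  rad <- sqrt((busy@positions[, , 1] - busy_cfg@arena@x)^2 +
                (busy@positions[, , 2] - busy_cfg@arena@y)^2)
  near_wall <- apply(rad > busy_cfg@arena@radius - busy_cfg@flyRadius -
                       2 * busy_cfg@speedMean, 1, any)
  gt <- groundTruth(busy)
  interior <- gt$frame > 1 & !near_wall[gt$frame] &
    !near_wall[pmax(gt$frame - 1, 1)]
  expect_gt(sum(interior), 20)
  expect_true(all(gt$moving_count[interior] == busy_cfg@nFlies))
})

test_that("the move/pause chain reaches its stationary occupancy", {
  # two-state Markov chain: long-run moving fraction = pGo / (pGo + pStop)
  cfg <- smallConfig(seed = 5, nFlies = 2L, pStop = 0.15, pGo = 0.45,
                     durationS = 100)
  sim <- simulateArena(cfg)
  frac <- mean(sim@walkState[-1, ])
  expect_lt(abs(frac - 0.75), 0.04)
})

test_that("trajectories stay inside the arena and are seed-reproducible", {
  cfg <- smallConfig(seed = 9, durationS = 4)
  sim <- simulateArena(cfg)
  r <- sqrt((sim@positions[, , 1] - cfg@arena@x)^2 +
              (sim@positions[, , 2] - cfg@arena@y)^2)
  expect_true(all(r <= cfg@arena@radius - cfg@flyRadius + 1e-9))
  sim2 <- simulateArena(smallConfig(seed = 9, durationS = 4))
  expect_identical(sim@positions, sim2@positions)
  expect_identical(sim@moving, sim2@moving)
  # and bit-identical frames, in any access order
  s1 <- renderFrames(sim); s2 <- renderFrames(sim2)
  expect_identical(getFrame(s1, 40), getFrame(s2, 40))
  expect_identical(getFrame(s1, 7), getFrame(s2, 7))
  expect_identical(getFrame(s1, 40), getFrame(s1, 40))
})

test_that("rendering draws one dark disc per fly with the right area", {
  cfg <- smallConfig(seed = 12, nFlies = 4L, noiseSd = 0, durationS = 0.5)
  sim <- simulateArena(cfg)
  fr <- getFrame(renderFrames(sim), 8)
  dark <- fr < (cfg@backgroundLevel + cfg@flyLevel) / 2
  expect_equal(nComponents(dark), 4L)
  # a lone disc's pixel area approximates pi r^2 within 15%
  one <- smallConfig(seed = 13, nFlies = 1L, noiseSd = 0, durationS = 0.2)
  fr1 <- getFrame(renderFrames(simulateArena(one)), 3)
  area <- sum(fr1 < (one@backgroundLevel + one@flyLevel) / 2)
  expect_lt(abs(area - pi * one@flyRadius^2) / (pi * one@flyRadius^2), 0.15)
})

test_that("seed is mandatory and infeasible configs are rejected", {
  expect_error(arenaSimConfig(), "seed")
  expect_error(smallConfig(seed = 1, flyRadius = 60), "fit")
  expect_error(smallConfig(seed = 1, pStop = 1.4), "pStop")
})

test_that("activity profiles modulate the moving fraction over epochs", {
  # sedation-style profile: normal activity, then a late collapse of going
  prof <- activityProfile(c(0, 10, 12, 30), pGoMult = c(1, 1, 0.05, 0.05),
                          pStopMult = c(1, 1, 4, 4))
  cfg <- smallConfig(seed = 21, nFlies = 8L, durationS = 30)
  sim <- simulateArena(cfg, prof)
  gt <- groundTruth(sim)
  early <- mean(gt$moving_count[gt$frame <= 10 * cfg@fps])
  late <- mean(gt$moving_count[gt$frame > 15 * cfg@fps])
  expect_gt(early, late + 1)  # ordering follows the profile
  # probabilities stay clamped even under extreme multipliers
  prof2 <- activityProfile(c(0, 1), pGoMult = c(50, 50))
  expect_s4_class(simulateArena(smallConfig(seed = 3, durationS = 1), prof2),
                  "ArenaSimulation")
})

test_that("fixtures round-trip: video, truth and config", {
  cfg <- smallConfig(seed = 31, durationS = 2)
  dir <- file.path(tempdir(), "fix1")
  paths <- makeFixture(cfg, dir = dir)
  stream <- openVideo(paths$video)
  expect_equal(nFrames(stream), 60L)  # 2 s x 30 fps
  truth <- readGroundTruth(paths$truth)
  expect_equal(nrow(truth), 60L)
  # ground truth recomputed from the stored config matches the shipped CSV
  js <- jsonlite::fromJSON(paths$config)
  cfg2 <- arenaSimConfig(nFlies = js$n_flies, width = js$frame[1],
                         height = js$frame[2],
                         arena = circularROI(js$arena$label,
                                             js$arena$center[1],
                                             js$arena$center[2],
                                             js$arena$radius),
                         flyRadius = js$fly_radius_px,
                         speedMean = js$speed_px_per_frame[["mean"]],
                         speedSd = js$speed_px_per_frame[["sd"]],
                         pStop = js$p_stop, pGo = js$p_go, turnSd = js$turn_sd,
                         backgroundLevel = js$background_level,
                         flyLevel = js$fly_level, noiseSd = js$gaussian_noise_sd,
                         fps = js$fps, durationS = js$duration_s,
                         seed = js$seed,
                         motionThreshold = js$motion_threshold_px)
  truth2 <- groundTruth(simulateArena(cfg2))
  expect_equal(truth$moving_count, truth2$moving_count)
  # and the written video frames equal the rendered ones bit for bit
  fr <- getFrame(renderFrames(simulateArena(cfg2)), 17)
  expect_identical(getFrame(stream, 17), fr)
})
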