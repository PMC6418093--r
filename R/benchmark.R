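# Counting-fidelity benchmark: the package's validation protocol. Mirrors the
# original validation (randomly sampled 5-s / 150-frame clips from 15 arena
# videos scored against ground truth), scaled onto the simulator.

#' Run the synthetic counting-fidelity benchmark
#'
#' Generates an ensemble of ground-truthed arena videos (by default 15 videos
#' of 10 flies, 640x480 at 30 fps, 30 s each, seeds 1-15, moderate activity,
#' low noise), samples one random post-warm-up clip per video, runs the
#' detection pipeline with the given parameters, and scores the per-frame
#' counts against the simulator's ground truth.
#'
#' Videos are rendered lazily, so the benchmark never materialises an
#' ensemble of full-length videos in memory or on disk.
#'
#' @param seeds one simulator seed per video (default 1-15).
#' @param nFlies,durationS,fps,width,height,flyRadius,noiseSd,pGo,pStop
#'   simulator settings passed to [arenaSimConfig()].
#' @param clipS clip length in seconds (5 s = 150 frames at 30 fps).
#' @param params [DetectionParams-class] under test.
#' @param clipSeed RNG seed for the random clip placement.
#' @param verbose print one line per video.
#' @return list with `pooled` (an [AccuracyReport-class]), `perClip`
#'   (data.frame of per-clip metrics) and `reports` (per-clip
#'   [AccuracyReport-class] list).
#' @export
countingBenchmark <- function(seeds = 1:15, nFlies = 10L, durationS = 30,
                              fps = 30, width = 640L, height = 480L,
                              flyRadius = 4, noiseSd = 3, pGo = 0.3,
                              pStop = 0.1, clipS = 5,
                              params = detectionParams(), clipSeed = 1L,
                              verbose = FALSE) {
  clip_len <- as.integer(round(clipS * fps))
  nframes <- as.integer(round(durationS * fps))
  if (nframes < params@warmupFrames + clip_len)
    stop("videos too short for a post-warm-up clip")
  set.seed(clipSeed)
  starts <- sample.int(nframes - params@warmupFrames - clip_len + 1,
                       length(seeds), replace = TRUE) + params@warmupFrames
  reports <- vector("list", length(seeds))
  per_clip <- vector("list", length(seeds))
  for (k in seq_along(seeds)) {
    cfg <- arenaSimConfig(nFlies = nFlies, width = width, height = height,
                          flyRadius = flyRadius, noiseSd = noiseSd,
                          pGo = pGo, pStop = pStop, fps = fps,
                          durationS = durationS, seed = seeds[k])
    sim <- simulateArena(cfg)
    stream <- renderFrames(sim)
    roiset <- roiSet(cfg@arena, width, height)
    rec <- detectStream(stream, roiset, params)
    truth <- groundTruth(sim)
    frames <- seq.int(starts[k], starts[k] + clip_len - 1)
    pred <- rec[[cfg@arena@label]][frames]
    tru <- truth$moving_count[match(frames, truth$frame)]
    reports[[k]] <- evaluateAccuracy(pred, tru, nFlies)
    per_clip[[k]] <- data.frame(
      video = k, seed = seeds[k], clip_start_frame = starts[k],
      n_frames = clip_len, accuracy_pct = reports[[k]]@accuracyPct,
      mean_error_pct = reports[[k]]@meanErrorPct)
    if (verbose) {
      message(sprintf(
        "video %2d (seed %d): clip %d-%d, accuracy %.1f%%, error %.2f%%",
        k, seeds[k], starts[k], max(frames), reports[[k]]@accuracyPct,
        reports[[k]]@meanErrorPct))
    }
  }
  list(pooled = poolAccuracy(reports),
       perClip = do.call(rbind, per_clip),
       reports = reports)
}
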