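# synthetic module: ground-truthed arena videos. Flies are two-state
# (move/pause) Markov walkers with persistent headings, reflected at the arena
# wall, rendered as anti-aliased dark discs on a bright diffuse background
# (emulating IR under-lighting) with additive Gaussian noise. The ground-truth
# moving count replaces a human annotator.

#' Simulator configuration
#'
#' Defaults describe the reference condition of the package's validation
#' benchmark: 10 flies in a single 640x480 arena filling the field of view,
#' 30 fps, dark 4 px-radius flies on a bright diffuse background with mild
#' sensor noise, moderate activity (`pGo`/(`pGo`+`pStop`) = 75% of flies
#' moving at stationarity) and a steady walking gait of ~3 px/frame.
#'
#' @param nFlies number of flies in the arena (1-30 supported).
#' @param width,height frame geometry in pixels.
#' @param arena a [CircularROI-class]; default: a radius-230 px arena centred
#'   in the frame.
#' @param flyRadius rendered fly radius in px.
#' @param speedMean,speedSd per-frame step length of a moving fly, px
#'   (negative draws are clamped to 0).
#' @param pStop per-frame probability that a moving fly pauses.
#' @param pGo per-frame probability that a paused fly resumes.
#' @param turnSd heading change sd per frame, radians (heading persistence).
#' @param backgroundLevel,flyLevel 8-bit intensities.
#' @param noiseSd additive Gaussian noise sd, intensity units.
#' @param fps frames per second.
#' @param durationS duration in seconds.
#' @param seed mandatory seed; together with the config it fully determines
#'   trajectories, frames and ground truth.
#' @param motionThreshold displacement (px/frame) at or above which a fly is
#'   "moving" in the ground truth. 1 px aligns the annotation with what a
#'   background-subtraction detector can possibly see.
#' @return an [ArenaSimConfig-class].
#' @export
arenaSimConfig <- function(nFlies = 10L, width = 640L, height = 480L,
                           arena = NULL, flyRadius = 4, speedMean = 3,
                           speedSd = 0.5, pStop = 0.1, pGo = 0.3,
                           turnSd = 0.3, backgroundLevel = 220, flyLevel = 40,
                           noiseSd = 3, fps = 30, durationS = 30, seed,
                           motionThreshold = 1.0) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(arena)) {
    arena <- circularROI("arena1", width / 2, height / 2,
                         min(width, height) / 2 - 10)
  }
  new("ArenaSimConfig",
      nFlies = as.integer(nFlies), width = as.integer(width),
      height = as.integer(height), arena = arena,
      flyRadius = as.numeric(flyRadius), speedMean = as.numeric(speedMean),
      speedSd = as.numeric(speedSd), pStop = as.numeric(pStop),
      pGo = as.numeric(pGo), turnSd = as.numeric(turnSd),
      backgroundLevel = as.numeric(backgroundLevel),
      flyLevel = as.numeric(flyLevel), noiseSd = as.numeric(noiseSd),
      fps = as.numeric(fps), durationS = as.numeric(durationS),
      seed = as.integer(seed), motionThreshold = as.numeric(motionThreshold))
}

#' @rdname arenaSimConfig
#' @param x an [ArenaSimConfig-class].
#' @export
setMethod("fps", "ArenaSimConfig", function(x) x@fps)

setMethod("show", "ArenaSimConfig", function(object) {
  cat(sprintf(
    "ArenaSimConfig: %d flies, %dx%d px, %g fps x %g s, seed %d\n",
    object@nFlies, object@width, object@height, object@fps, object@durationS,
    object@seed))
})

#' Piecewise-linear activity modulation
#'
#' Multipliers on the simulator's stop probability, go probability and step
#' length, linearly interpolated between breakpoints and held constant beyond
#' the ends. Modulated probabilities are clamped to `[0, 1]`. Use it to
#' inject startle spikes, slow activity ramps, or sedation decay.
#'
#' @param timeS breakpoint times in seconds, strictly increasing.
#' @param pStopMult,pGoMult,speedMult multipliers at each breakpoint
#'   (recycled to the length of `timeS`).
#' @return an [ActivityProfile-class].
#' @examples
#' # a startle at stimulus onset: brief surge in going, then decay to baseline
#' activityProfile(c(0, 120, 125, 150), pGoMult = c(1, 1, 3, 1))
#' @export
activityProfile <- function(timeS, pStopMult = 1, pGoMult = 1, speedMult = 1) {
  n <- length(timeS)
  new("ActivityProfile", timeS = as.numeric(timeS),
      pStopMult = rep_len(as.numeric(pStopMult), n),
      pGoMult = rep_len(as.numeric(pGoMult), n),
      speedMult = rep_len(as.numeric(speedMult), n))
}

setMethod("show", "ActivityProfile", function(object) {
  cat(sprintf("ActivityProfile: %d breakpoint(s) over [%g, %g] s\n",
              length(object@timeS), object@timeS[1],
              object@timeS[length(object@timeS)]))
})

# interpolate the profile at time t (scalar)
profileAt <- function(profile, t) {
  if (is.null(profile)) return(c(pStop = 1, pGo = 1, speed = 1))
  f <- function(v) stats::approx(profile@timeS, v, xout = t, rule = 2)$y
  c(pStop = f(profile@pStopMult), pGo = f(profile@pGoMult),
    speed = f(profile@speedMult))
}

#' Simulate fly trajectories in an arena
#'
#' Each fly is a two-state (move/pause) Markov walker. Moving flies step with
#' a persistent-heading random walk and are reflected at the arena wall;
#' paused flies keep their position exactly. A fly is "moving" in the ground
#' truth of frame i when its displacement from frame i-1 is at least the
#' motion threshold.
#'
#' @param config an [ArenaSimConfig-class].
#' @param profile optional [ActivityProfile-class].
#' @return an [ArenaSimulation-class].
#' @export
simulateArena <- function(config, profile = NULL) {
  stopifnot(is(config, "ArenaSimConfig"))
  set.seed(config@seed)
  n <- max(1L, as.integer(round(config@durationS * config@fps)))
  nf <- config@nFlies
  rmax <- config@arena@radius - config@flyRadius
  if (rmax <= 0) stop("fly does not fit in the arena")
  pos <- array(NA_real_, dim = c(n, nf, 2))
  moving <- matrix(FALSE, n, nf)
  state <- matrix(FALSE, n, nf)  # TRUE = move state
  # start positions uniform in the admissible disc, headings uniform
  rr <- rmax * sqrt(runif(nf))
  th <- runif(nf, 0, 2 * pi)
  x <- config@arena@x + rr * cos(th)
  y <- config@arena@y + rr * sin(th)
  heading <- runif(nf, 0, 2 * pi)
  m0 <- profileAt(profile, 0)
  ps0 <- min(1, max(0, config@pStop * m0[["pStop"]]))
  pg0 <- min(1, max(0, config@pGo * m0[["pGo"]]))
  pmove <- if (ps0 + pg0 > 0) pg0 / (ps0 + pg0) else 1
  st <- runif(nf) < pmove  # stationary-distribution start
  pos[1, , 1] <- x; pos[1, , 2] <- y
  state[1, ] <- st
  for (i in 2:max(2, n)) {
    if (i > n) break
    mult <- profileAt(profile, (i - 1) / config@fps)
    ps <- min(1, max(0, config@pStop * mult[["pStop"]]))
    pg <- min(1, max(0, config@pGo * mult[["pGo"]]))
    u <- runif(nf)
    st <- ifelse(st, u >= ps, u < pg)
    step <- pmax(0, rnorm(nf, config@speedMean * mult[["speed"]],
                          config@speedSd))
    heading <- heading + ifelse(st, rnorm(nf, 0, config@turnSd), 0)
    dx <- ifelse(st, step * cos(heading), 0)
    dy <- ifelse(st, step * sin(heading), 0)
    nx <- x + dx
    ny <- y + dy
    # reflective boundary: fold the radial overshoot back inside and mirror
    # the heading across the wall tangent
    rad <- sqrt((nx - config@arena@x)^2 + (ny - config@arena@y)^2)
    out <- which(rad > rmax)
    for (j in out) {
      phi <- atan2(ny[j] - config@arena@y, nx[j] - config@arena@x)
      rnew <- 2 * rmax - rad[j]
      if (rnew < 0) rnew <- rmax * stats::runif(1)  # pathological huge step
      nx[j] <- config@arena@x + rnew * cos(phi)
      ny[j] <- config@arena@y + rnew * sin(phi)
      heading[j] <- 2 * (phi + pi / 2) - heading[j]
    }
    disp <- sqrt((nx - x)^2 + (ny - y)^2)
    moving[i, ] <- disp >= config@motionThreshold
    x <- nx; y <- ny
    pos[i, , 1] <- x; pos[i, , 2] <- y
    state[i, ] <- st
  }
  new("ArenaSimulation", config = config, positions = pos, moving = moving,
      walkState = state)
}

setMethod("show", "ArenaSimulation", function(object) {
  cat(sprintf(
    "ArenaSimulation: %d flies x %d frames; mean moving fraction %.3f\n",
    object@config@nFlies, nrow(object@moving), mean(object@moving)))
})

#' @rdname groundTruth
#' @export
setMethod("groundTruth", "ArenaSimulation", function(x, roiset = NULL) {
  cfg <- x@config
  if (is.null(roiset)) roiset <- roiSet(cfg@arena, cfg@width, cfg@height)
  n <- nrow(x@moving)
  labs <- roiLabels(roiset)
  out <- vector("list", length(labs))
  for (k in seq_along(roiset@rois)) {
    r <- roiset@rois[[k]]
    inside <- (x@positions[, , 1, drop = FALSE] - r@x)^2 +
      (x@positions[, , 2, drop = FALSE] - r@y)^2 <= r@radius^2
    dim(inside) <- dim(x@moving)
    out[[k]] <- data.frame(
      frame = seq_len(n), roi_label = labs[k],
      moving_count = as.integer(rowSums(x@moving & inside)))
  }
  res <- do.call(rbind, out)
  res[order(res$frame, match(res$roi_label, labs)), , drop = FALSE]
})

#' Render a simulation as a frame stream
#'
#' Bright uniform background, anti-aliased dark discs at the fly positions,
#' additive Gaussian noise, clipped to 8 bits. Rendering is lazy and
#' deterministic per frame (the noise stream is seeded from the config seed
#' and the frame index), so the same config yields bit-identical frames in
#' any access order.
#'
#' @param sim an [ArenaSimulation-class].
#' @return a [FrameStream-class].
#' @export
renderFrames <- function(sim) {
  stopifnot(is(sim, "ArenaSimulation"))
  cfg <- sim@config
  n <- nrow(sim@moving)
  pos <- sim@positions
  provider <- function(i) {
    .cppRenderFrame(cfg@width, cfg@height, pos[i, , 1], pos[i, , 2],
                    cfg@flyRadius, cfg@backgroundLevel, cfg@flyLevel,
                    cfg@noiseSd, as.numeric(cfg@seed), as.integer(i))
  }
  newFrameStream(provider, n, cfg@fps, cfg@width, cfg@height)
}

#' Write a complete test fixture
#'
#' The universal fixture triplet: lossless video, ground-truth CSV
#' (`frame, roi_label, moving_count`) and the generating config as JSON.
#'
#' @param config an [ArenaSimConfig-class].
#' @param profile optional [ActivityProfile-class].
#' @param dir output directory.
#' @return list of paths (`video`, `truth`, `config`), invisibly.
#' @export
makeFixture <- function(config, profile = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulateArena(config, profile)
  stream <- renderFrames(sim)
  video <- file.path(dir, "video")
  writeVideo(stream, video)
  truth <- file.path(dir, "truth.csv")
  utils::write.csv(groundTruth(sim), truth, row.names = FALSE, quote = FALSE)
  cfg_path <- file.path(dir, "config.json")
  jsonlite::write_json(
    list(n_flies = config@nFlies, frame = c(config@width, config@height),
         arena = list(label = config@arena@label,
                      center = c(config@arena@x, config@arena@y),
                      radius = config@arena@radius),
         fly_radius_px = config@flyRadius,
         speed_px_per_frame = list(mean = config@speedMean,
                                   sd = config@speedSd),
         p_stop = config@pStop, p_go = config@pGo, turn_sd = config@turnSd,
         background_level = config@backgroundLevel, fly_level = config@flyLevel,
         gaussian_noise_sd = config@noiseSd, fps = config@fps,
         duration_s = config@durationS, seed = config@seed,
         motion_threshold_px = config@motionThreshold),
    cfg_path, auto_unbox = TRUE, digits = NA)
  invisible(list(video = video, truth = truth, config = cfg_path))
}

#' Read a fixture's ground-truth CSV
#'
#' @param path `truth.csv` written by [makeFixture()].
#' @return data.frame with columns `frame`, `roi_label`, `moving_count`.
#' @export
readGroundTruth <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "roi_label", "moving_count")
  if (!all(need %in% names(d))) stop("not a ground-truth CSV")
  d[, need]
}
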