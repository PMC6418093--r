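# Central S4 containers. Validity lives here; constructors and methods in the
# per-module files.

#' FrameStream: an ordered stream of 8-bit grayscale frames
#'
#' Frames are H x W integer matrices (0-255), origin top-left, with a fixed
#' nominal frame rate. Frames may be held in memory or produced lazily by a
#' provider function, so long recordings never need to be fully resident.
#' Timestamps are seconds from session start; when synthesised from the frame
#' rate, `timestamp[i] = (i - 1) / fps` exactly.
#'
#' @slot nframes number of frames.
#' @slot fps nominal frames per second (> 0).
#' @slot width,height frame geometry in pixels.
#' @slot timestamps numeric vector, one per frame, strictly increasing.
#' @slot provider function(i) returning frame `i` as an integer matrix.
#' @exportClass FrameStream
setClass("FrameStream",
  slots = c(
    nframes = "integer", fps = "numeric", width = "integer",
    height = "integer", timestamps = "numeric", provider = "function"
  )
)

setValidity("FrameStream", function(object) {
  if (length(object@fps) != 1 || is.na(object@fps) || object@fps <= 0)
    return("fps must be a single positive number")
  if (object@nframes < 0) return("nframes must be >= 0")
  if (length(object@timestamps) != object@nframes)
    return("one timestamp per frame required")
  if (object@nframes > 1 && any(diff(object@timestamps) <= 0))
    return("timestamps must be strictly increasing")
  if (object@width <= 0 || object@height <= 0)
    return("frame geometry must be positive")
  TRUE
})

#' VideoMeta: metadata of a written frame-sequence video
#'
#' @slot path container path.
#' @slot codec codec tag ("pgm" for the lossless frame-sequence container).
#' @slot frameCount number of frames (>= 0).
#' @slot fps frames per second (> 0).
#' @slot width,height resolution in pixels.
#' @exportClass VideoMeta
setClass("VideoMeta",
  slots = c(
    path = "character", codec = "character", frameCount = "integer",
    fps = "numeric", width = "integer", height = "integer"
  )
)

setValidity("VideoMeta", function(object) {
  if (object@frameCount < 0) return("frameCount must be >= 0")
  if (object@fps <= 0) return("fps must be > 0")
  TRUE
})

#' CircularROI: one circular arena region of interest
#'
#' Coordinates are continuous frame coordinates: the frame spans `[0, width]`
#' by `[0, height]` with the origin at the top-left corner, x rightwards and
#' y downwards; the pixel in row i, column j (1-based) has centre
#' `(j - 0.5, i - 0.5)`.
#'
#' @slot label unique ROI name.
#' @slot x,y centre in pixels.
#' @slot radius radius in pixels (> 0).
#' @exportClass CircularROI
setClass("CircularROI",
  slots = c(label = "character", x = "numeric", y = "numeric", radius = "numeric")
)

setValidity("CircularROI", function(object) {
  if (length(object@label) != 1 || !nzchar(object@label))
    return("label must be a non-empty string")
  if (!is.finite(object@radius) || object@radius <= 0)
    return("radius must be > 0")
  TRUE
})

#' ROISet: named, non-overlapping circular ROIs within a frame
#'
#' @slot rois list of [CircularROI-class].
#' @slot width,height frame geometry the ROIs live in.
#' @exportClass ROISet
setClass("ROISet",
  slots = c(rois = "list", width = "integer", height = "integer")
)

setValidity("ROISet", function(object) {
  if (length(object@rois) < 1) return("at least one ROI required")
  if (!all(vapply(object@rois, is, TRUE, "CircularROI")))
    return("all elements must be CircularROI objects")
  labs <- vapply(object@rois, function(r) r@label, "")
  if (anyDuplicated(labs)) return("ROI labels must be unique")
  for (r in object@rois) {
    if (r@x - r@radius < 0 || r@x + r@radius > object@width ||
        r@y - r@radius < 0 || r@y + r@radius > object@height)
      return(sprintf("ROI '%s' extends outside the %dx%d frame",
                     r@label, object@width, object@height))
  }
  n <- length(object@rois)
  if (n > 1) {
    for (a in seq_len(n - 1)) {
      for (b in seq.int(a + 1, n)) {
        ra <- object@rois[[a]]; rb <- object@rois[[b]]
        d <- sqrt((ra@x - rb@x)^2 + (ra@y - rb@y)^2)
        if (d < ra@radius + rb@radius)
          return(sprintf("ROIs '%s' and '%s' overlap", ra@label, rb@label))
      }
    }
  }
  TRUE
})

#' DetectionParams: tuning parameters of the motion-counting pipeline
#'
#' See [detectionParams()] for the meaning, units and defaults of each
#' parameter.
#'
#' @slot historyFrames background-model memory span, frames.
#' @slot knnThreshold squared-intensity distance threshold.
#' @slot knnK neighbour count k.
#' @slot nSamples long-age sample slots of the background model.
#' @slot blurKernel odd Gaussian kernel size, px.
#' @slot closeKernel,openKernel structuring element sizes, px.
#' @slot minArea,maxArea component area bounds, px.
#' @slot warmupFrames frames excluded from counting while the model converges.
#' @exportClass DetectionParams
setClass("DetectionParams",
  slots = c(
    historyFrames = "integer", knnThreshold = "numeric", knnK = "integer",
    nSamples = "integer", blurKernel = "integer", closeKernel = "integer",
    openKernel = "integer", minArea = "numeric", maxArea = "numeric",
    warmupFrames = "integer"
  )
)

setValidity("DetectionParams", function(object) {
  if (object@historyFrames < 1) return("historyFrames must be >= 1")
  if (object@knnThreshold <= 0) return("knnThreshold must be > 0")
  if (object@knnK < 1) return("knnK must be >= 1")
  if (object@nSamples < 1) return("nSamples must be >= 1")
  if (object@blurKernel < 1 || object@blurKernel %% 2 == 0)
    return("blurKernel must be odd and >= 1")
  if (object@closeKernel < 1 || object@openKernel < 1)
    return("kernel sizes must be >= 1")
  if (object@minArea < 0) return("minArea must be >= 0")
  if (object@maxArea <= 0) return("maxArea must be > 0")
  if (object@warmupFrames < 1) return("warmupFrames must be >= 1")
  TRUE
})

#' BackgroundModel: per-pixel sample state of the KNN segmenter
#'
#' Wraps the external-pointer state updated frame by frame. Stateful: applying
#' it to a frame both classifies the frame and inserts it into the model.
#'
#' @slot ptr external pointer to the sample buffers.
#' @slot width,height frame geometry.
#' @slot params the [DetectionParams-class] the model was created with.
#' @exportClass BackgroundModel
setClass("BackgroundModel",
  slots = c(ptr = "externalptr", width = "integer", height = "integer",
            params = "DetectionParams")
)

#' PulseTrain: periodic stimulus on-windows
#'
#' Pulse i (i = 0, 1, ...) is on during
#' `[startS + i/frequencyHz, startS + i/frequencyHz + pulseWidthMs/1000)`.
#' A width equal to the period gives continuous output (duty cycle 1).
#'
#' @slot frequencyHz pulse frequency, Hz (> 0).
#' @slot pulseWidthMs pulse width, ms (> 0, at most one period).
#' @slot startS train start, seconds.
#' @slot durationS train duration, seconds (> 0).
#' @exportClass PulseTrain
setClass("PulseTrain",
  slots = c(frequencyHz = "numeric", pulseWidthMs = "numeric",
            startS = "numeric", durationS = "numeric")
)

setValidity("PulseTrain", function(object) {
  if (object@frequencyHz <= 0) return("frequencyHz must be > 0")
  if (object@pulseWidthMs <= 0) return("pulseWidthMs must be > 0")
  if (object@pulseWidthMs > 1000 / object@frequencyHz + 1e-9)
    return("pulseWidthMs may not exceed the pulse period (1000/frequencyHz ms)")
  if (object@durationS <= 0) return("durationS must be > 0")
  TRUE
})

#' Epoch: one labelled experiment phase, optionally carrying a stimulus
#'
#' @slot label epoch name (e.g. "baseline", "stimulus", "recovery").
#' @slot startS,endS half-open interval `[startS, endS)`, seconds.
#' @slot pulse a [PulseTrain-class] or `NULL` (stored as a length-0/1 list).
#' @slot continuous `TRUE` for a continuous stimulus (e.g. ethanol vapour on).
#' @exportClass Epoch
setClass("Epoch",
  slots = c(label = "character", startS = "numeric", endS = "numeric",
            pulse = "list", continuous = "logical")
)

setValidity("Epoch", function(object) {
  if (object@endS <= object@startS) return("endS must be > startS")
  if (length(object@pulse) > 1) return("at most one pulse train per epoch")
  if (length(object@pulse) == 1 && !is(object@pulse[[1]], "PulseTrain"))
    return("pulse must contain a PulseTrain")
  if (length(object@pulse) == 1 && object@continuous)
    return("an epoch is either pulsed or continuous, not both")
  TRUE
})

#' StimulusProgram: ordered, non-overlapping epochs of an experiment
#'
#' @slot epochs list of [Epoch-class], ordered in time.
#' @slot totalS total program duration, seconds.
#' @exportClass StimulusProgram
setClass("StimulusProgram",
  slots = c(epochs = "list", totalS = "numeric")
)

setValidity("StimulusProgram", function(object) {
  if (object@totalS <= 0) return("totalS must be > 0")
  if (!all(vapply(object@epochs, is, TRUE, "Epoch")))
    return("epochs must be Epoch objects")
  if (length(object@epochs)) {
    st <- vapply(object@epochs, function(e) e@startS, 0)
    en <- vapply(object@epochs, function(e) e@endS, 0)
    if (is.unsorted(st, strictly = TRUE)) return("epochs must be ordered")
    if (any(st[-1] < en[-length(en)] - 1e-9)) return("epochs must not overlap")
    if (any(st < -1e-9) || any(en > object@totalS + 1e-9))
      return("epochs must lie within [0, totalS]")
  }
  TRUE
})

#' ArenaSimConfig: the stated world of the arena-video simulator
#'
#' See [arenaSimConfig()] for the meaning and defaults of each field.
#'
#' @slot nFlies number of flies (1-30 typical).
#' @slot width,height frame geometry, px.
#' @slot arena the [CircularROI-class] arena.
#' @slot flyRadius rendered fly disc radius, px.
#' @slot speedMean,speedSd step length distribution of a moving fly, px/frame.
#' @slot pStop,pGo per-frame move->pause and pause->move probabilities.
#' @slot turnSd heading persistence (turn-angle sd, radians/frame).
#' @slot backgroundLevel,flyLevel 8-bit intensities of background and fly.
#' @slot noiseSd additive Gaussian image noise sd, intensity units.
#' @slot fps frames per second.
#' @slot durationS simulated duration, seconds.
#' @slot seed mandatory RNG seed.
#' @slot motionThreshold displacement (px/frame) above which a fly counts as
#'   moving in the ground truth.
#' @exportClass ArenaSimConfig
setClass("ArenaSimConfig",
  slots = c(
    nFlies = "integer", width = "integer", height = "integer",
    arena = "CircularROI", flyRadius = "numeric", speedMean = "numeric",
    speedSd = "numeric", pStop = "numeric", pGo = "numeric", turnSd = "numeric",
    backgroundLevel = "numeric", flyLevel = "numeric", noiseSd = "numeric",
    fps = "numeric", durationS = "numeric", seed = "integer",
    motionThreshold = "numeric"
  )
)

setValidity("ArenaSimConfig", function(object) {
  if (object@nFlies < 1) return("nFlies must be >= 1")
  if (object@pStop < 0 || object@pStop > 1 || object@pGo < 0 || object@pGo > 1)
    return("pStop and pGo must lie in [0, 1]")
  if (object@flyRadius <= 0) return("flyRadius must be > 0")
  if (object@flyRadius >= object@arena@radius)
    return("fly does not fit in the arena")
  if (object@arena@x - object@arena@radius < 0 ||
      object@arena@x + object@arena@radius > object@width ||
      object@arena@y - object@arena@radius < 0 ||
      object@arena@y + object@arena@radius > object@height)
    return("arena extends outside the frame")
  if (length(object@seed) != 1 || is.na(object@seed))
    return("seed is mandatory")
  if (object@fps <= 0 || object@durationS <= 0)
    return("fps and durationS must be > 0")
  if (object@speedMean < 0 || object@speedSd < 0)
    return("speed distribution parameters must be >= 0")
  if (object@motionThreshold < 0) return("motionThreshold must be >= 0")
  TRUE
})

#' ActivityProfile: time-varying modulation of simulated activity
#'
#' Piecewise-linear multipliers on the stop probability, go probability and
#' step length, interpolated over time and clamped so probabilities stay in
#' `[0, 1]`. Used to emulate startle spikes, activity ramps or sedation decay.
#'
#' @slot timeS breakpoint times, seconds, strictly increasing.
#' @slot pStopMult,pGoMult,speedMult multiplier at each breakpoint (>= 0).
#' @exportClass ActivityProfile
setClass("ActivityProfile",
  slots = c(timeS = "numeric", pStopMult = "numeric", pGoMult = "numeric",
            speedMult = "numeric")
)

setValidity("ActivityProfile", function(object) {
  n <- length(object@timeS)
  if (n < 1) return("at least one breakpoint required")
  if (is.unsorted(object@timeS, strictly = TRUE))
    return("timeS must be strictly increasing")
  if (length(object@pStopMult) != n || length(object@pGoMult) != n ||
      length(object@speedMult) != n)
    return("one multiplier per breakpoint required")
  if (any(c(object@pStopMult, object@pGoMult, object@speedMult) < 0))
    return("multipliers must be >= 0")
  TRUE
})

#' ArenaSimulation: trajectories and ground truth of one simulated video
#'
#' @slot config the [ArenaSimConfig-class] that generated it.
#' @slot positions array `[frame, fly, c(x, y)]` of fly centres.
#' @slot moving logical matrix `[frame, fly]`: displacement since the previous
#'   frame at or above the motion threshold (frame 1 is `FALSE`).
#' @slot walkState logical matrix `[frame, fly]`: internal move/pause state.
#' @exportClass ArenaSimulation
setClass("ArenaSimulation",
  slots = c(config = "ArenaSimConfig", positions = "array",
            moving = "matrix", walkState = "matrix")
)

#' ActivitySeries: the per-ROI activity record of a session
#'
#' One row per analysed frame with columns `timestamp_s`, `active_count`
#' (NA during warm-up), `stimulus_on` (0/1) and `warmup` (0/1).
#'
#' @slot roi ROI label.
#' @slot data the record data.frame.
#' @exportClass ActivitySeries
setClass("ActivitySeries",
  slots = c(roi = "character", data = "data.frame")
)

setValidity("ActivitySeries", function(object) {
  d <- object@data
  need <- c("timestamp_s", "active_count", "stimulus_on", "warmup")
  if (!all(need %in% names(d)))
    return(paste("data must have columns", paste(need, collapse = ", ")))
  if (nrow(d) > 1 && any(diff(d$timestamp_s) < 0))
    return("timestamps must be non-decreasing")
  cnt <- d$active_count[!is.na(d$active_count)]
  if (length(cnt) && (any(cnt < 0) || any(cnt != round(cnt))))
    return("active_count must be non-negative integers")
  TRUE
})

#' SessionConfig: everything needed to run one experiment session
#'
#' @slot roiset the arena [ROISet-class].
#' @slot params [DetectionParams-class] for the counter.
#' @slot program a [StimulusProgram-class] or `NULL` (length-0/1 list).
#' @slot outDir output directory.
#' @slot saveRawVideo copy every input frame to a raw video sink.
#' @slot sessionName prefix of the per-ROI CSV files.
#' @exportClass SessionConfig
setClass("SessionConfig",
  slots = c(roiset = "ROISet", params = "DetectionParams", program = "list",
            outDir = "character", saveRawVideo = "logical",
            sessionName = "character")
)

setValidity("SessionConfig", function(object) {
  if (length(object@program) > 1 ||
      (length(object@program) == 1 && !is(object@program[[1]], "StimulusProgram")))
    return("program must be empty or contain one StimulusProgram")
  if (!nzchar(object@sessionName)) return("sessionName must be non-empty")
  TRUE
})

#' AccuracyReport: counting fidelity versus ground truth
#'
#' Two deliberately distinct metrics: `accuracyPct` is the percentage of
#' frames whose predicted count matches the true count exactly, and
#' `meanErrorPct` is the mean per-frame absolute miscount normalised by group
#' size (in percent). They are not complements of each other.
#'
#' @slot accuracyPct exact-match frame percentage (0-100).
#' @slot meanErrorPct mean per-frame |pred - true| / group size x 100.
#' @slot semErrorPct standard error of the per-clip mean error (NA for a
#'   single clip).
#' @slot nFrames frames compared.
#' @exportClass AccuracyReport
setClass("AccuracyReport",
  slots = c(accuracyPct = "numeric", meanErrorPct = "numeric",
            semErrorPct = "numeric", nFrames = "integer")
)

setValidity("AccuracyReport", function(object) {
  if (object@accuracyPct < 0 || object@accuracyPct > 100)
    return("accuracyPct must lie in [0, 100]")
  if (object@meanErrorPct < 0) return("meanErrorPct must be >= 0")
  TRUE
})
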