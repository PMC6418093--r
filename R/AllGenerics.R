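# Generics shared across modules.

#' Number of frames in a stream
#' @param x a [FrameStream-class].
#' @return integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Nominal frame rate
#' @param x a [FrameStream-class] or [ArenaSimConfig-class].
#' @return frames per second.
#' @export
setGeneric("fps", function(x) standardGeneric("fps"))

#' Fetch one frame
#' @param x a [FrameStream-class].
#' @param i frame index (1-based).
#' @return H x W integer matrix with values in 0-255.
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))

#' Frame timestamps in seconds from session start
#' @param x a [FrameStream-class].
#' @return numeric vector, one entry per frame.
#' @export
setGeneric("frameTimestamps", function(x) standardGeneric("frameTimestamps"))

#' ROI labels of a set
#' @param x a [ROISet-class].
#' @return character vector of labels, in ROI order.
#' @export
setGeneric("roiLabels", function(x) standardGeneric("roiLabels"))

#' Stimulus state at given times
#'
#' `TRUE` exactly when `t` falls inside a stimulus epoch and inside a pulse
#' on-window (or the epoch is continuous). Pulse i of a train is on during
#' `[start + i/f, start + i/f + width)`.
#'
#' @param x a [StimulusProgram-class] or [PulseTrain-class].
#' @param t time(s) in seconds; must lie within the program.
#' @return logical vector, one entry per time.
#' @export
setGeneric("isOn", function(x, t) standardGeneric("isOn"))

#' Duty cycle of a pulse train
#'
#' `min(1, frequencyHz * pulseWidthMs / 1000)`: the fraction of time the
#' stimulus is on within its epoch. Modulating pulse width at fixed frequency
#' is the usual way to scale delivered LED intensity.
#'
#' @param x a [PulseTrain-class].
#' @return fraction in (0, 1].
#' @export
setGeneric("dutyCycle", function(x) standardGeneric("dutyCycle"))

#' Epoch label at given times
#'
#' Epochs are half-open `[start, end)`: a boundary time belongs to the later
#' epoch. Times at the very end of the program are assigned to the last epoch.
#'
#' @param x a [StimulusProgram-class].
#' @param t time(s) in seconds within `[0, totalS]`.
#' @return character vector of epoch labels (NA between epochs).
#' @export
setGeneric("epochOf", function(x, t) standardGeneric("epochOf"))

#' Ground truth of a simulation
#'
#' Per frame and ROI, the number of flies whose displacement since the
#' previous frame is at least the motion threshold. The simulator's stand-in
#' for a human annotator.
#'
#' @param x an [ArenaSimulation-class].
#' @param roiset optional [ROISet-class]; defaults to the simulated arena.
#' @return data.frame with columns `frame`, `roi_label`, `moving_count`.
#' @export
setGeneric("groundTruth", function(x, roiset = NULL) standardGeneric("groundTruth"))
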