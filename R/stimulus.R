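# stimulus module: pulse trains, epochs, and stamping stimulus state onto
# activity records. Hardware drivers are out of scope; the program is pure
# timing.

#' Create a pulse train
#'
#' @param frequencyHz pulse frequency in Hz.
#' @param pulseWidthMs pulse width in ms; may equal the period
#'   (`1000/frequencyHz`), giving continuous output (e.g. 40 Hz x 25 ms).
#' @param startS train start in seconds.
#' @param durationS train duration in seconds.
#' @return a [PulseTrain-class].
#' @examples
#' dutyCycle(pulseTrain(40, 25, 0, 300))  # 1.0: full-duty framing
#' @export
pulseTrain <- function(frequencyHz, pulseWidthMs, startS = 0, durationS) {
  new("PulseTrain", frequencyHz = as.numeric(frequencyHz),
      pulseWidthMs = as.numeric(pulseWidthMs), startS = as.numeric(startS),
      durationS = as.numeric(durationS))
}

#' Create an epoch
#'
#' @param label epoch name; conventionally "baseline", "stimulus" or
#'   "recovery".
#' @param startS,endS half-open interval `[startS, endS)` in seconds.
#' @param pulse optional [PulseTrain-class] delivered during the epoch; when
#'   given without explicit start/duration it is anchored to the epoch.
#' @param continuous `TRUE` for a continuous (non-pulsed) stimulus such as
#'   ethanol vapour.
#' @return an [Epoch-class].
#' @export
epoch <- function(label, startS, endS, pulse = NULL, continuous = FALSE) {
  new("Epoch", label = as.character(label), startS = as.numeric(startS),
      endS = as.numeric(endS), pulse = if (is.null(pulse)) list() else list(pulse),
      continuous = isTRUE(continuous))
}

#' Assemble a stimulus program
#'
#' @param epochs list of [Epoch-class], ordered and non-overlapping.
#' @param totalS total program duration in seconds; defaults to the end of the
#'   last epoch.
#' @return a [StimulusProgram-class].
#' @export
stimulusProgram <- function(epochs, totalS = NULL) {
  if (is(epochs, "Epoch")) epochs <- list(epochs)
  if (is.null(totalS)) totalS <- max(vapply(epochs, function(e) e@endS, 0))
  new("StimulusProgram", epochs = epochs, totalS = as.numeric(totalS))
}

#' Load a stimulus program from JSON
#'
#' Expected shape:
#' `{"total_s": 540, "epochs": [{"label": "baseline", "start_s": 0, "end_s": 120},
#'   {"label": "stimulus", "start_s": 120, "end_s": 420,
#'    "pulse": {"hz": 40, "width_ms": 25}}, ...]}`.
#' An epoch may carry `"continuous": true` instead of a pulse.
#'
#' @param config path to a JSON file, a JSON string, or an equivalent list.
#' @return a [StimulusProgram-class].
#' @export
loadStimulusProgram <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::fromJSON(config, simplifyDataFrame = FALSE)
  }
  eps <- lapply(config$epochs, function(e) {
    p <- NULL
    if (!is.null(e$pulse)) {
      p <- pulseTrain(e$pulse$hz, e$pulse$width_ms, startS = e$start_s,
                      durationS = e$end_s - e$start_s)
    }
    epoch(e$label, e$start_s, e$end_s, pulse = p,
          continuous = isTRUE(e$continuous))
  })
  stimulusProgram(eps, totalS = config$total_s)
}

#' The paper-style nine-minute optogenetic program
#'
#' Two minutes of baseline, five minutes of pulsed stimulation, two minutes of
#' recovery.
#'
#' @param frequencyHz,pulseWidthMs pulse settings (default the full-duty
#'   40 Hz x 25 ms).
#' @param baselineS,stimulusS,recoveryS phase durations in seconds.
#' @return a [StimulusProgram-class].
#' @export
optogeneticProgram <- function(frequencyHz = 40, pulseWidthMs = 25,
                               baselineS = 120, stimulusS = 300,
                               recoveryS = 120) {
  on <- baselineS + stimulusS
  stimulusProgram(list(
    epoch("baseline", 0, baselineS),
    epoch("stimulus", baselineS, on,
          pulse = pulseTrain(frequencyHz, pulseWidthMs, startS = baselineS,
                             durationS = stimulusS)),
    epoch("recovery", on, on + recoveryS)
  ))
}

#' The paper-style twenty-minute ethanol program
#'
#' Five minutes of baseline, ten minutes of continuous vapour exposure, five
#' minutes of recovery.
#'
#' @param baselineS,exposureS,recoveryS phase durations in seconds.
#' @return a [StimulusProgram-class].
#' @export
ethanolProgram <- function(baselineS = 300, exposureS = 600, recoveryS = 300) {
  off <- baselineS + exposureS
  stimulusProgram(list(
    epoch("baseline", 0, baselineS),
    epoch("stimulus", baselineS, off, continuous = TRUE),
    epoch("recovery", off, off + recoveryS)
  ))
}

#' @rdname dutyCycle
#' @export
setMethod("dutyCycle", "PulseTrain", function(x) {
  min(1, x@frequencyHz * x@pulseWidthMs / 1000)
})

#' @rdname isOn
#' @export
setMethod("isOn", "PulseTrain", function(x, t) {
  rel <- t - x@startS
  inside <- rel >= 0 & rel < x@durationS
  phase <- rel - floor(rel * x@frequencyHz) / x@frequencyHz
  inside & phase < x@pulseWidthMs / 1000 + 1e-12
})

#' @rdname isOn
#' @export
setMethod("isOn", "StimulusProgram", function(x, t) {
  if (any(t < 0 | t > x@totalS)) stop("t outside the stimulus program")
  out <- rep(FALSE, length(t))
  for (e in x@epochs) {
    inside <- t >= e@startS & t < e@endS
    if (!any(inside)) next
    if (e@continuous) {
      out[inside] <- TRUE
    } else if (length(e@pulse)) {
      out[inside] <- isOn(e@pulse[[1]], t[inside])
    }
  }
  out
})

#' @rdname epochOf
#' @export
setMethod("epochOf", "StimulusProgram", function(x, t) {
  if (any(t < 0 | t > x@totalS)) stop("t outside the stimulus program")
  out <- rep(NA_character_, length(t))
  for (e in x@epochs) out[t >= e@startS & t < e@endS] <- e@label
  # the program's final instant belongs to the last epoch ending there
  if (length(x@epochs)) {
    last <- x@epochs[[length(x@epochs)]]
    out[is.na(out) & abs(t - last@endS) < 1e-9] <- last@label
  }
  out
})

#' Stamp stimulus state onto frame timestamps
#'
#' @param timestamps numeric vector of times in seconds.
#' @param program a [StimulusProgram-class] or `NULL`.
#' @return integer 0/1 vector (all 0 when `program` is `NULL`); times beyond
#'   the program are off.
#' @export
stampStimulus <- function(timestamps, program = NULL) {
  if (is.null(program)) return(integer(length(timestamps)))
  inside <- timestamps >= 0 & timestamps <= program@totalS
  out <- integer(length(timestamps))
  out[inside] <- as.integer(isOn(program, timestamps[inside]))
  out
}

setMethod("show", "PulseTrain", function(object) {
  cat(sprintf("PulseTrain: %g Hz x %g ms (duty %.3g) from %g s for %g s\n",
              object@frequencyHz, object@pulseWidthMs, dutyCycle(object),
              object@startS, object@durationS))
})

setMethod("show", "Epoch", function(object) {
  kind <- if (object@continuous) "continuous"
          else if (length(object@pulse)) "pulsed" else "no stimulus"
  cat(sprintf("Epoch '%s': [%g, %g) s, %s\n", object@label, object@startS,
              object@endS, kind))
})

setMethod("show", "StimulusProgram", function(object) {
  cat(sprintf("StimulusProgram: %d epoch(s), %g s total\n",
              length(object@epochs), object@totalS))
  for (e in object@epochs) show(e)
})
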