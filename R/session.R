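# session module: orchestrate an experiment. Streams frames, runs detection,
# stamps stimulus state, and emits the three canonical outputs: per-ROI CSVs,
# an (optional) raw video copy, and plot-ready live data.

#' Session configuration
#'
#' @param roiset the arena [ROISet-class].
#' @param params [DetectionParams-class]; defaults as documented there.
#' @param program optional [StimulusProgram-class]; when given, every record
#'   carries a 0/1 stimulus flag sampled at its frame timestamp.
#' @param outDir output directory for CSVs and the raw video.
#' @param saveRawVideo also write a lossless copy of every input frame. The
#'   raw sink receives each frame before analysis and is independent of the
#'   detection parameters: recording is not analysis.
#' @param sessionName prefix for output files (`<sessionName>_<roi>.csv`).
#' @return a [SessionConfig-class].
#' @export
sessionConfig <- function(roiset, params = detectionParams(), program = NULL,
                          outDir = ".", saveRawVideo = FALSE,
                          sessionName = "session") {
  new("SessionConfig", roiset = roiset, params = params,
      program = if (is.null(program)) list() else list(program),
      outDir = outDir, saveRawVideo = isTRUE(saveRawVideo),
      sessionName = sessionName)
}

setMethod("show", "SessionConfig", function(object) {
  cat(sprintf("SessionConfig '%s': %d ROI(s), %s, raw video %s\n",
              object@sessionName, length(object@roiset@rois),
              if (length(object@program)) "with stimulus program"
              else "no stimulus program",
              if (object@saveRawVideo) "on" else "off"))
})

#' Run an experiment session
#'
#' Streams every frame through the raw-video sink (if enabled) and the
#' detection pipeline, stamps the stimulus state at each frame timestamp, and
#' writes one CSV per ROI. Warm-up rows are kept (count empty, `warmup` flag
#' set) so the row count always equals the frame count. Replaying a written
#' session reproduces its CSVs bit for bit.
#'
#' @param stream a [FrameStream-class].
#' @param config a [SessionConfig-class].
#' @return named list of [ActivitySeries-class], one per ROI, with the output
#'   file paths in attribute `"paths"`.
#' @export
runSession <- function(stream, config) {
  stopifnot(is(stream, "FrameStream"), is(config, "SessionConfig"))
  dir.create(config@outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(config@outDir)) stop("output directory is not writable")
  if (config@saveRawVideo) {
    # recording is decoupled from analysis: the sink gets the frames as they
    # come, whatever the detection parameters are
    writeVideo(stream, file.path(config@outDir,
                                 paste0(config@sessionName, "_raw")))
  }
  rec <- detectStream(stream, config@roiset, config@params)
  program <- if (length(config@program)) config@program[[1]]
  stim <- stampStimulus(rec$timestamp_s, program)
  labs <- roiLabels(config@roiset)
  series <- setNames(vector("list", length(labs)), labs)
  paths <- setNames(character(length(labs)), labs)
  for (l in labs) {
    d <- data.frame(timestamp_s = rec$timestamp_s, active_count = rec[[l]],
                    stimulus_on = stim, warmup = as.integer(rec$warmup))
    series[[l]] <- new("ActivitySeries", roi = l, data = d)
    paths[l] <- file.path(config@outDir,
                          paste0(config@sessionName, "_", l, ".csv"))
    writeActivityCSV(series[[l]], paths[l])
  }
  attr(series, "paths") <- paths
  series
}

#' Write an activity series as CSV
#'
#' UTF-8, header `timestamp_s,active_count,stimulus_on,warmup`, one row per
#' analysed frame; timestamps with millisecond precision; warm-up counts
#' written empty. Formatting is fixed so identical sessions produce identical
#' bytes.
#'
#' @param series an [ActivitySeries-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeActivityCSV <- function(series, path) {
  stopifnot(is(series, "ActivitySeries"))
  d <- series@data
  lines <- c(
    "timestamp_s,active_count,stimulus_on,warmup",
    sprintf("%.3f,%s,%d,%d", d$timestamp_s,
            ifelse(is.na(d$active_count), "", as.character(d$active_count)),
            d$stimulus_on, d$warmup))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read an activity CSV
#'
#' Tolerant of column reordering and of extra columns; the four canonical
#' columns are matched by name.
#'
#' @param path CSV written by [writeActivityCSV()] (or equivalent).
#' @param roi ROI label; defaults to the text between the last underscore and
#'   the extension of the file name.
#' @return an [ActivitySeries-class].
#' @export
readActivityCSV <- function(path, roi = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp_s", "active_count", "stimulus_on", "warmup")
  if (!all(need %in% names(d)))
    stop(paste("activity CSV must carry columns", paste(need, collapse = ", ")))
  if (is.null(roi)) {
    roi <- sub("\\.csv$", "", basename(path))
    roi <- sub("^.*_", "", roi)
  }
  new("ActivitySeries", roi = roi,
      data = d[, need])
}

setMethod("show", "ActivitySeries", function(object) {
  d <- object@data
  n_valid <- sum(!is.na(d$active_count))
  cat(sprintf("ActivitySeries '%s': %d frame(s) (%d analysed), %s\n",
              object@roi, nrow(d), n_valid,
              if (n_valid) sprintf("mean count %.2f",
                                   mean(d$active_count, na.rm = TRUE))
              else "no analysed frames"))
})

#' Rolling view of an activity series for live plotting
#'
#' Purely observational: returns the plot-ready rows of the trailing window
#' without touching the series.
#'
#' @param series an [ActivitySeries-class] (or a list of them).
#' @param windowS window length in seconds; `Inf` for the full series.
#' @return data.frame with columns `roi`, `timestamp_s`, `active_count`,
#'   `stimulus_on`.
#' @export
livePlotState <- function(series, windowS = Inf) {
  if (is(series, "ActivitySeries")) series <- list(series)
  out <- lapply(series, function(s) {
    d <- s@data
    if (nrow(d) == 0) {
      return(data.frame(roi = character(0), timestamp_s = numeric(0),
                        active_count = integer(0), stimulus_on = integer(0)))
    }
    lo <- max(d$timestamp_s) - windowS
    d <- d[d$timestamp_s >= lo, , drop = FALSE]
    data.frame(roi = s@roi, timestamp_s = d$timestamp_s,
               active_count = d$active_count, stimulus_on = d$stimulus_on)
  })
  do.call(rbind, out)
}

#' Plot activity traces
#'
#' Simple base-graphics view of one or more activity series, with stimulus
#' periods shaded. Headless-safe smoke utility; analysis figures should be
#' built from the tidy tables instead.
#'
#' @param series an [ActivitySeries-class] or list of them.
#' @param windowS trailing window in seconds (default: everything).
#' @return the plotted data.frame, invisibly.
#' @export
plotActivity <- function(series, windowS = Inf) {
  d <- livePlotState(series, windowS)
  if (nrow(d) == 0) {
    graphics::plot.new()
    return(invisible(d))
  }
  rois <- unique(d$roi)
  graphics::plot(NA, xlim = range(d$timestamp_s),
                 ylim = c(0, max(d$active_count, na.rm = TRUE) + 1),
                 xlab = "time (s)", ylab = "active flies")
  on_t <- d$timestamp_s[d$stimulus_on == 1]
  if (length(on_t)) {
    graphics::rect(min(on_t), graphics::par("usr")[3], max(on_t),
                   graphics::par("usr")[4], col = "#dddddd", border = NA)
  }
  for (k in seq_along(rois)) {
    dd <- d[d$roi == rois[k], ]
    graphics::lines(dd$timestamp_s, dd$active_count, col = k)
  }
  graphics::legend("topright", legend = rois, col = seq_along(rois), lty = 1,
                   bty = "n")
  invisible(d)
}
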