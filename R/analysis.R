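# analysis module: downstream quantification. Time-base alignment, binning,
# replicate averaging, startle normalisation, window contrasts, and the
# counting-accuracy metrics. Everything operates on plain data.frames (or
# ActivitySeries), and emits tidy tables; repeated-measures statistics are
# deliberately delegated to external packages.

# coerce an ActivitySeries / data.frame to (time, value) columns
.timeValue <- function(x) {
  if (is(x, "ActivitySeries")) x <- x@data
  stopifnot(is.data.frame(x))
  tcol <- intersect(c("timestamp_s", "bin_start_s", "time_s"), names(x))[1]
  vcol <- intersect(c("active_count", "mean_count", "value"), names(x))[1]
  if (is.na(tcol) || is.na(vcol))
    stop("need a time column (timestamp_s/bin_start_s) and a value column ",
         "(active_count/mean_count/value)")
  data.frame(t = x[[tcol]], v = x[[vcol]])
}

#' Resample activity series onto a common time grid
#'
#' Live acquisition stamps frames with real time, so series from the same
#' experiment can have differing lengths. Each series is resampled onto the
#' grid of half-open cells `[i/rate, (i+1)/rate)` by averaging the raw
#' samples falling in each cell; empty cells are filled by previous-value
#' carry (leading empties by the first observed value). The grid covers the
#' shared duration (shortest series).
#'
#' @param seriesList list of [ActivitySeries-class] or data.frames with
#'   `timestamp_s` and `active_count`.
#' @param targetRateHz grid rate in Hz.
#' @param durationS nominal shared duration in seconds (the grid covers
#'   `durationS * targetRateHz` cells); defaults to the span of the shortest
#'   series.
#' @return list of data.frames with columns `timestamp_s` (cell start),
#'   `active_count` (cell mean) and `n` (raw samples in the cell).
#' @export
alignSeries <- function(seriesList, targetRateHz, durationS = NULL) {
  stopifnot(targetRateHz > 0, length(seriesList) >= 1)
  tv <- lapply(seriesList, function(s) {
    d <- .timeValue(s)
    d <- d[!is.na(d$v), , drop = FALSE]
    if (nrow(d) == 0) stop("series has no valid samples")
    d
  })
  ncell <- if (is.null(durationS)) {
    last <- min(vapply(tv, function(d) max(d$t), 0))
    if (last < 0) stop("series do not overlap the grid")
    floor(last * targetRateHz + 1e-9) + 1
  } else {
    as.integer(round(durationS * targetRateHz))
  }
  lapply(tv, function(d) {
    cell <- floor(d$t * targetRateHz + 1e-9)
    keep <- cell >= 0 & cell < ncell
    if (!any(keep)) stop("series does not overlap the grid")
    agg <- tapply(d$v[keep], factor(cell[keep], levels = 0:(ncell - 1)), mean)
    n <- tapply(rep(1, sum(keep)), factor(cell[keep], levels = 0:(ncell - 1)),
                sum)
    v <- as.numeric(agg)
    n <- as.integer(ifelse(is.na(n), 0L, n))
    # previous-value carry; leading gaps take the first observed value
    filled <- v
    if (anyNA(filled)) {
      first <- which(!is.na(filled))[1]
      if (first > 1) filled[seq_len(first - 1)] <- filled[first]
      for (i in seq_along(filled)) {
        if (is.na(filled[i])) filled[i] <- filled[i - 1]
      }
    }
    data.frame(timestamp_s = (0:(ncell - 1)) / targetRateHz,
               active_count = filled, n = n)
  })
}

#' Average a series over fixed time bins
#'
#' Means over half-open bins `[k * binS, (k+1) * binS)`; the classic 10-s
#' binning of group activity traces. Warm-up (NA) samples are ignored.
#'
#' @param x an [ActivitySeries-class], raw records data.frame, or an already
#'   binned data.frame (re-binning to a coarser width).
#' @param binS bin width in seconds (> 0).
#' @return data.frame with `bin_start_s`, `bin_width_s`, `mean_count`,
#'   `n_frames`.
#' @export
binSeries <- function(x, binS) {
  stopifnot(binS > 0)
  d <- .timeValue(x)
  d <- d[!is.na(d$v), , drop = FALSE]
  if (nrow(d) == 0) stop("cannot bin an empty series")
  bin <- floor(d$t / binS + 1e-9)
  lev <- seq.int(min(bin), max(bin))
  m <- tapply(d$v, factor(bin, levels = lev), mean)
  n <- tapply(rep(1, nrow(d)), factor(bin, levels = lev), sum)
  data.frame(bin_start_s = lev * binS, bin_width_s = binS,
             mean_count = as.numeric(m),
             n_frames = as.integer(ifelse(is.na(n), 0L, n)))
}

#' Normalise a series to the startle window by subtraction
#'
#' Animals startle at stimulus onset (light or vapour); traces are therefore
#' expressed relative to the mean activity of the 30 s following onset, by
#' subtraction (not division). The mean of the normalised series over the
#' startle window is 0 by construction, and adding any constant to the input
#' leaves the output unchanged.
#'
#' @param x series (raw or binned; see [binSeries()]).
#' @param onsetS stimulus onset in seconds.
#' @param windowS startle window length in seconds (default 30).
#' @return `x` with its value column replaced by the normalised values.
#' @export
normalizeToStartle <- function(x, onsetS, windowS = 30) {
  d <- if (is(x, "ActivitySeries")) x@data else x
  tv <- .timeValue(x)
  in_win <- tv$t >= onsetS & tv$t < onsetS + windowS & !is.na(tv$v)
  if (!any(in_win)) stop("startle window lies outside the series")
  ref <- mean(tv$v[in_win])
  vcol <- intersect(c("active_count", "mean_count", "value"), names(d))[1]
  d[[vcol]] <- d[[vcol]] - ref
  if (is(x, "ActivitySeries")) {
    data.frame(timestamp_s = d$timestamp_s, value = d[[vcol]])
  } else {
    d
  }
}

#' Contrast two time windows of a series
#'
#' Group activity averaged over an event window compared with a baseline
#' window; e.g. light onset (120-150 s) against baseline (40-70 s), or light
#' offset (420-450 s) against subsequent baseline (500-530 s). Windows are
#' half-open.
#'
#' @param x series (raw or binned).
#' @param eventWindow,baselineWindow `c(start, end)` in seconds.
#' @param mode `"absolute"` (mean(event) - mean(baseline)) or `"percent"`
#'   (100 x difference / mean(baseline)).
#' @return a single number.
#' @export
windowContrast <- function(x, eventWindow, baselineWindow,
                           mode = c("absolute", "percent")) {
  mode <- match.arg(mode)
  tv <- .timeValue(x)
  tv <- tv[!is.na(tv$v), , drop = FALSE]
  win_mean <- function(w) {
    sel <- tv$t >= w[1] & tv$t < w[2]
    if (!any(sel)) stop("window [", w[1], ", ", w[2], ") outside the series")
    mean(tv$v[sel])
  }
  ev <- win_mean(eventWindow)
  bl <- win_mean(baselineWindow)
  if (mode == "absolute") return(ev - bl)
  if (abs(bl) < .Machine$double.eps^0.5)
    stop("percent contrast undefined: baseline mean is 0")
  100 * (ev - bl) / bl
}

#' The full optogenetic normalisation chain
#'
#' The standard trace-processing order for light-stimulation experiments:
#' average over 1-s bins, subtract the mean of the 30-s post-onset startle
#' window, then average over 10-s bins.
#'
#' @param x raw series.
#' @param onsetS stimulus onset in seconds.
#' @param windowS startle window in seconds.
#' @param preBinS,finalBinS the two bin widths in seconds.
#' @return binned data.frame (see [binSeries()]) of normalised activity.
#' @export
normalizeAndBin <- function(x, onsetS, windowS = 30, preBinS = 1,
                            finalBinS = 10) {
  fine <- binSeries(x, preBinS)
  norm <- normalizeToStartle(fine, onsetS, windowS)
  binSeries(norm, finalBinS)
}

#' Average binned series across biological replicates
#'
#' One biological replicate is one arena of flies. Series must share the bin
#' grid; the result carries the per-bin mean and standard error
#' (sd / sqrt(n), sd with the n-1 denominator).
#'
#' @param replicates list of binned data.frames (see [binSeries()]) on
#'   identical grids.
#' @return data.frame with `bin_start_s`, `mean_count`, `sem_count`, `n`.
#' @export
averageReplicates <- function(replicates) {
  stopifnot(length(replicates) >= 1)
  g <- replicates[[1]]$bin_start_s
  for (r in replicates) {
    if (!isTRUE(all.equal(r$bin_start_s, g)))
      stop("replicates must share an identical bin grid")
  }
  vals <- sapply(replicates, function(r) r$mean_count)
  vals <- matrix(vals, nrow = length(g))
  n <- length(replicates)
  if (n < 2) {
    warning("single replicate: SEM undefined, returning mean only")
    sem <- rep(NA_real_, length(g))
  } else {
    sem <- apply(vals, 1, sd) / sqrt(n)
  }
  data.frame(bin_start_s = g, mean_count = rowMeans(vals), sem_count = sem,
             n = n)
}

#' Tidy long-format export of replicate series
#'
#' For external statistics packages (repeated-measures ANOVA and post-hocs
#' are out of scope here): one row per replicate x bin.
#'
#' @param replicates named list of binned data.frames.
#' @param group optional group label attached to every row.
#' @return data.frame with `group`, `replicate`, `bin_start_s`, `value`.
#' @export
tidyReplicates <- function(replicates, group = NA_character_) {
  if (is.null(names(replicates)))
    names(replicates) <- paste0("rep", seq_along(replicates))
  out <- mapply(function(r, nm) {
    data.frame(group = group, replicate = nm, bin_start_s = r$bin_start_s,
               value = r$mean_count)
  }, replicates, names(replicates), SIMPLIFY = FALSE)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Counting accuracy against ground truth
#'
#' Two distinct metrics (they are not complements): `accuracyPct`, the
#' percentage of frames whose predicted count equals the true count exactly,
#' and `meanErrorPct`, the mean per-frame absolute miscount normalised by the
#' group size, in percent.
#'
#' @param pred integer vector of predicted per-frame counts.
#' @param truth integer vector of true per-frame counts, frame-aligned with
#'   `pred`.
#' @param groupSize number of animals in the arena (> 0).
#' @return an [AccuracyReport-class] (single clip: `semErrorPct` is NA).
#' @export
evaluateAccuracy <- function(pred, truth, groupSize) {
  if (length(pred) != length(truth))
    stop("pred and truth must be frame-aligned (equal length)")
  if (length(pred) == 0) stop("no frames to compare")
  if (groupSize <= 0) stop("groupSize must be > 0")
  err <- abs(pred - truth) / groupSize * 100
  new("AccuracyReport",
      accuracyPct = 100 * mean(pred == truth),
      meanErrorPct = mean(err),
      semErrorPct = NA_real_,
      nFrames = length(pred))
}

#' Pool per-clip accuracy reports
#'
#' Pooled exact-match accuracy is frame-weighted; the error rate is the mean
#' of the per-clip means with its standard error across clips.
#'
#' @param reports list of [AccuracyReport-class], one per clip.
#' @return an [AccuracyReport-class].
#' @export
poolAccuracy <- function(reports) {
  stopifnot(length(reports) >= 1)
  n <- vapply(reports, function(r) r@nFrames, 0L)
  acc <- vapply(reports, function(r) r@accuracyPct, 0)
  err <- vapply(reports, function(r) r@meanErrorPct, 0)
  sem <- if (length(err) >= 2) sd(err) / sqrt(length(err)) else NA_real_
  new("AccuracyReport",
      accuracyPct = sum(acc * n) / sum(n),
      meanErrorPct = mean(err),
      semErrorPct = sem,
      nFrames = as.integer(sum(n)))
}

setMethod("show", "AccuracyReport", function(object) {
  cat(sprintf(
    "AccuracyReport: accuracy %.1f%%, mean error %.2f%%%s (%d frames)\n",
    object@accuracyPct, object@meanErrorPct,
    if (is.na(object@semErrorPct)) ""
    else sprintf(" +/- %.2f%%", object@semErrorPct),
    object@nFrames))
})
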