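# roi module: circular arena regions, masking, and centroid attribution.

#' Create a circular ROI
#'
#' @param label unique name of the arena.
#' @param x,y centre in continuous frame coordinates (pixels; the frame spans
#'   `[0, width]` x `[0, height]`, origin top-left).
#' @param radius radius in pixels (> 0).
#' @return a [CircularROI-class].
#' @export
circularROI <- function(label, x, y, radius) {
  new("CircularROI", label = as.character(label), x = as.numeric(x),
      y = as.numeric(y), radius = as.numeric(radius))
}

#' Bundle ROIs into a validated set
#'
#' Rejects ROIs extending outside the frame, duplicate labels and overlapping
#' disks (overlap would make centroid attribution ambiguous).
#'
#' @param rois list of [CircularROI-class] objects (or a single one).
#' @param width,height frame geometry in pixels.
#' @return an [ROISet-class].
#' @export
roiSet <- function(rois, width, height) {
  if (is(rois, "CircularROI")) rois <- list(rois)
  new("ROISet", rois = rois, width = as.integer(width),
      height = as.integer(height))
}

#' Load an ROI set from a JSON config
#'
#' Expected shape:
#' `{"frame": [w, h], "rois": [{"label": "arena1", "center": [x, y], "radius": r}, ...]}`.
#'
#' @param config path to a JSON file, a JSON string, or an equivalent list.
#' @return an [ROISet-class].
#' @export
loadROIs <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::fromJSON(config, simplifyDataFrame = FALSE)
  }
  if (is.null(config$frame) || length(config$frame) != 2)
    stop("config must give the frame geometry as [width, height]")
  rois <- lapply(config$rois, function(r) {
    if (is.null(r$label) || is.null(r$center) || is.null(r$radius))
      stop("each ROI needs label, center and radius")
    circularROI(r$label, r$center[[1]], r$center[[2]], r$radius)
  })
  roiSet(rois, config$frame[[1]], config$frame[[2]])
}

#' @describeIn roiSet labels in ROI order.
#' @param x an [ROISet-class].
#' @export
setMethod("roiLabels", "ROISet", function(x) {
  vapply(x@rois, function(r) r@label, "")
})

setMethod("show", "CircularROI", function(object) {
  cat(sprintf("CircularROI '%s': centre (%.1f, %.1f), radius %.1f px\n",
              object@label, object@x, object@y, object@radius))
})

setMethod("show", "ROISet", function(object) {
  cat(sprintf("ROISet: %d ROI(s) in a %dx%d frame\n", length(object@rois),
              object@width, object@height))
  for (r in object@rois) show(r)
})

#' Rasterise an ROI to a binary mask
#'
#' A pixel belongs to the mask exactly when its centre lies within the ROI
#' radius of the ROI centre.
#'
#' @param roi a [CircularROI-class].
#' @param width,height frame geometry in pixels.
#' @return H x W logical matrix.
#' @export
roiMask <- function(roi, width, height) {
  stopifnot(is(roi, "CircularROI"))
  cx <- matrix(rep(seq_len(width) - 0.5, each = height), nrow = height)
  cy <- matrix(rep(seq_len(height) - 0.5, times = width), nrow = height)
  (cx - roi@x)^2 + (cy - roi@y)^2 <= roi@radius^2
}

#' Attribute component centroids to ROIs
#'
#' A component belongs to the unique ROI containing its centroid; components
#' between arenas belong to none. A blob straddling an arena edge is counted
#' for the arena holding its centroid.
#'
#' @param x,y centroid coordinates (vectors, continuous frame coordinates).
#' @param roiset an [ROISet-class].
#' @return character vector of ROI labels, `NA` where no ROI contains the
#'   centroid.
#' @export
assignComponent <- function(x, y, roiset) {
  stopifnot(is(roiset, "ROISet"), length(x) == length(y))
  out <- rep(NA_character_, length(x))
  for (r in roiset@rois) {
    inside <- (x - r@x)^2 + (y - r@y)^2 <= r@radius^2
    hit <- inside & !is.na(inside)
    clash <- hit & !is.na(out)
    if (any(clash)) stop("centroid contained in more than one ROI")
    out[hit] <- r@label
  }
  out
}
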