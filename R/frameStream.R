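# frame_source module: the only code that touches container formats.
#
# The container is a lossless frame-sequence directory: numbered binary PGM
# (P5) frames plus a stream.json side-car carrying fps and geometry (frame
# rate in image containers is unreliable; the side-car is authoritative).
# ASCII PGM (P2) and colour PPM (P6/P3, converted to grayscale by luma) are
# accepted on read.

#' Construct an in-memory frame stream
#'
#' @param frames list of H x W integer matrices (values 0-255), all the same
#'   geometry.
#' @param fps nominal frames per second.
#' @param timestamps optional per-frame timestamps (seconds); defaults to
#'   `(i - 1) / fps` exactly.
#' @return a [FrameStream-class].
#' @examples
#' fs <- frameStream(list(matrix(0L, 4, 6), matrix(255L, 4, 6)), fps = 30)
#' nFrames(fs)
#' @export
frameStream <- function(frames, fps, timestamps = NULL) {
  stopifnot(is.list(frames), length(frames) >= 1)
  d <- dim(frames[[1]])
  for (f in frames) {
    if (!is.matrix(f) || !identical(dim(f), d))
      stop("all frames must be matrices of identical geometry")
  }
  frames <- lapply(frames, function(f) {
    storage.mode(f) <- "integer"
    f
  })
  newFrameStream(function(i) frames[[i]], length(frames), fps,
                 width = d[2], height = d[1], timestamps = timestamps)
}

# internal: lazy stream over a provider closure
newFrameStream <- function(provider, nframes, fps, width, height,
                           timestamps = NULL) {
  if (is.null(timestamps)) timestamps <- (seq_len(nframes) - 1) / fps
  new("FrameStream",
      nframes = as.integer(nframes), fps = as.numeric(fps),
      width = as.integer(width), height = as.integer(height),
      timestamps = as.numeric(timestamps), provider = provider)
}

#' @describeIn frameStream number of frames.
#' @param x a [FrameStream-class].
#' @export
setMethod("nFrames", "FrameStream", function(x) x@nframes)

#' @rdname frameStream
#' @export
setMethod("fps", "FrameStream", function(x) x@fps)

#' @rdname frameStream
#' @export
setMethod("frameTimestamps", "FrameStream", function(x) x@timestamps)

#' @rdname frameStream
#' @param i frame index.
#' @export
setMethod("getFrame", "FrameStream", function(x, i) {
  if (i < 1 || i > x@nframes) stop("frame index out of range")
  f <- x@provider(i)
  storage.mode(f) <- "integer"
  f
})

setMethod("show", "FrameStream", function(object) {
  cat(sprintf("FrameStream: %d frame(s), %dx%d px, %.3g fps (%.2f s)\n",
              object@nframes, object@width, object@height, object@fps,
              if (object@nframes) object@timestamps[object@nframes] else 0))
})

setMethod("show", "VideoMeta", function(object) {
  cat(sprintf("VideoMeta: %s [%s], %d frame(s), %dx%d px, %.3g fps\n",
              object@path, object@codec, object@frameCount, object@width,
              object@height, object@fps))
})

# ---- PGM/PPM primitives ----------------------------------------------------

# Read one PGM (P2/P5) or PPM (P3/P6) image as an H x W integer matrix,
# converting colour to grayscale by Rec.601 luma.
readPGM <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  token <- local({
    buf <- character(0)
    function() {
      repeat {
        ch <- readChar(con, 1, useBytes = TRUE)
        if (length(ch) == 0 || !nzchar(ch)) stop("unexpected end of PNM header")
        if (ch == "#") {
          repeat {
            ch <- readChar(con, 1, useBytes = TRUE)
            if (!length(ch) || ch == "\n") break
          }
          next
        }
        if (grepl("[[:space:]]", ch)) {
          if (length(buf)) {
            out <- paste(buf, collapse = "")
            buf <<- character(0)
            return(out)
          }
          next
        }
        buf <<- c(buf, ch)
      }
    }
  })
  magic <- token()
  if (!magic %in% c("P2", "P5", "P3", "P6"))
    stop(sprintf("'%s' is not a PGM/PPM image (magic '%s')", path, magic))
  w <- as.integer(token()); h <- as.integer(token())
  maxval <- as.integer(token())
  if (is.na(w) || is.na(h) || w <= 0 || h <= 0) stop("corrupt PNM header")
  if (is.na(maxval) || maxval <= 0 || maxval > 255)
    stop("only 8-bit PNM images are supported")
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- as.integer(w) * as.integer(h) * nch
  vals <- if (magic %in% c("P5", "P6")) {
    as.integer(readBin(con, "raw", n = n))
  } else {
    scan(con, what = integer(), n = n, quiet = TRUE)
  }
  if (length(vals) < n) stop(sprintf("'%s': truncated pixel data", path))
  if (nch == 3L) {
    r <- vals[seq(1, n, by = 3)]
    g <- vals[seq(2, n, by = 3)]
    b <- vals[seq(3, n, by = 3)]
    vals <- as.integer(round(0.299 * r + 0.587 * g + 0.114 * b))
  }
  # PNM stores row-major (top row first)
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

writePGM <- function(frame, path) {
  stopifnot(is.matrix(frame))
  v <- as.vector(t(frame))
  if (anyNA(v) || any(v < 0) || any(v > 255))
    stop("frame values must lie in 0-255")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n255\n", ncol(frame), nrow(frame)), con,
            eos = NULL)
  writeBin(as.raw(v), con)
  invisible(path)
}

# ---- container operations --------------------------------------------------

#' Open a recorded video as a frame stream
#'
#' Reads a frame-sequence video directory (numbered PGM/PPM frames plus a
#' `stream.json` side-car) or a single PGM/PPM image. Frames are read lazily
#' and colour input is converted to grayscale by luma; iteration is
#' repeatable, two passes yield identical pixels.
#'
#' @param path directory written by [writeVideo()] (or any directory of
#'   PGM/PPM frames in lexical order), or a single image file.
#' @param fps optional override of the container frame rate; mandatory when
#'   the container carries none.
#' @return a [FrameStream-class].
#' @export
openVideo <- function(path, fps = NULL) {
  if (!file.exists(path)) stop(sprintf("'%s' does not exist", path))
  if (!dir.exists(path)) {
    frame <- readPGM(path)
    return(newFrameStream(function(i) frame, 1L, fps %||% 1,
                          width = ncol(frame), height = nrow(frame)))
  }
  files <- sort(list.files(path, pattern = "\\.(pgm|ppm)$", full.names = TRUE))
  if (length(files) == 0)
    stop(sprintf("'%s' contains no frames (empty stream)", path))
  meta_path <- file.path(path, "stream.json")
  meta <- if (file.exists(meta_path)) jsonlite::fromJSON(meta_path) else NULL
  use_fps <- fps %||% meta$fps
  if (is.null(use_fps))
    stop("container carries no frame rate; supply fps=")
  first <- readPGM(files[1])
  newFrameStream(function(i) readPGM(files[i]), length(files), use_fps,
                 width = ncol(first), height = nrow(first))
}

#' Write a frame stream as a lossless video
#'
#' Writes numbered binary PGM frames plus a JSON side-car with fps and
#' geometry. The container is lossless, so fixtures round-trip bit for bit.
#'
#' @param stream a non-empty [FrameStream-class].
#' @param path output directory (created if needed).
#' @param codec codec tag; only the lossless `"pgm"` frame sequence is
#'   supported.
#' @return a [VideoMeta-class], invisibly.
#' @export
writeVideo <- function(stream, path, codec = "pgm") {
  stopifnot(is(stream, "FrameStream"))
  if (nFrames(stream) == 0) stop("refusing to write an empty stream")
  if (!identical(codec, "pgm"))
    stop(sprintf("unsupported codec '%s' (only 'pgm' is available)", codec))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop(sprintf("cannot create '%s'", path))
  for (i in seq_len(nFrames(stream))) {
    writePGM(getFrame(stream, i), file.path(path, sprintf("frame_%06d.pgm", i)))
  }
  jsonlite::write_json(
    list(fps = fps(stream), width = stream@width, height = stream@height,
         nframes = nFrames(stream), codec = codec),
    file.path(path, "stream.json"), auto_unbox = TRUE, digits = NA)
  invisible(new("VideoMeta", path = path, codec = codec,
                frameCount = nFrames(stream), fps = fps(stream),
                width = stream@width, height = stream@height))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
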