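# FrameStack container and multi-page grayscale stack I/O.
#
# Stacks are stored as portable graymap (PGM) files with one concatenated
# page per frame -- the netpbm convention for multi-image files -- in either
# binary (P5, 8/16-bit) or plain-text (P2) flavor. A JSON sidecar
# (<path>.json) records frame rate, channel and intensity scale so that
# write/load round-trips are lossless up to quantization.

#' FrameStack: one channel's movie
#'
#' @param data numeric array `T x H x W`, non-negative finite intensities.
#' @param frame_rate Hz (> 0).
#' @param channel `"voltage"` or `"calcium"`.
#' @param origin provenance string.
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(data, frame_rate = 30,
                        channel = c("voltage", "calcium"), origin = "memory") {
  channel <- match.arg(channel)
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("data must be a T x H x W array")
  if (dim(data)[1] < 1L) stopf("stack needs at least one frame")
  if (frame_rate <= 0) stopf("frame_rate must be > 0")
  if (any(!is.finite(data))) stopf("stack intensities must be finite")
  structure(list(data = data, frame_rate = frame_rate, channel = channel,
                 origin = origin), class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<frame_stack> %d frames of %d x %d, %.3g Hz, channel=%s\n",
              d[1], d[2], d[3], x$frame_rate, x$channel))
  invisible(x)
}

n_frames <- function(stack) dim(stack$data)[1]

#' Write a FrameStack as a multi-page 16-bit grayscale PGM file
#'
#' Frames are quantized to `[0, 65535]` with a common scale (recorded in
#' the sidecar) and appended as successive PGM pages. `format = "P2"`
#' writes plain text (used for small fixtures), `"P5"` binary.
#'
#' @param stack a [frame_stack()].
#' @param path output file path; a `<path>.json` sidecar is written too.
#' @param format `"P5"` (binary, default) or `"P2"` (ASCII).
#' @param scale counts per intensity unit; default auto (90% of full range
#'   at the stack maximum).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, format = c("P5", "P2"), scale = NULL) {
  format <- match.arg(format)
  d <- dim(stack$data)
  mx <- max(stack$data)
  if (is.null(scale)) scale <- if (mx > 0) 0.9 * 65535 / mx else 1
  con <- file(path, "wb")
  on.exit(close(con))
  for (k in seq_len(d[1])) {
    img <- matrix(as.integer(pmin(65535, pmax(0, round(stack$data[k, , ] * scale)))),
                  d[2], d[3])
    hdr <- sprintf("%s\n%d %d\n65535\n", format, d[3], d[2])
    writeChar(hdr, con, eos = NULL)
    if (format == "P5") {
      v <- as.integer(t(img))   # row-major raster
      writeBin(as.raw(rbind(v %/% 256L, v %% 256L)), con)
    } else {
      writeLines(apply(img, 1, paste, collapse = " "), con)
    }
  }
  jsonlite::write_json(list(frame_rate = stack$frame_rate,
                            channel = stack$channel, scale = scale,
                            n_frames = d[1]),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# tokenizer for PGM headers: whitespace-separated, '#' comments to newline
pgm_read_token <- function(con) {
  tok <- ""
  repeat {
    ch <- readChar(con, 1, useBytes = TRUE)
    if (!length(ch) || ch == "") {
      if (nzchar(tok)) return(tok) else return(NULL)
    }
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1, useBytes = TRUE)
        if (!length(ch) || ch == "" || ch == "\n") break
      }
      next
    }
    if (grepl("[[:space:]]", ch)) {
      if (nzchar(tok)) return(tok)
    } else tok <- paste0(tok, ch)
  }
}

#' Load a multi-page grayscale PGM stack
#'
#' Reads all concatenated P2/P5 pages; pages must agree in size. The frame
#' rate comes from the JSON sidecar if present, else from `rate`. Color
#' (PPM) input is rejected.
#'
#' @param path file written by [write_stack()] (or any multi-page PGM).
#' @param rate frame rate, Hz; required when no sidecar exists.
#' @param channel channel label override.
#' @return A [frame_stack()]; intensities are de-scaled by the sidecar
#'   scale when available, raw counts otherwise.
#' @export
load_stack <- function(path, rate = NULL, channel = NULL) {
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else NULL
  if (is.null(meta) && is.null(rate))
    stopf("no frame-rate metadata for '%s'; pass rate=", path)
  con <- file(path, "rb")
  on.exit(close(con))
  frames <- list()
  repeat {
    magic <- pgm_read_token(con)
    if (is.null(magic)) break
    if (magic %in% c("P3", "P6")) stopf("color (PPM) input not supported")
    if (!magic %in% c("P2", "P5")) stopf("not a PGM page: magic '%s'", magic)
    w <- as.integer(pgm_read_token(con))
    h <- as.integer(pgm_read_token(con))
    maxval <- as.integer(pgm_read_token(con))
    if (any(is.na(c(w, h, maxval)))) stopf("ragged or truncated PGM header")
    if (magic == "P5") {
      if (maxval > 255) {
        raw <- readBin(con, "integer", n = w * h, size = 2, signed = FALSE,
                       endian = "big")
      } else {
        raw <- as.integer(readBin(con, "raw", n = w * h))
      }
      if (length(raw) != w * h) stopf("truncated PGM raster")
      img <- matrix(raw, h, w, byrow = TRUE)
    } else {
      vals <- integer(w * h)
      for (i in seq_len(w * h)) {
        tok <- pgm_read_token(con)
        if (is.null(tok)) stopf("truncated P2 raster")
        vals[i] <- as.integer(tok)
      }
      img <- matrix(vals, h, w, byrow = TRUE)
    }
    frames[[length(frames) + 1L]] <- img
  }
  if (!length(frames)) stopf("no PGM pages in '%s'", path)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stopf("ragged pages: frame sizes differ")
  arr <- array(0, c(length(frames), dims[1, 1], dims[2, 1]))
  for (k in seq_along(frames)) arr[k, , ] <- frames[[k]]
  scale <- if (!is.null(meta$scale)) meta$scale else 1
  frame_stack(arr / scale,
              frame_rate = if (!is.null(meta$frame_rate)) meta$frame_rate else rate,
              channel = channel %||%
                (if (!is.null(meta$channel)) meta$channel else "voltage"),
              origin = path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
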