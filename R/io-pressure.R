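# ASCII frame-block dialect for pressure-mat exports, modelled on
# mat-scanner text exports: "#" metadata header, then per frame a header
# line "Frame <k>, t=<seconds>" followed by nr rows of nc comma-separated
# raw counts. A simplified, documented stand-in for proprietary binary
# formats; it preserves their structure (timestamped blocks of a raw-count
# sensel grid).

#' Write / read a pressure-mat frame stream
#'
#' `write_pressure_frames()` writes a [render_pressure_mat()] stream in the
#' package's ASCII frame-block dialect; `read_pressure_frames()` parses it
#' back. Raw counts round-trip exactly. Frames must share one grid shape;
#' a shape change or ragged row fails with the offending frame index.
#'
#' @param stream A `pressure_stream`.
#' @param path File path.
#' @param meta Named list of extra `# key: value` metadata.
#' @return `read_pressure_frames()` returns a `pressure_stream`;
#'   `write_pressure_frames()` returns `path` invisibly.
#' @export
write_pressure_frames <- function(stream, path, meta = list()) {
  stopifnot(inherits(stream, "pressure_stream"))
  d <- dim(stream$frames)
  sp <- stream$spec
  hdr <- c("# pawsway pressure-mat stream v1",
           "# device: pressure_mat",
           sprintf("# rate_hz: %s", format(sp$rate)),
           sprintf("# grid: %d x %d", d[1], d[2]),
           sprintf("# sensel_pitch_cm: %.17g", sp$sensel_pitch),
           sprintf("# calibration_scale: %.17g", stream$calibration_scale),
           sprintf("# unit: %s", stream$unit),
           "# coordinates: columns = x_ap cranial+, rows = y_ml left+ (top row leftmost), grid centred on mat centre",
           vapply(names(meta), function(k) sprintf("# %s: %s", k, format(meta[[k]])),
                  character(1)))
  blocks <- vapply(seq_len(d[3]), function(k) {
    m <- stream$frames[, , k]
    paste0(sprintf("Frame %d, t=%.9f\n", k, stream$time[k]),
           paste(apply(m, 1, paste, collapse = ","), collapse = "\n"))
  }, character(1))
  writeLines(c(hdr, blocks), path)
  invisible(path)
}

#' @rdname write_pressure_frames
#' @export
read_pressure_frames <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- read_hash_meta(path)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  hdr_idx <- grep("^Frame ", body)
  if (length(hdr_idx) == 0) stop(sprintf("%s: no frame blocks found", basename(path)),
                                 call. = FALSE)
  m <- regmatches(body[hdr_idx], regexec("^Frame\\s+(\\d+),\\s*t=([0-9eE.+-]+)$",
                                         body[hdr_idx]))
  if (any(lengths(m) != 3)) {
    stop(sprintf("%s: malformed frame header at block %d", basename(path),
                 which(lengths(m) != 3)[1]), call. = FALSE)
  }
  times <- as.numeric(vapply(m, `[`, character(1), 3))
  ends <- c(hdr_idx[-1] - 1L, length(body))
  n_frames <- length(hdr_idx)
  shape <- NULL
  frames <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    rows <- body[(hdr_idx[k] + 1L):ends[k]]
    parts <- strsplit(rows, ",", fixed = TRUE)
    widths <- lengths(parts)
    if (length(unique(widths)) != 1) {
      stop(sprintf("%s: ragged rows in frame %d", basename(path), k), call. = FALSE)
    }
    mk <- matrix(as.numeric(unlist(parts)), nrow = length(rows), byrow = TRUE)
    if (any(is.na(mk))) {
      stop(sprintf("%s: non-numeric count in frame %d", basename(path), k), call. = FALSE)
    }
    if (is.null(shape)) shape <- dim(mk)
    else if (!all(dim(mk) == shape)) {
      stop(sprintf("%s: grid shape changes at frame %d (%d x %d, expected %d x %d)",
                   basename(path), k, nrow(mk), ncol(mk), shape[1], shape[2]),
           call. = FALSE)
    }
    frames[[k]] <- mk
  }
  if (is.unsorted(times, strictly = TRUE)) {
    ord <- order(times)
    times <- times[ord]; frames <- frames[ord]
  }
  arr <- array(unlist(frames), dim = c(shape[1], shape[2], n_frames))
  num_meta <- function(key, default) {
    v <- suppressWarnings(as.numeric(meta[[key]] %||% NA_real_))
    if (length(v) == 1 && is.finite(v)) v else default
  }
  spec <- device_spec("pressure_mat",
                      rate = num_meta("rate_hz", 60),
                      sensel_pitch = num_meta("sensel_pitch_cm", 1 / sqrt(1.4)),
                      grid_dim = shape)
  structure(list(time = times, frames = arr, spec = spec,
                 calibration_scale = num_meta("calibration_scale", NA_real_),
                 unit = meta$unit %||% "raw_count"),
            class = "pressure_stream")
}
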