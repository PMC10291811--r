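# On-disk format for force-platform streams: a plain CSV with "#" metadata
# header lines, then columns time,fx,fy,fz,mx,my,mz (s, N, N cm).
# Coordinates: x = anterior-posterior (cranial +), y = medial-lateral
# (left +), origin at the plate centre; stated in every file header.

FORCE_COLUMNS <- c("time", "fx", "fy", "fz", "mx", "my", "mz")

#' Write / read a force-platform stream
#'
#' `write_force_csv()` writes the seven-channel plate stream with a metadata
#' header; `read_force_csv()` parses it back, validating the column set,
#' strictly increasing timestamps and finiteness. The round trip is
#' value-identical to better than 1e-9.
#'
#' @param stream A data frame with columns `time, fx, fy, fz, mx, my, mz`.
#' @param path File path.
#' @param meta Named list of extra metadata written as `# key: value` lines.
#' @return `read_force_csv()` returns a tibble with attributes `rate` and
#'   `meta`; `write_force_csv()` returns `path` invisibly.
#' @export
write_force_csv <- function(stream, path, meta = list()) {
  stopifnot(all(FORCE_COLUMNS %in% names(stream)))
  hdr <- c("# pawsway force-plate stream v1",
           "# device: force_plate",
           sprintf("# rate_hz: %s", format(attr(stream, "rate") %||% meta$rate_hz %||% NA)),
           "# units: time s; forces N; moments N.cm",
           "# coordinates: x_ap cranial+, y_ml left+, origin at plate centre",
           vapply(names(meta), function(k) sprintf("# %s: %s", k, format(meta[[k]])),
                  character(1)))
  writeLines(hdr, path)
  readr::write_csv(dplyr::as_tibble(stream[FORCE_COLUMNS]), path,
                   append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_force_csv
#' @export
read_force_csv <- function(path) {
  meta <- read_hash_meta(path)
  out <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  missing <- setdiff(FORCE_COLUMNS, names(out))
  if (length(missing) > 0) {
    stop(sprintf("force stream %s: missing column(s) %s", basename(path),
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  out <- out[FORCE_COLUMNS]
  bad <- which(!stats::complete.cases(out) |
                 rowSums(!sapply(out, is.finite)) > 0)
  if (length(bad) > 0) {
    stop(sprintf("force stream %s: non-finite value in data row %d",
                 basename(path), bad[1]), call. = FALSE)
  }
  if (nrow(out) > 1 && any(diff(out$time) <= 0)) {
    stop(sprintf("force stream %s: timestamps not strictly increasing at row %d",
                 basename(path), which(diff(out$time) <= 0)[1] + 1L), call. = FALSE)
  }
  attr(out, "rate") <- suppressWarnings(as.numeric(meta$rate_hz))
  attr(out, "meta") <- meta
  attr(out, "device") <- "force_plate"
  out
}

# "# key: value" metadata header lines.
read_hash_meta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- regmatches(hdr, regexec("^#\\s*([A-Za-z0-9_.-]+):\\s*(.*)$", hdr))
  kv <- kv[lengths(kv) == 3]
  stats::setNames(lapply(kv, `[`, 3), vapply(kv, `[`, character(1), 2))
}
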