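#' Recording container
#'
#' Four equal-length channels — X, Y, Z acceleration and the finger-pulse
#' waveform — plus the sampling rate and provenance. Sample `i` (1-based)
#' occurs at time `(i - 1) / sample_rate` seconds; every module uses this
#' convention.
#'
#' @param x,y,z Acceleration series (equal length).
#' @param pulse Pulse-sensor series (same length).
#' @param sample_rate Sampling rate in Sa/s.
#' @param participant_id Participant identifier.
#' @param position One of `"prone"`, `"back"`, `"right_side"`, `"left_side"`.
#' @return An object of class `recording`.
#' @export
recording <- function(x, y, z, pulse, sample_rate,
                      participant_id = "P1", position = "prone") {
  n <- length(x)
  if (length(y) != n || length(z) != n || length(pulse) != n) {
    stopf("all four channels must have identical length")
  }
  if (n < 1) stopf("channels must contain at least one sample")
  if (!is.numeric(sample_rate) || sample_rate <= 0) stopf("sample_rate must be > 0")
  vals <- c(x, y, z, pulse)
  if (any(!is.finite(vals))) stopf("recording contains non-finite samples")
  position <- match.arg(position, bb_positions)
  structure(
    list(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
         pulse = as.numeric(pulse), sample_rate = sample_rate,
         participant_id = as.character(participant_id), position = position),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf(
    "<recording> %s / %s: %d samples x 4 channels @ %g Sa/s (%.1f s)\n",
    x$participant_id, x$position, length(x$x), x$sample_rate,
    length(x$x) / x$sample_rate
  ))
  invisible(x)
}

#' Read a raw 4-column trace file
#'
#' Parses a plain-text recording: one sample per line, four
#' whitespace-separated numeric fields in the order X-acceleration,
#' Y-acceleration, Z-acceleration, finger pulse. A 180 s acquisition at
#' 250 Sa/s yields 45,000 lines.
#'
#' @param path File path.
#' @param sample_rate Sampling rate in Sa/s (default 250).
#' @param participant_id,position Metadata attached to the recording.
#' @return A [recording()].
#' @export
read_recording <- function(path, sample_rate = 250,
                           participant_id = "P1", position = "prone") {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stopf("empty recording file: %s", path)
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  nf <- lengths(parts)
  bad <- which(nf != 4)
  if (length(bad) > 0) {
    stopf("parse error in %s: line %d has %d fields (expected 4)",
          path, bad[1], nf[bad[1]])
  }
  vals <- suppressWarnings(as.numeric(unlist(parts, use.names = FALSE)))
  if (anyNA(vals)) {
    bad_line <- ceiling(which(is.na(vals))[1] / 4)
    stopf("parse error in %s: non-numeric field on line %d", path, bad_line)
  }
  m <- matrix(vals, ncol = 4, byrow = TRUE)
  recording(m[, 1], m[, 2], m[, 3], m[, 4],
            sample_rate = sample_rate,
            participant_id = participant_id, position = position)
}

#' Write a recording as a raw 4-column trace file
#'
#' One line per sample, four space-separated fields with 6 decimal digits.
#'
#' @param rec A [recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  lines <- sprintf("%.6f %.6f %.6f %.6f", rec$x, rec$y, rec$z, rec$pulse)
  con <- file(path, open = "wb")   # "\n" endings on every platform
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
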