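#' Number of complete windows in a sample count
#'
#' Windows are contiguous, non-overlapping blocks of `window_len` samples
#' starting at the first sample; any trailing remainder is discarded. A
#' full study of 10 participants x 4 positions x 180 s at 250 Sa/s cut into
#' 125-sample windows gives `count_windows(250 * 180 * 4 * 10, 125)` =
#' 14,400 windows.
#'
#' @param total_samples Total sample count.
#' @param window_len Window length in samples.
#' @return `floor(total_samples / window_len)`.
#' @export
count_windows <- function(total_samples, window_len) {
  if (window_len < 1) stopf("window_len must be >= 1")
  as.integer(total_samples %/% window_len)
}

#' Extract the 12-feature vector from one window
#'
#' Per axis: sum, population standard deviation and maximum of the
#' (optionally rectified) filtered samples. For X only, the same three
#' statistics of the first-difference magnitude (`delta_abs`), computed
#' within the window (124 values for a 125-sample window), are inserted
#' after the X statistics. Column order is fixed; see [feature_names()].
#'
#' @param window_x,window_y,window_z Equal-length filtered windows.
#' @param rectify_acc Take `abs()` of the samples before sum/std/max
#'   (default TRUE: a zero-mean bandpassed signal makes plain sums
#'   uninformative, so the sums are meant to carry energy). The
#'   first-difference features are magnitudes by definition either way.
#' @return Named numeric vector of length 12.
#' @export
#' @examples
#' extract_features(rep(2, 125), rep(0, 125), rep(0, 125))[c("Xsum", "Xmax")]
extract_features <- function(window_x, window_y, window_z, rectify_acc = TRUE) {
  L <- length(window_x)
  if (length(window_y) != L || length(window_z) != L) {
    stopf("windows must have equal length")
  }
  if (L < 2) stopf("window too short")
  dx <- delta_abs(window_x)
  rx <- if (rectify_acc) abs(window_x) else window_x
  ry <- if (rectify_acc) abs(window_y) else window_y
  rz <- if (rectify_acc) abs(window_z) else window_z
  out <- c(
    sum(rx), pop_sd(rx), max(rx),
    sum(dx), pop_sd(dx), max(dx),
    sum(ry), pop_sd(ry), max(ry),
    sum(rz), pop_sd(rz), max(rz)
  )
  names(out) <- bb_feature_names
  out
}

## Vectorized per-recording feature block: channel reshaped to
## window_len x n_windows, statistics per column. Matches extract_features
## exactly (same population-sd convention).
axis_feature_block <- function(channel, n_windows, window_len, rectify, with_delta) {
  m <- matrix(channel[seq_len(n_windows * window_len)], nrow = window_len)
  r <- if (rectify) abs(m) else m
  mu <- colMeans(r)
  std <- sqrt(pmax(0, colMeans(r * r) - mu * mu))
  mx <- apply(r, 2, max)
  block <- cbind(colSums(r), std, mx)
  if (with_delta) {
    d <- abs(m[-1, , drop = FALSE] - m[-window_len, , drop = FALSE])
    dmu <- colMeans(d)
    dstd <- sqrt(pmax(0, colMeans(d * d) - dmu * dmu))
    block <- cbind(block, colSums(d), dstd, apply(d, 2, max))
  }
  block
}

#' Build the feature matrix and labels for a set of recordings
#'
#' For each recording: bandpass-filter all four channels, detect peaks on
#' the filtered pulse channel, segment the acceleration channels into
#' `window_len`-sample windows, extract the 12 features per window, and
#' label each window by pulse-peak presence. Rows and labels are aligned
#' one-to-one.
#'
#' @param recordings A list of [recording()]s (or a `sim_dataset`, whose
#'   recordings are taken), all sharing one sample rate.
#' @param filter_spec A [filter_spec()].
#' @param window_len Window length in samples (default 125).
#' @param rectify_acc See [extract_features()].
#' @param peak_spec A [peak_spec()] for the label-generating peak detector.
#' @return A `data.frame` with the 12 feature columns (in [feature_names()]
#'   order), then `label` (0/1), `participant`, `position`, `window_index`.
#' @export
build_feature_matrix <- function(recordings,
                                 filter_spec = bedbeat::filter_spec(),
                                 window_len = 125,
                                 rectify_acc = TRUE,
                                 peak_spec = bedbeat::peak_spec()) {
  if (inherits(recordings, "sim_dataset")) {
    recordings <- lapply(recordings, `[[`, "recording")
  }
  if (inherits(recordings, "recording")) recordings <- list(recordings)
  if (length(recordings) == 0) stopf("no recordings supplied")
  fs <- unique(vapply(recordings, `[[`, numeric(1), "sample_rate"))
  if (length(fs) != 1) stopf("recordings have mixed sample rates: %s",
                             paste(fs, collapse = ", "))
  blocks <- lapply(recordings, function(rec) {
    n_windows <- count_windows(length(rec$x), window_len)
    if (n_windows == 0) stopf("recording %s/%s shorter than one window",
                              rec$participant_id, rec$position)
    fx <- bandpass(rec$x, fs, filter_spec)
    fy <- bandpass(rec$y, fs, filter_spec)
    fz <- bandpass(rec$z, fs, filter_spec)
    fp <- bandpass(rec$pulse, fs, filter_spec)
    feats <- cbind(
      axis_feature_block(fx, n_windows, window_len, rectify_acc, with_delta = TRUE),
      axis_feature_block(fy, n_windows, window_len, rectify_acc, with_delta = FALSE),
      axis_feature_block(fz, n_windows, window_len, rectify_acc, with_delta = FALSE)
    )
    colnames(feats) <- bb_feature_names
    peaks <- detect_pulse_peaks(fp, fs, peak_spec)
    labels <- label_windows(peaks, length(fp), window_len)
    df <- as.data.frame(feats)
    df$label <- labels
    df$participant <- rec$participant_id
    df$position <- rec$position
    df$window_index <- seq_len(n_windows)
    df
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Split a feature table into the design matrix and label vector
#'
#' @param features A table from [build_feature_matrix()].
#' @return List with `X` (numeric matrix, 12 columns) and `y` (integer 0/1).
#' @export
feature_xy <- function(features) {
  miss <- setdiff(c(bb_feature_names, "label"), names(features))
  if (length(miss) > 0) stopf("missing columns: %s", paste(miss, collapse = ", "))
  list(X = as.matrix(features[, bb_feature_names, drop = FALSE]),
       y = as.integer(features$label))
}

#' Write a feature table to CSV
#'
#' Columns: the 12 features, `label`, `participant`, `position`,
#' `window_index`.
#'
#' @param features Table from [build_feature_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}
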