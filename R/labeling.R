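#' Pulse-peak detection specification
#'
#' @param min_separation_s Refractory separation between accepted peaks in
#'   seconds (default 0.3, excluding physiologically impossible
#'   double-detections).
#' @param prominence_frac Minimum topographic prominence of an accepted
#'   peak, as a fraction of the channel's amplitude range (default 0.3).
#' @return An object of class `peak_spec`.
#' @export
peak_spec <- function(min_separation_s = 0.3, prominence_frac = 0.3) {
  if (min_separation_s <= 0) stopf("min_separation_s must be > 0")
  if (prominence_frac <= 0 || prominence_frac >= 1) {
    stopf("prominence_frac must lie in (0, 1)")
  }
  structure(list(min_separation_s = min_separation_s,
                 prominence_frac = prominence_frac),
            class = "peak_spec")
}

## Topographic prominence of candidate peaks: walk outward from each peak
## until a higher sample (or the boundary), take the minimum in between on
## each side; prominence = height - max(left_min, right_min).
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    i <- p
    left_min <- h
    while (i > 1) {
      i <- i - 1
      if (x[i] > h) break
      if (x[i] < left_min) left_min <- x[i]
    }
    i <- p
    right_min <- h
    while (i < length(x)) {
      i <- i + 1
      if (x[i] > h) break
      if (x[i] < right_min) right_min <- x[i]
    }
    h - max(left_min, right_min)
  }, numeric(1))
}

#' Detect heartbeat peaks on the pulse channel
#'
#' Local maxima whose topographic prominence is at least
#' `prominence_frac * (max - min)` of the channel, thinned so consecutive
#' accepted peaks are at least `min_separation_s` apart (higher peaks win).
#' Intended to run on the bandpass-filtered pulse channel.
#'
#' @param pulse Numeric pulse series (length >= 2).
#' @param sample_rate Sampling rate in Sa/s.
#' @param spec A [peak_spec()].
#' @return Strictly increasing integer vector of peak sample indices
#'   (1-based; sample `i` is at time `(i - 1) / sample_rate` s). A flat
#'   channel yields an empty vector with a warning.
#' @export
detect_pulse_peaks <- function(pulse, sample_rate, spec = peak_spec()) {
  stopifnot(inherits(spec, "peak_spec"))
  if (length(pulse) < 2) stopf("pulse channel too short")
  rng <- max(pulse) - min(pulse)
  if (rng == 0) {
    warnf("flat pulse channel: no peaks detectable")
    return(integer(0))
  }
  n <- length(pulse)
  core <- 2:(n - 1)
  cand <- core[pulse[core] > pulse[core - 1] & pulse[core] >= pulse[core + 1]]
  if (length(cand) == 0) return(integer(0))
  prom <- peak_prominence(pulse, cand)
  cand <- cand[prom >= spec$prominence_frac * rng]
  if (length(cand) == 0) return(integer(0))
  ## refractory thinning, strongest peaks first
  min_gap <- spec$min_separation_s * sample_rate
  ord <- cand[order(-pulse[cand], cand)]
  kept <- integer(0)
  for (p in ord) {
    if (all(abs(kept - p) >= min_gap)) kept <- c(kept, p)
  }
  sort(kept)
}

#' Per-window heartbeat labels from peak indices
#'
#' Window `w` (1-based) spans samples `(w-1)*window_len + 1` to
#' `w*window_len`; its label is 1 iff at least one peak index falls inside.
#' The trailing partial window is discarded.
#'
#' @param peak_indices Integer peak sample indices (1-based).
#' @param n_samples Total number of samples in the channel.
#' @param window_len Window length in samples (default 125, i.e. 0.5 s at
#'   250 Sa/s).
#' @return Integer 0/1 vector of length `floor(n_samples / window_len)`.
#' @export
#' @examples
#' label_windows(c(11, 301), 500, 125)  # 1 0 1 0
label_windows <- function(peak_indices, n_samples, window_len = 125) {
  if (window_len < 1) stopf("window_len must be >= 1")
  if (length(peak_indices) > 0 && any(peak_indices > n_samples)) {
    stopf("peak index beyond the recording")
  }
  n_windows <- n_samples %/% window_len
  if (n_windows == 0) {
    warnf("window_len (%d) exceeds the %d available samples: zero windows",
          window_len, n_samples)
    return(integer(0))
  }
  labels <- integer(n_windows)
  if (length(peak_indices) > 0) {
    w <- (as.integer(peak_indices) - 1L) %/% as.integer(window_len) + 1L
    w <- w[w <= n_windows]
    labels[unique(w)] <- 1L
  }
  labels
}
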