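#' Bandpass filter specification
#'
#' A Butterworth bandpass used on all four channels before any feature or
#' label computation. Defaults: 0.5--20 Hz, overall order 4, applied
#' forward--backward (zero phase) so filtering never shifts beat peaks
#' relative to the pulse-derived labels.
#'
#' @param low_hz Lower band edge in Hz (default 0.5).
#' @param high_hz Upper band edge in Hz (default 20).
#' @param order Overall filter order; must be even (poles are split between
#'   the two band edges). Default 4.
#' @param zero_phase Apply forward--backward (default TRUE). The effective
#'   magnitude response is then the squared single-pass response.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(low_hz = 0.5, high_hz = 20, order = 4, zero_phase = TRUE) {
  if (low_hz <= 0 || high_hz <= low_hz) stopf("need 0 < low_hz < high_hz")
  if (order < 2 || order %% 2 != 0) stopf("order must be an even integer >= 2")
  structure(list(low_hz = low_hz, high_hz = high_hz, order = as.integer(order),
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

butter_coeffs <- function(spec, sample_rate) {
  nyq <- sample_rate / 2
  if (spec$high_hz >= nyq) {
    stopf("high_hz (%g) must be below the Nyquist frequency (%g)",
          spec$high_hz, nyq)
  }
  bt <- signal::butter(spec$order / 2,
                       c(spec$low_hz, spec$high_hz) / nyq,
                       type = "pass")
  list(b = as.numeric(bt$b), a = as.numeric(bt$a))
}

## Step-matched initial filter state (transposed direct form II): the state
## for which a unit-step input produces the steady-state output immediately,
## eliminating the start-up transient. Scaled by the first input sample.
lfilter_zi <- function(b, a) {
  b <- b / a[1]; a <- a / a[1]
  n <- length(a) - 1
  A <- matrix(0, n, n)               # companion matrix of a
  A[1, ] <- -a[-1]
  if (n > 1) A[cbind(2:n, 1:(n - 1))] <- 1
  B <- b[-1] - a[-1] * b[1]
  solve(diag(n) - t(A), B)
}

## Single-pass IIR filter with initial state (df2t), C++ inner loop.
lfilter <- function(b, a, x, zi) df2t_filter_cpp(b / a[1], a / a[1], x, zi)

#' Bandpass-filter one channel
#'
#' Designs the Butterworth filter for this sampling rate and applies it.
#' With `zero_phase = TRUE` the channel is filtered forward and backward
#' with reflected-edge padding and step-matched initial conditions, so
#' passband components keep their timing and a constant (DC) input maps to
#' (numerically) zero.
#'
#' @param channel Numeric sample series.
#' @param sample_rate Sampling rate in Sa/s.
#' @param spec A [filter_spec()].
#' @return Filtered series of the same length.
#' @export
#' @examples
#' t <- seq(0, 4, by = 1 / 250)
#' y <- bandpass(sin(2 * pi * 5 * t), 250, filter_spec())
bandpass <- function(channel, sample_rate, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  co <- butter_coeffs(spec, sample_rate)
  b <- co$b; a <- co$a
  npad <- 3L * (length(a) - 1L)
  if (length(channel) <= max(3L * spec$order, npad)) {
    stopf("channel too short to filter (need > %d samples)",
          max(3L * spec$order, npad))
  }
  zi <- lfilter_zi(b, a)
  ## odd (point-reflected) extension at both ends
  head_ext <- 2 * channel[1] - channel[seq(npad + 1, 2)]
  tail_ext <- 2 * channel[length(channel)] -
    channel[seq(length(channel) - 1, length(channel) - npad)]
  ext <- c(head_ext, channel, tail_ext)
  y <- lfilter(b, a, ext, zi * ext[1])
  if (spec$zero_phase) {
    y <- rev(lfilter(b, a, rev(y), zi * y[length(y)]))
  }
  y[(npad + 1):(npad + length(channel))]
}

#' Analytic frequency response of the bandpass design
#'
#' Evaluates the designed filter's magnitude response at the requested
#' frequencies (squared when `zero_phase`, since the filter is applied twice).
#'
#' @param freq_hz Frequencies at which to evaluate, in Hz.
#' @param sample_rate Sampling rate in Sa/s.
#' @param spec A [filter_spec()].
#' @return Numeric vector of gains.
#' @export
bandpass_response <- function(freq_hz, sample_rate, spec = filter_spec()) {
  co <- butter_coeffs(spec, sample_rate)
  w <- 2 * pi * freq_hz / sample_rate
  z <- exp(-1i * w)
  hb <- sapply(z, function(zz) sum(co$b * zz^(seq_along(co$b) - 1)))
  ha <- sapply(z, function(zz) sum(co$a * zz^(seq_along(co$a) - 1)))
  g <- Mod(hb / ha)
  if (spec$zero_phase) g^2 else g
}

#' First-difference magnitude of a channel
#'
#' `delta_abs(x)[i] = |x[i + 1] - x[i]|`: a rectified first difference that
#' emphasizes sharp transients such as the ballistocardiographic beat
#' complex. Output is one sample shorter than the input.
#'
#' @param channel Numeric series of length >= 2.
#' @return Nonnegative series of length `length(channel) - 1`.
#' @export
#' @examples
#' delta_abs(c(1, 3, 2))  # 2 1
delta_abs <- function(channel) {
  if (length(channel) < 2) stopf("delta_abs needs at least 2 samples")
  abs(diff(channel))
}
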