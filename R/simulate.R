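#' Simulation configuration for one bed recording
#'
#' Describes a single (participant, position) recording: acquisition length
#' and rate, cardiac rhythm, the shape and axis coupling of the beat-induced
#' transient, respiration, sensor noise, and the pulse-sensor response.
#' Acceleration is in arbitrary-but-consistent units; every downstream
#' filter and feature is scale-covariant, so only relative amplitudes matter.
#'
#' @param duration_s Recording length in seconds (default 180).
#' @param sample_rate Sampling rate in Sa/s (default 250).
#' @param heart_rate_bpm Mean heart rate in beats/minute. The resting band is
#'   40--120 bpm (0.6--2 Hz); values outside it are allowed but flagged with
#'   a warning.
#' @param ibi_jitter_frac Multiplicative inter-beat-interval jitter: each
#'   interval is `60/heart_rate_bpm * (1 + U(-j, j))`. Must satisfy
#'   `0 <= j < 0.5`.
#' @param position One of `"prone"`, `"back"`, `"right_side"`, `"left_side"`.
#' @param beat_amp Peak amplitude of the beat transient (acceleration units).
#' @param beat_decay_s Exponential decay time constant of the transient (s).
#' @param beat_osc_hz Oscillation frequency of the transient (Hz); must sit
#'   inside the 0.5--20 Hz analysis band to survive filtering.
#' @param axis_mix Nonnegative length-3 vector of per-axis beat coupling
#'   gains (X, Y, Z). X-dominant by default: cardiac recoil couples mainly
#'   into the head--foot axis of the bed frame.
#' @param resp_rate_bpm Respiration rate in breaths/minute.
#' @param resp_amp Respiration amplitude (acceleration units); injected with
#'   a fixed Z-dominant axis profile and mostly removed by the 0.5 Hz
#'   high-pass edge.
#' @param noise_sd Standard deviation of white accelerometer noise.
#' @param ppg_delay_s Pulse-transit delay from the mechanical beat to the
#'   finger-pulse peak (s).
#' @param ppg_width_s Gaussian width (sd, in s) of one pulse waveform.
#' @param ppg_noise_sd Standard deviation of pulse-channel noise.
#' @param participant_id Participant identifier carried into the recording.
#' @param seed Integer seed; one seed drives every random draw for the
#'   recording.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(duration_s = 10, heart_rate_bpm = 72, seed = 1)
sim_config <- function(duration_s = 180,
                       sample_rate = 250,
                       heart_rate_bpm = 60,
                       ibi_jitter_frac = 0.1,
                       position = "prone",
                       beat_amp = 1,
                       beat_decay_s = 0.15,
                       beat_osc_hz = 8,
                       axis_mix = c(1, 0.35, 0.25),
                       resp_rate_bpm = 15,
                       resp_amp = 0.4,
                       noise_sd = 0.1,
                       ppg_delay_s = 0.2,
                       ppg_width_s = 0.05,
                       ppg_noise_sd = 0.02,
                       participant_id = "P1",
                       seed = 1L) {
  if (!is.numeric(sample_rate) || sample_rate <= 0) stopf("sample_rate must be > 0")
  if (!is.numeric(duration_s) || duration_s < 0) stopf("duration_s must be >= 0")
  if (ibi_jitter_frac < 0 || ibi_jitter_frac >= 0.5) {
    stopf("ibi_jitter_frac must lie in [0, 0.5), got %g", ibi_jitter_frac)
  }
  if (heart_rate_bpm <= 0) stopf("heart_rate_bpm must be > 0")
  if (heart_rate_bpm < 40 || heart_rate_bpm > 120) {
    warnf("heart_rate_bpm = %g is outside the resting 40-120 bpm band", heart_rate_bpm)
  }
  position <- match.arg(position, bb_positions)
  if (length(axis_mix) != 3 || any(axis_mix < 0)) {
    stopf("axis_mix must be 3 nonnegative gains")
  }
  structure(
    list(
      duration_s = duration_s, sample_rate = sample_rate,
      heart_rate_bpm = heart_rate_bpm, ibi_jitter_frac = ibi_jitter_frac,
      position = position, beat_amp = beat_amp, beat_decay_s = beat_decay_s,
      beat_osc_hz = beat_osc_hz, axis_mix = as.numeric(axis_mix),
      resp_rate_bpm = resp_rate_bpm, resp_amp = resp_amp, noise_sd = noise_sd,
      ppg_delay_s = ppg_delay_s, ppg_width_s = ppg_width_s,
      ppg_noise_sd = ppg_noise_sd, participant_id = as.character(participant_id),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Draw ground-truth beat times
#'
#' Beat times are cumulative sums of jittered inter-beat intervals with mean
#' `60/heart_rate_bpm`, started at a uniform phase offset inside the first
#' interval so that recordings do not all begin on a beat. Intervals are
#' floored at 0.3 s, a physiological refractory bound. Beats are only kept
#' if their pulse-sensor peak (`ppg_delay_s` later, plus the bump width)
#' still falls inside the acquisition: the pulse reference can only mark
#' beats whose pulse wave arrives before the recording stops. Reproducible
#' under the config's seed.
#'
#' @param config A [sim_config()].
#' @return Numeric vector of strictly increasing beat times (s) in
#'   `[0, duration_s)`.
#' @export
#' @examples
#' tt <- draw_beat_times(sim_config(duration_s = 60, ibi_jitter_frac = 0, seed = 7))
#' length(tt)  # 60 beats at 60 bpm
draw_beat_times <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$heart_rate_bpm <= 0) stopf("heart_rate_bpm must be > 0")
  if (config$duration_s <= 0) return(numeric(0))
  ibi <- 60 / config$heart_rate_bpm
  j <- config$ibi_jitter_frac
  ## tail margin: the pulse peak of every kept beat must lie in-recording
  margin <- config$ppg_delay_s + 2 * config$ppg_width_s
  local_seed(config$seed, {
    t0 <- runif(1, 0, max(ibi - margin, 0.05 * ibi))
    ## Upper bound on the number of intervals that can fit.
    n_max <- ceiling(config$duration_s / (max(ibi * (1 - j), 0.3))) + 2L
    gaps <- ibi * (1 + runif(n_max, -j, j))
    gaps <- pmax(gaps, 0.3)
    times <- t0 + c(0, cumsum(gaps))
    times[times < config$duration_s - margin]
  })
}

## Per-position coupling of the beat transient into the three axes.
## A fixed permutation/attenuation of axis_mix: side positions swap the
## lateral axes, non-prone positions attenuate overall coupling. X remains
## dominant in every position.
position_axis_gain <- function(axis_mix, position) {
  switch(position,
    prone      = axis_mix,
    back       = axis_mix * 0.8,
    right_side = axis_mix[c(1, 3, 2)] * 0.9,
    left_side  = axis_mix[c(1, 3, 2)] * 0.7
  )
}

#' Synthesize a raw recording from a config and beat times
#'
#' Each beat injects an exponentially damped sinusoid (amplitude
#' `beat_amp`, decay `beat_decay_s`, frequency `beat_osc_hz`) into the three
#' acceleration channels, scaled by `axis_mix` permuted/attenuated per
#' `position`. A respiratory sinusoid and white noise are added. The pulse
#' channel is a train of unit Gaussian bumps centred `ppg_delay_s` after each
#' beat (sd `ppg_width_s`) plus its own noise.
#'
#' @param config A [sim_config()].
#' @param truth Beat times from [draw_beat_times()] (seconds).
#' @return A [recording()] with `round(duration_s * sample_rate)` samples per
#'   channel.
#' @export
synthesize_recording <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$sample_rate
  n <- round(config$duration_s * fs)
  if (any(truth < 0) || any(truth >= config$duration_s)) {
    stopf("beat times must lie within [0, duration_s)")
  }
  beat <- numeric(n)
  if (n > 0 && length(truth) > 0 && config$beat_amp != 0) {
    klen <- ceiling(6 * config$beat_decay_s * fs)
    for (tb in truth) {
      i0 <- floor(tb * fs) + 1L          # first sample at/after the beat
      idx <- i0:min(n, i0 + klen)
      tt <- (idx - 1) / fs - tb
      tt[tt < 0] <- 0
      beat[idx] <- beat[idx] +
        config$beat_amp * exp(-tt / config$beat_decay_s) *
          sin(2 * pi * config$beat_osc_hz * tt)
    }
  }
  gain <- position_axis_gain(config$axis_mix, config$position)
  tvec <- if (n > 0) (seq_len(n) - 1) / fs else numeric(0)

  local_seed(config$seed + 1L, {
    resp_phase <- runif(1, 0, 2 * pi)
    resp <- config$resp_amp * sin(2 * pi * config$resp_rate_bpm / 60 * tvec + resp_phase)
    resp_gain <- c(0.2, 0.3, 1.0)   # breathing couples mainly into Z
    ch <- lapply(1:3, function(a) {
      gain[a] * beat + resp_gain[a] * resp +
        if (config$noise_sd > 0) rnorm(n, 0, config$noise_sd) else numeric(n)
    })
    pulse <- numeric(n)
    if (n > 0 && length(truth) > 0) {
      w <- config$ppg_width_s
      half <- ceiling(4 * w * fs)
      for (tb in truth) {
        tc <- tb + config$ppg_delay_s
        ic <- round(tc * fs) + 1L
        lo <- max(1L, ic - half)
        hi <- min(n, ic + half)
        if (lo > hi) next           # bump falls entirely outside the trace
        idx <- lo:hi
        tt <- (idx - 1) / fs - tc
        pulse[idx] <- pulse[idx] + exp(-tt^2 / (2 * w^2))
      }
    }
    if (config$ppg_noise_sd > 0) pulse <- pulse + rnorm(n, 0, config$ppg_noise_sd)
    recording(ch[[1]], ch[[2]], ch[[3]], pulse,
              sample_rate = fs,
              participant_id = config$participant_id,
              position = config$position)
  })
}

#' Simulate one recording with its ground truth
#'
#' @param config A [sim_config()].
#' @return List with elements `recording` (a [recording()]) and `truth`
#'   (beat times in seconds).
#' @export
#' @examples
#' sim <- simulate_recording(sim_config(duration_s = 20, seed = 3))
#' length(sim$recording$x) / sim$recording$sample_rate  # 20 s
simulate_recording <- function(config) {
  truth <- draw_beat_times(config)
  list(recording = synthesize_recording(config, truth), truth = truth)
}

#' Simulate a multi-participant study
#'
#' Generates one recording per (participant, position) pair. Each participant
#' receives a resting heart rate drawn uniformly from `hr_range_bpm`; each
#' recording gets its own derived seed so the whole study is reproducible
#' from the one `seed` argument.
#'
#' @param n_participants Number of participants (default 10).
#' @param positions Character vector of lying positions (default all four).
#' @param duration_s,sample_rate Per-recording acquisition settings.
#' @param hr_range_bpm Length-2 range from which per-participant heart rates
#'   are drawn (default 50--90 bpm, inside the resting band).
#' @param seed Master integer seed.
#' @param ... Further arguments passed to [sim_config()] (noise levels,
#'   transient shape, ...).
#' @return List of entries, each with `recording`, `truth`, `participant_id`
#'   and `position`; class `sim_dataset`.
#' @export
simulate_dataset <- function(n_participants = 10,
                             positions = bb_positions,
                             duration_s = 180,
                             sample_rate = 250,
                             hr_range_bpm = c(50, 90),
                             seed = 1L,
                             ...) {
  if (n_participants < 1) stopf("need at least one participant")
  positions <- match.arg(positions, bb_positions, several.ok = TRUE)
  hrs <- local_seed(seed, runif(n_participants, hr_range_bpm[1], hr_range_bpm[2]))
  out <- list()
  for (p in seq_len(n_participants)) {
    for (q in seq_along(positions)) {
      cfg <- sim_config(
        duration_s = duration_s, sample_rate = sample_rate,
        heart_rate_bpm = hrs[p], position = positions[q],
        participant_id = sprintf("P%d", p),
        seed = as.integer(seed + 101L * (p - 1L) + 7L * (q - 1L) + 1L),
        ...
      )
      sim <- simulate_recording(cfg)
      out[[length(out) + 1L]] <- list(
        recording = sim$recording, truth = sim$truth,
        participant_id = cfg$participant_id, position = positions[q]
      )
    }
  }
  structure(out, class = "sim_dataset")
}

#' Write a simulated dataset to raw trace files
#'
#' One 4-column text file per recording, named `P<participant>_pos<k>.txt`
#' (k = 1..4 for prone, back, right side, left side), plus a sidecar
#' `*_beats.txt` holding one ground-truth beat time (seconds, 6 decimals)
#' per line.
#'
#' @param dataset A `sim_dataset` from [simulate_dataset()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of recording file paths.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (entry in dataset) {
    k <- match(entry$position, bb_positions)
    stem <- sprintf("%s_pos%d", entry$participant_id, k)
    path <- file.path(dir, paste0(stem, ".txt"))
    write_recording(entry$recording, path)
    write_beat_times(entry$truth, file.path(dir, paste0(stem, "_beats.txt")))
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Write/read ground-truth beat times
#'
#' Plain text, one beat time in seconds per line, 6 decimals.
#'
#' @param times Numeric vector of beat times (s).
#' @param path File path.
#' @return `write_beat_times` returns `path` invisibly; `read_beat_times`
#'   returns the numeric vector.
#' @export
write_beat_times <- function(times, path) {
  writeLines(sprintf("%.6f", times), path)
  invisible(path)
}

#' @rdname write_beat_times
#' @export
read_beat_times <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path)
  if (length(lines) == 0) return(numeric(0))
  as.numeric(lines)
}
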