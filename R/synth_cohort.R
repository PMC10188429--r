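#' EEG frequency-band specification
#'
#' A band is a named frequency interval with an amplitude, used by the
#' synthetic generator to build band-structured EEG. Conventional edges are
#' delta 0.5--3, theta 4--7, alpha 8--12, beta 15--30 and gamma 30--60 Hz
#' (the gamma band is open-ended in the literature; 60 Hz is this package's
#' synthesis ceiling, safely below the 125 Hz Nyquist limit at 250 Hz).
#'
#' @param name One of `"delta"`, `"theta"`, `"alpha"`, `"beta"`, `"gamma"`.
#' @param low_hz,high_hz Band edges in Hz, `0 < low_hz < high_hz`.
#' @param amplitude Non-negative amplitude in arbitrary microvolt-like units.
#' @return An object of class `band_spec`.
#' @export
band_spec <- function(name, low_hz, high_hz, amplitude) {
  name <- match.arg(name, c("delta", "theta", "alpha", "beta", "gamma"))
  if (!(is.numeric(low_hz) && is.numeric(high_hz) && low_hz > 0 && low_hz < high_hz)) {
    stopf("band '%s': need 0 < low_hz < high_hz (got %s, %s)", name, low_hz, high_hz)
  }
  if (!is.numeric(amplitude) || amplitude < 0) {
    stopf("band '%s': amplitude must be >= 0", name)
  }
  structure(list(name = name, low_hz = low_hz, high_hz = high_hz,
                 amplitude = amplitude), class = "band_spec")
}

#' Default EEG bands with chosen amplitudes
#'
#' @param amplitudes Named numeric vector of per-band amplitudes; names drawn
#'   from delta/theta/alpha/beta/gamma. Unnamed bands default to 0.
#' @return List of [band_spec()] objects in canonical order.
#' @export
default_bands <- function(amplitudes = c(delta = 1, theta = 0.8, alpha = 1.2,
                                         beta = 0.6, gamma = 0.3)) {
  edges <- list(delta = c(0.5, 3), theta = c(4, 7), alpha = c(8, 12),
                beta = c(15, 30), gamma = c(30, 60))
  lapply(names(edges), function(nm) {
    amp <- if (nm %in% names(amplitudes)) unname(amplitudes[[nm]]) else 0
    band_spec(nm, edges[[nm]][1], edges[[nm]][2], amp)
  })
}

#' Subject profile for the synthetic cohort generator
#'
#' Bundles the class-conditional band amplitudes with per-subject nuisance
#' parameters: a multiplicative gain (electrode contact / amplifier
#' variability), a broadband sensor-noise scale, and optional artifacts
#' (mains line noise and intermittent muscle bursts).
#'
#' @param subject_id Opaque identifier string.
#' @param label `"delirium"` or `"control"`.
#' @param bands List of [band_spec()], one amplitude per band.
#' @param gain Positive per-subject multiplicative factor on the band signal.
#' @param noise_sd Standard deviation of additive white Gaussian sensor noise.
#' @param background_sd RMS of the 1/f ("pink") broadband background that
#'   underlies all scalp EEG; class-independent. The low-frequency wander
#'   it contributes dominates short analysis windows (few spectral degrees
#'   of freedom) while long windows average over it.
#' @param artifact_config `NULL`, or a list with any of `line_hz`, `line_amp`
#'   (sinusoidal mains interference) and `burst_rate` (events/s),
#'   `burst_amp`, `burst_dur` (muscle-burst noise).
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, label = c("control", "delirium"),
                            bands = default_bands(), gain = 1, noise_sd = 0.3,
                            background_sd = 1, artifact_config = NULL) {
  label <- match.arg(label)
  if (!is.numeric(gain) || gain <= 0) stopf("gain must be > 0 (got %s)", gain)
  if (!is.numeric(noise_sd) || noise_sd < 0) stopf("noise_sd must be >= 0")
  if (!is.numeric(background_sd) || background_sd < 0) stopf("background_sd must be >= 0")
  stopifnot(length(bands) >= 1, all(vapply(bands, inherits, TRUE, "band_spec")))
  if (anyDuplicated(vapply(bands, `[[`, "", "name"))) {
    stopf("exactly one amplitude per band: duplicated band name in profile")
  }
  structure(list(subject_id = as.character(subject_id), label = label,
                 bands = bands, gain = gain, noise_sd = noise_sd,
                 background_sd = background_sd,
                 artifact_config = artifact_config),
            class = "subject_profile")
}

#' Canonical class profiles
#'
#' `control_profile()` uses the default band amplitudes. `delirium_profile()`
#' applies multiplicative effects expressing EEG "slowing": by default delta
#' and theta amplitudes doubled and alpha halved relative to control.
#' Passing `effect = c(delta = 2)` gives a delta-band-only class difference.
#'
#' @param effect Named multipliers applied to the control amplitudes.
#' @param ... Passed on to [subject_profile()].
#' @return A `subject_profile`.
#' @export
control_profile <- function(...) {
  subject_profile(subject_id = "control-template", label = "control", ...)
}

#' @rdname control_profile
#' @export
delirium_profile <- function(effect = c(delta = 2, theta = 2, alpha = 0.5), ...) {
  amps <- c(delta = 1, theta = 0.8, alpha = 1.2, beta = 0.6, gamma = 0.3)
  for (nm in names(effect)) amps[[nm]] <- amps[[nm]] * effect[[nm]]
  subject_profile(subject_id = "delirium-template", label = "delirium",
                  bands = default_bands(amps), ...)
}

new_recording <- function(subject_id, label, data, sampling_interval) {
  if (!is.matrix(data) || nrow(data) != 8L) {
    stopf("recording data must be an 8 x N matrix (got %s x %s)",
          nrow(data), ncol(data))
  }
  if (ncol(data) < 1L) stopf("recording must contain at least one sample")
  assert_finite(data, "recording data")
  if (!is.numeric(sampling_interval) || sampling_interval <= 0) {
    stopf("sampling_interval must be > 0")
  }
  structure(list(subject_id = as.character(subject_id),
                 label = match.arg(label, c("control", "delirium")),
                 data = data, sampling_interval = sampling_interval),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s (%s): 8 x %d samples @ %g ms (%.1f s)\n",
              x$subject_id, x$label, ncol(x$data), 1000 * x$sampling_interval,
              ncol(x$data) * x$sampling_interval))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An `eeg_recording`.
#' @export
recording_duration <- function(rec) ncol(rec$data) * rec$sampling_interval

# Unit-RMS 1/f ("pink") noise via spectral shaping: white Gaussian spectrum
# scaled by 1/sqrt(f) above a 0.5 Hz corner (flat below, so power does not
# blow up at DC).
pink_noise <- function(n, fs, corner_hz = 0.5) {
  X <- stats::fft(stats::rnorm(n))
  f <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * fs / n
  shape <- 1 / sqrt(pmax(f, corner_hz))
  shape[1] <- 0                       # zero-mean
  x <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

#' Generate one synthetic 8-channel EEG recording
#'
#' Each channel is a sum of narrowband components, one per configured band:
#' a sinusoid whose frequency is drawn uniformly inside the band
#' (independently per channel, giving per-subject frequency jitter) with a
#' uniform random phase, scaled by `amplitude * gain`; plus Gaussian
#' broadband noise and any configured artifacts. Alternatively
#' `mode = "filtered_noise"` synthesises each band as band-pass-filtered
#' Gaussian noise with matched RMS, a less tonal but harder-to-verify
#' texture.
#'
#' @param profile A [subject_profile()].
#' @param duration Recording length in seconds (> 0).
#' @param seed Integer RNG seed; the output is a deterministic function of
#'   `(profile, duration, seed)`.
#' @param sampling_interval Seconds per sample; default 0.004 (250 Hz).
#' @param mode `"sinusoid"` (default) or `"filtered_noise"`.
#' @param freq_jitter Fraction of the half-bandwidth by which each
#'   channel's component frequency may deviate from the band centre
#'   (small jitter, default 0.2; 1 spreads draws across the full band).
#' @param env_sd Log-sd of a slowly varying multiplicative amplitude
#'   envelope applied per band (shared across channels, emulating the
#'   waxing and waning of rhythmic activity with global brain state).
#'   0 (the default) keeps amplitudes stationary, the narrowband regime
#'   whose spectra are easiest to verify.
#' @param env_hz Bandwidth of the amplitude envelope in Hz (default 1).
#' @return An `eeg_recording` with an `8 x round(duration/sampling_interval)`
#'   data matrix.
#' @export
generate_recording <- function(profile, duration, seed,
                               sampling_interval = 0.004,
                               mode = c("sinusoid", "filtered_noise"),
                               freq_jitter = 0.2, env_sd = 0, env_hz = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(profile, "subject_profile"))
  if (!is.numeric(duration) || duration <= 0) {
    stopf("duration must be > 0 seconds (got %s)", duration)
  }
  n <- round(duration / sampling_interval)
  if (n < 1) stopf("duration %g s too short for sampling interval %g s",
                   duration, sampling_interval)
  t <- (seq_len(n) - 1L) * sampling_interval
  fs <- 1 / sampling_interval

  data <- with_seed(seed, {
    x <- matrix(0, nrow = 8L, ncol = n)
    # per-band amplitude envelopes, common to all channels (global state)
    envs <- lapply(profile$bands, function(b) {
      if (env_sd <= 0 || b$amplitude <= 0) return(NULL)
      z <- stats::rnorm(n)
      bf <- signal::butter(2, min(env_hz / (fs / 2), 0.99), type = "low")
      zl <- signal::filtfilt(bf, z)
      zl <- zl / stats::sd(zl)
      exp(env_sd * zl - env_sd^2 / 2)
    })
    for (ch in 1:8) {
      acc <- numeric(n)
      for (bi in seq_along(profile$bands)) {
        b <- profile$bands[[bi]]
        if (b$amplitude <= 0) next
        env <- envs[[bi]] %||% 1
        if (mode == "sinusoid") {
          hi <- min(b$high_hz, 0.45 * fs)
          mid <- (b$low_hz + hi) / 2
          f <- mid + freq_jitter * (hi - b$low_hz) / 2 * stats::runif(1, -1, 1)
          phi <- stats::runif(1, 0, 2 * pi)
          acc <- acc + b$amplitude * env * sin(2 * pi * f * t + phi)
        } else {
          w <- stats::rnorm(n)
          bf <- signal::butter(4, c(b$low_hz, min(b$high_hz, 0.45 * fs)) / (fs / 2),
                               type = "pass")
          y <- signal::filter(bf, w)
          y_rms <- sqrt(mean(y^2))
          if (y_rms > 0) acc <- acc + (b$amplitude / sqrt(2)) * env * y / y_rms
        }
      }
      acc <- profile$gain * acc
      if ((profile$background_sd %||% 0) > 0) {
        acc <- acc + profile$gain * profile$background_sd * pink_noise(n, fs)
      }
      if (profile$noise_sd > 0) acc <- acc + stats::rnorm(n, sd = profile$noise_sd)
      x[ch, ] <- acc
    }
    ac <- profile$artifact_config
    if (!is.null(ac)) {
      if (!is.null(ac$line_amp) && ac$line_amp > 0) {
        line_hz <- ac$line_hz %||% 60
        phi <- stats::runif(1, 0, 2 * pi)
        line <- ac$line_amp * sin(2 * pi * line_hz * t + phi)
        x <- sweep(x, 2, line, `+`)
      }
      if (!is.null(ac$burst_rate) && ac$burst_rate > 0) {
        n_bursts <- stats::rpois(1, ac$burst_rate * duration)
        dur <- ac$burst_dur %||% 0.2
        amp <- ac$burst_amp %||% 1
        len <- max(2L, round(dur / sampling_interval))
        env <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = len)))
        for (k in seq_len(n_bursts)) {
          start <- sample.int(max(1L, n - len), 1)
          idx <- start:(start + len - 1L)
          ch <- sample.int(8L, 1)
          x[ch, idx] <- x[ch, idx] + amp * env * stats::rnorm(len)
        }
      }
    }
    x
  })
  new_recording(profile$subject_id, profile$label, data, sampling_interval)
}

#' Generate a synthetic cohort of labelled recordings
#'
#' Builds `n_subjects` recordings with unique subject ids; `fraction_delirium`
#' of subjects (rounded) receive the delirium template and the rest the
#' control template. Per-subject gain is drawn log-normally
#' (`sdlog = gain_sdlog`) around the template gain, so absolute amplitude is
#' not a trivial class giveaway; band-frequency jitter arises inside
#' [generate_recording()].
#'
#' @param n_subjects Number of subjects (>= 2); default 12.
#' @param fraction_delirium Proportion in (0, 1) labelled delirium.
#' @param templates List with `delirium` and `control` [subject_profile()]s.
#' @param duration Per-recording length in seconds.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @param gain_sdlog Log-sd of the per-subject gain draw (0 disables).
#' @param sampling_interval Seconds per sample (default 0.004).
#' @param mode Synthesis mode, see [generate_recording()].
#' @param freq_jitter Per-channel frequency jitter, see [generate_recording()].
#' @param env_sd,env_hz Optional amplitude-envelope non-stationarity, see
#'   [generate_recording()] (default off).
#' @return List of `eeg_recording` objects (class `eeg_cohort`).
#' @export
generate_cohort <- function(n_subjects = 12, fraction_delirium = 0.5,
                            templates = list(delirium = delirium_profile(),
                                             control = control_profile()),
                            duration = 60, seed = 1, gain_sdlog = 0.2,
                            sampling_interval = 0.004,
                            mode = c("sinusoid", "filtered_noise"),
                            freq_jitter = 0.2, env_sd = 0, env_hz = 1) {
  mode <- match.arg(mode)
  if (n_subjects < 2) stopf("need at least 2 subjects")
  if (!(fraction_delirium > 0 && fraction_delirium < 1)) {
    stopf("fraction_delirium must lie strictly between 0 and 1")
  }
  n_pos <- round(n_subjects * fraction_delirium)
  if (n_pos < 1 || n_pos > n_subjects - 1) {
    stopf("fraction_delirium = %g leaves one class empty for %d subjects",
          fraction_delirium, n_subjects)
  }
  labels <- c(rep("delirium", n_pos), rep("control", n_subjects - n_pos))
  draws <- with_seed(seed, list(
    gains = stats::rlnorm(n_subjects, meanlog = 0, sdlog = gain_sdlog),
    seeds = sample.int(.Machine$integer.max - 1L, n_subjects)
  ))
  recs <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    tmpl <- templates[[labels[i]]]
    prof <- subject_profile(sprintf("S%02d", i), labels[i], bands = tmpl$bands,
                            gain = tmpl$gain * draws$gains[i],
                            noise_sd = tmpl$noise_sd,
                            artifact_config = tmpl$artifact_config)
    recs[[i]] <- generate_recording(prof, duration, draws$seeds[i],
                                    sampling_interval, mode, freq_jitter,
                                    env_sd = env_sd, env_hz = env_hz)
  }
  structure(recs, class = "eeg_cohort")
}
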