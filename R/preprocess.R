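#' Preprocessing configuration
#'
#' Parameters of the cleaning chain: zero-phase band-pass filtering,
#' common-average re-referencing, epoching, and ICA-based artifact removal.
#' Defaults follow common clinical-EEG practice: 0.5--40 Hz passband,
#' common-average reference, ICA components rejected when their excess
#' kurtosis exceeds `ica_kurtosis_threshold` (spiky artifacts) or when more
#' than `ica_highfreq_power_threshold` of their spectral power lies above
#' 30 Hz (muscle/line contamination).
#'
#' @param highpass_hz,lowpass_hz Passband edges in Hz.
#' @param reference `"common_average"` or `"none"`.
#' @param epoch_length Epoch length in seconds.
#' @param ica_enabled Logical; when `FALSE`, [ica_clean()] is a pass-through.
#' @param ica_kurtosis_threshold Excess-kurtosis rejection threshold.
#' @param ica_highfreq_power_threshold Proportion of component power above
#'   30 Hz beyond which the component is rejected.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(highpass_hz = 0.5, lowpass_hz = 40,
                              reference = c("common_average", "none"),
                              epoch_length = 10, ica_enabled = TRUE,
                              ica_kurtosis_threshold = 10,
                              ica_highfreq_power_threshold = 0.5) {
  reference <- match.arg(reference)
  if (!(highpass_hz >= 0 && highpass_hz < lowpass_hz)) {
    stopf("need 0 <= highpass_hz < lowpass_hz (got %s, %s)", highpass_hz, lowpass_hz)
  }
  if (epoch_length <= 0) stopf("epoch_length must be > 0")
  if (ica_kurtosis_threshold < 0 || ica_highfreq_power_threshold < 0) {
    stopf("ICA rejection thresholds must be >= 0")
  }
  structure(list(highpass_hz = highpass_hz, lowpass_hz = lowpass_hz,
                 reference = reference, epoch_length = epoch_length,
                 ica_enabled = ica_enabled,
                 ica_kurtosis_threshold = ica_kurtosis_threshold,
                 ica_highfreq_power_threshold = ica_highfreq_power_threshold),
            class = "preprocess_config")
}

#' Zero-phase band-pass filter
#'
#' Applies a 4th-order Butterworth band-pass (forward-backward, so zero
#' phase and squared magnitude response) independently to each channel.
#'
#' @param rec An `eeg_recording`.
#' @param cfg A [preprocess_config()].
#' @return Filtered `eeg_recording` of the same shape.
#' @export
bandpass_filter <- function(rec, cfg) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(cfg, "preprocess_config"))
  fs <- 1 / rec$sampling_interval
  nyq <- fs / 2
  if (cfg$lowpass_hz >= nyq) {
    stopf("lowpass_hz = %g must be below the Nyquist frequency %g Hz",
          cfg$lowpass_hz, nyq)
  }
  bf <- signal::butter(4, c(max(cfg$highpass_hz, 1e-6), cfg$lowpass_hz) / nyq,
                       type = "pass")
  out <- rec$data
  for (ch in seq_len(nrow(out))) {
    out[ch, ] <- signal::filtfilt(bf, rec$data[ch, ])
  }
  log_stage("filter", sprintf("%g-%g Hz %s", cfg$highpass_hz, cfg$lowpass_hz,
                              content_digest(out)))
  new_recording(rec$subject_id, rec$label, out, rec$sampling_interval)
}

#' Common-average re-referencing
#'
#' Subtracts the instantaneous cross-channel mean at every time point, the
#' standard estimate of common-mode physiological and environmental noise.
#'
#' @param rec An `eeg_recording` (>= 2 channels).
#' @return Re-referenced `eeg_recording`; column means are ~0.
#' @export
rereference <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$data) < 2) stopf("re-referencing requires at least 2 channels")
  out <- sweep(rec$data, 2, colMeans(rec$data), `-`)
  log_stage("rereference", content_digest(out))
  new_recording(rec$subject_id, rec$label, out, rec$sampling_interval)
}

#' Cut a recording into consecutive non-overlapping epochs
#'
#' @param rec An `eeg_recording`.
#' @param cfg A [preprocess_config()]; `epoch_length` in seconds.
#' @return List of `eeg_recording` epochs (trailing remainder dropped);
#'   subject id and label are propagated.
#' @export
epoch_recording <- function(rec, cfg) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(cfg, "preprocess_config"))
  n_per <- round(cfg$epoch_length / rec$sampling_interval)
  n <- ncol(rec$data)
  if (n_per > n) {
    stopf("epoch_length %g s exceeds recording duration %g s",
          cfg$epoch_length, n * rec$sampling_interval)
  }
  k <- n %/% n_per
  lapply(seq_len(k), function(i) {
    idx <- ((i - 1L) * n_per + 1L):(i * n_per)
    new_recording(rec$subject_id, rec$label, rec$data[, idx, drop = FALSE],
                  rec$sampling_interval)
  })
}

# Symmetric fixed-point ICA with the logcosh negentropy contrast.
# Returns list(S = components x N, A = mixing channels x components,
# center, converged). Rank-deficient inputs reduce the component count;
# on non-convergence the iteration is restarted from fresh seeds before
# giving up (near-Gaussian components rotate freely and can stall the
# symmetric update).
fastica_decompose <- function(x, seed, max_iter = 500, tol = 1e-4,
                              restarts = 3) {
  center <- rowMeans(x)
  xc <- x - center
  n <- ncol(xc)
  cv <- tcrossprod(xc) / n
  eg <- eigen(cv, symmetric = TRUE)
  keep <- eg$values > max(eg$values) * 1e-9
  d <- eg$values[keep]
  E <- eg$vectors[, keep, drop = FALSE]
  K <- diag(1 / sqrt(d), nrow = length(d)) %*% t(E)     # whitening
  K_inv <- E %*% diag(sqrt(d), nrow = length(d))        # de-whitening
  z <- K %*% xc
  m <- nrow(z)

  sym_decor <- function(w) {
    sv <- eigen(tcrossprod(w), symmetric = TRUE)
    sv$vectors %*% diag(1 / sqrt(pmax(sv$values, 1e-12)), m) %*%
      t(sv$vectors) %*% w
  }
  run_once <- function(seed_k) {
    w <- with_seed(seed_k, matrix(stats::rnorm(m * m), m, m))
    w <- sym_decor(w)
    for (it in seq_len(max_iter)) {
      wz <- w %*% z
      g <- tanh(wz)
      gprime <- 1 - g^2
      w_new <- sym_decor(g %*% t(z) / n - diag(rowMeans(gprime), m) %*% w)
      delta <- max(abs(1 - abs(rowSums(w_new * w))))
      w <- w_new
      if (delta < tol) return(list(w = w, converged = TRUE))
    }
    list(w = w, converged = FALSE)
  }
  res <- NULL
  for (k in seq_len(restarts)) {
    res <- run_once(seed + (k - 1L) * 1000L)
    if (res$converged) break
  }
  s <- res$w %*% z
  a <- K_inv %*% t(res$w)   # x ~ a %*% s + center
  list(S = s, A = a, center = center, converged = res$converged)
}

fraction_power_above <- function(sig, fs, cutoff_hz = 30) {
  n <- length(sig)
  sp <- abs(stats::fft(sig - mean(sig)))^2
  half <- sp[seq_len(floor(n / 2) + 1L)]
  freqs <- (seq_along(half) - 1L) * fs / n
  tot <- sum(half)
  if (tot == 0) return(0)
  sum(half[freqs > cutoff_hz]) / tot
}

#' ICA-based artifact removal
#'
#' Decomposes the recording into statistically independent components with
#' a negentropy-maximising fixed-point algorithm (symmetric FastICA,
#' logcosh contrast), zeroes components flagged as artifactual -- excess
#' kurtosis above `ica_kurtosis_threshold` or more than
#' `ica_highfreq_power_threshold` of spectral power above 30 Hz -- and
#' reconstructs the signal from the retained components. When
#' `cfg$ica_enabled` is `FALSE` the input is returned untouched. If the
#' fixed-point iteration fails to converge within the iteration cap the
#' recording is returned unmodified with a warning.
#'
#' @param rec An `eeg_recording` of at least `min_seconds` duration.
#' @param cfg A [preprocess_config()].
#' @param seed Integer seed for the ICA initialisation (logged).
#' @param min_seconds Minimum duration for stable unmixing (default 10 s).
#' @return Cleaned `eeg_recording`; attribute `"ica_rejected"` lists the
#'   indices of zeroed components.
#' @export
ica_clean <- function(rec, cfg, seed = 1, min_seconds = 10) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(cfg, "preprocess_config"))
  if (!isTRUE(cfg$ica_enabled)) return(rec)
  if (recording_duration(rec) < min_seconds) {
    stopf("ICA requires a recording of at least %g s (got %.2f s)",
          min_seconds, recording_duration(rec))
  }
  dec <- fastica_decompose(rec$data, seed = seed)
  if (!dec$converged) {
    warning(sprintf(
      "ICA failed to converge for subject %s; recording returned unmodified",
      rec$subject_id), call. = FALSE)
    return(rec)
  }
  fs <- 1 / rec$sampling_interval
  kurt <- apply(dec$S, 1, e1071::kurtosis, type = 3)
  hi <- apply(dec$S, 1, fraction_power_above, fs = fs)
  reject <- which(kurt > cfg$ica_kurtosis_threshold |
                  hi > cfg$ica_highfreq_power_threshold)
  s_keep <- dec$S
  if (length(reject)) s_keep[reject, ] <- 0
  clean <- dec$A %*% s_keep + dec$center
  log_stage("ica", sprintf("seed=%d rejected=[%s] %s", seed,
                           paste(reject, collapse = ","), content_digest(clean)))
  out <- new_recording(rec$subject_id, rec$label, clean, rec$sampling_interval)
  attr(out, "ica_rejected") <- reject
  out
}

#' Run the full cleaning chain on one recording
#'
#' Pipeline order: band-pass filter, re-reference, then ICA cleaning.
#' The "uncleaned" analysis arm skips only the ICA stage -- filtering and
#' re-referencing still apply.
#'
#' @param rec An `eeg_recording`.
#' @param cfg A [preprocess_config()].
#' @param seed Seed forwarded to [ica_clean()].
#' @param arm `"cleaned"` (ICA on, subject to `cfg$ica_enabled`) or
#'   `"uncleaned"` (ICA skipped).
#' @return Preprocessed `eeg_recording`.
#' @export
preprocess_recording <- function(rec, cfg = preprocess_config(), seed = 1,
                                 arm = c("cleaned", "uncleaned")) {
  arm <- match.arg(arm)
  out <- bandpass_filter(rec, cfg)
  if (cfg$reference == "common_average") out <- rereference(out)
  if (arm == "cleaned") out <- ica_clean(out, cfg, seed = seed)
  out
}
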