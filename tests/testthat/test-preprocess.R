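test_that("band-pass attenuates DC and mains while passing mid-band signals", {
  dt <- 0.004; n <- 10000   # 40 s so 0.5 Hz high-pass transients die out
  tt <- (0:(n - 1)) * dt
  cfg <- preprocess_config(highpass_hz = 0.5, lowpass_hz = 40)
  run <- function(sig) {
    rec <- recording_from_matrix(matrix(rep(sig, each = 8), 8, byrow = FALSE))
    out <- bandpass_filter(rec, cfg)
    # steady-state amplitude, away from filtfilt edge transients
    max(abs(out$data[1, 4000:6000]))
  }
  expect_lt(run(rep(1, n)), 0.01)                       # DC outside passband
  expect_equal(run(sin(2 * pi * 10 * tt)), 1, tolerance = 0.05)
  expect_lt(run(sin(2 * pi * 60 * tt)), 0.2)
  bad <- preprocess_config(highpass_hz = 0.5, lowpass_hz = 200)
  expect_error(bandpass_filter(make_test_recording(), bad), "Nyquist")
})

test_that("filter responses match the design's frequency-response magnitude", {
  # filtfilt applies |H|^2; evaluate the Butterworth transfer function
  # directly from its polynomial coefficients (independent oracle)
  fs <- 250
  bf <- signal::butter(4, c(0.5, 40) / (fs / 2), type = "pass")
  H2 <- function(fq) {
    z <- exp(-1i * 2 * pi * fq / fs)
    num <- sum(bf$b * z^(seq_along(bf$b) - 1))
    den <- sum(bf$a * z^(seq_along(bf$a) - 1))
    Mod(num / den)^2
  }
  expect_equal(H2(10), 1, tolerance = 0.05)
  expect_lt(H2(60), 0.2)
  expect_lt(H2(0), 0.01)
})

test_that("common-average re-referencing zeroes the cross-channel mean", {
  m <- matrix(c(1, 3), 2, 1)
  two <- eegvit:::new_recording("X", "control", rbind(m, matrix(0, 6, 1)), 0.004)
  # direct two-channel example embedded in 8 channels: mean subtraction
  out <- rereference(two)
  expect_equal(out$data[1:2, 1], c(0.5, 2.5))   # mean of (1,3,0,...,0) = 0.5
  set.seed(5)
  rec <- recording_from_matrix(matrix(rnorm(800), 8, 100))
  ref <- rereference(rec)
  expect_true(all(abs(colMeans(ref$data)) < 1e-9))
  # invariance to common-mode offsets
  shifted <- recording_from_matrix(sweep(rec$data, 2, rnorm(100), `+`))
  expect_equal(rereference(shifted)$data, ref$data)
})

test_that("epoching partitions the recording and drops the remainder", {
  cfg <- preprocess_config(epoch_length = 2)
  rec <- make_test_recording(duration = 10)
  ep <- epoch_recording(rec, cfg)
  expect_length(ep, 5)
  rec2 <- make_test_recording(duration = 10.5)
  ep2 <- epoch_recording(rec2, cfg)
  expect_length(ep2, 5)
  rebuilt <- do.call(cbind, lapply(ep2, `[[`, "data"))
  expect_identical(rebuilt, rec2$data[, 1:2500])
  expect_identical(ep2[[1]]$subject_id, rec2$subject_id)
  expect_identical(ep2[[1]]$label, rec2$label)
  expect_error(epoch_recording(make_test_recording(duration = 1), cfg),
               "epoch_length")
})

test_that("ICA pass-through and near-identity modes behave as contracts state", {
  rec <- make_test_recording(duration = 12)
  off <- preprocess_config(ica_enabled = FALSE)
  expect_identical(ica_clean(rec, off, seed = 1), rec)
  # thresholds at infinity: reconstruction identity up to round-off
  lax <- preprocess_config(ica_kurtosis_threshold = Inf,
                           ica_highfreq_power_threshold = Inf)
  # near-Gaussian synthetic channels may legitimately fail to unmix; both
  # the converged and the warned-unmodified path must reduce to identity
  out <- suppressWarnings(ica_clean(rec, lax, seed = 1))
  expect_lt(max(abs(out$data - rec$data)) / max(abs(rec$data)), 1e-6)
  expect_error(ica_clean(make_test_recording(duration = 2),
                         preprocess_config(), seed = 1), "at least")
})

test_that("ICA recovers known sources and strips a heavy-tailed spike train", {
  set.seed(21)
  n <- 5000; dt <- 0.004
  tt <- (0:(n - 1)) * dt
  s1 <- sin(2 * pi * 10 * tt)
  spikes <- numeric(n)
  spikes[sample.int(n, 40)] <- 12 * sample(c(-1, 1), 40, TRUE)
  expect_gt(e1071::kurtosis(spikes), 20)
  mix <- matrix(rnorm(16), 8, 2)
  # noiseless mixture: the covariance has rank 2 and whitening reduces
  # the problem to exactly the two true sources
  x <- mix %*% rbind(s1, spikes)
  rec <- recording_from_matrix(x, dt = dt)

  dec <- eegvit:::fastica_decompose(x, seed = 2)
  expect_true(dec$converged)
  # permutation/sign-invariant matching: each true source must correlate
  # >= 0.95 in absolute value with some recovered component
  for (src in list(s1, spikes)) {
    cors <- apply(dec$S, 1, function(comp) abs(stats::cor(comp, src)))
    expect_gte(max(cors), 0.95)
  }

  cfg <- preprocess_config(ica_kurtosis_threshold = 10,
                           ica_highfreq_power_threshold = Inf)
  clean <- ica_clean(rec, cfg, seed = 2)
  # projected spike power via the known source: regress channels on spikes
  spike_pow <- function(dat) {
    sum(vapply(1:8, function(ch) {
      sum(stats::lm.fit(cbind(1, spikes), dat[ch, ])$fitted.values^2)
    }, 0))
  }
  expect_gt(spike_pow(rec$data) / spike_pow(clean$data), 10)
})

test_that("every preprocessing stage preserves channel count, subject and label", {
  rec <- make_test_recording(subject = "KEEP", label = "delirium",
                             duration = 12)
  cfg <- preprocess_config()
  for (f in list(function(r) bandpass_filter(r, cfg),
                 rereference,
                 function(r) suppressWarnings(ica_clean(r, cfg, seed = 3)),
                 function(r) suppressWarnings(preprocess_recording(r, cfg, seed = 3)))) {
    out <- f(rec)
    expect_identical(nrow(out$data), 8L)
    expect_identical(out$subject_id, "KEEP")
    expect_identical(out$label, "delirium")
  }
  # uncleaned arm: filtering + re-referencing applied, ICA skipped
  unc <- preprocess_recording(rec, cfg, seed = 3, arm = "uncleaned")
  expect_equal(unc$data, rereference(bandpass_filter(rec, cfg))$data)
})
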