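# Shared fixtures and independent oracles for the test suite.

# Independent periodogram oracle: power per DFT bin with frequencies,
# written directly against stats::fft (never via package spectral code).
oracle_periodogram <- function(x, fs) {
  n <- length(x)
  p <- abs(stats::fft(x))^2 / n
  half <- seq_len(floor(n / 2) + 1L)
  list(freq = (half - 1L) * fs / n, power = p[half])
}

oracle_band_power <- function(x, fs, lo, hi) {
  pg <- oracle_periodogram(x - mean(x), fs)
  sum(pg$power[pg$freq >= lo & pg$freq <= hi])
}

# Hand-evaluated corner-aligned bilinear interpolant at one point
# (u, v are fractional 0-based source coordinates).
oracle_bilinear_point <- function(src, u, v) {
  i0 <- min(floor(u), nrow(src) - 2); j0 <- min(floor(v), ncol(src) - 2)
  a <- u - i0; b <- v - j0
  (1 - a) * (1 - b) * src[i0 + 1, j0 + 1] + (1 - a) * b * src[i0 + 1, j0 + 2] +
    a * (1 - b) * src[i0 + 2, j0 + 1] + a * b * src[i0 + 2, j0 + 2]
}

oracle_bilinear_resize <- function(src, R, C) {
  out <- matrix(0, R, C)
  for (i in seq_len(R)) for (j in seq_len(C)) {
    u <- if (R == 1) 0 else (i - 1) * (nrow(src) - 1) / (R - 1)
    v <- if (C == 1) 0 else (j - 1) * (ncol(src) - 1) / (C - 1)
    out[i, j] <- oracle_bilinear_point(src, u, v)
  }
  out
}

# Brute-force enumeration of valid slice start rows (0-based).
oracle_slice_starts <- function(N, n_rows, stride) {
  starts <- integer(0)
  s <- 0L
  while (s + n_rows <= N) { starts <- c(starts, s); s <- s + stride }
  starts
}

# Tiny deterministic recording fixture.
make_test_recording <- function(subject = "T01", label = "control",
                                duration = 10, seed = 404, noise_sd = 0.3) {
  generate_recording(
    subject_profile(subject, label, noise_sd = noise_sd),
    duration = duration, seed = seed)
}

# Recording with fully specified data matrix.
recording_from_matrix <- function(data, subject = "M01", label = "control",
                                  dt = 0.004) {
  eegvit:::new_recording(subject, label, data, dt)
}

# Synthetic wave-image fixture (bare pixels wrapped with a label).
make_test_image <- function(pixels, label) {
  structure(list(pixels = pixels, side = nrow(pixels), domain = "time",
                 source = list(subject_id = "img", label = label,
                               origin_row = 0L)),
            class = "wave_image")
}

# Micro ViT configuration for fast structural tests.
micro_vit <- function(...) {
  do.call(vit_config, utils::modifyList(
    list(image_side = 32, patch_side = 8, embed_dim = 32, depth = 1,
         heads = 2, mlp_ratio = 2, n_classes = 2, batch_size = 16,
         learning_rate = 0.001, epochs = 2, seed = 7), list(...)))
}
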