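# Corner-aligned bilinear interpolation weights: output sample i (0-based,
# D outputs) reads source position i * (S - 1) / (D - 1), so source corners
# map exactly onto destination corners.
bilinear_weights <- function(n_src, n_dst) {
  w <- matrix(0, n_dst, n_src)
  if (n_src == 1L) { w[, 1] <- 1; return(w) }
  pos <- if (n_dst == 1L) 0 else (seq_len(n_dst) - 1) * (n_src - 1) / (n_dst - 1)
  lo <- pmin(floor(pos), n_src - 2)
  frac <- pos - lo
  for (i in seq_len(n_dst)) {
    w[i, lo[i] + 1L] <- 1 - frac[i]
    w[i, lo[i] + 2L] <- frac[i]
  }
  w
}

#' Separable corner-aligned bilinear resize
#'
#' @param x Numeric matrix.
#' @param out_rows,out_cols Target dimensions.
#' @return `out_rows x out_cols` matrix; every output pixel is a convex
#'   combination of the four surrounding source pixels.
#' @export
bilinear_resize <- function(x, out_rows, out_cols) {
  stopifnot(is.matrix(x), out_rows >= 1, out_cols >= 1)
  assert_finite(x, "resize input")
  bilinear_weights(nrow(x), out_rows) %*% x %*% t(bilinear_weights(ncol(x), out_cols))
}

new_wave_image <- function(pixels, domain, source) {
  structure(list(pixels = pixels, side = nrow(pixels), domain = domain,
                 source = source), class = "wave_image")
}

# Min-max normalization to [0, 1]; constant images map to 0.5.
normalize_pixels <- function(px) {
  rng <- range(px)
  if (rng[2] - rng[1] < .Machine$double.eps * max(1, abs(rng[2]))) {
    return(matrix(0.5, nrow(px), ncol(px)))
  }
  (px - rng[1]) / (rng[2] - rng[1])
}

slice_source <- function(slice) {
  list(subject_id = slice$subject_id, label = slice$label,
       origin_row = slice$origin_row)
}

#' Render a data slice as a time-domain wave image
#'
#' The 8 x n slice is resized to `side x side` by separable corner-aligned
#' bilinear interpolation and min-max normalized to `[0, 1]` per slice
#' (constant slices map to 0.5). The 8 channels become the rows of one
#' grayscale image.
#'
#' @param slice A `data_slice` with finite data.
#' @param side Image side in pixels (>= 16; 224 matches the standard ViT
#'   input, 64 the desk preset).
#' @return A `wave_image` with `domain = "time"`.
#' @export
slice_to_image <- function(slice, side = 224) {
  stopifnot(inherits(slice, "data_slice"))
  if (side < 16) stopf("image side must be >= 16 (got %d)", side)
  assert_finite(slice$data, "slice data")
  px <- bilinear_resize(slice$data, side, side)
  new_wave_image(normalize_pixels(px), "time", slice_source(slice))
}

#' Render a data slice as a frequency-domain (spectral) image
#'
#' Per channel, the magnitude of the one-sided discrete Fourier transform
#' (length `floor(n/2) + 1`) is computed and compressed as `log(1 + |X|)`;
#' the resulting 8 x (n/2 + 1) array is then resized and normalized exactly
#' like [slice_to_image()], so both domains yield images of identical shape
#' and intensity range.
#'
#' @inheritParams slice_to_image
#' @return A `wave_image` with `domain = "frequency"`.
#' @export
slice_to_spectral_image <- function(slice, side = 224) {
  stopifnot(inherits(slice, "data_slice"))
  n <- slice$n_rows
  if (n < 2) stopf("spectral image needs n_rows >= 2 (got %d)", n)
  if (side < 16) stopf("image side must be >= 16 (got %d)", side)
  assert_finite(slice$data, "slice data")
  n_half <- floor(n / 2) + 1L
  spec <- t(apply(slice$data, 1, function(ch) {
    abs(stats::fft(ch))[seq_len(n_half)]
  }))
  px <- bilinear_resize(log1p(spec), side, side)
  new_wave_image(normalize_pixels(px), "frequency", slice_source(slice))
}

#' @export
print.wave_image <- function(x, ...) {
  cat(sprintf("<wave_image> %dx%d (%s domain) subject %s label %s origin %d\n",
              x$side, x$side, x$domain, x$source$subject_id %||% "?",
              x$source$label %||% "?", x$source$origin_row %||% -1L))
  invisible(x)
}

#' Write a wave image as an 8-bit grayscale PNG
#'
#' @param img A `wave_image`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the path written; the filename embeds provenance
#'   (subject, label, origin row, domain).
#' @export
write_wave_png <- function(img, dir = ".") {
  stopifnot(inherits(img, "wave_image"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, sprintf("%s_%s_row%06d_%s.png",
                                 img$source$subject_id %||% "unknown",
                                 img$source$label %||% "unlabelled",
                                 img$source$origin_row %||% 0L, img$domain))
  png::writePNG(img$pixels, target = path)
  invisible(path)
}
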