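#' Rows needed for a slice duration
#'
#' A data slice is an 8 x n window of samples; at a 4 ms sampling interval,
#' a 1 s slice holds 250 rows and a 5 s slice holds 1250 rows. Non-integer
#' ratios are rounded down with a message.
#'
#' @param time_span Slice duration in seconds (> 0).
#' @param sampling_interval Seconds per sample (> 0).
#' @return Integer number of rows.
#' @export
rows_for_duration <- function(time_span, sampling_interval = 0.004) {
  if (!is.numeric(time_span) || time_span <= 0) stopf("time_span must be > 0")
  if (!is.numeric(sampling_interval) || sampling_interval <= 0) {
    stopf("sampling_interval must be > 0")
  }
  ratio <- time_span / sampling_interval
  n <- floor(ratio + 1e-9)
  if (abs(ratio - n) > 1e-6) {
    message(sprintf("time_span %g s is not a multiple of %g s; using %d rows",
                    time_span, sampling_interval, n))
  }
  as.integer(n)
}

#' Minimum detectable frequency of a slice
#'
#' A window of span T seconds contains a full cycle only of frequencies at
#' or above 1/T Hz; slower waves appear as incomplete trends. This is the
#' mechanism linking slice length to which EEG bands a wave image can
#' represent: a 0.1 s slice resolves nothing below 10 Hz, a 5 s slice
#' resolves down to 0.2 Hz.
#'
#' @param time_span Slice duration in seconds (> 0).
#' @return Frequency in Hz (`1 / time_span`).
#' @export
min_detectable_frequency <- function(time_span) {
  if (!is.numeric(time_span) || any(time_span <= 0)) {
    stopf("time_span must be > 0")
  }
  1 / time_span
}

#' Stride between consecutive overlapping slices
#'
#' `stride = round(n_rows * (1 - overlap_ratio))`, rounding half away from
#' zero and floored at 1; consecutive slices then share `n_rows - stride`
#' rows.
#'
#' @param n_rows Slice length in rows (>= 1).
#' @param overlap_ratio Fraction of rows shared, in `[0, 1)`.
#' @return Integer stride.
#' @export
stride_for_overlap <- function(n_rows, overlap_ratio) {
  if (!(is.numeric(n_rows) && n_rows >= 1)) stopf("n_rows must be >= 1")
  if (!(is.numeric(overlap_ratio) && overlap_ratio >= 0 && overlap_ratio < 1)) {
    stopf("overlap_ratio must lie in [0, 1): stride would be 0 at ratio >= 1")
  }
  s <- floor(n_rows * (1 - overlap_ratio) + 0.5)   # round half away from zero
  as.integer(max(1, s))
}

new_data_slice <- function(subject_id, label, data, origin_row,
                           sampling_interval) {
  structure(list(subject_id = subject_id, label = label, data = data,
                 n_rows = ncol(data), time_span = ncol(data) * sampling_interval,
                 origin_row = origin_row, sampling_interval = sampling_interval),
            class = "data_slice")
}

#' Cut a recording into overlapping data slices
#'
#' Slices start at 0-based origin rows `0, s, 2s, ...` (half-open windows
#' `[origin, origin + n_rows)`) while a full window fits, giving
#' `floor((N - n_rows) / s) + 1` slices. Each slice inherits the
#' recording's subject id and label.
#'
#' @param rec An `eeg_recording` with N samples.
#' @param n_rows Slice length in rows (`<= N`).
#' @param overlap_ratio Fraction of shared rows, see [stride_for_overlap()].
#' @return List of `data_slice` objects.
#' @export
make_slices <- function(rec, n_rows, overlap_ratio = 0.9) {
  stopifnot(inherits(rec, "eeg_recording"))
  n_total <- ncol(rec$data)
  if (n_rows > n_total) {
    stopf("n_rows = %d exceeds recording length %d (subject %s)",
          n_rows, n_total, rec$subject_id)
  }
  s <- stride_for_overlap(n_rows, overlap_ratio)
  starts <- seq.int(0L, n_total - n_rows, by = s)
  lapply(starts, function(o) {
    new_data_slice(rec$subject_id, rec$label,
                   rec$data[, (o + 1L):(o + n_rows), drop = FALSE],
                   origin_row = o, sampling_interval = rec$sampling_interval)
  })
}

slice_labels <- function(slices) vapply(slices, `[[`, "", "label")
slice_subjects <- function(slices) vapply(slices, `[[`, "", "subject_id")

#' Subject-grouped train/test split
#'
#' Subjects -- never individual slices -- are randomly assigned to sides,
#' so that no subject contributes slices to both the training and the test
#' set. This is the only split that prevents leakage through overlapping
#' windows. Each side is guaranteed at least one subject of each class.
#'
#' @param slices List of `data_slice` (>= 2 subjects, both classes present).
#' @param test_fraction Approximate fraction of subjects held out.
#' @param seed Integer seed; assignment is deterministic given it.
#' @return A `split_assignment`: lists `train_slices`/`test_slices`,
#'   character vectors `train_subjects`/`test_subjects`, and the seed.
#' @export
split_by_subject <- function(slices, test_fraction = 0.25, seed = 1) {
  subj <- slice_subjects(slices)
  lab <- slice_labels(slices)
  subj_lab <- tapply(lab, subj, function(l) unique(l)[1])
  ids <- names(subj_lab)
  if (length(ids) < 2) stopf("need at least 2 subjects to split")
  if (length(unique(subj_lab)) < 2) {
    stopf("both classes must be present among subjects")
  }
  n_test <- max(1L, round(length(ids) * test_fraction))
  if (n_test >= length(ids)) stopf("test_fraction leaves no training subjects")
  # class coverage must be possible on both sides
  for (cl in c("delirium", "control")) {
    if (sum(subj_lab == cl) < 2) {
      stopf(paste0("cannot cover class '%s' on both sides: only %d subject(s); ",
                   "a grouped split would leak or leave a side without the class"),
            cl, sum(subj_lab == cl))
    }
  }
  if (n_test < 2 || length(ids) - n_test < 2) {
    stopf(paste0("test_fraction = %g yields %d test subject(s) out of %d; ",
                 "each side needs at least one subject per class (>= 2 subjects)"),
          test_fraction, n_test, length(ids))
  }
  test_ids <- with_seed(seed, {
    repeat {
      cand <- sample(ids, n_test)
      cl_test <- subj_lab[cand]
      cl_train <- subj_lab[setdiff(ids, cand)]
      if (length(unique(cl_test)) == 2 && length(unique(cl_train)) == 2) break
    }
    cand
  })
  train_ids <- setdiff(ids, test_ids)
  structure(list(train_subjects = sort(train_ids),
                 test_subjects = sort(test_ids),
                 train_slices = slices[subj %in% train_ids],
                 test_slices = slices[subj %in% test_ids],
                 seed = seed),
            class = "split_assignment")
}

#' Balance classes by down-sampling the majority class
#'
#' Randomly removes majority-class slices (without replacement) until the
#' positive:negative ratio reaches `target_ratio` (default 1). Applied
#' independently to the training and test sides after splitting, so the
#' test set is never informed by training-set counts.
#'
#' @param slices List of `data_slice` with both classes present.
#' @param seed Integer seed.
#' @param target_ratio Desired majority:minority ratio (>= 1).
#' @return Down-sampled list of slices (original order preserved).
#' @export
balance_classes <- function(slices, seed = 1, target_ratio = 1) {
  lab <- slice_labels(slices)
  tab <- table(factor(lab, levels = c("control", "delirium")))
  if (any(tab == 0)) stopf("both classes must be present to balance")
  minority <- names(tab)[which.min(tab)]
  majority <- setdiff(names(tab), minority)
  n_keep <- min(tab[[majority]], ceiling(tab[[minority]] * target_ratio))
  if (tab[[majority]] <= n_keep) return(slices)
  maj_idx <- which(lab == majority)
  keep_maj <- with_seed(seed, sort(sample(maj_idx, n_keep)))
  slices[sort(c(which(lab == minority), keep_maj))]
}

#' Export a slice manifest for audit
#'
#' @param slices List of `data_slice`.
#' @param side Optional split-side tag recycled across rows.
#' @return A data.frame (subject_id, label, origin_row, n_rows, side).
#' @export
slice_manifest <- function(slices, side = NA_character_) {
  data.frame(subject_id = slice_subjects(slices),
             label = slice_labels(slices),
             origin_row = vapply(slices, `[[`, 0, "origin_row"),
             n_rows = vapply(slices, `[[`, 0L, "n_rows"),
             side = side,
             stringsAsFactors = FALSE)
}
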