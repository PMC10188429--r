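test_that("rows_for_duration reproduces the printed duration-to-rows table", {
  # 25 rows = 0.1 s, 125 = 0.5 s, 250 = 1 s, 400 = 1.6 s, 1250 = 5 s at 4 ms
  expect_identical(rows_for_duration(0.1, 0.004), 25L)
  expect_identical(rows_for_duration(0.5, 0.004), 125L)
  expect_identical(rows_for_duration(1, 0.004), 250L)
  expect_identical(rows_for_duration(1.6, 0.004), 400L)
  expect_identical(rows_for_duration(5, 0.004), 1250L)
  expect_identical(rows_for_duration(0.004, 0.004), 1L)
  expect_error(rows_for_duration(-1, 0.004), "time_span")
})

test_that("min_detectable_frequency is 1/T at the studied spans", {
  expect_equal(min_detectable_frequency(0.1), 10)
  expect_equal(min_detectable_frequency(5), 0.2)
  expect_equal(min_detectable_frequency(1), 1)
  expect_error(min_detectable_frequency(0), "time_span")
  # identity: composition with rows_for_duration recovers 1/T
  for (T in c(0.1, 0.5, 1, 1.6, 5)) {
    n <- rows_for_duration(T, 0.004)
    expect_equal(min_detectable_frequency(n * 0.004), 1 / T)
  }
})

test_that("stride arithmetic matches enumeration of shared rows", {
  expect_identical(stride_for_overlap(250, 0), 250L)
  expect_identical(stride_for_overlap(250, 0.3), 175L)
  expect_identical(stride_for_overlap(1250, 0.9), 125L)
  expect_error(stride_for_overlap(250, 1), "overlap_ratio")
  # consecutive slices share exactly n - stride origin rows
  rec <- make_test_recording(duration = 2)
  sl <- make_slices(rec, 250, 0.3)
  rows1 <- sl[[1]]$origin_row + seq_len(250) - 1L
  rows2 <- sl[[2]]$origin_row + seq_len(250) - 1L
  expect_length(intersect(rows1, rows2), 75)
  sl9 <- make_slices(make_test_recording(duration = 10), 1250, 0.9)
  expect_equal(diff(vapply(sl9, `[[`, 0, "origin_row"))[1], 125)
})

test_that("slice counts match brute-force start-row enumeration", {
  rec <- recording_from_matrix(matrix(rnorm(8 * 2000), 8))
  for (N in c(250, 777, 1000, 2000)) {
    sub <- recording_from_matrix(rec$data[, seq_len(N), drop = FALSE])
    for (n_rows in c(25, 250, N)) {
      if (n_rows > N) next
      for (ov in c(0, 0.3, 0.5, 0.75, 0.9, 0.95)) {
        s <- stride_for_overlap(n_rows, ov)
        sl <- make_slices(sub, n_rows, ov)
        starts <- oracle_slice_starts(N, n_rows, s)
        expect_identical(vapply(sl, `[[`, 0, "origin_row"), as.numeric(starts))
        expect_length(sl, floor((N - n_rows) / s) + 1)
      }
    }
  }
  expect_length(make_slices(recording_from_matrix(matrix(0, 8, 250)), 250, 0.9), 1)
  expect_error(make_slices(recording_from_matrix(matrix(0, 8, 100)), 250, 0.9),
               "M01")
})

test_that("non-overlapping slices reconstruct the recording prefix", {
  rec <- make_test_recording(duration = 4.3)
  sl <- make_slices(rec, 250, 0)
  rebuilt <- do.call(cbind, lapply(sl, `[[`, "data"))
  expect_identical(rebuilt, rec$data[, seq_len(ncol(rebuilt))])
})

test_that("subject-grouped splits are disjoint, class-covering and deterministic", {
  co <- generate_cohort(n_subjects = 12, duration = 2, seed = 2)
  slices <- unlist(lapply(co, make_slices, n_rows = 125, overlap_ratio = 0),
                   recursive = FALSE)
  sp <- split_by_subject(slices, 0.25, seed = 42)
  expect_length(sp$test_subjects, 3)
  expect_length(sp$train_subjects, 9)
  expect_length(intersect(sp$train_subjects, sp$test_subjects), 0)
  lab_of <- function(s) vapply(s, `[[`, "", "label")
  expect_setequal(unique(lab_of(sp$test_slices)), c("delirium", "control"))
  expect_setequal(unique(lab_of(sp$train_slices)), c("delirium", "control"))
  sp2 <- split_by_subject(slices, 0.25, seed = 42)
  expect_identical(sp$test_subjects, sp2$test_subjects)
})

test_that("no subject leaks between sides over many random seeds", {
  co <- generate_cohort(n_subjects = 8, duration = 1, seed = 9)
  slices <- unlist(lapply(co, make_slices, n_rows = 50, overlap_ratio = 0.5),
                   recursive = FALSE)
  for (seed in 1:100) {
    sp <- split_by_subject(slices, 0.3, seed = seed)
    test_subj <- unique(vapply(sp$test_slices, `[[`, "", "subject_id"))
    train_subj <- unique(vapply(sp$train_slices, `[[`, "", "subject_id"))
    expect_length(intersect(test_subj, train_subj), 0)
  }
})

test_that("class balancing down-samples to the stated ratio without duplication", {
  mk <- function(lab, i) {
    s <- make_slices(recording_from_matrix(matrix(i, 8, 25),
                                           subject = paste0(lab, i),
                                           label = lab), 25, 0)[[1]]
    s
  }
  slices <- c(lapply(1:10, mk, lab = "delirium"), lapply(1:5, mk, lab = "control"))
  bal <- balance_classes(slices, seed = 1)
  labs <- vapply(bal, `[[`, "", "label")
  expect_equal(sum(labs == "delirium"), 5)
  expect_equal(sum(labs == "control"), 5)
  ids <- paste(vapply(bal, `[[`, "", "subject_id"),
               vapply(bal, `[[`, 0, "origin_row"))
  expect_false(anyDuplicated(ids) > 0)
  # already balanced input passes through
  expect_length(balance_classes(bal, seed = 2), 10)
  # heavily imbalanced input lands within the stated band
  big <- c(lapply(1:100, mk, lab = "delirium"), lapply(1:10, mk, lab = "control"))
  labs2 <- vapply(balance_classes(big, seed = 3), `[[`, "", "label")
  ratio <- sum(labs2 == "delirium") / sum(labs2 == "control")
  expect_gte(ratio, 1 / 1.5); expect_lte(ratio, 1.5)
  expect_error(balance_classes(lapply(1:3, mk, lab = "control"), 1), "class")
})
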