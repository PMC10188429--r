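# Recording I/O: a plain-CSV dialect (self-describing header comments),
# a minimal EDF reader/writer (16-bit, one data record), and cohort
# manifests tying files to subject ids and labels.

#' Write a recording as CSV
#'
#' Rows are time points and the 8 channels are columns `ch1..ch8`; subject
#' id, label and sampling interval are carried in `#`-prefixed header
#' lines, so the file round-trips without external metadata.
#'
#' @param rec An `eeg_recording`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# subject_id: %s", rec$subject_id),
               sprintf("# label: %s", rec$label),
               sprintf("# sampling_interval: %.17g", rec$sampling_interval),
               paste(sprintf("ch%d", 1:8), collapse = ",")), con)
  # %.17g keeps doubles bit-exact through the round-trip
  vals <- matrix(sprintf("%.17g", t(rec$data)), ncol(rec$data), 8)
  writeLines(apply(vals, 1, paste, collapse = ","), con)
  invisible(path)
}

#' Read a recording from the package CSV dialect
#'
#' @param path CSV file written by [write_recording_csv()].
#' @return An `eeg_recording`.
#' @export
read_recording_csv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  hdr <- readLines(path, n = 10)
  meta <- hdr[startsWith(hdr, "# ")]
  get_meta <- function(key) {
    ln <- grep(sprintf("^# %s:", key), meta, value = TRUE)
    if (!length(ln)) stopf("%s: missing '# %s:' header line", path, key)
    trimws(sub(sprintf("^# %s:", key), "", ln[1]))
  }
  dat <- utils::read.csv(path, comment.char = "#")
  if (ncol(dat) != 8) {
    stopf("%s: expected exactly 8 channel columns, found %d", path, ncol(dat))
  }
  data <- t(as.matrix(dat))
  dimnames(data) <- NULL
  new_recording(get_meta("subject_id"), get_meta("label"),
                data, as.numeric(get_meta("sampling_interval")))
}

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  formatC(s, width = width, flag = "-")
}

#' Write a recording as EDF (European Data Format)
#'
#' A minimal EDF writer: all samples go into a single data record whose
#' duration equals the recording length; each channel is scaled to the
#' full 16-bit digital range. The subject id is stored in the patient
#' field. EDF has no label field, so class labels travel in the cohort
#' manifest.
#'
#' @param rec An `eeg_recording`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_recording_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  ns <- nrow(rec$data)
  n <- ncol(rec$data)
  pmin <- apply(rec$data, 1, min)
  pmax <- apply(rec$data, 1, max)
  flat <- pmax - pmin < 1e-12
  pmax[flat] <- pmin[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(pad_field(x, width), con, nchars = width,
                                     eos = NULL)
  wr("0", 8)
  wr(rec$subject_id, 80)
  wr("eegvit synthetic cohort", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256 + ns * 256, 8)
  wr("", 44)
  wr(1, 8)                                   # one data record
  wr(sprintf("%.6g", n * rec$sampling_interval), 8)
  wr(ns, 4)
  for (f in list(list(sprintf("ch%d", seq_len(ns)), 16),
                 list(rep("synthetic", ns), 80),
                 list(rep("uV", ns), 8),
                 list(sprintf("%.6g", pmin), 8),
                 list(sprintf("%.6g", pmax), 8),
                 list(rep(dmin, ns), 8),
                 list(rep(dmax, ns), 8),
                 list(rep("none", ns), 80),
                 list(rep(n, ns), 8),
                 list(rep("", ns), 32))) {
    for (v in f[[1]]) wr(v, f[[2]])
  }
  for (ch in seq_len(ns)) {
    dig <- round((rec$data[ch, ] - pmin[ch]) / (pmax[ch] - pmin[ch]) *
                   (dmax - dmin) + dmin)
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Supports the subset written by [write_recording_edf()] plus standard
#' multi-record EDF with a uniform sampling rate across the 8 signals.
#'
#' @param path EDF file.
#' @param label Class label (`"delirium"`/`"control"`), normally supplied
#'   from the cohort manifest; EDF itself carries none.
#' @return An `eeg_recording`.
#' @export
read_recording_edf <- function(path, label = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8)                                      # version
  subject_id <- rd(80)
  rd(80); rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns != 8) {
    stopf("%s: expected exactly 8 signal channels, header reports %s", path, ns)
  }
  fields <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  fields(16); fields(80); fields(8)
  pmin <- as.numeric(fields(8)); pmax <- as.numeric(fields(8))
  dmin <- as.numeric(fields(8)); dmax <- as.numeric(fields(8))
  fields(80)
  spr <- as.integer(fields(8))
  fields(32)
  if (length(unique(spr)) != 1) {
    stopf("%s: non-uniform sampling across channels (samples/record: %s)",
          path, paste(unique(spr), collapse = ", "))
  }
  n_per <- spr[1]
  data <- matrix(0, ns, n_per * n_rec)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = n_per, size = 2, endian = "little")
      if (length(dig) != n_per) stopf("%s: truncated data record %d", path, r)
      phys <- (dig - dmin[ch]) / (dmax[ch] - dmin[ch]) *
        (pmax[ch] - pmin[ch]) + pmin[ch]
      data[ch, ((r - 1) * n_per + 1):(r * n_per)] <- phys
    }
  }
  if (is.null(label)) {
    stopf("%s: EDF carries no class label; supply one (e.g. from the cohort manifest)",
          path)
  }
  new_recording(subject_id, label, data, rec_dur / n_per)
}

#' Read a recording from CSV or EDF
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"csv"` or `"edf"`.
#' @param label Label for EDF inputs (CSV embeds its own).
#' @return An `eeg_recording`.
#' @export
read_recording <- function(path, format = c("auto", "csv", "edf"),
                           label = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  if (format == "csv") read_recording_csv(path) else
    read_recording_edf(path, label = label)
}

#' Write a cohort plus its manifest
#'
#' One file per recording plus `manifest.csv` with columns subject_id,
#' label, path.
#'
#' @param cohort List of `eeg_recording`s.
#' @param dir Output directory (created).
#' @param format `"csv"` or `"edf"`.
#' @return Invisibly, the manifest data.frame.
#' @export
write_cohort <- function(cohort, dir, format = c("csv", "edf")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(rec) {
    fn <- file.path(dir, sprintf("%s.%s", rec$subject_id, format))
    if (format == "csv") write_recording_csv(rec, fn) else
      write_recording_edf(rec, fn)
    data.frame(subject_id = rec$subject_id, label = rec$label, path = fn,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Load a cohort from its manifest
#'
#' @param manifest_path Path to a manifest CSV (subject_id, label, path).
#' @return List of `eeg_recording`s (class `eeg_cohort`).
#' @export
read_cohort <- function(manifest_path) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "label", "path")
  if (!all(need %in% names(man))) {
    stopf("manifest %s must contain columns %s", manifest_path,
          paste(need, collapse = ", "))
  }
  if (anyNA(man$label) || any(man$label == "")) {
    bad <- man$subject_id[is.na(man$label) | man$label == ""]
    stopf("manifest %s: missing label for subject(s) %s", manifest_path,
          paste(bad, collapse = ", "))
  }
  recs <- lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) {
      p2 <- file.path(dirname(manifest_path), basename(p))
      if (file.exists(p2)) p <- p2 else stopf("manifest entry not found: %s", p)
    }
    rec <- read_recording(p, label = man$label[i])
    if (rec$subject_id != man$subject_id[i]) {
      rec$subject_id <- man$subject_id[i]
    }
    rec
  })
  structure(recs, class = "eeg_cohort")
}
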