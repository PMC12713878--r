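#' Read an airflow trace from CSV or EDF
#'
#' CSV files must have a header `time_s,flow` on a uniform time grid
#' (inspiration positive, linear units). EDF files are read with a built-in
#' minimal EDF parser (fixed-layout ASCII headers, 16-bit samples, physical
#' calibration applied); the channel is selected by its header label.
#'
#' @param path Path to a `.csv` or `.edf` file.
#' @param flow_channel EDF channel label (required for EDF input).
#' @param check_filters For EDF input, warn when the channel's prefilter
#'   header reports a low-pass cutoff below 12.5 Hz, which distorts
#'   breath-level flow morphology.
#' @return A tibble `time_s`, `flow` with attribute `sampling_rate` (Hz).
#' @export
read_flow <- function(path, flow_channel = NULL, check_filters = FALSE) {
  if (!file.exists(path)) stop_input(sprintf("file not found: %s", path))
  if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    if (is.null(flow_channel)) stop_input("`flow_channel` is required for EDF input")
    read_edf_channel(path, flow_channel, check_filters = check_filters)
  } else {
    read_flow_csv(path)
  }
}

read_flow_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    time_s = readr::col_double(), flow = readr::col_double()
  ), progress = FALSE)
  if (!all(c("time_s", "flow") %in% names(df))) {
    stop_input("flow CSV must have header columns `time_s, flow`")
  }
  dt <- diff(df$time_s)
  med <- median(dt)
  if (!is.finite(med) || med <= 0) stop_input("non-increasing time column")
  if (max(abs(dt - med)) / med > 0.01) {
    stop_input("non-uniform time step: jitter exceeds 1% of the sampling interval")
  }
  out <- tibble::tibble(time_s = df$time_s, flow = df$flow)
  attr(out, "sampling_rate") <- 1 / med
  out
}

# -- minimal EDF support ------------------------------------------------------
# EDF stores a 256-byte ASCII global header, 256 ASCII bytes per signal of
# channel metadata, then data records of little-endian int16 samples. Only
# reading is supported; the writer below is an internal fixture builder.

read_chars <- function(con, n) trimws(rawToChar(readBin(con, "raw", n)))

read_edf_header <- function(con) {
  hdr <- list(
    version = read_chars(con, 8), patient = read_chars(con, 80),
    recording = read_chars(con, 80), startdate = read_chars(con, 8),
    starttime = read_chars(con, 8), header_bytes = as.integer(read_chars(con, 8)),
    reserved = read_chars(con, 44), n_records = as.integer(read_chars(con, 8)),
    record_duration = as.numeric(read_chars(con, 8)),
    n_signals = as.integer(read_chars(con, 4))
  )
  ns <- hdr$n_signals
  field <- function(w) vapply(seq_len(ns), function(i) read_chars(con, w), character(1))
  hdr$labels <- field(16)
  hdr$transducer <- field(80)
  hdr$phys_dim <- field(8)
  hdr$phys_min <- as.numeric(field(8))
  hdr$phys_max <- as.numeric(field(8))
  hdr$dig_min <- as.numeric(field(8))
  hdr$dig_max <- as.numeric(field(8))
  hdr$prefilter <- field(80)
  hdr$samples_per_record <- as.integer(field(8))
  hdr$sig_reserved <- field(32)
  hdr
}

read_edf_channel <- function(path, channel, check_filters = FALSE) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- read_edf_header(con)
  ci <- which(hdr$labels == channel)
  if (length(ci) != 1) {
    stop_input(sprintf("channel not found: '%s' (available: %s)",
                       channel, paste(hdr$labels, collapse = ", ")))
  }
  if (check_filters) {
    lp <- regmatches(hdr$prefilter[ci],
                     regexpr("LP[: ]*([0-9.]+)", hdr$prefilter[ci]))
    if (length(lp) == 1) {
      cutoff <- as.numeric(sub("LP[: ]*", "", lp))
      if (is.finite(cutoff) && cutoff < 12.5) {
        warn(sprintf(
          "flow channel '%s' low-pass filtered at %.1f Hz (< 12.5 Hz); breath morphology may be distorted",
          channel, cutoff
        ))
      }
    }
  }
  spr <- hdr$samples_per_record
  rec_len <- sum(spr)
  samples <- numeric(hdr$n_records * spr[ci])
  offset <- c(0, cumsum(spr))[ci]
  for (r in seq_len(hdr$n_records)) {
    rec <- readBin(con, "integer", n = rec_len, size = 2, endian = "little")
    samples[((r - 1) * spr[ci] + 1):(r * spr[ci])] <- rec[(offset + 1):(offset + spr[ci])]
  }
  scale <- (hdr$phys_max[ci] - hdr$phys_min[ci]) / (hdr$dig_max[ci] - hdr$dig_min[ci])
  phys <- (samples - hdr$dig_min[ci]) * scale + hdr$phys_min[ci]
  fs <- spr[ci] / hdr$record_duration
  out <- tibble::tibble(time_s = (seq_along(phys) - 1) / fs, flow = phys)
  attr(out, "sampling_rate") <- fs
  out
}

# internal EDF writer for building test fixtures programmatically;
# signals: named list of numeric vectors (equal duration), one value set of
# physical calibration per signal inferred from its range
write_edf <- function(path, signals, sampling_rate, record_duration = 1,
                      prefilter = "") {
  ns <- length(signals)
  spr <- as.integer(sampling_rate * record_duration)
  n_records <- as.integer(floor(length(signals[[1]]) / spr))
  prefilter <- rep_len(prefilter, ns)
  pad <- function(x, w) {
    s <- substr(as.character(x), 1, w)
    paste0(s, strrep(" ", w - nchar(s)))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    pad("0", 8), pad("X", 80), pad("simulated", 80), pad("01.01.26", 8),
    pad("00.00.00", 8), pad(256 * (ns + 1), 8), pad("", 44),
    pad(n_records, 8), pad(record_duration, 8), pad(ns, 4)
  ), con, eos = NULL)
  phys_min <- vapply(signals, function(x) floor(min(x)) - 1, numeric(1))
  phys_max <- vapply(signals, function(x) ceiling(max(x)) + 1, numeric(1))
  dig_min <- rep(-32768, ns)
  dig_max <- rep(32767, ns)
  wfield <- function(vals, w) writeChar(paste(vapply(vals, pad, character(1), w = w), collapse = ""), con, eos = NULL)
  wfield(names(signals), 16)
  wfield(rep("", ns), 80)
  wfield(rep("au", ns), 8)
  wfield(phys_min, 8)
  wfield(phys_max, 8)
  wfield(dig_min, 8)
  wfield(dig_max, 8)
  wfield(prefilter, 80)
  wfield(rep(spr, ns), 8)
  wfield(rep("", ns), 32)
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      x <- signals[[s]][((r - 1) * spr + 1):(r * spr)]
      dig <- round((x - phys_min[s]) / (phys_max[s] - phys_min[s]) *
                     (dig_max[s] - dig_min[s]) + dig_min[s])
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read scored annotations from CSV
#'
#' Expects the schema `onset_s,duration_s,kind,label` with kind one of
#' `resp_event`, `arousal`, `stage`; rows are validated and sorted (see
#' [as_annotations()] for the label vocabulary and invariants).
#'
#' @param path Path to the annotations CSV.
#' @return An `annotation_set` tibble.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, col_types = readr::cols(
    onset_s = readr::col_double(), duration_s = readr::col_double(),
    kind = readr::col_character(), label = readr::col_character()
  ), progress = FALSE)
  as_annotations(df)
}

#' Write annotations to CSV
#'
#' Inverse of [read_annotations()]: writing then reading reproduces the
#' annotation table exactly.
#'
#' @param annotations An `annotation_set` (or coercible data frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  annotations <- as_annotations(annotations)
  readr::write_csv(tibble::as_tibble(unclass(annotations)), path)
  invisible(path)
}

#' Write a flow trace to CSV
#'
#' @param flow A tibble `time_s`, `flow`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_flow_csv <- function(flow, path) {
  readr::write_csv(flow[, c("time_s", "flow")], path)
  invisible(path)
}
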