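# Recording container, EDF and delimited-table I/O, epoch segmentation.
#
# EDF I/O is implemented directly against the format's fixed ASCII header +
# 16-bit little-endian sample layout; samples are scaled between the digital
# and declared physical range, so a write/read round trip is exact up to the
# quantization step (phys_max - phys_min) / 65535.

#' The 19 scalp channels of the International 10-20 montage
#'
#' Channel order used throughout: frontal to occipital, left to right,
#' matching the standard clinical 19-electrode layout.
#'
#' @return Character vector of 19 channel labels.
#' @export
channels_1020 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz",
    "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

#' Posterior channels (central, parietal, occipital)
#' @return Character vector, subset of [channels_1020()].
#' @export
posterior_channels <- function() {
  c("C3", "Cz", "C4", "P3", "Pz", "P4", "T5", "T6", "O1", "O2")
}

#' Default condition vocabulary: 7 emotional sounds plus two resting states
#' @return Character vector of condition labels.
#' @export
condition_vocabulary <- function() {
  c("barking", "crying", "vomiting", "coughing", "scratching",
    "birdsong", "laughter", "rest_open", "rest_closed")
}

#' Construct a multichannel EEG recording
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz (positive scalar).
#' @param channel_labels character vector, one unique label per row.
#' @param subject_id subject identifier string.
#' @param group group label (e.g. "control", "coma") or "unknown".
#' @return An object of class `eeg_recording`.
#' @export
new_recording <- function(data, fs, channel_labels,
                          subject_id = "S0", group = "unknown") {
  data <- as.matrix(data)
  if (!is.numeric(data) || ncol(data) < 2L)
    stop("recording needs a numeric channels x samples matrix with >= 2 samples")
  if (!all(is.finite(data)))
    stop("recording contains non-finite samples")
  if (length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a positive scalar")
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(data))
    stop("one channel label per data row required")
  if (anyDuplicated(channel_labels))
    stop("channel labels must be unique")
  structure(
    list(data = data, fs = fs, channel_labels = channel_labels,
         subject_id = as.character(subject_id), group = as.character(group)),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s (%s): %d ch x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$group, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pad_ascii <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop(sprintf("EDF field '%s' exceeds %d chars", x, width))
  formatC(x, width = -width)
}

edf_num <- function(x, width = 8L) {
  s <- formatC(x, format = "g", digits = 7, width = 1)
  if (nchar(s) > width) s <- formatC(x, format = "g", digits = 4, width = 1)
  if (nchar(s) > width) stop("cannot format numeric EDF field")
  pad_ascii(s, width)
}

#' Write a recording to an EDF file
#'
#' Samples are quantized to 16-bit integers over a symmetric physical range
#' covering the data; the quantization step is
#' `(phys_max - phys_min) / 65535` microvolts.
#'
#' @param recording an [new_recording()] object.
#' @param path output file path.
#' @param phys_range optional `c(min, max)` physical range in microvolts;
#'   defaults to a symmetric range just covering the data.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path, phys_range = NULL) {
  x <- recording$data
  fs <- recording$fs
  n <- ncol(x)
  ns <- nrow(x)
  if (is.null(phys_range)) {
    m <- max(1e-6, max(abs(x)))
    m <- ceiling(m * 1.01)
    phys_range <- c(-m, m)
  }
  pmin <- phys_range[1]; pmax <- phys_range[2]
  if (!(pmin < pmax)) stop("invalid physical range")
  # one data record per second when the length allows it, else a single record
  if (abs(fs - round(fs)) < 1e-9 && n %% round(fs) == 0) {
    spr <- as.integer(round(fs)); nrec <- n %/% spr; recdur <- 1
  } else {
    spr <- n; nrec <- 1L; recdur <- n / fs
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_ascii("0", 8),
    pad_ascii(recording$subject_id, 80),
    pad_ascii(paste("group", recording$group), 80),
    pad_ascii("01.01.26", 8), pad_ascii("00.00.00", 8),
    pad_ascii(as.character(256L + 256L * ns), 8),
    pad_ascii("", 44),
    pad_ascii(as.character(nrec), 8),
    edf_num(recdur, 8),
    pad_ascii(as.character(ns), 4))
  sig <- paste0(
    paste(vapply(recording$channel_labels, pad_ascii, "", width = 16), collapse = ""),
    paste(rep(pad_ascii("", 80), ns), collapse = ""),
    paste(rep(pad_ascii("uV", 8), ns), collapse = ""),
    paste(rep(edf_num(pmin), ns), collapse = ""),
    paste(rep(edf_num(pmax), ns), collapse = ""),
    paste(rep(pad_ascii("-32768", 8), ns), collapse = ""),
    paste(rep(pad_ascii("32767", 8), ns), collapse = ""),
    paste(rep(pad_ascii("", 80), ns), collapse = ""),
    paste(rep(pad_ascii(as.character(spr), 8), ns), collapse = ""),
    paste(rep(pad_ascii("", 32), ns), collapse = ""))
  writeChar(paste0(hdr, sig), con, eos = NULL, useBytes = TRUE)
  scale <- 65535 / (pmax - pmin)
  dig <- round((x - pmin) * scale) - 32768
  dig[dig > 32767] <- 32767L
  dig[dig < -32768] <- -32768L
  storage.mode(dig) <- "integer"
  for (r in seq_len(nrec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (s in seq_len(ns))
      writeBin(dig[s, idx], con, size = 2L, endian = "little")
  }
  invisible(path)
}

read_edf_field <- function(raw, off, width) {
  trimws(rawToChar(raw[(off + 1L):(off + width)]))
}

#' Read an EDF/EDF+ recording
#'
#' Channels are selected by a label whitelist (default: the 19 channels of
#' [channels_1020()]); labels are normalized by stripping an "EEG " prefix
#' and any "-ref" suffix. Extra channels (EOG, polygraphy, annotations) are
#' dropped with a notice. Physical units are converted to microvolts when the
#' EDF dimension field is V/mV/uV; an unknown unit passes through with a
#' warning. All selected channels must share one sampling rate.
#'
#' @param path EDF file path.
#' @param channels label whitelist, or `NULL` to keep every data channel.
#' @param subject_id,group optional metadata overrides (default: taken from
#'   the EDF patient/recording header fields).
#' @param on_nonfinite `"error"` (default) rejects non-finite samples;
#'   `"impute"` linearly interpolates across them.
#' @return An [new_recording()] object.
#' @export
read_edf <- function(path, channels = channels_1020(),
                     subject_id = NULL, group = NULL,
                     on_nonfinite = c("error", "impute")) {
  on_nonfinite <- match.arg(on_nonfinite)
  if (!file.exists(path)) stop("EDF file not found: ", path)
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 256L)
  if (length(hdr) < 256L) stop("malformed EDF header: file too short")
  ver <- read_edf_field(hdr, 0L, 8L)
  if (!ver %in% c("0")) stop("malformed EDF header: unknown version '", ver, "'")
  patient <- read_edf_field(hdr, 8L, 80L)
  recinfo <- read_edf_field(hdr, 88L, 80L)
  nrec <- suppressWarnings(as.integer(read_edf_field(hdr, 236L, 8L)))
  recdur <- suppressWarnings(as.numeric(read_edf_field(hdr, 244L, 8L)))
  ns <- suppressWarnings(as.integer(read_edf_field(hdr, 252L, 4L)))
  if (is.na(nrec) || is.na(recdur) || is.na(ns) || ns < 1L || recdur <= 0)
    stop("malformed EDF header: bad record counts")
  sig <- readBin(con, "raw", 256L * ns)
  if (length(sig) < 256L * ns) stop("malformed EDF header: truncated signal block")
  fld <- function(off, width) {
    vapply(seq_len(ns) - 1L,
           function(i) read_edf_field(sig, off * ns + i * width, width), "")
  }
  labels <- fld(0L, 16L)
  phys_dim <- fld(96L, 8L)
  pmin <- as.numeric(fld(104L, 8L))
  pmax <- as.numeric(fld(112L, 8L))
  dmin <- as.numeric(fld(120L, 8L))
  dmax <- as.numeric(fld(128L, 8L))
  spr <- as.integer(fld(216L, 8L))
  if (any(is.na(pmin) | is.na(pmax) | is.na(dmin) | is.na(dmax) | is.na(spr)))
    stop("malformed EDF header: bad signal fields")
  expected <- 256L + 256L * ns + 2 * as.numeric(nrec) * sum(as.numeric(spr))
  if (!is.na(sz) && sz < expected) stop("malformed EDF file: truncated data")

  norm_lab <- sub("-.*$", "", sub("^EEG[ _]*", "", labels, ignore.case = TRUE))
  is_annot <- grepl("annotation", labels, ignore.case = TRUE)
  if (is.null(channels)) {
    keep <- which(!is_annot)
  } else {
    keep <- which(!is_annot & (norm_lab %in% channels | labels %in% channels))
    if (length(keep) == 0L) {
      message("no channels matched the whitelist; keeping all ",
              sum(!is_annot), " data channels")
      keep <- which(!is_annot)
    }
  }
  dropped <- setdiff(seq_len(ns), keep)
  if (length(dropped) > 0L)
    message("read_edf: ignoring ", length(dropped), " channel(s): ",
            paste(labels[dropped], collapse = ", "))
  if (length(unique(spr[keep])) != 1L)
    stop("unsupported layout: selected channels have mixed sampling rates")
  fs <- spr[keep[1]] / recdur
  nsamp <- as.integer(spr[keep[1]]) * nrec

  data <- matrix(0, length(keep), nsamp)
  row_of <- match(seq_len(ns), keep)
  for (r in seq_len(nrec)) {
    for (s in seq_len(ns)) {
      vals <- readBin(con, "integer", n = spr[s], size = 2L,
                      signed = TRUE, endian = "little")
      if (!is.na(row_of[s])) {
        g <- (pmax[s] - pmin[s]) / (dmax[s] - dmin[s])
        idx <- ((r - 1L) * spr[s] + 1L):(r * spr[s])
        data[row_of[s], idx] <- (vals - dmin[s]) * g + pmin[s]
      }
    }
  }
  # unit conversion to microvolts
  for (i in seq_along(keep)) {
    u <- tolower(phys_dim[keep[i]])
    if (u %in% c("uv", "µv", "")) next
    if (u == "mv") data[i, ] <- data[i, ] * 1e3
    else if (u == "v") data[i, ] <- data[i, ] * 1e6
    else warning("unknown physical dimension '", phys_dim[keep[i]],
                 "' on channel ", labels[keep[i]], "; passing through")
  }
  if (!all(is.finite(data))) {
    if (on_nonfinite == "error")
      stop("recording contains non-finite samples after loading")
    for (i in seq_len(nrow(data))) {
      bad <- !is.finite(data[i, ])
      if (any(bad))
        data[i, bad] <- stats::approx(which(!bad), data[i, !bad],
                                      xout = which(bad), rule = 2)$y
    }
  }
  new_recording(data, fs, norm_lab[keep],
                subject_id = subject_id %||% (if (nzchar(patient)) patient else "S0"),
                group = group %||% sub("^group ", "", recinfo))
}

#' Validate an event table
#'
#' @param events data.frame with columns `onset_s`, `duration_s`, `label`.
#' @param vocabulary allowed condition labels (`NULL` disables the check).
#' @param record_length_s optional recording length for range checking.
#' @return The validated table, sorted by onset, class `event_table`.
#' @export
validate_events <- function(events, vocabulary = condition_vocabulary(),
                            record_length_s = NULL) {
  req <- c("onset_s", "duration_s", "label")
  if (!all(req %in% names(events)))
    stop("event table needs columns: ", paste(req, collapse = ", "))
  events <- events[order(events$onset_s), req, drop = FALSE]
  events$label <- as.character(events$label)
  if (nrow(events) > 0) {
    if (any(!is.finite(events$onset_s)) || any(!is.finite(events$duration_s)))
      stop("non-finite onsets/durations")
    if (any(events$onset_s < 0)) stop("negative event onset")
    if (any(events$duration_s <= 0)) stop("non-positive event duration")
    if (nrow(events) > 1) {
      if (any(diff(events$onset_s) <= 0))
        stop("event onsets must be strictly increasing")
      ends <- events$onset_s + events$duration_s
      if (any(ends[-length(ends)] > events$onset_s[-1] + 1e-9))
        stop("overlapping stimulus intervals")
    }
    if (!is.null(vocabulary) && !all(events$label %in% vocabulary))
      stop("unknown condition label(s): ",
           paste(setdiff(events$label, vocabulary), collapse = ", "))
    if (!is.null(record_length_s) &&
        any(events$onset_s + events$duration_s > record_length_s + 1e-9))
      stop("event extends beyond the end of the recording")
  }
  rownames(events) <- NULL
  class(events) <- c("event_table", "data.frame")
  events
}

#' Read an event table from a delimited file
#'
#' @param path TSV/CSV path with header `onset_s`, `duration_s`, `label`.
#' @param vocabulary allowed labels (see [validate_events()]).
#' @return A validated `event_table`.
#' @export
read_events <- function(path, vocabulary = condition_vocabulary()) {
  tab <- utils::read.delim(path, sep = guess_sep(path), stringsAsFactors = FALSE)
  validate_events(tab, vocabulary = vocabulary)
}

#' Write an event table
#' @param events event table.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.table(as.data.frame(events), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

guess_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Cut a recording into per-condition epoch fragments
#'
#' Each event row becomes one epoch: the half-open sample slice
#' `[onset_sample, onset_sample + duration_samples)`, with second-to-sample
#' conversion by round-half-to-even. Epochs sharing a label are collected into
#' one fragment per condition; samples between events are not analyzed.
#'
#' @param recording an [new_recording()] object.
#' @param events a validated `event_table`.
#' @return Named list of `condition_fragment` objects (fields: `condition`,
#'   `epochs` — list of channels x samples matrices, `fs`, `subject_id`,
#'   `group`, `channel_labels`).
#' @export
segment <- function(recording, events) {
  events <- validate_events(events, vocabulary = NULL,
                            record_length_s = ncol(recording$data) / recording$fs)
  n <- ncol(recording$data)
  out <- list()
  for (i in seq_len(nrow(events))) {
    a <- round(events$onset_s[i] * recording$fs)        # 0-based start
    len <- round(events$duration_s[i] * recording$fs)
    if (a + len > n) stop("event ", i, " extends beyond the recording")
    ep <- recording$data[, (a + 1L):(a + len), drop = FALSE]
    lab <- events$label[i]
    out[[lab]] <- c(out[[lab]], list(ep))
  }
  lapply(stats::setNames(names(out), names(out)), function(lab) {
    structure(list(condition = lab, epochs = out[[lab]], fs = recording$fs,
                   subject_id = recording$subject_id, group = recording$group,
                   channel_labels = recording$channel_labels),
              class = "condition_fragment")
  })
}

#' @export
print.condition_fragment <- function(x, ...) {
  cat(sprintf("<condition_fragment> %s: %d epoch(s) of %d ch, total %.1f s\n",
              x$condition, length(x$epochs), nrow(x$epochs[[1]]),
              sum(vapply(x$epochs, ncol, 0L)) / x$fs))
  invisible(x)
}

feature_key_cols <- c("subject", "condition", "channel", "feature")

check_feature_table <- function(tab) {
  cols <- c("subject", "group", "condition", "channel", "feature", "value")
  if (!all(cols %in% names(tab)))
    stop("feature table needs columns: ", paste(cols, collapse = ", "))
  key <- do.call(paste, c(tab[feature_key_cols], sep = "\r"))
  if (anyDuplicated(key))
    stop("duplicate (subject, condition, channel, feature) keys in feature table")
  tab[cols]
}

#' Write a long-format feature table
#'
#' Columns, in stable order: subject, group, condition, channel, feature,
#' value. Duplicate (subject, condition, channel, feature) keys are an error.
#'
#' @param tab data.frame of feature rows.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(tab, path) {
  tab <- check_feature_table(as.data.frame(tab))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a long-format feature table
#' @param path TSV path written by [write_feature_table()].
#' @return data.frame with validated columns and unique keys.
#' @export
read_feature_table <- function(path) {
  check_feature_table(utils::read.delim(path, sep = "\t",
                                        stringsAsFactors = FALSE))
}

#' Write / read a wide PSD bin table
#'
#' One row per (subject, condition, channel); 18 power columns
#' `psd_2_3` ... `psd_19_20` in microvolts squared.
#'
#' @param tab PSD data.frame.
#' @param path TSV path.
#' @return `path` / data.frame.
#' @export
write_psd_table <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_psd_table
#' @export
read_psd_table <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Write / read a subjective-ratings table
#'
#' Long format: subject, group, stimulus, scale, value. Scales follow the
#' study design: pleasantness in \[-5, 5\]; arousal, fear, empathy and
#' irritation in \[0, 10\].
#'
#' @param tab ratings data.frame.
#' @param path TSV path.
#' @return `path` / data.frame.
#' @export
write_ratings <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ratings
#' @export
read_ratings <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
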