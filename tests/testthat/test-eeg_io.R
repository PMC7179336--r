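test_that("EDF header arithmetic gives the expected data shape", {
  rec <- new_recording(matrix(0, 19, 15000) + rnorm(19 * 15000, sd = 5),
                       250, channels_1020())
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  r2 <- read_edf(path)
  expect_identical(dim(r2$data), c(19L, 15000L))
  expect_equal(r2$fs, 250)
  expect_identical(r2$channel_labels, channels_1020())
})

test_that("EDF round trip is exact up to the declared quantization step", {
  set.seed(31)
  rec <- new_recording(matrix(rnorm(3 * 1000, sd = 40), 3, 1000), 250,
                       c("Fp1", "Cz", "O2"), "T1", "control")
  path <- withr::local_tempfile(fileext = ".edf")
  pr <- c(-150, 150)
  write_edf(rec, path, phys_range = pr)
  r2 <- read_edf(path)
  step <- (pr[2] - pr[1]) / 65535
  expect_lte(max(abs(r2$data - rec$data)), step / 2 + 1e-12)
  # brute-force re-quantization reproduces the stored samples exactly
  dig <- round((rec$data - pr[1]) / (pr[2] - pr[1]) * 65535) - 32768
  expected <- (dig + 32768) / 65535 * (pr[2] - pr[1]) + pr[1]
  expect_equal(r2$data, expected, tolerance = 1e-9)
  expect_identical(r2$subject_id, "T1")
  expect_identical(r2$group, "control")
})

test_that("mixed sampling rates among selected channels are rejected", {
  rec <- new_recording(matrix(rnorm(2 * 500), 2, 500), 250, c("Fp1", "Fp2"))
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  raw <- readBin(path, "raw", file.info(path)$size)
  # samples-per-record block starts at 256 + ns * 216; patch signal 2
  off <- 256L + 2L * 216L + 8L
  raw[(off + 1L):(off + 8L)] <- charToRaw(formatC("125", width = -8))
  writeBin(raw, path)
  expect_error(read_edf(path, channels = NULL), "mixed sampling rates")
})

test_that("malformed EDF headers are rejected", {
  path <- withr::local_tempfile(fileext = ".edf")
  writeBin(charToRaw("not an edf file"), path)
  expect_error(read_edf(path), "malformed")
})

test_that("extra channels are dropped by the whitelist with a notice", {
  rec <- new_recording(matrix(rnorm(3 * 500), 3, 500), 250,
                       c("Fp1", "EOG1", "Cz"))
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  expect_message(r2 <- read_edf(path), "ignoring 1 channel")
  expect_identical(r2$channel_labels, c("Fp1", "Cz"))
})

test_that("recording invariants are enforced", {
  expect_error(new_recording(matrix(c(1, NA, 3, 4), 2, 2), 250, c("a", "b")),
               "non-finite")
  expect_error(new_recording(matrix(1:4, 2, 2), -1, c("a", "b")), "positive")
  expect_error(new_recording(matrix(1:4, 2, 2), 250, c("a", "a")), "unique")
  expect_error(new_recording(matrix(1:2, 2, 1), 250, c("a", "b")),
               ">= 2 samples")
})

test_that("event tables validate ordering, overlap and vocabulary", {
  path <- withr::local_tempfile(fileext = ".tsv")
  ev <- data.frame(onset_s = seq(0, by = 31, length.out = 8),
                   duration_s = 30, label = "laughter")
  write_events(validate_events(ev), path)
  back <- read_events(path)
  expect_equal(nrow(back), 8L)
  expect_s3_class(back, "event_table")

  writeLines("onset_s\tduration_s\tlabel", path)
  expect_equal(nrow(read_events(path)), 0L)

  bad <- data.frame(onset_s = c(0, 10), duration_s = c(20, 5),
                    label = "laughter")
  expect_error(validate_events(bad), "overlap")
  expect_error(validate_events(data.frame(onset_s = 0, duration_s = 5,
                                          label = "mystery")),
               "unknown condition")
  expect_error(validate_events(ev, record_length_s = 100), "beyond")
})

test_that("segmentation slices the study design into per-condition epochs", {
  fs <- 250
  stimuli <- setdiff(condition_vocabulary(), c("rest_open", "rest_closed"))
  set.seed(5)
  onset <- 1
  rows <- list()
  for (lab in sample(rep(stimuli, each = 8L))) {
    rows[[length(rows) + 1L]] <- data.frame(onset_s = onset, duration_s = 30,
                                            label = lab)
    onset <- onset + 30 + runif(1, 0.7, 2.0)
  }
  ev <- validate_events(do.call(rbind, rows))
  n <- ceiling((onset + 1) * fs)
  rec <- new_recording(matrix(rnorm(n), 1, n), fs, "Cz")
  frags <- segment(rec, ev)
  expect_length(frags, 7L)
  for (fr in frags) {
    expect_length(fr$epochs, 8L)
    expect_true(all(vapply(fr$epochs, ncol, 0L) == 7500L))
    expect_equal(sum(vapply(fr$epochs, ncol, 0L)) / fs, 240)
  }
  # epochs are verbatim slices of the recording (exhaustive reconstruction)
  for (i in seq_len(nrow(ev))) {
    a <- round(ev$onset_s[i] * fs)
    fr <- frags[[ev$label[i]]]
    k <- sum(ev$label[seq_len(i)] == ev$label[i])
    expect_identical(fr$epochs[[k]],
                     rec$data[, (a + 1):(a + 7500), drop = FALSE])
  }
})

test_that("segmenting a single rest label yields one fragment", {
  rec <- new_recording(matrix(rnorm(250 * 20), 1, 250 * 20), 250, "Cz")
  ev <- validate_events(data.frame(onset_s = 1, duration_s = 10,
                                   label = "rest_closed"))
  frags <- segment(rec, ev)
  expect_length(frags, 1L)
  expect_identical(names(frags), "rest_closed")
})

test_that("feature tables round-trip losslessly and reject duplicate keys", {
  tab <- data.frame(subject = "S001", group = "control",
                    condition = "rest_closed", channel = "Cz",
                    feature = "FD", value = 1.2345678901)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(tab, path)
  back <- read_feature_table(path)
  expect_equal(back, tab)

  dup <- rbind(tab, transform(tab, value = 9))
  expect_error(write_feature_table(dup, path), "duplicate")

  # full-study cell count by explicit enumeration
  grid <- expand.grid(subject = sprintf("P%03d", 1:141),
                      channel = channels_1020(),
                      condition = condition_vocabulary(),
                      feature = feature_names())
  expect_identical(nrow(grid), 141L * 19L * 9L * 6L)
})
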