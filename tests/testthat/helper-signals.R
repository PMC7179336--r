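# Shared signal builders and independent oracles used across test files.

FS <- 250

make_sine <- function(f, dur_s = 10, fs = FS, amp = 1) {
  amp * sin(2 * pi * f * seq(0, dur_s, by = 1 / fs))
}

# amplitude-modulated carrier: (1 + m cos 2 pi fm t) sin(2 pi fc t)
make_am <- function(fc = 10, fm = 2, m = 0.5, dur_s = 30, fs = FS) {
  t <- seq(0, dur_s, by = 1 / fs)
  list(x = (1 + m * cos(2 * pi * fm * t)) * sin(2 * pi * fc * t),
       modulator = 1 + m * cos(2 * pi * fm * t), t = t)
}

rand_bandlimited <- function(n, lo = 1.6, hi = 30, fs = FS, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bandpass(rnorm(n), fs, band_spec(lo, hi))
}

# Hann-tapered copy: makes the series effectively circular, so periodogram
# moments and time-domain difference variances describe the same object
hann_taper <- function(x) {
  n <- length(x)
  x * (0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1)))
}

# brute-force one-way ANOVA from explicit sums of squares
bf_anova_F <- function(values, groups) {
  groups <- as.factor(groups)
  grand <- mean(values)
  gm <- tapply(values, groups, mean)
  ni <- tapply(values, groups, length)
  ssb <- sum(ni * (gm - grand)^2)
  ssw <- sum((values - gm[groups])^2)
  df1 <- nlevels(groups) - 1L
  df2 <- length(values) - nlevels(groups)
  (ssb / df1) / (ssw / df2)
}

# spectral-moment Hjorth parameters from the periodogram, using the exact
# first-difference frequency response |1 - e^{-iw}|^2 = (2 sin(w/2))^2
hjorth_spectral <- function(x) {
  n <- length(x)
  S <- Mod(stats::fft(x - mean(x)))^2 / n
  w <- 2 * pi * (seq_len(n) - 1L) / n
  w2 <- (2 * sin(w / 2))^2
  m0 <- sum(S); m2 <- sum(w2 * S); m4 <- sum(w2^2 * S)
  c(mobility = sqrt(m2 / m0), complexity = sqrt(m4 * m0) / m2)
}

# minimal feature table for stats-stage tests: one value per
# (subject, group, channel), single feature/condition
null_feature_table <- function(n_per_group = 15, groups = letters[1:5],
                               channels = channels_1020(),
                               feature = "FD", condition = "rest_closed") {
  subjects <- sprintf("S%03d", seq_len(n_per_group * length(groups)))
  grid <- expand.grid(subject = subjects, channel = channels,
                      stringsAsFactors = FALSE)
  grid$group <- rep(rep(groups, each = n_per_group), times = length(channels))
  grid$condition <- condition
  grid$feature <- feature
  grid$value <- rnorm(nrow(grid))
  grid
}

# small two-group cohort spec for pipeline tests
demo_spec <- function(seed, conditions = c("rest_closed", "laughter"),
                      n_subjects = 3, n_channels = 4) {
  prof <- group_profiles()
  cohort_spec(
    groups = list(control = list(n_subjects = n_subjects,
                                 profile = prof$control),
                  coma = list(n_subjects = n_subjects, profile = prof$coma)),
    conditions = conditions,
    design = list(n_epochs = 2L, epoch_s = 10, gap_range = c(0.7, 2),
                  lead_s = 1),
    n_channels = n_channels, seed = seed)
}
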