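test_that("Higuchi dimension is exact for a line and correct for noise", {
  expect_equal(higuchi_fd(seq_len(1000), 8), 1, tolerance = 1e-6)
  set.seed(21)
  fd_white <- mean(replicate(20, higuchi_fd(rnorm(10000), 8)))
  expect_gt(fd_white, 1.95); expect_lt(fd_white, 2.05)
  expect_error(higuchi_fd(rep(1, 1000), 8), "constant")
  expect_error(higuchi_fd(rnorm(1000), 1), "k_max")
  expect_error(higuchi_fd(rnorm(50), 8), "too short")
})

test_that("Higuchi dimension tracks the Hurst exponent of fBm", {
  for (H in c(0.3, 0.7)) {
    fd <- mean(vapply(1:20, function(i) higuchi_fd(gen_fbm(5000, H, seed = i), 8), 0.0))
    expect_equal(fd, 2 - H, tolerance = 0.1)
  }
})

test_that("Hjorth parameters match sinusoid and white-noise closed forms", {
  s <- make_sine(10)
  expect_equal(hjorth_mobility(s), 2 * sin(pi * 10 / FS), tolerance = 0.01)
  expect_equal(hjorth_complexity(s), 1, tolerance = 0.01)
  set.seed(22)
  w <- rnorm(1e5)
  expect_equal(hjorth_mobility(w), sqrt(2), tolerance = 0.02)
  expect_equal(hjorth_complexity(w), sqrt(1.5), tolerance = 0.02)
  expect_error(hjorth_mobility(rep(3, 100)), "zero variance")
  expect_error(hjorth_complexity(seq_len(100)), "zero variance")
})

test_that("Hilbert envelope recovers constant and AM modulators", {
  env <- trim_envelope(hilbert_envelope(make_sine(10)), FS)
  expect_lt(max(abs(env - 1)), 0.02)

  am <- make_am(fc = 10, fm = 2, m = 0.5)
  env2 <- trim_envelope(hilbert_envelope(am$x), FS)
  mod <- trim_envelope(am$modulator, FS)
  expect_lt(sqrt(mean((env2 - mod)^2)) / mean(mod), 0.03)

  expect_error(hilbert_envelope(rep(0, 500)), "all-zero")
  expect_error(trim_envelope(rep(1, 100), FS), "too short")
})

test_that("envelope mean frequency finds the modulation rate", {
  am <- make_am(fc = 10, fm = 2, m = 0.5)
  env <- trim_envelope(hilbert_envelope(am$x), FS)
  expect_equal(envelope_mean_frequency(env, FS), 2, tolerance = 0.2)

  # equal-power modulators at 1 and 3 Hz -> centroid at 2 Hz
  t <- seq(0, 30, by = 1 / FS)
  x2 <- (1 + 0.4 * cos(2 * pi * t) + 0.4 * cos(2 * pi * 3 * t)) *
    sin(2 * pi * 10 * t)
  env2 <- trim_envelope(hilbert_envelope(x2), FS)
  expect_equal(envelope_mean_frequency(env2, FS), 2, tolerance = 0.2)

  flat <- trim_envelope(hilbert_envelope(make_sine(10)), FS)
  emf <- envelope_mean_frequency(flat, FS)
  expect_identical(as.numeric(emf), 0)
  expect_true(attr(emf, "degenerate"))
})

test_that("envelope coefficient of variation equals m/sqrt(2) for AM depth m", {
  for (m in c(0.5, 0.8)) {
    am <- make_am(fc = 10, fm = 2, m = m)
    env <- trim_envelope(hilbert_envelope(am$x), FS)
    expect_equal(envelope_cv(env), m / sqrt(2), tolerance = 0.05 * m / sqrt(2))
  }
  const <- trim_envelope(hilbert_envelope(make_sine(10)), FS)
  expect_lt(envelope_cv(const), 0.02)
  expect_error(envelope_cv(rep(0, 100)), "non-positive")
})

test_that("unit-bin PSD integrates tones and respects Parseval", {
  x <- make_sine(10.5, dur_s = 60)
  pb <- psd_unit_bins(x, FS)
  expect_identical(nrow(pb), 18L)
  expect_true(all(pb$power >= 0))
  expect_equal(sum(pb$power), 0.5, tolerance = 0.025)
  expect_gte(pb$power[pb$bin_lo == 10] / sum(pb$power), 0.95)

  y <- rand_bandlimited(60 * FS, 2, 20, seed = 23)
  expect_equal(sum(psd_unit_bins(y, FS)$power), var(y), tolerance = 0.05)
  expect_error(psd_unit_bins(rnorm(100), FS), "shorter than 2 s")
})

test_that("white-noise bin powers are flat when averaged over seeds", {
  P <- rowMeans(vapply(1:20, function(i) {
    set.seed(300 + i)
    psd_unit_bins(rnorm(60 * FS), FS)$power
  }, numeric(18L)))
  expect_lt(max(P) / min(P), 1.2)
})

test_that("features are invariant to positive amplitude scaling", {
  set.seed(24)
  for (rep_i in 1:3) {
    x <- rand_bandlimited(3000, 1.6, 30)
    env <- trim_envelope(hilbert_envelope(x), FS)
    base <- c(higuchi_fd(x, 8), hjorth_mobility(x), hjorth_complexity(x),
              envelope_mean_frequency(env, FS), envelope_cv(env))
    for (c_scale in c(0.1, 3, 100)) {
      xs <- c_scale * x
      envs <- trim_envelope(hilbert_envelope(xs), FS)
      scaled <- c(higuchi_fd(xs, 8), hjorth_mobility(xs),
                  hjorth_complexity(xs),
                  envelope_mean_frequency(envs, FS), envelope_cv(envs))
      expect_equal(scaled, base, tolerance = 1e-6)
    }
  }
})

test_that("band-power shifts move the features in the documented directions", {
  set.seed(25)
  base <- 10 * gen_colored_noise(30 * FS, FS, 1.2) +
    4 * make_sine(10.5, dur_s = 30)[1:(30 * FS)]
  slow <- bandpass(rnorm(30 * FS), FS, band_spec(2, 6, order = 8))
  fast <- bandpass(rnorm(30 * FS), FS, band_spec(15, 19, order = 8))
  add_feats <- function(x) {
    wb <- bandpass(x, FS, band_spec(1.6, 30))
    env <- trim_envelope(hilbert_envelope(wb), FS)
    c(emf = envelope_mean_frequency(env, FS), mob = hjorth_mobility(wb),
      rat = envelope_cv(env))
  }
  # moderate fast-band dose: strong enough to shift the spectrum, weak
  # enough that the added component's own (slow) envelope does not dominate
  f0 <- add_feats(base)
  f_slow <- add_feats(base + 12 * slow / sd(slow))
  f_fast <- add_feats(base + 5 * fast / sd(fast))
  expect_lt(f_slow["emf"], f0["emf"])
  expect_lt(f_slow["mob"], f0["mob"])
  expect_gt(f_slow["rat"], f0["rat"])
  expect_gt(f_fast["emf"], f0["emf"])
  expect_gt(f_fast["mob"], f0["mob"])
})

test_that("fragment extraction counts, averages and epoch order behave", {
  set.seed(26)
  fs <- 250
  epoch <- matrix(rnorm(3 * 5 * fs, sd = 10), 3, 5 * fs)
  epoch2 <- matrix(rnorm(3 * 5 * fs, sd = 10), 3, 5 * fs)
  frag <- structure(list(condition = "rest_closed",
                         epochs = list(epoch, epoch2), fs = fs,
                         subject_id = "S1", group = "control",
                         channel_labels = c("Fp1", "Cz", "O2")),
                    class = "condition_fragment")
  res <- extract_all(frag)
  expect_identical(nrow(res$features), 3L * 6L)
  expect_identical(nrow(res$psd), 3L)
  expect_identical(res$n_epochs_kept, 2L)

  # duplicated epochs average to the single-epoch value
  frag1 <- frag; frag1$epochs <- list(epoch)
  fragd <- frag; fragd$epochs <- list(epoch, epoch)
  expect_equal(extract_all(fragd)$features$value,
               extract_all(frag1)$features$value)

  # permutation invariance
  fragp <- frag; fragp$epochs <- list(epoch2, epoch)
  expect_equal(extract_all(fragp)$features$value, res$features$value)

  # artifact rejection can empty a fragment
  frag_big <- frag
  frag_big$epochs <- lapply(frag$epochs, function(e) e * 100)
  expect_warning(empty <- extract_all(frag_big), "no epochs survived")
  expect_identical(empty$n_epochs_kept, 0L)
})
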