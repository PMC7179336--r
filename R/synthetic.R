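# Seeded synthetic EEG cohorts with the statistical structure the analysis
# assumes: 1/f colored-noise background, a coherent amplitude-modulated
# alpha oscillation weighted toward posterior channels, group-specific band
# boosts, per-condition effect injections, and subjective ratings coupled to
# the injected subject-level factors through a linear latent model.
#
# The signal model is a statistical emulation of group-specific resting
# spectra (slow-wave excess in coma, 5-9 Hz excess after stroke, strong
# posterior alpha in controls) — not a biophysical forward model.

#' Spectrally shaped Gaussian noise
#'
#' White Gaussian noise shaped in the frequency domain so that power falls
#' as `1 / f^exponent` (flat below 1 Hz), then rescaled to unit variance.
#'
#' @param n number of samples (>= 256).
#' @param fs sampling rate in Hz.
#' @param exponent spectral slope (0 = white; EEG background is ~1-1.5).
#' @param seed optional integer seed; `NULL` continues the current RNG
#'   stream.
#' @return Numeric series of length `n`, zero mean, unit variance.
#' @export
gen_colored_noise <- function(n, fs, exponent = 1, seed = NULL) {
  if (n < 256L) stop("need n >= 256")
  if (exponent < 0) stop("exponent must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  w <- stats::rnorm(n)
  if (exponent == 0) return((w - mean(w)) / stats::sd(w))
  X <- stats::fft(w)
  f <- (seq_len(n) - 1L) * fs / n
  f <- pmin(f, fs - f)              # two-sided frequency axis
  g <- pmax(f, 1)^(-exponent / 2)
  g[1L] <- 0                        # drop DC
  y <- Re(stats::fft(X * g, inverse = TRUE)) / n
  (y - mean(y)) / stats::sd(y)
}

fgn_autocov <- function(k, hurst) {
  0.5 * (abs(k + 1)^(2 * hurst) - 2 * abs(k)^(2 * hurst) +
           abs(k - 1)^(2 * hurst))
}

#' Fractional Brownian motion by circulant embedding
#'
#' Exact-covariance simulation (Davies-Harte): fractional Gaussian noise is
#' drawn through the eigendecomposition of the circulant embedding of its
#' autocovariance and cumulated into an fBm path. Serves as the ground-truth
#' generator for fractal-dimension recovery (theoretical FD = 2 - H).
#'
#' @param n path length.
#' @param hurst Hurst exponent in (0, 1).
#' @param seed optional integer seed.
#' @return fBm path of length `n` (unit-variance increments).
#' @export
gen_fbm <- function(n, hurst, seed = NULL) {
  if (hurst <= 0 || hurst >= 1) stop("hurst must lie in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  m <- 2L * n
  g <- fgn_autocov(0:n, hurst)
  crow <- c(g, rev(g[2:n]))
  lam <- Re(stats::fft(crow))
  lam[lam < 0] <- 0                 # tiny negatives from rounding
  W <- complex(length.out = m)
  W[1L] <- sqrt(lam[1L] / m) * stats::rnorm(1L)
  W[n + 1L] <- sqrt(lam[n + 1L] / m) * stats::rnorm(1L)
  a <- stats::rnorm(n - 1L); b <- stats::rnorm(n - 1L)
  W[2:n] <- sqrt(lam[2:n] / (2 * m)) * complex(real = a, imaginary = b)
  W[m:(n + 2L)] <- Conj(W[2:n])
  fgn <- Re(stats::fft(W))[seq_len(n)]
  cumsum(fgn)
}

#' Spectral profile of a simulated group
#'
#' @param exponent 1/f slope of the background noise.
#' @param base_uv background standard deviation in microvolts.
#' @param band_boosts list of `list(low_hz, high_hz, gain)`: band-limited
#'   noise added with power `gain` times the background power in that band.
#' @param alpha list `(freq_hz, amp_uv, mod_hz, depth, spatial)`: coherent
#'   rhythmic component — a sinusoid at `freq_hz`, amplitude-modulated at
#'   `mod_hz` with depth in \[0, 1\], RMS amplitude `amp_uv` on the
#'   strongest channels. `spatial` is `"posterior"` (occipital-dominant, the
#'   physiological alpha topography; default) or `"uniform"` (e.g. the
#'   widespread rhythmic delta/theta of severe brain injury).
#' @param subject_sd lognormal sd of the per-subject multipliers on the
#'   background (`base`), alpha amplitude (`alpha`) and band-boost gains
#'   (`band`).
#' @return A `spectral_profile` list.
#' @export
spectral_profile <- function(exponent = 1.2, base_uv = 10,
                             band_boosts = list(),
                             alpha = list(freq_hz = 10.5, amp_uv = 10,
                                          mod_hz = 1.5, depth = 0.6),
                             subject_sd = list(base = 0.2, alpha = 0.3,
                                               band = 0.5)) {
  stopifnot(exponent >= 0, base_uv > 0,
            alpha$depth >= 0, alpha$depth <= 1)
  for (b in band_boosts) stopifnot(b$gain > 0, b$low_hz < b$high_hz)
  structure(list(exponent = exponent, base_uv = base_uv,
                 band_boosts = band_boosts, alpha = alpha,
                 subject_sd = subject_sd),
            class = "spectral_profile")
}

#' Default group spectral profiles
#'
#' Emulations of the study groups' resting spectra. Controls and mTBI
#' patients: physiological background (1/f exponent 1.2) with a strong
#' posterior amplitude-modulated alpha and a beta band whose per-subject
#' spread drives the fast-band correlations (the mTBI profile differs only
#' in a slightly reduced alpha amplitude, mirroring the reported group
#' ranking of alpha power — no nonlinear feature separates the two).
#' Schizophrenia: moderate alpha with
#' faster amplitude modulation (raising the alpha-envelope mean frequency)
#' and stronger beta. Stroke: slowed background, a 5-9 Hz excess and a
#' widespread 9 Hz rhythm replacing the posterior alpha. Coma: severe
#' background slowing (exponent 3), a dominant 2-7 Hz excess with a
#' deeply modulated widespread delta rhythm, no physiological alpha and no
#' beta — which yields the group's low mobility/complexity, low envelope
#' mean frequency and high envelope instability.
#'
#' @return Named list of [spectral_profile()] objects.
#' @export
group_profiles <- function() {
  posterior_alpha <- list(freq_hz = 10.5, amp_uv = 14, mod_hz = 1.5,
                          depth = 0.6, spatial = "posterior")
  beta <- function(g) list(low_hz = 15, high_hz = 25, gain = g)
  list(
    control = spectral_profile(
      exponent = 1.2, base_uv = 10, band_boosts = list(beta(0.8)),
      alpha = posterior_alpha),
    mTBI = spectral_profile(
      exponent = 1.2, base_uv = 10, band_boosts = list(beta(0.8)),
      alpha = utils::modifyList(posterior_alpha, list(amp_uv = 11))),
    schizophrenia = spectral_profile(
      exponent = 1.2, base_uv = 10, band_boosts = list(beta(1.2)),
      alpha = list(freq_hz = 10.5, amp_uv = 9, mod_hz = 2.5, depth = 0.7,
                   spatial = "posterior")),
    stroke = spectral_profile(
      exponent = 1.8, base_uv = 9,
      band_boosts = list(list(low_hz = 5, high_hz = 9, gain = 6), beta(0.1)),
      alpha = list(freq_hz = 9, amp_uv = 11, mod_hz = 0.8, depth = 0.7,
                   spatial = "uniform")),
    coma = spectral_profile(
      exponent = 3.0, base_uv = 8,
      band_boosts = list(list(low_hz = 2, high_hz = 7, gain = 15)),
      alpha = list(freq_hz = 3, amp_uv = 8, mod_hz = 0.5, depth = 0.9,
                   spatial = "uniform"))
  )
}

#' Cohort specification
#'
#' @param groups named list: `name = list(n_subjects, profile)` with a
#'   [spectral_profile()] per group (default: all five study groups at
#'   `n_per_group`).
#' @param conditions condition labels to record; resting state plus any of
#'   the seven stimulus labels in [condition_vocabulary()].
#' @param design list `(n_epochs, epoch_s, gap_range, lead_s)`: number of
#'   presentations per condition, epoch length in seconds, inter-stimulus
#'   gap range, lead-in before the first event.
#' @param effects list of `list(group, condition, band = c(lo, hi) | "alpha",
#'   gain)` — extra band power (relative to background, same convention as
#'   profile boosts) or an alpha amplitude multiplier, injected only inside
#'   that condition's epochs.
#' @param couplings rating couplings: `scale = list(latent, rho)` with
#'   latent one of "slow", "fast", "alpha"; the rating's latent part is
#'   `rho * z + sqrt(1-rho^2) * noise` on the subject's factor `z`.
#' @param n_per_group subjects per group for the default group list.
#' @param n_channels leading channels of the 10-20 montage to simulate.
#' @param fs sampling rate in Hz.
#' @param seed mandatory integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(groups = NULL,
                        conditions = "rest_closed",
                        design = list(n_epochs = 4L, epoch_s = 10,
                                      gap_range = c(0.7, 2.0), lead_s = 1),
                        effects = list(),
                        couplings = default_couplings(),
                        n_per_group = 15L, n_channels = 19L,
                        fs = 250, seed) {
  if (missing(seed) || is.null(seed)) stop("cohort_spec: seed is mandatory")
  if (is.null(groups))
    groups <- lapply(group_profiles(),
                     function(p) list(n_subjects = n_per_group, profile = p))
  for (g in groups)
    if (g$n_subjects < 2L) stop("need >= 2 subjects per group")
  if (!all(conditions %in% condition_vocabulary()))
    stop("unknown condition label(s)")
  if (design$gap_range[1] <= 0)
    stop("inter-stimulus gaps must be positive (events may not overlap)")
  if (n_channels < 1L || n_channels > 19L) stop("n_channels must be 1..19")
  structure(list(groups = groups, conditions = conditions, design = design,
                 effects = effects, couplings = couplings,
                 n_channels = as.integer(n_channels), fs = fs,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default rating-feature couplings
#'
#' Irritation rises with the slow-wave factor (hence falls with the Hjorth
#' parameters), empathy and arousal rise with the fast-band factor (hence
#' with the fractal dimension); pleasantness and fear are uncoupled.
#'
#' @return Named list of `list(latent, rho)`.
#' @export
default_couplings <- function() {
  list(irritation = list(latent = "slow", rho = 0.6),
       empathy    = list(latent = "fast", rho = 0.5),
       arousal    = list(latent = "fast", rho = 0.4))
}

# fraction of the clamped-1/f background variance lying in [lo, hi]
band_fraction <- function(lo, hi, exponent, fs) {
  num <- clamped_powerlaw_integral(lo, hi, exponent)
  den <- clamped_powerlaw_integral(0, fs / 2, exponent)
  num / den
}

clamped_powerlaw_integral <- function(a, b, e) {
  # integral of max(f,1)^-e over [a, b]
  flat <- max(0, min(b, 1) - min(a, 1))
  a1 <- max(a, 1); b1 <- max(b, 1)
  tail <- if (b1 > a1) {
    if (abs(e - 1) < 1e-12) log(b1 / a1)
    else (b1^(1 - e) - a1^(1 - e)) / (1 - e)
  } else 0
  flat + tail
}

# variance of x carried by frequencies inside [lo, hi] (two-sided DFT sum);
# band-boost components are normalized by this, not by their total variance,
# so the configured gain refers to power actually delivered inside the band
inband_var <- function(x, fs, lo, hi) {
  n <- length(x)
  X <- Mod(stats::fft(x))^2 / n^2
  f <- (seq_len(n) - 1L) * fs / n
  f <- pmin(f, fs - f)
  sum(X[f >= lo & f <= hi])
}

alpha_channel_weights <- function(labels, spatial = "posterior") {
  if (identical(spatial, "uniform"))
    return(stats::setNames(rep(0.9, length(labels)), labels))
  w <- rep(0.3, length(labels))
  names(w) <- labels
  w[labels %in% c("O1", "O2")] <- 1.0
  w[labels %in% c("P3", "Pz", "P4", "T5", "T6")] <- 0.85
  w[labels %in% c("C3", "Cz", "C4")] <- 0.7
  w[labels %in% c("T3", "T4")] <- 0.45
  w[labels %in% c("Fp1", "Fp2")] <- 0.2
  w
}

# raised-cosine on/off ramp over the first/last `ramp` samples of a window
ramp_window <- function(len, ramp) {
  r <- min(ramp, len %/% 2L)
  if (r < 1L) return(rep(1, len))
  up <- 0.5 - 0.5 * cos(pi * seq_len(r) / r)
  c(up, rep(1, len - 2L * r), rev(up))
}

#' Generate one synthetic subject
#'
#' Lays out `n_epochs` presentations per condition in random order with
#' 0.7-2.0 s gaps, then synthesizes a multichannel recording: independent
#' 1/f background per channel, a shared amplitude-modulated alpha sinusoid
#' weighted toward posterior channels, the profile's band boosts, and any
#' per-condition effect injections (ramped on/off inside epochs).
#'
#' @param profile a [spectral_profile()].
#' @param design design list (see [cohort_spec()]).
#' @param conditions condition labels to present.
#' @param seed integer seed (mandatory: generation is always reproducible).
#' @param subject_id,group metadata for the recording.
#' @param n_channels,fs montage size and sampling rate.
#' @param effects per-condition effect list (already filtered to this group).
#' @return List with `recording`, `events`, and `latents` (the subject's
#'   standard-normal factors `slow`, `fast`, `alpha`, `base`).
#' @export
gen_subject <- function(profile, design, conditions, seed,
                        subject_id = "S0", group = "unknown",
                        n_channels = 19L, fs = 250, effects = list()) {
  if (is.null(seed)) stop("gen_subject: seed is mandatory")
  set.seed(as.integer(seed))
  labels <- channels_1020()[seq_len(n_channels)]

  # subject-level latent factors -> multiplicative deviations
  z <- list(slow = stats::rnorm(1), fast = stats::rnorm(1),
            alpha = stats::rnorm(1), base = stats::rnorm(1))
  ssd <- profile$subject_sd
  base_uv <- profile$base_uv * exp(ssd$base * z$base)
  alpha_amp <- profile$alpha$amp_uv * exp(ssd$alpha * z$alpha)

  # event layout: random presentation order, jittered gaps
  pres <- sample(rep(conditions, each = design$n_epochs))
  t0 <- design$lead_s %||% 1
  onset <- numeric(length(pres))
  for (i in seq_along(pres)) {
    onset[i] <- t0
    t0 <- t0 + design$epoch_s +
      stats::runif(1, design$gap_range[1], design$gap_range[2])
  }
  events <- validate_events(data.frame(onset_s = onset,
                                       duration_s = design$epoch_s,
                                       label = pres))
  n <- as.integer(ceiling(t0 + 0.5) * fs)       # whole seconds, EDF-friendly
  tt <- (seq_len(n) - 1L) / fs

  # shared AM alpha carrier, unit RMS
  ph <- stats::runif(2, 0, 2 * pi)
  am <- 1 + profile$alpha$depth * cos(2 * pi * profile$alpha$mod_hz * tt + ph[1])
  carrier <- am * sin(2 * pi * profile$alpha$freq_hz * tt + ph[2])
  carrier <- carrier / sqrt(mean(carrier^2))
  wts <- alpha_channel_weights(labels, profile$alpha$spatial %||% "posterior")

  data <- matrix(0, n_channels, n)
  boost_bands <- lapply(profile$band_boosts, function(b)
    band_spec(b$low_hz, b$high_hz, order = 8L, purpose = "wideband"))
  for (ch in seq_len(n_channels)) {
    sig <- base_uv * gen_colored_noise(n, fs, profile$exponent)
    for (k in seq_along(profile$band_boosts)) {
      b <- profile$band_boosts[[k]]
      zk <- if (b$high_hz <= 10) z$slow else z$fast
      gain <- b$gain * exp(ssd$band * zk)
      comp <- bandpass(stats::rnorm(n), fs, boost_bands[[k]])
      comp <- comp / sqrt(inband_var(comp, fs, b$low_hz, b$high_hz))
      sig <- sig + comp * base_uv *
        sqrt(gain * band_fraction(b$low_hz, b$high_hz, profile$exponent, fs))
    }
    data[ch, ] <- sig + alpha_amp * wts[ch] * carrier
  }

  # per-condition effect injections, ramped inside epoch windows
  for (ef in effects) {
    rows <- which(events$label == ef$condition)
    if (length(rows) == 0L) next
    for (r in rows) {
      a <- round(events$onset_s[r] * fs) + 1L
      len <- round(events$duration_s[r] * fs)
      idx <- a:(a + len - 1L)
      rmp <- ramp_window(len, round(0.2 * fs))
      if (identical(ef$band, "alpha")) {
        add <- (ef$gain - 1) * alpha_amp * carrier[idx] * rmp
        for (ch in seq_len(n_channels)) data[ch, idx] <- data[ch, idx] + wts[ch] * add
      } else {
        bs <- band_spec(ef$band[1], ef$band[2], order = 8L)
        amp <- base_uv * sqrt(ef$gain *
                                band_fraction(ef$band[1], ef$band[2],
                                              profile$exponent, fs))
        for (ch in seq_len(n_channels)) {
          comp <- bandpass(stats::rnorm(len + 2L * 250L), fs, bs)
          comp <- comp[251:(250 + len)]
          comp <- comp / sqrt(inband_var(comp, fs, ef$band[1], ef$band[2]))
          data[ch, idx] <- data[ch, idx] + amp * comp * rmp
        }
      }
    }
  }

  list(recording = new_recording(data, fs, labels, subject_id, group),
       events = events, latents = z)
}

rating_scales <- function() {
  data.frame(scale = c("pleasantness", "arousal", "fear", "empathy",
                       "irritation"),
             lo = c(-5, 0, 0, 0, 0), hi = c(5, 10, 10, 10, 10),
             mu = c(0, 5, 5, 5, 5), sd = c(2, 2, 2, 2, 2),
             stringsAsFactors = FALSE)
}

#' Generate a full synthetic cohort
#'
#' One recording + event table per subject (deterministic per-subject seeds
#' derived from the spec seed), plus a subjective-ratings table for every
#' non-comatose subject and stimulus condition: each rating is a clamped
#' Gaussian on the scale's printed range whose standardized latent part is
#' `rho * z + sqrt(1 - rho^2) * noise` on the subject factor named in the
#' coupling, so configured rating-feature couplings hold in expectation.
#'
#' @param spec a [cohort_spec()].
#' @return List with `subjects` (each: `recording`, `events`, `latents`,
#'   `subject_id`, `group`), `ratings` (long data.frame; empty when no
#'   stimulus conditions are present), and `spec`.
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  subjects <- list()
  ratings <- list()
  stimuli <- setdiff(spec$conditions, c("rest_open", "rest_closed"))
  scales <- rating_scales()
  i <- 0L
  for (gname in names(spec$groups)) {
    g <- spec$groups[[gname]]
    efs <- Filter(function(e) identical(e$group, gname), spec$effects)
    for (k in seq_len(g$n_subjects)) {
      i <- i + 1L
      sid <- sprintf("S%03d", i)
      sseed <- (spec$seed %% 100000L) * 20011L + i * 7919L
      subj <- gen_subject(g$profile, spec$design, spec$conditions,
                          seed = sseed, subject_id = sid, group = gname,
                          n_channels = spec$n_channels, fs = spec$fs,
                          effects = efs)
      subj$subject_id <- sid; subj$group <- gname
      subjects[[sid]] <- subj
      if (gname != "coma" && length(stimuli) > 0L) {
        for (stim in stimuli) {
          val <- vapply(seq_len(nrow(scales)), function(j) {
            sc <- scales[j, ]
            cp <- spec$couplings[[sc$scale]]
            zlat <- if (is.null(cp)) stats::rnorm(1) else
              cp$rho * subj$latents[[cp$latent]] +
              sqrt(1 - cp$rho^2) * stats::rnorm(1)
            min(sc$hi, max(sc$lo, sc$mu + sc$sd * zlat))
          }, 0.0)
          ratings[[length(ratings) + 1L]] <-
            data.frame(subject = sid, group = gname, stimulus = stim,
                       scale = scales$scale, value = val,
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  rat <- if (length(ratings)) do.call(rbind, ratings) else
    data.frame(subject = character(), group = character(),
               stimulus = character(), scale = character(),
               value = numeric(), stringsAsFactors = FALSE)
  rownames(rat) <- NULL
  list(subjects = subjects, ratings = rat, spec = spec)
}
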