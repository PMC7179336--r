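# Nonlinear / time-domain EEG features and unit-bin PSD.
#
# Feature set and bands:
#   FD               Higuchi fractal dimension      2-20 Hz filtered signal
#   HjorthMobility   sqrt(var(y') / var(y))         1.6-30 Hz
#   HjorthComplexity mobility(y') / mobility(y)     1.6-30 Hz
#   EMF              envelope mean frequency        1.6-30 Hz Hilbert envelope
#   EMFA             envelope mean frequency        8-13 Hz Hilbert envelope
#   RAT              envelope std / mean            1.6-30 Hz Hilbert envelope
# Derivatives are unscaled first differences (per-sample convention), which
# keeps the white-noise closed forms exact: mobility -> sqrt(2),
# complexity -> sqrt(3/2).

#' Names of the six extracted features
#' @return Character vector.
#' @export
feature_names <- function() {
  c("FD", "EMF", "EMFA", "RAT", "HjorthMobility", "HjorthComplexity")
}

#' Higuchi fractal dimension
#'
#' Estimates the fractal dimension of a series from the scaling of the mean
#' normalized curve length with the lag: for each `k = 1..k_max` and offset
#' `m = 1..k`, the length of the sub-series `x[m], x[m+k], ...` is
#' `L_m(k) = (sum |increments|) * (n-1) / (N_m * k) / k`, and the dimension
#' is minus the least-squares slope of `ln L(k)` on `ln k`. Values lie in
#' \[1, 2\]: 1 for smooth curves, 2 for uncorrelated noise; for fractional
#' Brownian motion FD = 2 - H.
#'
#' @param x numeric series, length at least `10 * k_max`, non-constant.
#' @param k_max maximum lag (default 8, common practice for multi-second
#'   windows at 250 Hz; the estimate is insensitive to k_max in 6..16).
#' @return Fractal dimension estimate (scalar).
#' @export
higuchi_fd <- function(x, k_max = 8L) {
  n <- length(x)
  if (k_max < 2L) stop("k_max must be at least 2")
  if (n < 10L * k_max) stop("series too short: need length >= 10 * k_max")
  if (stats::sd(x) == 0) stop("degenerate input: constant signal")
  Lk <- numeric(k_max)
  for (k in seq_len(k_max)) {
    Lm <- numeric(k)
    for (m in seq_len(k)) {
      sub <- x[seq.int(m, n, by = k)]
      nm <- length(sub) - 1L
      Lm[m] <- sum(abs(diff(sub))) * (n - 1) / (nm * k) / k
    }
    Lk[k] <- mean(Lm)
  }
  lk <- log(seq_len(k_max))
  ll <- log(Lk)
  -sum((lk - mean(lk)) * (ll - mean(ll))) / sum((lk - mean(lk))^2)
}

#' Hjorth mobility
#'
#' `sqrt(var(y') / var(y))` with the derivative taken as the unscaled first
#' difference. A time-domain proxy for mean frequency: for a sinusoid of
#' frequency f sampled at fs it equals `2 sin(pi f / fs)`.
#'
#' @param x numeric series, length >= 3, non-constant.
#' @return Mobility (non-negative scalar, per-sample units).
#' @export
hjorth_mobility <- function(x) {
  if (length(x) < 3L) stop("series too short for Hjorth parameters")
  v <- stats::var(x)
  if (v == 0) stop("degenerate input: zero variance")
  sqrt(stats::var(diff(x)) / v)
}

#' Hjorth complexity
#'
#' `mobility(y') / mobility(y)`: 1 for a pure sinusoid, larger for
#' broader-band signals (sqrt(3/2) for white noise).
#'
#' @param x numeric series, length >= 4; `var(x) > 0` and `var(diff(x)) > 0`.
#' @return Complexity (scalar >= ~1 for band-limited signals).
#' @export
hjorth_complexity <- function(x) {
  if (length(x) < 4L) stop("series too short for Hjorth complexity")
  d <- diff(x)
  if (stats::var(x) == 0 || stats::var(d) == 0)
    stop("degenerate input: zero variance")
  hjorth_mobility(d) / hjorth_mobility(x)
}

#' Amplitude envelope via the Hilbert transform
#'
#' Magnitude of the analytic signal, computed by zeroing negative
#' frequencies in the DFT. The input should already be band-pass filtered;
#' trim edges with [trim_envelope()] before computing statistics, since the
#' discrete Hilbert transform is unreliable near the endpoints.
#'
#' @param x band-limited numeric series, length >= 64.
#' @return Non-negative envelope series, same length as `x`.
#' @export
hilbert_envelope <- function(x) {
  n <- length(x)
  if (n < 64L) stop("series too short for a stable Hilbert envelope")
  if (all(x == 0)) stop("degenerate input: all-zero signal")
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n %/% 2L + 1L] <- 1; h[2L:(n %/% 2L)] <- 2
  } else {
    h[1L] <- 1; h[2L:((n + 1L) %/% 2L)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

#' Trim envelope edges
#'
#' Drops `trim_s` seconds from each end to suppress Hilbert end effects.
#'
#' @param env envelope series.
#' @param fs sampling rate in Hz.
#' @param trim_s seconds to drop per edge (default 0.5).
#' @return Trimmed series.
#' @export
trim_envelope <- function(env, fs, trim_s = 0.5) {
  k <- round(trim_s * fs)
  n <- length(env)
  if (2L * k >= n - 1L) stop("envelope too short to trim ", trim_s, " s per edge")
  env[(k + 1L):(n - k)]
}

#' Envelope mean frequency (EMF / EMFA)
#'
#' Average frequency of the envelope's fluctuations: the amplitude-spectrum
#' centroid of the mean-removed envelope over `(0, cap_hz]`. The cap keeps
#' the measure in the physiologically meaningful amplitude-modulation range.
#' A near-constant envelope (coefficient of variation below
#' `degenerate_cv`) has no oscillatory energy to summarize: the function
#' returns 0 with attribute `degenerate = TRUE`.
#'
#' @param env trimmed envelope series, at least 2 s of samples.
#' @param fs sampling rate in Hz.
#' @param cap_hz upper frequency bound of the centroid (default 12 Hz).
#' @param mode `"centroid"` (default) or `"peak"` (modal frequency).
#' @param degenerate_cv coefficient-of-variation floor (default 0.01).
#' @return Mean envelope frequency in Hz.
#' @export
envelope_mean_frequency <- function(env, fs, cap_hz = 12,
                                    mode = c("centroid", "peak"),
                                    degenerate_cv = 0.01) {
  mode <- match.arg(mode)
  n <- length(env)
  if (n < 2 * fs) stop("envelope shorter than 2 s")
  m <- mean(env)
  if (m <= 0 || stats::sd(env) / m < degenerate_cv)
    return(structure(0, degenerate = TRUE))
  A <- Mod(stats::fft(env - m))
  f <- (seq_len(n) - 1L) * fs / n
  i <- which(f > 0 & f <= cap_hz)
  if (sum(A[i]) == 0) return(structure(0, degenerate = TRUE))
  if (mode == "peak") f[i][which.max(A[i])]
  else sum(f[i] * A[i]) / sum(A[i])
}

#' Envelope coefficient of variation (RAT)
#'
#' Ratio of the envelope's standard deviation to its mean; dimensionless
#' instability index of the wideband amplitude. For sinusoidal amplitude
#' modulation of depth m it equals `m / sqrt(2)`.
#'
#' @param env trimmed envelope series.
#' @return `sd(env) / mean(env)`.
#' @export
envelope_cv <- function(env) {
  m <- mean(env)
  if (!is.finite(m) || m <= 0) stop("degenerate input: non-positive envelope mean")
  stats::sd(env) / m
}

#' Welch power spectral density
#'
#' Averaged modified periodogram with Hann-windowed segments at 50% overlap,
#' one-sided density scaling (integral over frequency equals the signal
#' variance). Segment length defaults to 4 s — a 0.25 Hz grid at 250 Hz, so
#' the Hann main lobe of a tonal component stays inside one unit bin.
#'
#' @param x numeric series (demeaned internally).
#' @param fs sampling rate in Hz.
#' @param seg_s segment length in seconds (shortened to the series length).
#' @return List with `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs, seg_s = 4) {
  n <- length(x)
  x <- x - mean(x)
  L <- min(n, round(seg_s * fs))
  w <- 0.5 - 0.5 * cos(2 * pi * seq.int(0L, L - 1L) / L)   # periodic Hann
  step <- max(1L, L %/% 2L)
  starts <- seq.int(1L, n - L + 1L, by = step)
  acc <- numeric(L)
  for (s in starts) {
    X <- stats::fft(x[s:(s + L - 1L)] * w)
    acc <- acc + Mod(X)^2
  }
  acc <- acc / length(starts) / (fs * sum(w^2))
  half <- L %/% 2L
  psd <- acc[1:(half + 1L)]
  psd[2:(half + (L %% 2L == 0L))] <- 2 * psd[2:(half + (L %% 2L == 0L))]
  list(freq = (0:half) * fs / L, psd = psd)
}

#' PSD integrated over unit-width bins, 2-20 Hz
#'
#' Integrates the Welch density over the 18 one-hertz intervals 2-3, 3-4,
#' ..., 19-20 Hz by trapezoid on the spectral grid (with interpolated bin
#' edges); adjacent bins share edge ordinates, so the bin total equals the
#' integral over 2-20 Hz.
#'
#' @param x numeric series, at least 2 s of samples.
#' @param fs sampling rate in Hz.
#' @param seg_s Welch segment length in seconds (default 4).
#' @return data.frame with `bin_lo`, `bin_hi`, `power` (microvolts squared),
#'   18 rows.
#' @export
psd_unit_bins <- function(x, fs, seg_s = 4) {
  if (length(x) < 2 * fs) stop("series shorter than 2 s")
  if (fs / 2 < 20) stop("sampling rate too low for 2-20 Hz bins")
  sp <- welch_psd(x, fs, seg_s = seg_s)
  power <- vapply(2:19, function(b) {
    inner <- which(sp$freq > b & sp$freq < b + 1)
    fgrid <- c(b, sp$freq[inner], b + 1)
    pgrid <- c(stats::approx(sp$freq, sp$psd, xout = b)$y,
               sp$psd[inner],
               stats::approx(sp$freq, sp$psd, xout = b + 1)$y)
    sum(diff(fgrid) * (pgrid[-1] + pgrid[-length(pgrid)]) / 2)
  }, 0.0)
  data.frame(bin_lo = 2:19, bin_hi = 3:20, power = power)
}

psd_col_names <- function() sprintf("psd_%d_%d", 2:19, 3:20)

feature_band <- c(FD = "fd", EMF = "wideband", EMFA = "alpha",
                  RAT = "wideband", HjorthMobility = "wideband",
                  HjorthComplexity = "wideband")

filter_rows <- function(epoch, fs, band, mode) {
  out <- t(apply(epoch, 1L, bandpass, fs = fs, band = band, mode = mode))
  if (nrow(epoch) == 1L) dim(out) <- c(1L, ncol(epoch))
  out
}

epoch_features <- function(epoch, fs, config, wideband = NULL) {
  feats <- config$features$which
  bands_needed <- unique(c("wideband", unname(feature_band[feats])))
  nch <- nrow(epoch)
  filt <- list(wideband = wideband)
  for (bn in bands_needed) {
    if (!is.null(filt[[bn]])) next
    filt[[bn]] <- filter_rows(epoch, fs, config$bands[[bn]], config$filter$mode)
  }
  vals <- matrix(NA_real_, nch, length(feats),
                 dimnames = list(NULL, feats))
  psd <- NULL
  want_env <- any(c("EMF", "RAT") %in% feats)
  for (ch in seq_len(nch)) {
    wb <- filt[["wideband"]][ch, ]
    if (want_env) {
      env <- trim_envelope(hilbert_envelope(wb), fs, config$features$trim_s)
      if ("EMF" %in% feats)
        vals[ch, "EMF"] <- envelope_mean_frequency(
          env, fs, cap_hz = config$features$emf_cap_hz,
          mode = config$features$emf_mode)
      if ("RAT" %in% feats) vals[ch, "RAT"] <- envelope_cv(env)
    }
    if ("EMFA" %in% feats) {
      enva <- trim_envelope(hilbert_envelope(filt[["alpha"]][ch, ]), fs,
                            config$features$trim_s)
      vals[ch, "EMFA"] <- envelope_mean_frequency(
        enva, fs, cap_hz = config$features$emf_cap_hz,
        mode = config$features$emf_mode)
    }
    if ("FD" %in% feats)
      vals[ch, "FD"] <- higuchi_fd(filt[["fd"]][ch, ], config$features$k_max)
    if ("HjorthMobility" %in% feats)
      vals[ch, "HjorthMobility"] <- hjorth_mobility(wb)
    if ("HjorthComplexity" %in% feats)
      vals[ch, "HjorthComplexity"] <- hjorth_complexity(wb)
  }
  psd <- t(vapply(seq_len(nch),
                  function(ch) psd_unit_bins(filt[["wideband"]][ch, ], fs,
                                             seg_s = config$features$welch_seg_s)$power,
                  numeric(18L)))
  list(features = vals, psd = psd, wideband = filt[["wideband"]])
}

#' Extract all features and PSD bins from a condition fragment
#'
#' Per epoch: the wideband-filtered epoch is screened by
#' [reject_artifacts()]; features are computed per channel on the band
#' appropriate to each feature and the unit-bin PSD on the wideband signal;
#' surviving epochs are then averaged per channel. Computing per epoch and
#' averaging (rather than concatenating presentations) avoids spurious
#' discontinuities in the Hilbert and FFT steps.
#'
#' @param fragment a `condition_fragment` from [segment()].
#' @param config configuration list (see [default_config()]).
#' @return List with `features` (long data.frame: subject, group, condition,
#'   channel, feature, value), `psd` (wide data.frame with `psd_2_3` ...
#'   `psd_19_20`), and `n_epochs_kept`.
#' @export
extract_all <- function(fragment, config = default_config()) {
  fs <- fragment$fs
  acc_f <- NULL; acc_p <- NULL; kept <- 0L
  for (ep in fragment$epochs) {
    wb <- filter_rows(ep, fs, config$bands$wideband, config$filter$mode)
    if (!reject_artifacts(wb, config$artifact$threshold_uv)) next
    res <- epoch_features(ep, fs, config, wideband = wb)
    kept <- kept + 1L
    acc_f <- if (is.null(acc_f)) res$features else acc_f + res$features
    acc_p <- if (is.null(acc_p)) res$psd else acc_p + res$psd
  }
  labels <- fragment$channel_labels
  if (kept == 0L) {
    warning("fragment '", fragment$condition, "': no epochs survived ",
            "artifact rejection")
    return(list(features = data.frame(), psd = data.frame(),
                n_epochs_kept = 0L))
  }
  fv <- acc_f / kept
  pv <- acc_p / kept
  feats <- colnames(fv)
  long <- data.frame(
    subject = fragment$subject_id, group = fragment$group,
    condition = fragment$condition,
    channel = rep(labels, times = length(feats)),
    feature = rep(feats, each = length(labels)),
    value = as.vector(fv), stringsAsFactors = FALSE)
  psd <- data.frame(subject = fragment$subject_id, group = fragment$group,
                    condition = fragment$condition, channel = labels,
                    stringsAsFactors = FALSE)
  psd[psd_col_names()] <- as.data.frame(pv)
  list(features = long, psd = psd, n_epochs_kept = kept)
}

#' Extract features for a whole cohort
#'
#' Segments every recording by its events and row-binds the per-fragment
#' outputs of [extract_all()].
#'
#' @param cohort list of subjects, each a list with `recording` and `events`
#'   (the structure returned by [gen_cohort()]).
#' @param config configuration list (see [default_config()]).
#' @return List with long `features` and wide `psd` data.frames.
#' @export
extract_cohort <- function(cohort, config = default_config()) {
  f_list <- list(); p_list <- list()
  for (subj in cohort$subjects) {
    frags <- segment(subj$recording, subj$events)
    for (fr in frags) {
      res <- extract_all(fr, config)
      if (nrow(res$features)) {
        f_list[[length(f_list) + 1L]] <- res$features
        p_list[[length(p_list) + 1L]] <- res$psd
      }
    }
  }
  list(features = do.call(rbind, f_list), psd = do.call(rbind, p_list))
}
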