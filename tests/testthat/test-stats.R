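test_that("ANOVA F matches brute-force sums of squares", {
  set.seed(41)
  for (rep_i in 1:10) {
    k <- sample(2:5, 1)
    ni <- sample(3:10, k, replace = TRUE)
    tab <- data.frame(subject = sprintf("S%03d", seq_len(sum(ni))),
                      group = rep(letters[1:k], times = ni),
                      condition = "rest_closed", channel = "Cz",
                      feature = "FD", value = rnorm(sum(ni)))
    rep_out <- group_anova_rest(tab)
    expect_equal(rep_out$F, bf_anova_F(tab$value, tab$group),
                 tolerance = 1e-9)
    expect_identical(rep_out$df1, k - 1L)
    expect_identical(rep_out$df2, sum(ni) - k)
  }
})

test_that("identical groups give F near zero and p near one", {
  set.seed(42)
  vals <- rnorm(12)
  tab <- data.frame(subject = sprintf("S%03d", 1:24),
                    group = rep(c("a", "b"), each = 12),
                    condition = "rest_closed", channel = "Cz",
                    feature = "FD", value = c(vals, vals))
  rep_out <- group_anova_rest(tab)
  expect_equal(rep_out$F, 0, tolerance = 1e-12)
  expect_equal(rep_out$p_raw, 1, tolerance = 1e-12)
})

test_that("Bonferroni adjustment uses the channel family and is monotone", {
  set.seed(43)
  tab <- null_feature_table(n_per_group = 5, groups = c("a", "b"),
                            channels = channels_1020()[1:6])
  rep_out <- group_anova_rest(tab)
  expect_equal(rep_out$p_adj, pmin(1, rep_out$p_raw * 6))
  expect_true(all(rep_out$p_adj >= rep_out$p_raw))
  rep_all <- group_anova_rest(tab, family = "all_cells")
  expect_true(all(rep_all$p_adj >= rep_out$p_adj - 1e-12))
})

test_that("significant channel sets render in the reporting style", {
  rep_out <- structure(
    data.frame(feature = "FD", channel = channels_1020(),
               significant = c(rep(TRUE, 17), FALSE, FALSE)),
    class = c("stat_report", "data.frame"))
  expect_identical(significant_channels(rep_out, "FD"), "all except O1, O2")
  rep_out$significant <- rep(TRUE, 19)
  expect_identical(significant_channels(rep_out, "FD"), "all")
  rep_out$significant <- rep(FALSE, 19)
  expect_identical(significant_channels(rep_out, "FD"), "none")
})

test_that("stimulation-vs-rest contrast detects forced shifts with Table-2 signs", {
  set.seed(44)
  base <- null_feature_table(n_per_group = 12, groups = "control",
                             channels = c("Fp1", "Cz", "O2"))
  stim <- base
  stim$condition <- "crying"
  stim$value <- base$value + 1.0 + rnorm(nrow(base), sd = 0.1)
  feats <- rbind(base, stim)
  sv <- stim_vs_rest(feats, "control", "crying")
  expect_true(all(sv$significant))
  expect_true(all(sv$sign == "-"))     # lower in rest

  stim0 <- base; stim0$condition <- "crying"
  sv0 <- stim_vs_rest(rbind(base, stim0), "control", "crying")
  expect_true(all(sv0$p_raw == 1))
  expect_true(all(sv0$statistic == 0))
})

test_that("an injected fast-band effect raises FD during stimulation", {
  spec <- cohort_spec(
    groups = list(control = list(n_subjects = 20,
                                 profile = group_profiles()$control)),
    conditions = c("rest_closed", "crying"),
    design = list(n_epochs = 2, epoch_s = 10, gap_range = c(0.7, 2),
                  lead_s = 1),
    effects = list(list(group = "control", condition = "crying",
                        band = c(15, 25), gain = 1.5)),
    n_channels = 19, seed = 77)
  cfg <- default_config()
  cfg$features$which <- "FD"
  res <- extract_cohort(gen_cohort(spec), cfg)
  sv <- stim_vs_rest(res$features, "control", "crying")
  expect_gte(mean(sv$significant), 0.7)
  expect_true(all(sv$sign[sv$significant] == "-"))   # FD higher under stimulus
})

test_that("PSD-feature correlations recover exact and null relations", {
  set.seed(45)
  n <- 100
  subjects <- sprintf("S%03d", 1:n)
  psd <- data.frame(subject = subjects, group = "g",
                    condition = "rest_closed", channel = "Cz")
  for (cn in sprintf("psd_%d_%d", 2:19, 3:20)) psd[[cn]] <- rnorm(n)^2
  feats <- data.frame(subject = subjects, group = "g",
                      condition = "rest_closed", channel = "Cz",
                      feature = "FD", value = psd$psd_5_6)
  cm <- psd_feature_correlations(feats, psd, pooling = "per_channel")
  expect_equal(cm$r[cm$bin_lo == 5], 1, tolerance = 1e-12)

  # independent columns: a |r| > 0.35 pass at n = 100 is a ~3e-4 event per
  # entry, so the 18-entry map should be (almost) empty
  feats$value <- rnorm(n)
  cm0 <- psd_feature_correlations(feats, psd, pooling = "per_channel")
  expect_lte(sum(cm0$significant), 1)

  # constant column is flagged not-computable
  feats$value <- 1
  cmc <- psd_feature_correlations(feats, psd, pooling = "per_channel")
  expect_true(all(!cmc$computable))
  expect_true(all(!cmc$significant))
})

test_that("rating correlations hit r = 1 on identical data and skip coma", {
  feats <- data.frame(subject = sprintf("S%03d", 1:20),
                      group = rep(c("control", "coma"), each = 10),
                      condition = "barking", channel = "Cz",
                      feature = "HjorthMobility",
                      value = rnorm(20))
  ratings <- data.frame(subject = sprintf("S%03d", 1:10), group = "control",
                        stimulus = "barking", scale = "irritation",
                        value = feats$value[1:10])
  expect_message(rc <- rating_feature_correlations(ratings, feats),
                 "no ratings")
  expect_equal(rc$r, 1, tolerance = 1e-12)
  expect_false("coma" %in% rc$group)
})

test_that("irritation-mobility coupling is recovered across replicate cohorts", {
  one_rep <- function(seed) {
    prof <- spectral_profile(
      exponent = 1.5, base_uv = 10,
      band_boosts = list(list(low_hz = 2, high_hz = 7, gain = 4)),
      alpha = list(freq_hz = 10, amp_uv = 3, mod_hz = 1, depth = 0.5,
                   spatial = "uniform"))
    spec <- cohort_spec(
      groups = list(patient = list(n_subjects = 30, profile = prof)),
      conditions = "barking",
      design = list(n_epochs = 1, epoch_s = 8, gap_range = c(0.7, 2),
                    lead_s = 1),
      couplings = list(irritation = list(latent = "slow", rho = 0.6)),
      n_channels = 1, seed = seed)
    cfg <- default_config()
    cfg$features$which <- "HjorthMobility"
    cfg$artifact$threshold_uv <- Inf   # no artifacts simulated; keep all n
    cohort <- gen_cohort(spec)
    res <- extract_cohort(cohort, cfg)
    rc <- rating_feature_correlations(cohort$ratings, res$features)
    rc$r[rc$scale == "irritation" & rc$feature == "HjorthMobility"]
  }
  rs <- vapply(1:200, one_rep, 0.0)
  expect_lt(mean(rs), 0)
  expect_gte(mean(rs <= -0.3), 0.8)
})
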