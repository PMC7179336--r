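# Statistical stage: between-group resting contrasts, paired
# stimulation-vs-rest contrasts, and PSD / rating correlation maps.
#
# Multiplicity convention: the Bonferroni family is the set of channels
# tested within one feature (the reporting unit is a per-feature channel
# list), adjustable via `family`. Omnibus tests use one-way ANOVA on the
# group factor — consistent with F(4, ~140)-style statistics for five
# groups — with Tukey HSD post-hocs only where the adjusted omnibus p falls
# below alpha.

#' Between-group contrasts of resting features
#'
#' One-way ANOVA of feature value on group, per (feature, channel), on the
#' chosen resting condition; Bonferroni adjustment across the family and
#' Tukey HSD post-hoc pairs for significant omnibus tests.
#'
#' @param features long feature table (subject, group, condition, channel,
#'   feature, value) with one value per subject per cell.
#' @param condition resting condition analyzed (default `"rest_closed"`).
#' @param alpha significance level after adjustment (default 0.05).
#' @param family `"channels_within_feature"` (default: m = channels tested
#'   for that feature) or `"all_cells"` (m = every (feature, channel) test).
#' @return A `stat_report`: data.frame with columns feature, channel, df1,
#'   df2, F, p_raw, p_adj, significant, and one `mean_<group>` column per
#'   group; Tukey pair results in `attr(, "posthoc")`.
#' @export
group_anova_rest <- function(features, condition = "rest_closed",
                             alpha = 0.05,
                             family = c("channels_within_feature",
                                        "all_cells")) {
  family <- match.arg(family)
  dat <- features[features$condition == condition, , drop = FALSE]
  if (nrow(dat) == 0L) stop("no rows for condition '", condition, "'")
  groups <- sort(unique(dat$group))
  if (length(groups) < 2L) stop("need at least two groups")
  rows <- list(); posthoc <- list()
  for (feat in unique(dat$feature)) {
    dfeat <- dat[dat$feature == feat, ]
    for (ch in unique(dfeat$channel)) {
      cell <- dfeat[dfeat$channel == ch, ]
      cnt <- table(cell$group)
      if (length(cnt) < 2L || any(cnt < 2L)) {
        message("skipping ", feat, "/", ch, ": empty or singleton group cell")
        next
      }
      cell$group <- factor(cell$group, levels = groups)
      fit <- stats::aov(value ~ group, data = cell)
      an <- summary(fit)[[1L]]
      gm <- tapply(cell$value, cell$group, mean)
      row <- data.frame(feature = feat, channel = ch,
                        df1 = as.integer(an$Df[1L]),
                        df2 = as.integer(an$Df[2L]),
                        F = an$`F value`[1L], p_raw = an$`Pr(>F)`[1L],
                        stringsAsFactors = FALSE)
      for (g in groups) row[[paste0("mean_", g)]] <- unname(gm[g])
      rows[[paste(feat, ch)]] <- row
      posthoc[[paste(feat, ch)]] <- fit
    }
  }
  rep <- do.call(rbind, rows)
  rownames(rep) <- NULL
  m <- if (family == "all_cells") nrow(rep) else
    stats::ave(rep$p_raw, rep$feature, FUN = length)
  rep$p_adj <- pmin(1, rep$p_raw * m)
  rep$significant <- is_significant(rep$p_adj, alpha)
  tk <- list()
  for (i in which(rep$significant)) {
    key <- paste(rep$feature[i], rep$channel[i])
    t1 <- stats::TukeyHSD(posthoc[[key]])$group
    tk[[key]] <- data.frame(feature = rep$feature[i], channel = rep$channel[i],
                            pair = rownames(t1), diff = t1[, "diff"],
                            p_tukey = t1[, "p adj"], stringsAsFactors = FALSE,
                            row.names = NULL)
  }
  structure(rep,
            posthoc = if (length(tk)) do.call(rbind, c(tk, make.row.names = FALSE)) else NULL,
            alpha = alpha, condition = condition, family = family,
            class = c("stat_report", "data.frame"))
}

#' Channel list string for a feature's significant channels
#'
#' Renders the set of significant channels in the compact reporting style
#' "all", "all except X, Y" or an explicit list.
#'
#' @param report a `stat_report`.
#' @param feature feature name.
#' @return Character scalar.
#' @export
significant_channels <- function(report, feature) {
  sub <- report[report$feature == feature, ]
  if (nrow(sub) == 0L) return("none tested")
  sig <- sub$channel[sub$significant]
  if (length(sig) == 0L) return("none")
  if (length(sig) == nrow(sub)) return("all")
  if (length(sig) > nrow(sub) / 2)
    return(paste("all except",
                 paste(setdiff(sub$channel, sig), collapse = ", ")))
  paste(sig, collapse = ", ")
}

#' Paired stimulation-versus-rest contrast within a group
#'
#' Per (feature, channel): a paired t-test of the condition value against
#' the resting value over the group's subjects (Wilcoxon signed-rank when
#' fewer than 8 pairs), Bonferroni-adjusted across channels within each
#' feature. The sign column follows the study's convention: "+" when the
#' value is higher in rest, "-" when lower in rest.
#'
#' @param features long feature table.
#' @param group group to analyze.
#' @param condition stimulus condition.
#' @param rest_condition baseline condition (default eyes-closed rest).
#' @param alpha significance level (default 0.05).
#' @return data.frame: feature, channel, n, statistic, p_raw, p_adj,
#'   significant, sign, mean_rest, mean_stim.
#' @export
stim_vs_rest <- function(features, group, condition,
                         rest_condition = "rest_closed", alpha = 0.05) {
  dat <- features[features$group == group, ]
  stim <- dat[dat$condition == condition, ]
  rest <- dat[dat$condition == rest_condition, ]
  if (nrow(stim) == 0L || nrow(rest) == 0L)
    stop("missing condition or rest rows for group '", group, "'")
  rows <- list()
  for (feat in unique(stim$feature)) {
    sfeat <- stim[stim$feature == feat, ]
    for (ch in unique(sfeat$channel)) {
      s <- sfeat[sfeat$channel == ch, ]
      r <- rest[rest$feature == feat & rest$channel == ch, ]
      common <- intersect(s$subject, r$subject)
      if (length(common) < 2L) {
        message("skipping ", feat, "/", ch, ": fewer than 2 pairs")
        next
      }
      if (length(common) < length(unique(s$subject)))
        message(feat, "/", ch, ": unpaired subjects dropped")
      sv <- s$value[match(common, s$subject)]
      rv <- r$value[match(common, r$subject)]
      d <- sv - rv
      if (all(d == 0)) {
        stat <- 0; p <- 1
      } else if (length(common) >= 8L) {
        tt <- stats::t.test(sv, rv, paired = TRUE)
        stat <- unname(tt$statistic); p <- tt$p.value
      } else {
        wt <- suppressWarnings(stats::wilcox.test(sv, rv, paired = TRUE,
                                                  exact = FALSE))
        stat <- unname(wt$statistic); p <- wt$p.value
      }
      rows[[paste(feat, ch)]] <-
        data.frame(feature = feat, channel = ch, n = length(common),
                   statistic = stat, p_raw = p,
                   mean_rest = mean(rv), mean_stim = mean(sv),
                   sign = if (mean(rv) >= mean(sv)) "+" else "-",
                   stringsAsFactors = FALSE)
    }
  }
  rep <- do.call(rbind, rows)
  rownames(rep) <- NULL
  m <- stats::ave(rep$p_raw, rep$feature, FUN = length)
  rep$p_adj <- pmin(1, rep$p_raw * m)
  rep$significant <- is_significant(rep$p_adj, alpha)
  structure(rep, group = group, condition = condition,
            rest_condition = rest_condition, alpha = alpha,
            class = c("stat_report", "data.frame"))
}

# alpha >= 1 is the documented degenerate configuration accepting every test
is_significant <- function(p_adj, alpha) {
  if (alpha >= 1) rep(TRUE, length(p_adj)) else p_adj < alpha
}

pearson_cell <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(x), computable = FALSE))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       computable = TRUE)
}

#' Correlation map between unit-bin PSD and nonlinear features
#'
#' Pearson r per (1-Hz bin, feature). Observations are (subject, condition)
#' cell means averaged over channels (default) or (subject, condition,
#' channel) triples. Entries are masked as significant when `p < alpha` and
#' `|r| > r_display`; non-significant entries keep their r but are flagged.
#'
#' @param features long feature table.
#' @param psd wide PSD table (`psd_2_3` ... `psd_19_20` columns).
#' @param alpha significance level (default 0.05).
#' @param r_display display threshold on `|r|` (default 0.35).
#' @param pooling `"channel_mean"` (default) or `"per_channel"`.
#' @return A `correlation_map` data.frame: bin_lo, bin_hi, feature, r, p, n,
#'   computable, significant.
#' @export
psd_feature_correlations <- function(features, psd, alpha = 0.05,
                                     r_display = 0.35,
                                     pooling = c("channel_mean",
                                                 "per_channel")) {
  pooling <- match.arg(pooling)
  bins <- psd_col_names()
  if (pooling == "channel_mean") {
    fagg <- stats::aggregate(value ~ subject + condition + feature,
                             data = features, FUN = mean)
    pagg <- stats::aggregate(psd[bins],
                             by = psd[c("subject", "condition")], FUN = mean)
    unit <- c("subject", "condition")
  } else {
    fagg <- features[c("subject", "condition", "channel", "feature", "value")]
    pagg <- psd[c("subject", "condition", "channel", bins)]
    unit <- c("subject", "condition", "channel")
  }
  fwide <- stats::reshape(fagg, idvar = unit, timevar = "feature",
                          direction = "wide")
  names(fwide) <- sub("^value\\.", "", names(fwide))
  obs <- merge(fwide, pagg, by = unit)
  feats <- setdiff(names(fwide), unit)
  rows <- list()
  for (b in seq_along(bins)) {
    for (feat in feats) {
      pc <- pearson_cell(obs[[bins[b]]], obs[[feat]])
      rows[[paste(b, feat)]] <-
        data.frame(bin_lo = b + 1L, bin_hi = b + 2L, feature = feat,
                   r = pc$r, p = pc$p, n = pc$n, computable = pc$computable,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$significant <- out$computable & !is.na(out$p) &
    out$p < alpha & abs(out$r) > r_display
  structure(out, alpha = alpha, r_display = r_display, pooling = pooling,
            class = c("correlation_map", "data.frame"))
}

#' Correlation map between subjective ratings and features
#'
#' Pearson r per (rating scale, feature) within (group, condition) strata:
#' feature values are channel means per subject for the stimulus condition,
#' matched with that subject's rating of the stimulus. Groups without
#' ratings (comatose patients by design) are skipped with a log message.
#'
#' @param ratings long ratings table (subject, group, stimulus, scale,
#'   value).
#' @param features long feature table.
#' @param alpha,r_display significance and display thresholds.
#' @return A `correlation_map` data.frame: group, condition, scale, feature,
#'   r, p, n, computable, significant.
#' @export
rating_feature_correlations <- function(ratings, features, alpha = 0.05,
                                        r_display = 0.35) {
  rows <- list()
  for (g in sort(unique(features$group))) {
    rg <- ratings[ratings$group == g, ]
    if (nrow(rg) == 0L) {
      message("group '", g, "' has no ratings; skipped")
      next
    }
    fg <- features[features$group == g, ]
    for (cond in intersect(unique(fg$condition), unique(rg$stimulus))) {
      fc <- fg[fg$condition == cond, ]
      fagg <- stats::aggregate(value ~ subject + feature, data = fc,
                               FUN = mean)
      rc <- rg[rg$stimulus == cond, ]
      for (sc in unique(rc$scale)) {
        rsc <- rc[rc$scale == sc, ]
        for (feat in unique(fagg$feature)) {
          fv <- fagg[fagg$feature == feat, ]
          common <- intersect(fv$subject, rsc$subject)
          pc <- pearson_cell(fv$value[match(common, fv$subject)],
                             rsc$value[match(common, rsc$subject)])
          rows[[length(rows) + 1L]] <-
            data.frame(group = g, condition = cond, scale = sc,
                       feature = feat, r = pc$r, p = pc$p, n = pc$n,
                       computable = pc$computable, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0L) stop("no (group, condition) strata with ratings")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$significant <- out$computable & !is.na(out$p) &
    out$p < alpha & abs(out$r) > r_display
  structure(out, alpha = alpha, r_display = r_display,
            class = c("correlation_map", "data.frame"))
}
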