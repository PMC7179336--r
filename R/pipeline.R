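# Pipeline orchestration: YAML configuration, the three run stages
# (simulate -> extract -> stats) and reproducibility manifests.  The
# analysis/ scripts in the repository are thin drivers over these functions.

#' Read a run configuration from YAML
#'
#' Any key present in the file overrides the matching [default_config()]
#' entry; bands may be given as `[low, high]` pairs. All parameters are
#' validated before anything is computed.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return Validated configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (!is.null(user$bands)) {
      for (bn in names(user$bands)) {
        b <- user$bands[[bn]]
        ord <- user$filter$order %||% cfg$filter$order
        cfg$bands[[bn]] <- band_spec(b[[1]], b[[2]], order = ord,
                                     purpose = cfg$bands[[bn]]$purpose %||% "wideband")
      }
    }
    for (sec in c("filter", "artifact", "features", "stats"))
      for (k in names(user[[sec]])) cfg[[sec]][[k]] <- user[[sec]][[k]]
  }
  stopifnot(cfg$artifact$threshold_uv > 0,
            cfg$features$k_max >= 2,
            cfg$features$trim_s >= 0,
            cfg$stats$alpha > 0, cfg$stats$alpha <= 1,
            cfg$stats$r_display >= 0,
            all(cfg$features$which %in% feature_names()))
  cfg
}

#' Read a cohort specification from YAML
#'
#' Fields mirror [cohort_spec()]; group profiles may override any
#' [spectral_profile()] field of the named default profile.
#'
#' @param path YAML file path.
#' @return A `cohort_spec`.
#' @export
read_cohort_spec <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("cohort spec: seed is mandatory")
  defaults <- group_profiles()
  groups <- NULL
  if (!is.null(y$groups)) {
    groups <- lapply(y$groups, function(g) {
      prof <- defaults[[g$profile %||% g$name]] %||% spectral_profile()
      for (k in intersect(names(g), c("exponent", "base_uv", "band_boosts",
                                      "alpha", "subject_sd")))
        prof[[k]] <- g[[k]]
      list(n_subjects = g$n_subjects, profile = prof)
    })
    names(groups) <- vapply(y$groups, `[[`, "", "name")
  }
  args <- list(seed = y$seed)
  if (!is.null(groups)) args$groups <- groups
  for (k in c("conditions", "effects", "n_per_group", "n_channels", "fs"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  if (!is.null(y$design)) {
    d <- formals(cohort_spec)$design
    d <- eval(d)
    for (k in names(y$design)) d[[k]] <- y$design[[k]]
    args$design <- d
  }
  if (!is.null(y$effects))
    args$effects <- lapply(y$effects, function(e) {
      if (!identical(e$band, "alpha")) e$band <- as.numeric(unlist(e$band))
      e
    })
  do.call(cohort_spec, args)
}

config_hash <- function(obj) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(dir, config, files, extra = list()) {
  man <- c(list(package = "nleeg",
                version = as.character(utils::packageVersion("nleeg")),
                config_hash = config_hash(config),
                files = as.list(tools::md5sum(file.path(dir, files)))),
           extra)
  names(man$files) <- files
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(man)
}

#' Simulate a cohort to disk
#'
#' Generates the cohort and writes one EDF recording and one events TSV per
#' subject, a cohort roster, the ratings table, and a `manifest.json` with
#' the spec hash, package version and per-file checksums. Identical specs
#' (including the seed) give byte-identical outputs.
#'
#' @param spec a [cohort_spec()] or path to a YAML spec.
#' @param out_dir output directory (created if missing).
#' @return The manifest, invisibly.
#' @export
run_simulate <- function(spec, out_dir) {
  if (is.character(spec)) spec <- read_cohort_spec(spec)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- gen_cohort(spec)
  files <- character()
  roster <- list()
  for (sid in names(cohort$subjects)) {
    subj <- cohort$subjects[[sid]]
    edf <- paste0(sid, ".edf"); ev <- paste0(sid, "_events.tsv")
    write_edf(subj$recording, file.path(out_dir, edf))
    write_events(subj$events, file.path(out_dir, ev))
    files <- c(files, edf, ev)
    roster[[sid]] <- data.frame(subject = sid, group = subj$group,
                                edf = edf, events = ev,
                                stringsAsFactors = FALSE)
  }
  utils::write.table(do.call(rbind, roster), file.path(out_dir, "cohort.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_ratings(cohort$ratings, file.path(out_dir, "ratings.tsv"))
  files <- c(files, "cohort.tsv", "ratings.tsv")
  write_manifest(out_dir, spec, files, extra = list(seed = spec$seed))
}

#' Load a simulated cohort directory
#'
#' @param dir directory written by [run_simulate()].
#' @return Cohort list (`subjects`, `ratings`) as from [gen_cohort()].
#' @export
load_cohort_dir <- function(dir) {
  roster <- utils::read.delim(file.path(dir, "cohort.tsv"),
                              stringsAsFactors = FALSE)
  subjects <- list()
  for (i in seq_len(nrow(roster))) {
    sid <- roster$subject[i]
    subjects[[sid]] <- list(
      recording = read_edf(file.path(dir, roster$edf[i]),
                           subject_id = sid, group = roster$group[i]),
      events = read_events(file.path(dir, roster$events[i])),
      subject_id = sid, group = roster$group[i])
  }
  list(subjects = subjects,
       ratings = read_ratings(file.path(dir, "ratings.tsv")))
}

#' Extract features for a simulated cohort directory
#'
#' Reads the cohort back from disk, runs [extract_cohort()], and writes
#' `features.tsv`, `psd.tsv`, a JSON provenance sidecar echoing every
#' analysis parameter, and a manifest.
#'
#' @param cohort_dir directory written by [run_simulate()].
#' @param out_dir output directory.
#' @param config configuration list (see [read_run_config()]).
#' @return The manifest, invisibly.
#' @export
run_extract <- function(cohort_dir, out_dir, config = default_config()) {
  if (!dir.exists(cohort_dir)) stop("input path not found: ", cohort_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- load_cohort_dir(cohort_dir)
  res <- extract_cohort(cohort, config)
  write_feature_table(res$features, file.path(out_dir, "features.tsv"))
  write_psd_table(res$psd, file.path(out_dir, "psd.tsv"))
  jsonlite::write_json(config, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  write_manifest(out_dir, config,
                 c("features.tsv", "psd.tsv", "provenance.json"))
}

#' Run the statistical stage on extracted tables
#'
#' Between-group resting ANOVA (with Tukey post-hocs and per-feature
#' channel-list strings), the PSD-feature correlation map, and — when a
#' ratings table is available — rating-feature correlations. Results are
#' written as TSV plus a JSON summary.
#'
#' @param extract_dir directory written by [run_extract()].
#' @param out_dir output directory.
#' @param config configuration list.
#' @param ratings_path optional path to a ratings TSV (e.g. from the
#'   simulation directory).
#' @return List of the computed reports, invisibly.
#' @export
run_stats <- function(extract_dir, out_dir, config = default_config(),
                      ratings_path = NULL) {
  if (!dir.exists(extract_dir)) stop("input path not found: ", extract_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  features <- read_feature_table(file.path(extract_dir, "features.tsv"))
  psd <- read_psd_table(file.path(extract_dir, "psd.tsv"))
  st <- config$stats
  reports <- list()
  if (st$rest_condition %in% features$condition) {
    an <- group_anova_rest(features, condition = st$rest_condition,
                           alpha = st$alpha,
                           family = if (st$family == "all_cells")
                             "all_cells" else "channels_within_feature")
    utils::write.table(as.data.frame(an), file.path(out_dir, "anova_rest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ph <- attr(an, "posthoc")
    if (!is.null(ph))
      utils::write.table(ph, file.path(out_dir, "anova_rest_tukey.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    reports$anova_rest <- an
    reports$channel_lists <- vapply(unique(an$feature),
                                    function(f) significant_channels(an, f), "")
  }
  cm <- psd_feature_correlations(features, psd, alpha = st$alpha,
                                 r_display = st$r_display,
                                 pooling = st$pooling)
  utils::write.table(as.data.frame(cm),
                     file.path(out_dir, "psd_feature_correlations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  reports$psd_correlations <- cm
  if (!is.null(ratings_path) && file.exists(ratings_path)) {
    ratings <- read_ratings(ratings_path)
    stim_conds <- intersect(unique(features$condition),
                            unique(ratings$stimulus))
    if (nrow(ratings) > 0L && length(stim_conds) > 0L) {
      rc <- rating_feature_correlations(ratings, features,
                                        alpha = st$alpha,
                                        r_display = st$r_display)
      utils::write.table(as.data.frame(rc),
                         file.path(out_dir, "rating_feature_correlations.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      reports$rating_correlations <- rc
    }
  }
  summary <- list(
    alpha = st$alpha, r_display = st$r_display,
    channel_lists = as.list(reports$channel_lists %||% list()),
    n_significant_psd_correlations = sum(cm$significant))
  jsonlite::write_json(summary, file.path(out_dir, "stats_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(out_dir, config,
                 intersect(list.files(out_dir),
                           c("anova_rest.tsv", "anova_rest_tukey.tsv",
                             "psd_feature_correlations.tsv",
                             "rating_feature_correlations.tsv",
                             "stats_summary.json")))
  invisible(reports)
}
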