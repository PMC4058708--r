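#' Default pipeline configuration
#'
#' Every threshold with a published value defaults to it: significance
#' criteria fractions 0.05 and 0.50, 2-s Hann windows, 1-25 Hz grid, 1-100 Hz
#' band-pass, average reference, 300-s clinical epochs, clinical windows
#' 0-24/0-48/0-72 h. Package-level defaults fill the rest: G(n,m) reference
#' with n_rand = 50 draws; a 3 uV absolute amplitude floor in the peak
#' criteria (the published relative criteria alone detect "peaks" in pure
#' noise, so attenuated recordings would masquerade as dense random networks;
#' see the methods vignette); sum-of-ranks orientation with C inverted; and
#' desk-scale simulation sizes (10 + 10 subjects, 60-s epochs at hours
#' 6/30/60).
#'
#' @param ... named overrides of any config entry.
#' @return A config list.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1,
    out_dir = ".",
    # simulate
    n_survivors = 10, n_nonsurvivors = 10,
    epoch_duration = 60, epoch_hours = c(6, 30, 60),
    # analyze
    criteria = list(ratio_local = 0.05, ratio_max = 0.50,
                    neighborhood_s = 2, amplitude_floor = 3),
    band = c(1, 100), rereference = TRUE,
    n_rand = 50,
    # report
    windows = c(24, 48, 72),
    orientation = c(network_size = 1, n_connections = 1,
                    C_rel = -1, L_rel = 1)
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Unspecified entries fall back to [default_config()].
#'
#' @param path YAML file.
#' @return A config list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (nm in names(user)) {
    if (nm == "criteria") cfg$criteria[names(user$criteria)] <- user$criteria
    else if (nm == "orientation") cfg$orientation[names(user$orientation)] <-
        unlist(user$orientation)
    else cfg[[nm]] <- if (is.list(user[[nm]])) user[[nm]] else
      unlist(user[[nm]])
  }
  cfg
}

.cfg_criteria <- function(cfg) do.call(criteria_config, cfg$criteria)

#' Simulate a cohort to disk
#'
#' Generates the synthetic cohort of [generate_cohort()] and writes one EDF
#' file per subject-epoch, a `metadata.csv` (subject labels), an
#' `epochs.csv` (file, subject, start hour) and a `manifest.csv` with MD5
#' checksums of every written file.
#'
#' @param config a config list (see [default_config()]).
#' @return The manifest data.frame, invisibly.
#' @export
run_simulate <- function(config = default_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(config$out_dir, 2) != 0)
    .stopf("output directory not writable: %s", config$out_dir)
  profile <- config$effect_profile
  if (is.null(profile)) profile <- default_effect_profile()
  cohort <- generate_cohort(config$n_survivors, config$n_nonsurvivors,
                            effect_profile = profile,
                            seed = config$seed,
                            epoch_duration = config$epoch_duration,
                            epoch_hours = config$epoch_hours)
  epoch_rows <- list()
  for (subj in cohort) {
    for (ep in subj$epochs) {
      f <- sprintf("%s_h%03d.edf", subj$subject_id, ep$start_hour)
      write_edf(ep$recording, file.path(config$out_dir, f),
                patient_id = subj$subject_id)
      epoch_rows[[length(epoch_rows) + 1L]] <- data.frame(
        file = f, subject_id = subj$subject_id, start_hour = ep$start_hour)
    }
  }
  epochs <- do.call(rbind, epoch_rows)
  utils::write.csv(epochs, file.path(config$out_dir, "epochs.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort_metadata(cohort),
                   file.path(config$out_dir, "metadata.csv"),
                   row.names = FALSE)
  files <- c(epochs$file, "epochs.csv", "metadata.csv")
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(config$out_dir, files))))
  utils::write.csv(manifest, file.path(config$out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Analyze a simulated or recorded cohort on disk
#'
#' Reads every epoch EDF listed in `epochs.csv`, preprocesses it (average
#' reference, band-pass), runs the spectral and network stages and writes
#' `metrics.csv` with one row per subject-epoch.
#'
#' @param config a config list; `out_dir` must contain `epochs.csv`,
#'   `metadata.csv` and the EDF files.
#' @return The metrics data.frame, invisibly.
#' @export
run_analyze <- function(config = default_config()) {
  epath <- file.path(config$out_dir, "epochs.csv")
  mpath <- file.path(config$out_dir, "metadata.csv")
  if (!file.exists(epath) || !file.exists(mpath))
    .stopf("missing epochs.csv / metadata.csv in %s", config$out_dir)
  epochs <- utils::read.csv(epath, stringsAsFactors = FALSE)
  metadata <- utils::read.csv(mpath, stringsAsFactors = FALSE)
  orphan <- setdiff(epochs$subject_id, metadata$subject_id)
  if (length(orphan) > 0L)
    .stopf("recordings without metadata: %s", paste(orphan, collapse = ", "))
  crit <- .cfg_criteria(config)
  cache <- new.env(parent = emptyenv())
  rows <- lapply(seq_len(nrow(epochs)), function(i) {
    rec <- read_recording(file.path(config$out_dir, epochs$file[i]))
    rec <- preprocess(rec, band = config$band,
                      rereference = config$rereference)
    cbind(data.frame(subject_id = epochs$subject_id[i],
                     start_hour = epochs$start_hour[i]),
          analyze_epoch(rec, crit, n_rand = config$n_rand,
                        seed = config$seed, cache = cache))
  })
  metrics <- do.call(rbind, rows)
  utils::write.csv(metrics, file.path(config$out_dir, "metrics.csv"),
                   row.names = FALSE)
  invisible(metrics)
}

#' Analyze an in-memory synthetic cohort
#'
#' Same computation as [run_analyze()] without the EDF round trip: each
#' epoch recording is preprocessed and analyzed, yielding the per-epoch
#' metrics table.
#'
#' @param cohort output of [generate_cohort()].
#' @param config a config list.
#' @return data.frame with one row per subject-epoch.
#' @export
analyze_cohort <- function(cohort, config = default_config()) {
  crit <- .cfg_criteria(config)
  cache <- new.env(parent = emptyenv())
  rows <- list()
  for (subj in cohort) {
    for (ep in subj$epochs) {
      rec <- preprocess(ep$recording, band = config$band,
                        rereference = config$rereference)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(subject_id = subj$subject_id, start_hour = ep$start_hour),
        analyze_epoch(rec, crit, n_rand = config$n_rand,
                      seed = config$seed, cache = cache))
    }
  }
  do.call(rbind, rows)
}

#' Outcome-contrast report over clinical windows
#'
#' For each window (0-24, 0-48, 0-72 h): per-metric survivor versus
#' non-survivor pooled t-tests, the sum-of-ranks composite with its Wilcoxon
#' rank-sum test, Spearman correlations with the CPC score, and the ROC of
#' the composite for predicting poor outcome.
#'
#' @param metrics per-epoch metrics table (from [run_analyze()] or
#'   [analyze_cohort()]).
#' @param metadata subject metadata table.
#' @param config a config list.
#' @return List with `contrasts` (data.frame), `correlations` (data.frame)
#'   and `roc` (list per window).
#' @export
cohort_report <- function(metrics, metadata, config = default_config()) {
  if (length(unique(metadata$survivor)) < 2)
    .stopf("need both survivors and non-survivors in the metadata")
  summaries <- subject_summaries(metrics, config$windows)
  contrast_rows <- list(); corr_rows <- list(); rocs <- list()
  test_metrics <- c("network_size", "n_connections", "L_rel", "C_rel", "SWI")
  for (w in config$windows) {
    s <- summaries[summaries$window_h == w, , drop = FALSE]
    md <- metadata[match(s$subject_id, metadata$subject_id), ]
    surv <- as.logical(md$survivor)
    for (mc in test_metrics) {
      r <- compare_groups(s[[mc]], surv)
      contrast_rows[[length(contrast_rows) + 1L]] <- data.frame(
        window_h = w, metric = mc,
        survivor_mean = r$mean1, survivor_sd = r$sd1, n_survivors = r$n1,
        nonsurvivor_mean = r$mean2, nonsurvivor_sd = r$sd2,
        n_nonsurvivors = r$n2, statistic = r$t, p = r$p)
      cr <- correlate_cpc(s[[mc]], md$cpc)
      corr_rows[[length(corr_rows) + 1L]] <- data.frame(
        window_h = w, metric = mc, rho = cr$rho, p = cr$p, n = cr$n)
    }
    sr <- sum_of_ranks(s, surv, orientation = config$orientation)
    contrast_rows[[length(contrast_rows) + 1L]] <- data.frame(
      window_h = w, metric = "sum_of_ranks",
      survivor_mean = sr$mean1, survivor_sd = sr$sd1,
      n_survivors = sum(surv & !is.na(sr$scores)),
      nonsurvivor_mean = sr$mean2, nonsurvivor_sd = sr$sd2,
      n_nonsurvivors = sum(!surv & !is.na(sr$scores)),
      statistic = sr$W, p = sr$p)
    cr <- correlate_cpc(sr$scores, md$cpc)
    corr_rows[[length(corr_rows) + 1L]] <- data.frame(
      window_h = w, metric = "sum_of_ranks", rho = cr$rho, p = cr$p, n = cr$n)
    rocs[[as.character(w)]] <- roc_analysis(sr$scores, !surv, direction = ">")
  }
  list(contrasts = do.call(rbind, contrast_rows),
       correlations = do.call(rbind, corr_rows),
       roc = rocs)
}

#' Write the cohort report to disk
#'
#' Emits `report_contrasts.csv` (survivor/non-survivor comparisons and
#' sum-of-ranks per window), `report_correlations.csv` (Spearman rho with
#' CPC), `report_subgroups.csv` (SSEP and visual-EEG contrasts at the first
#' window, when both groups exist) and `report_roc.csv` (composite ROC
#' curves).
#'
#' @param config a config list; `out_dir` must contain `metrics.csv` and
#'   `metadata.csv`.
#' @return The report list, invisibly.
#' @export
run_report <- function(config = default_config()) {
  metrics <- utils::read.csv(file.path(config$out_dir, "metrics.csv"),
                             stringsAsFactors = FALSE)
  metadata <- utils::read.csv(file.path(config$out_dir, "metadata.csv"),
                              stringsAsFactors = FALSE)
  rep <- cohort_report(metrics, metadata, config)
  utils::write.csv(rep$contrasts,
                   file.path(config$out_dir, "report_contrasts.csv"),
                   row.names = FALSE)
  utils::write.csv(rep$correlations,
                   file.path(config$out_dir, "report_correlations.csv"),
                   row.names = FALSE)
  roc_rows <- do.call(rbind, lapply(names(rep$roc), function(w)
    cbind(data.frame(window_h = as.numeric(w)), rep$roc[[w]]$curve)))
  utils::write.csv(roc_rows, file.path(config$out_dir, "report_roc.csv"),
                   row.names = FALSE)
  sub_rows <- list()
  summaries <- subject_summaries(metrics, config$windows)
  s1 <- summaries[summaries$window_h == config$windows[1], , drop = FALSE]
  for (g in c("ssep", "visual_eeg")) {
    tab <- tryCatch(subgroup_compare(s1, metadata, g), error = function(e) NULL)
    if (!is.null(tab))
      sub_rows[[g]] <- cbind(data.frame(grouping = g), tab)
  }
  if (length(sub_rows) > 0)
    utils::write.csv(do.call(rbind, sub_rows),
                     file.path(config$out_dir, "report_subgroups.csv"),
                     row.names = FALSE)
  invisible(rep)
}
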