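#' Analysis-band and grid defaults of the pipeline
#'
#' Spectral GC is integrated between 0.05 and 0.9 Hz on a 513-point grid up
#' to the Nyquist frequency of the 535 ms acquisition, with a fixed model
#' order of six.
#'
#' @return Named list: `band`, `order`, `order_candidates`, `n_freq`.
#' @export
analysis_defaults <- function() {
  list(band = c(0.05, 0.9), order = 6L, order_candidates = 2:20,
       n_freq = 513L)
}

# small stable FNV-1a hash of a config for manifests (no external digest dep)
config_hash <- function(config) {
  s <- paste(names(unlist(config)), format(unlist(config), digits = 15),
             collapse = "|")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Write a synthetic cohort to disk
#'
#' Emits the cohort metadata CSV, one time-series CSV per subject (columns =
#' ROI names) with a sidecar JSON of run boundaries, the structural metric
#' CSV, and a manifest recording the seed and a config hash.
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory.
#' @param force Overwrite a non-empty existing directory (default FALSE).
#' @return (Invisibly) the generated `dvs_cohort`.
#' @export
run_synth <- function(config = cohort_config(), out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !force)
    stop("output directory ", out_dir,
         " is not empty; use force = TRUE to overwrite")
  dir.create(file.path(out_dir, "timeseries"), recursive = TRUE,
             showWarnings = FALSE)
  cohort <- generate_cohort(config)
  utils::write.csv(cohort$subjects,
                   file.path(out_dir, "cohort_metadata.csv"),
                   row.names = FALSE)
  for (i in seq_len(nrow(cohort$subjects))) {
    ss <- simulate_subject_series(cohort, i)
    id <- cohort$subjects$subject_id[i]
    utils::write.csv(as.data.frame(ss$series),
                     file.path(out_dir, "timeseries",
                               paste0(id, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(run_lengths = rep(config$samples_per_run, config$n_runs)),
    file.path(out_dir, "runs.json"), auto_unbox = FALSE)
  utils::write.csv(generate_structural_table(cohort),
                   file.path(out_dir, "structural_metrics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(seed = config$seed, config_hash = config_hash(config),
         n_subjects = nrow(cohort$subjects)),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE)
  invisible(cohort)
}

#' Connectivity table for a whole cohort
#'
#' Runs [pairwise_connectivity()] for every subject with complete fMRI,
#' simulating each subject's ROI series from the cohort's generative models
#' (or reading them from a [run_synth()] directory).
#'
#' @param cohort A `dvs_cohort`.
#' @param connections Connection subset (default: all 12 stream
#'   connections).
#' @param order VAR order (default 6).
#' @param series_dir Optional [run_synth()] output directory to read the
#'   series from instead of re-simulating.
#' @return Long data frame (stacked [pairwise_connectivity()] output with a
#'   `subject_id` column).
#' @export
cohort_connectivity <- function(cohort,
                                connections =
                                  stream_connections(visual_stream_atlas()),
                                order = analysis_defaults()$order,
                                series_dir = NULL) {
  cfg <- cohort$config
  fs <- 1 / cfg$tr_seconds
  defaults <- analysis_defaults()
  keep <- which(cohort$subjects$fmri_complete)
  out <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    id <- cohort$subjects$subject_id[i]
    if (is.null(series_dir)) {
      ss <- simulate_subject_series(cohort, i)
      series <- ss$series
      run <- ss$run
    } else {
      series <- as.matrix(utils::read.csv(
        file.path(series_dir, "timeseries", paste0(id, ".csv")),
        check.names = FALSE))
      lens <- unlist(jsonlite::read_json(
        file.path(series_dir, "runs.json"))$run_lengths)
      run <- rep(seq_along(lens), lens)
    }
    tbl <- pairwise_connectivity(series, run, connections, order = order,
                                 fs = fs, band = defaults$band,
                                 n_freq = defaults$n_freq)
    tbl$subject_id <- id
    out[[j]] <- tbl
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Fast connectivity table for the designated pair only
#'
#' Computes per-subject FC and directed TGC for the designated left dorsal
#' connection (L SOG to L SPL) by simulating only the bivariate pair model.
#' Because the pair channels are drawn first from the subject's BOLD
#' substream, the values are identical to those obtained from the full
#' 14-ROI simulation; this path just skips the 12 background channels.
#'
#' @param cohort A `dvs_cohort`.
#' @return Long connectivity table (as [cohort_connectivity()]) restricted
#'   to the designated connection, for subjects with complete fMRI.
#' @export
designated_pair_connectivity <- function(cohort) {
  cfg <- cohort$config
  fs <- 1 / cfg$tr_seconds
  defaults <- analysis_defaults()
  conns <- data.frame(roi_a = "L SOG", roi_b = "L SPL", subsystem = "DVS",
                      connection = designated_functional_connection(),
                      stringsAsFactors = FALSE)
  keep <- which(cohort$subjects$fmri_complete)
  out <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    m <- pair_var_model(cohort$subjects$coupling[i], fs = fs)
    b <- simulate_bold(m, cfg$n_runs, cfg$samples_per_run,
                       seed = subject_seed(cfg$seed, i, 3))
    colnames(b$series) <- c("L SOG", "L SPL")
    tbl <- pairwise_connectivity(b$series, b$run, conns,
                                 order = defaults$order, fs = fs,
                                 band = defaults$band,
                                 n_freq = defaults$n_freq)
    tbl$subject_id <- cohort$subjects$subject_id[i]
    out[[j]] <- tbl
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Calibration summary of the synthetic cohort
#'
#' Generates one default cohort per replicate seed, computes the group
#' response-time gap and the brain-behavior Spearman correlations of FC and
#' directed TGC on the designated connection over the brain-behavior subset,
#' and averages across replicates. This is the quantity the generator is
#' calibrated against; averaging reduces the sizeable per-cohort sampling
#' noise of a rank correlation at n = 44.
#'
#' @param seeds Integer vector of cohort seeds (one replicate each).
#' @param config_fn Function mapping a seed to a [cohort_config()] (default:
#'   packaged defaults with that seed).
#' @return List with `rt_gap_ms`, `rho_tgc`, `rho_fc`, `n_behavior`
#'   (per-replicate values in the `replicates` element).
#' @export
cohort_calibration <- function(seeds,
                               config_fn = function(s)
                                 cohort_config(seed = s)) {
  reps <- lapply(seeds, function(s) {
    cohort <- generate_cohort(config_fn(s))
    subj <- cohort$subjects
    tbl <- designated_pair_connectivity(cohort)
    rts <- stats::setNames(subj$response_time_ms, subj$subject_id)
    rts[!(subj$fmri_complete & subj$rt_complete)] <- NA
    conn <- designated_functional_connection()
    bb_tgc <- brain_behavior(tbl, rts, conn, "tgc", "a->b")
    bb_fc <- brain_behavior(tbl, rts, conn, "fc", "undirected")
    gap <- mean(subj$response_time_ms[subj$group == "nongamer"],
                na.rm = TRUE) -
      mean(subj$response_time_ms[subj$group == "gamer"], na.rm = TRUE)
    c(gap = gap, rho_tgc = bb_tgc$rho, rho_fc = bb_fc$rho, n = bb_tgc$n)
  })
  reps <- do.call(rbind, reps)
  list(rt_gap_ms = mean(reps[, "gap"]),
       rho_tgc = mean(reps[, "rho_tgc"]),
       rho_fc = mean(reps[, "rho_fc"]),
       n_behavior = stats::median(reps[, "n"]),
       replicates = as.data.frame(reps))
}

#' Run the full group analysis
#'
#' Applies the completeness-based exclusions, computes the per-subject
#' connectivity table, group comparisons (FC and directed TGC,
#' Holm-corrected within subsystem families), the brain-behavior
#' correlations on the designated left dorsal connection, and the
#' structural FA/QA group comparisons. Effective sample sizes per analysis
#' are logged and returned.
#'
#' @param cohort A `dvs_cohort` (e.g. from [generate_cohort()]).
#' @param out_dir Optional directory; when given, result CSVs and a JSON
#'   summary are written there.
#' @param connections Connection subset (default all 12).
#' @param series_dir Optional [run_synth()] directory to read series from.
#' @return List with `connectivity` (per-subject table), `fc_tests`,
#'   `tgc_tests`, `structural_tests`, `brain_behavior` (FC and TGC results
#'   for the designated connection), and `effective_n`.
#' @export
run_analyze <- function(cohort, out_dir = NULL,
                        connections =
                          stream_connections(visual_stream_atlas()),
                        series_dir = NULL) {
  subj <- cohort$subjects
  groups <- stats::setNames(subj$group, subj$subject_id)
  rts <- stats::setNames(subj$response_time_ms, subj$subject_id)

  functional <- subj$fmri_complete
  functional_bb <- subj$fmri_complete & subj$rt_complete
  structural <- subj$tract_complete
  structural_bb <- subj$tract_complete & subj$rt_complete
  effective_n <- list(functional = sum(functional),
                      functional_brain_behavior = sum(functional_bb),
                      structural = sum(structural),
                      structural_brain_behavior = sum(structural_bb))
  message(sprintf(
    "effective n: functional %d, functional brain-behavior %d, structural %d, structural brain-behavior %d",
    effective_n$functional, effective_n$functional_brain_behavior,
    effective_n$structural, effective_n$structural_brain_behavior))

  conn_tbl <- cohort_connectivity(cohort, connections,
                                  series_dir = series_dir)
  fc_tests <- compare_groups(conn_tbl, groups, "fc")
  tgc_tests <- compare_groups(conn_tbl, groups, "tgc")

  rts_bb <- rts
  rts_bb[!functional_bb[match(names(rts), subj$subject_id)]] <- NA
  designated <- designated_functional_connection()
  bb <- list()
  if (designated %in% conn_tbl$connection) {
    bb$fc <- brain_behavior(conn_tbl, rts_bb, designated, "fc",
                            "undirected")
    bb$tgc <- brain_behavior(conn_tbl, rts_bb, designated, "tgc", "a->b")
  }

  struct_tbl <- generate_structural_table(cohort)
  struct_tbl <- struct_tbl[struct_tbl$subject_id %in%
                             subj$subject_id[structural], ]
  structural_tests <- structural_group_comparison(struct_tbl, groups)

  res <- list(connectivity = conn_tbl, fc_tests = fc_tests,
              tgc_tests = tgc_tests, structural_tests = structural_tests,
              brain_behavior = bb, effective_n = effective_n)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(conn_tbl, file.path(out_dir, "connectivity.csv"),
                     row.names = FALSE)
    utils::write.csv(fc_tests, file.path(out_dir, "fc_tests.csv"),
                     row.names = FALSE)
    utils::write.csv(tgc_tests, file.path(out_dir, "tgc_tests.csv"),
                     row.names = FALSE)
    utils::write.csv(structural_tests,
                     file.path(out_dir, "structural_tests.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(effective_n = effective_n, brain_behavior = bb,
           seed = cohort$config$seed,
           config_hash = config_hash(cohort$config)),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE,
      digits = NA)
  }
  res
}

#' Summarize significant connections as a plain-text report
#'
#' Writes a markdown summary of the Holm-corrected significant group
#' differences and the designated brain-behavior correlations from a
#' [run_analyze()] result.
#'
#' @param results A [run_analyze()] result list.
#' @param out_dir Directory for `report.md` (created if needed).
#' @param alpha Significance threshold (default 0.05).
#' @return (Invisibly) the path of the written report.
#' @export
run_report <- function(results, out_dir, alpha = 0.05) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  all_tests <- rbind(results$fc_tests, results$tgc_tests,
                     results$structural_tests)
  sig <- all_tests[all_tests$p_holm < alpha, , drop = FALSE]
  lines <- c("# Group comparison report", "")
  if (nrow(sig) == 0) {
    lines <- c(lines, "No significant connections after Holm correction.")
  } else {
    lines <- c(lines,
               "Connections significant after Holm correction:", "",
               sprintf("- %s [%s, %s%s]: p_raw = %.4f, p_holm = %.4f (medians %.4f vs %.4f)",
                       sig$connection, sig$family, sig$metric,
                       ifelse(sig$direction == "undirected", "",
                              paste0(", ", sig$direction)),
                       sig$p_raw, sig$p_holm,
                       sig$median_gamer, sig$median_nongamer))
  }
  if (length(results$brain_behavior)) {
    lines <- c(lines, "", "Brain-behavior correlations (designated connection):", "")
    for (b in results$brain_behavior)
      lines <- c(lines, sprintf(
        "- %s %s (%s): rho = %.3f, p = %.4f, n = %d",
        b$connection, toupper(b$metric), b$direction, b$rho, b$p, b$n))
  }
  path <- file.path(out_dir, "report.md")
  writeLines(lines, path)
  invisible(path)
}
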