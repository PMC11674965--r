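#' Configuration of the synthetic cohort generator
#'
#' Packages the study conditions the downstream analysis assumes: cohort
#' composition (28 gamers, 19 nongamers), acquisition sizing (4 runs of 860
#' samples at TR = 535 ms, i.e. 3440 volumes at fs = 1.87 Hz), a directed
#' VAR coupling on the left occipito-parietal (L SOG to L SPL) connection
#' that differs between groups, a response-time model with a ~190 ms group
#' gap and a negative monotone link to coupling strength, and upward group
#' shifts of the structural anisotropy metrics on the dorsal connections.
#'
#' @param n_gamers,n_nongamers Group sizes.
#' @param n_runs,samples_per_run Functional run structure (total volumes =
#'   `n_runs * samples_per_run`).
#' @param tr_seconds Repetition time in seconds; sampling rate is its
#'   reciprocal.
#' @param coupling_gamer,coupling_nongamer Group-mean VAR cross-coefficient
#'   on the L SOG to L SPL direction (lag 1, unitless).
#' @param coupling_sd Between-subject SD of the coupling coefficient.
#' @param rt_mean_nongamer Nongamer mean response time (ms).
#' @param rt_gap Group response-time gap in ms (gamers faster).
#' @param rt_noise_sd Residual response-time SD (ms).
#' @param behavior_link_strength Response-time decrease (ms) per 1 SD of
#'   coupling; positive values produce the negative brain-behavior
#'   correlation the model assumes.
#' @param fa_shift,qa_shift Upward group shifts of FA / QA applied to the
#'   gamers on the designated dorsal connections (unitless).
#' @param seed Integer base seed; per-subject streams are derived from it
#'   by a counter scheme, so adding subjects never perturbs existing ones.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_gamers = 28L, n_nongamers = 19L,
                          n_runs = 4L, samples_per_run = 860L,
                          tr_seconds = 0.535,
                          coupling_gamer = 0.21, coupling_nongamer = 0.15,
                          coupling_sd = 0.075,
                          rt_mean_nongamer = 620, rt_gap = 190,
                          rt_noise_sd = 30, behavior_link_strength = 8,
                          fa_shift = 0.05, qa_shift = 0.06,
                          seed = 1L) {
  cfg <- list(n_gamers = as.integer(n_gamers),
              n_nongamers = as.integer(n_nongamers),
              n_runs = as.integer(n_runs),
              samples_per_run = as.integer(samples_per_run),
              tr_seconds = tr_seconds,
              coupling_gamer = coupling_gamer,
              coupling_nongamer = coupling_nongamer,
              coupling_sd = coupling_sd,
              rt_mean_nongamer = rt_mean_nongamer,
              rt_gap = rt_gap,
              rt_noise_sd = rt_noise_sd,
              behavior_link_strength = behavior_link_strength,
              fa_shift = fa_shift, qa_shift = qa_shift,
              seed = as.integer(seed))
  with(cfg, stopifnot(n_gamers >= 1, n_nongamers >= 1, n_runs >= 1,
                      samples_per_run >= 1, tr_seconds > 0,
                      coupling_sd >= 0, rt_noise_sd >= 0))
  # both group-level coupling configurations must define stationary systems
  for (cpl in c(cfg$coupling_gamer, cfg$coupling_nongamer))
    invisible(pair_var_model(cpl, fs = 1 / cfg$tr_seconds))
  structure(cfg, class = "cohort_config")
}

#' @rdname cohort_config
#' @param path YAML file whose top-level keys are `cohort_config` arguments.
#' @export
cohort_config_from_yaml <- function(path) {
  do.call(cohort_config, yaml::read_yaml(path))
}

# Shared own-lag dynamics of the simulated pair: AR components at lags 1 and
# 6 on both channels, so the true generating order matches the analysis
# order of six.
.pair_own_lags <- c(0.25, 0, 0, 0, 0, 0.20)
# instantaneous (innovation-correlation) component accompanying the lagged
# coupling: coupled regions share common input, so undirected correlation
# exceeds what the lagged path alone would produce
.pair_innov_scale <- 0.5

#' Bivariate VAR(6) generating model for the designated pair
#'
#' Channel 1 is the source (L SOG), channel 2 the target (L SPL). Both
#' channels share own-lag coefficients at lags 1 and 6; the directed
#' influence is a single lag-1 cross-coefficient from source to target.
#' Innovations have unit variance and a contemporaneous correlation of half
#' the coupling coefficient (shared-input component), so undirected and
#' directed connectivity co-vary across subjects the way the analysis
#' assumes.
#'
#' @param coupling Lag-1 cross-coefficient (source to target).
#' @param fs Sampling rate (Hz).
#' @return A stationary `var_model`; an error if `coupling` makes the
#'   system non-stationary.
#' @export
pair_var_model <- function(coupling, fs = 1 / 0.535) {
  coeffs <- lapply(seq_along(.pair_own_lags), function(k)
    diag(2) * .pair_own_lags[k])
  coeffs[[1]][2, 1] <- coupling
  s12 <- max(min(.pair_innov_scale * coupling, 0.95), -0.95)
  sigma <- matrix(c(1, s12, s12, 1), 2, 2)
  var_model(coeffs, sigma, fs = fs)
}

# Counter-based per-subject substreams: subject i's seed for purpose k
# (1 = coupling, 2 = response time, 3 = BOLD, 4 = structural) depends only
# on (base seed, i, k).
subject_seed <- function(seed, i, purpose) {
  (as.numeric(seed) + i * 100003 + purpose * 10007) %% 2147483629
}

#' Generate a synthetic cohort
#'
#' Draws per-subject directed coupling coefficients around the group means,
#' assigns completeness flags mirroring a realistic exclusion pattern (one
#' gamer without tractography, one nongamer without fMRI, one subject per
#' group without response time), and generates response times via
#' [generate_response_times()].
#'
#' @param config A [cohort_config()].
#' @return A list of class `dvs_cohort` with `subjects` (data frame:
#'   `subject_id`, `group`, `coupling`, `response_time_ms`,
#'   `fmri_complete`, `rt_complete`, `tract_complete`) and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_gamers + config$n_nongamers
  group <- rep(c("gamer", "nongamer"),
               c(config$n_gamers, config$n_nongamers))
  within_idx <- c(seq_len(config$n_gamers), seq_len(config$n_nongamers))
  subject_id <- sprintf("%s%02d", ifelse(group == "gamer", "g", "n"),
                        within_idx)

  mu <- ifelse(group == "gamer", config$coupling_gamer,
               config$coupling_nongamer)
  coupling <- vapply(seq_len(n), function(i) {
    set.seed(subject_seed(config$seed, i, 1))
    stats::rnorm(1, mu[i], config$coupling_sd)
  }, numeric(1))
  # stationarity gate on every emitted subject system
  for (i in seq_len(n))
    invisible(pair_var_model(coupling[i], fs = 1 / config$tr_seconds))

  subjects <- data.frame(
    subject_id = subject_id, group = group, coupling = coupling,
    fmri_complete = TRUE, rt_complete = TRUE, tract_complete = TRUE,
    stringsAsFactors = FALSE)
  # exclusion pattern: first gamer lacks tractography, second gamer lacks RT,
  # first nongamer lacks fMRI, second nongamer lacks RT
  g_idx <- which(group == "gamer")
  n_idx <- which(group == "nongamer")
  if (length(g_idx) >= 1) subjects$tract_complete[g_idx[1]] <- FALSE
  if (length(g_idx) >= 2) subjects$rt_complete[g_idx[2]] <- FALSE
  if (length(n_idx) >= 1) subjects$fmri_complete[n_idx[1]] <- FALSE
  if (length(n_idx) >= 2) subjects$rt_complete[n_idx[2]] <- FALSE

  cohort <- structure(list(subjects = subjects, config = config),
                      class = "dvs_cohort")
  cohort$subjects$response_time_ms <- generate_response_times(cohort)
  cohort
}

#' @export
print.dvs_cohort <- function(x, ...) {
  tab <- table(x$subjects$group)
  cat(sprintf("Synthetic cohort: %d subjects (%s)\n", nrow(x$subjects),
              paste(sprintf("%d %s", tab, names(tab)), collapse = ", ")))
  invisible(x)
}

#' Generate response times from per-subject coupling
#'
#' Response time is a decreasing linear function of the standardized
#' coupling plus Gaussian noise:
#' \deqn{RT_i = \mu_{NG} - \Delta \cdot 1[\mathrm{gamer}] -
#'   \beta (c_i - \mu_{\mathrm{group}}) / s_c + \epsilon_i,}
#' with the coupling standardized against its own group's nominal mean so
#' the expected group gap equals `rt_gap` exactly. Subjects flagged
#' `rt_complete = FALSE` receive `NA`.
#'
#' @param cohort A `dvs_cohort`.
#' @param coupling Optional override of the per-subject coupling summaries
#'   (defaults to the cohort's true coupling coefficients).
#' @return Numeric vector of response times in ms (NA where incomplete).
#' @export
generate_response_times <- function(cohort, coupling = NULL) {
  cfg <- cohort$config
  subj <- cohort$subjects
  if (is.null(coupling)) coupling <- subj$coupling
  stopifnot(length(coupling) == nrow(subj))
  if (cfg$behavior_link_strength < 0)
    warning("behavior_link_strength < 0 gives a positive coupling-RT ",
            "correlation; the model assumes a negative link")
  mu <- ifelse(subj$group == "gamer", cfg$coupling_gamer,
               cfg$coupling_nongamer)
  z <- if (cfg$coupling_sd > 0) (coupling - mu) / cfg$coupling_sd else 0
  rt <- vapply(seq_len(nrow(subj)), function(i) {
    set.seed(subject_seed(cfg$seed, i, 2))
    cfg$rt_mean_nongamer - cfg$rt_gap * (subj$group[i] == "gamer") -
      cfg$behavior_link_strength * z[i] +
      stats::rnorm(1, 0, cfg$rt_noise_sd)
  }, numeric(1))
  if (any(rt[subj$rt_complete] <= 0))
    stop("response-time model produced nonpositive RT; check configuration")
  rt[!subj$rt_complete] <- NA_real_
  rt
}

# AR(1) coefficient and innovation SD of the 12 background ROIs
.background_ar <- 0.3

#' Simulate the 14-ROI BOLD-like series for one subject
#'
#' The designated pair (L SOG, L SPL) is driven by the subject's bivariate
#' VAR(6); the remaining 12 atlas ROIs are independent AR(1) channels, which
#' keeps the full atlas table shape at negligible cost. Runs are independent
#' realizations.
#'
#' @param cohort A `dvs_cohort`.
#' @param i Subject row index (or subject id).
#' @return List with `series` (matrix, one named column per atlas ROI) and
#'   `run` (integer run index per row).
#' @export
simulate_subject_series <- function(cohort, i) {
  cfg <- cohort$config
  if (is.character(i)) i <- match(i, cohort$subjects$subject_id)
  stopifnot(!is.na(i), i >= 1, i <= nrow(cohort$subjects))
  atlas <- visual_stream_atlas()
  model <- pair_var_model(cohort$subjects$coupling[i],
                          fs = 1 / cfg$tr_seconds)
  bold <- simulate_bold(model, cfg$n_runs, cfg$samples_per_run,
                        seed = subject_seed(cfg$seed, i, 3))
  n_tot <- nrow(bold$series)
  series <- matrix(NA_real_, n_tot, nrow(atlas),
                   dimnames = list(NULL, atlas$name))
  series[, "L SOG"] <- bold$series[, 1]
  series[, "L SPL"] <- bold$series[, 2]
  other <- setdiff(atlas$name, c("L SOG", "L SPL"))
  # background channels continue the same RNG stream as the pair simulation
  for (roi in other) {
    for (r in seq_len(cfg$n_runs)) {
      eps <- stats::rnorm(cfg$samples_per_run + 100L)
      x <- as.numeric(stats::filter(eps, .background_ar,
                                    method = "recursive"))
      series[bold$run == r, roi] <- x[101:(cfg$samples_per_run + 100L)]
    }
  }
  list(series = series, run = bold$run)
}

# designated connections of the analysis
designated_functional_connection <- function() "L SOG--L SPL"
designated_structural_connection <- function() "L SOG--L IPL"

# per-connection baseline distributions of the structural metrics
.fa_base <- list(mean = 0.45, sd = 0.05)
.qa_base <- list(mean = 0.35, sd = 0.08)
# connections whose gamer distributions are shifted upward
.fa_shift_connections <- "L SOG--L IPL"
.qa_shift_connections <- c("L SOG--L IPL", "R SOG--R SPL", "R SOG--R IPL")

#' Generate per-subject, per-connection structural metrics
#'
#' FA and QA are drawn around fixed baselines for each of the 12
#' connections; gamers receive the configured upward shifts on the
#' designated dorsal connections only (FA on the left occipito-parietal
#' connection; QA additionally on the right dorsal connections). FA is
#' clipped into (0, 1) with a warning if a shift pushes it outside; QA is
#' clipped to be positive.
#'
#' @param cohort A `dvs_cohort`.
#' @return Data frame with columns `subject_id`, `connection`, `fa`, `qa`
#'   (one row per subject per connection, all subjects included; exclusion
#'   by completeness happens at analysis time).
#' @export
generate_structural_table <- function(cohort) {
  cfg <- cohort$config
  subj <- cohort$subjects
  conns <- stream_connections(visual_stream_atlas())
  rows <- vector("list", nrow(subj))
  clipped <- 0L
  for (i in seq_len(nrow(subj))) {
    set.seed(subject_seed(cfg$seed, i, 4))
    fa <- stats::rnorm(nrow(conns), .fa_base$mean, .fa_base$sd)
    qa <- stats::rnorm(nrow(conns), .qa_base$mean, .qa_base$sd)
    if (subj$group[i] == "gamer") {
      fa <- fa + cfg$fa_shift *
        (conns$connection %in% .fa_shift_connections)
      qa <- qa + cfg$qa_shift *
        (conns$connection %in% .qa_shift_connections)
    }
    out_of_range <- fa <= 0 | fa >= 1
    clipped <- clipped + sum(out_of_range)
    fa <- pmin(pmax(fa, 1e-3), 1 - 1e-3)
    qa <- pmax(qa, 1e-3)
    rows[[i]] <- data.frame(subject_id = subj$subject_id[i],
                            connection = conns$connection,
                            subsystem = conns$subsystem,
                            fa = fa, qa = qa, stringsAsFactors = FALSE)
  }
  if (clipped > 0)
    warning(clipped, " FA value(s) fell outside (0, 1) and were clipped")
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
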