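test_that("the default cohort has the study composition and exclusion pattern", {
  cohort <- generate_cohort(cohort_config(seed = 3))
  subj <- cohort$subjects
  expect_equal(nrow(subj), 47L)
  expect_equal(sum(subj$group == "gamer"), 28L)
  expect_equal(sum(subj$group == "nongamer"), 19L)

  # completeness flags reproduce the per-analysis effective sample sizes
  expect_equal(sum(subj$fmri_complete), 46L)
  expect_equal(sum(subj$fmri_complete & subj$rt_complete), 44L)
  expect_equal(sum(subj$tract_complete), 46L)
  expect_equal(sum(subj$tract_complete & subj$rt_complete), 44L)
  expect_true(all(is.na(subj$response_time_ms) == !subj$rt_complete))
  expect_true(all(subj$response_time_ms > 0, na.rm = TRUE))
})

test_that("cohort generation is seed-deterministic and group couplings differ as configured", {
  c1 <- generate_cohort(cohort_config(seed = 9))
  c2 <- generate_cohort(cohort_config(seed = 9))
  expect_identical(c1$subjects, c2$subjects)
  c3 <- generate_cohort(cohort_config(seed = 10))
  expect_false(identical(c1$subjects, c3$subjects))

  # adding subjects never perturbs existing per-subject draws
  big <- generate_cohort(cohort_config(n_gamers = 30, seed = 9))
  expect_equal(big$subjects$coupling[1:28], c1$subjects$coupling[1:28])

  # group coupling means track the configured difference over seeds
  mean_diff <- mean(vapply(1:10, function(s) {
    subj <- generate_cohort(cohort_config(seed = s))$subjects
    mean(subj$coupling[subj$group == "gamer"]) -
      mean(subj$coupling[subj$group == "nongamer"])
  }, numeric(1)))
  expect_lt(abs(mean_diff - 0.06), 0.025)
})

test_that("response times fall with coupling and carry the configured group gap", {
  # noise-free monotone map: within-group Spearman is exactly -1
  cfg0 <- cohort_config(rt_noise_sd = 0, seed = 5)
  cohort0 <- generate_cohort(cfg0)
  s0 <- cohort0$subjects[cohort0$subjects$rt_complete, ]
  for (g in c("gamer", "nongamer")) {
    sg <- s0[s0$group == g, ]
    expect_equal(stats::cor(sg$coupling, sg$response_time_ms,
                            method = "spearman"), -1)
  }

  # no behavioral link and no group coupling difference: the association
  # vanishes over seeds (the RT gap alone cannot induce one)
  rho_null <- vapply(1:15, function(s) {
    cfg <- cohort_config(behavior_link_strength = 0, coupling_gamer = 0.15,
                         coupling_nongamer = 0.15, seed = s)
    subj <- generate_cohort(cfg)$subjects
    keep <- subj$rt_complete
    stats::cor(subj$coupling[keep], subj$response_time_ms[keep],
               method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(rho_null)), 0.15)

  # wrong-sign link warns
  cohortw <- generate_cohort(cohort_config(seed = 5))
  cohortw$config$behavior_link_strength <- -5
  expect_warning(generate_response_times(cohortw), "negative link")

  # the group RT gap is centred on the configured ~190 ms
  gaps <- vapply(1:10, function(s) {
    subj <- generate_cohort(cohort_config(seed = s))$subjects
    mean(subj$response_time_ms[subj$group == "nongamer"], na.rm = TRUE) -
      mean(subj$response_time_ms[subj$group == "gamer"], na.rm = TRUE)
  }, numeric(1))
  expect_equal(mean(gaps), 190, tolerance = 10)
})

test_that("subject series carry the full atlas shape and the pair substream is stable", {
  cfg <- small_cohort_config(seed = 8)
  cohort <- generate_cohort(cfg)
  ss <- simulate_subject_series(cohort, 2)
  expect_equal(colnames(ss$series), visual_stream_atlas()$name)
  expect_equal(nrow(ss$series), cfg$n_runs * cfg$samples_per_run)
  expect_false(anyNA(ss$series))

  # the designated pair is identical whether or not the 12 background
  # channels are generated (the fast path used for calibration)
  m <- pair_var_model(cohort$subjects$coupling[2], fs = 1 / cfg$tr_seconds)
  b <- simulate_bold(m, cfg$n_runs, cfg$samples_per_run,
                     seed = dvsconn:::subject_seed(cfg$seed, 2, 3))
  expect_identical(ss$series[, "L SOG"], b$series[, 1])
  expect_identical(ss$series[, "L SPL"], b$series[, 2])
})

test_that("structural metrics respect their ranges and group shifts", {
  cohort <- generate_cohort(cohort_config(seed = 13))
  tbl <- generate_structural_table(cohort)
  expect_equal(nrow(tbl), 47L * 12L)
  expect_true(all(tbl$fa > 0 & tbl$fa < 1))
  expect_true(all(tbl$qa > 0))
  expect_equal(anyDuplicated(tbl[, c("subject_id", "connection")]), 0L)

  # zero shifts: group medians equal in expectation
  diffs <- vapply(1:40, function(s) {
    cohort0 <- generate_cohort(cohort_config(fa_shift = 0, qa_shift = 0,
                                             seed = s))
    t0 <- generate_structural_table(cohort0)
    sel <- t0$connection == "L SOG--L IPL"
    grp <- cohort0$subjects$group[match(t0$subject_id[sel],
                                        cohort0$subjects$subject_id)]
    stats::median(t0$fa[sel][grp == "gamer"]) -
      stats::median(t0$fa[sel][grp == "nongamer"])
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.01)

  # shifts land only on the designated dorsal connections
  grp <- cohort$subjects$group[match(tbl$subject_id,
                                     cohort$subjects$subject_id)]
  fa_gap <- vapply(unique(tbl$connection), function(cn) {
    sel <- tbl$connection == cn
    mean(tbl$fa[sel & grp == "gamer"]) -
      mean(tbl$fa[sel & grp == "nongamer"])
  }, numeric(1))
  expect_gt(fa_gap["L SOG--L IPL"], 0.02)
  expect_lt(max(abs(fa_gap[setdiff(names(fa_gap), "L SOG--L IPL")])), 0.04)

  # extreme shift clips FA into (0, 1) with a warning
  cohort_hot <- generate_cohort(cohort_config(fa_shift = 0.9, seed = 13))
  expect_warning(tbl_hot <- generate_structural_table(cohort_hot),
                 "clipped")
  expect_true(all(tbl_hot$fa < 1))
})

test_that("FA group shift is detectable at the configured power", {
  # Wilcoxon on the designated structural connection rejects at alpha =
  # 0.05 in at least 80% of seeded replicates at default shifts
  rejects <- vapply(1:200, function(s) {
    cohort <- generate_cohort(cohort_config(seed = 5000 + s))
    tbl <- generate_structural_table(cohort)
    keep <- cohort$subjects$subject_id[cohort$subjects$tract_complete]
    sel <- tbl$connection == "L SOG--L IPL" & tbl$subject_id %in% keep
    grp <- cohort$subjects$group[match(tbl$subject_id[sel],
                                       cohort$subjects$subject_id)]
    ranksum_test(tbl$fa[sel][grp == "gamer"],
                 tbl$fa[sel][grp == "nongamer"])$p < 0.05
  }, logical(1))
  expect_gte(mean(rejects), 0.8)
})

test_that("equal couplings and zero shifts give uniform null p-values", {
  # downstream Wilcoxon p on the designated structural connection is
  # uniform when no group difference is configured
  p_null <- vapply(1:300, function(s) {
    cohort <- generate_cohort(cohort_config(fa_shift = 0, qa_shift = 0,
                                            seed = 20000 + s))
    tbl <- generate_structural_table(cohort)
    sel <- tbl$connection == "L SOG--L IPL"
    grp <- cohort$subjects$group[match(tbl$subject_id[sel],
                                       cohort$subjects$subject_id)]
    ranksum_test(tbl$fa[sel][grp == "gamer"],
                 tbl$fa[sel][grp == "nongamer"])$p
  }, numeric(1))
  # rank-test p-values are discrete, so ties are expected; the KS check
  # against the uniform is approximate
  ks <- suppressWarnings(stats::ks.test(p_null, "punif"))
  expect_gt(ks$p.value, 0.01)

  # and the downstream group TGC difference is consistent with zero under
  # equal couplings (scaled-down cohorts for tractability)
  p_tgc <- vapply(1:60, function(s) {
    cfg <- small_cohort_config(seed = 30000 + s, coupling_gamer = 0.15,
                               coupling_nongamer = 0.15)
    cohort <- generate_cohort(cfg)
    tbl <- designated_pair_connectivity(cohort)
    tgc <- tbl[tbl$metric == "tgc" & tbl$direction == "a->b", ]
    grp <- cohort$subjects$group[match(tgc$subject_id,
                                       cohort$subjects$subject_id)]
    ranksum_test(tgc$value[grp == "gamer"],
                 tgc$value[grp == "nongamer"])$p
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(p_tgc, "punif"))$p.value,
            0.01)
  expect_lte(mean(p_tgc < 0.05), 0.15)
})
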