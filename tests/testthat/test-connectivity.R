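test_that("Pearson FC obeys its algebraic contract", {
  expect_equal(pearson_fc(1:10, 1:10), 1.0)
  expect_equal(pearson_fc(1:10, -(1:10)), -1.0)
  # hand computation: cov 1.0, sd sqrt(5/3) each
  expect_equal(pearson_fc(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)

  set.seed(41)
  x <- stats::rnorm(50)
  y <- stats::rnorm(50)
  expect_equal(pearson_fc(x, y), pearson_fc(y, x))
  expect_equal(pearson_fc(2.5 * x + 7, y), pearson_fc(x, y))
  expect_error(pearson_fc(rep(1, 10), x[1:10]), "degenerate")
})

test_that("the parametric spectrum matches closed forms and reconstructs S = H Sigma H*", {
  # pure noise: flat unit spectrum
  m0 <- var_model(list(), diag(2), fs = 2)
  sp0 <- var_spectrum(m0, c(0, 0.3, 1))
  for (i in 1:3) expect_equal(Re(sp0$S[, , i]), diag(2), tolerance = 1e-12)

  # univariate AR(1), a = 0.5: power at DC = 1/(1-0.5)^2 = 4
  m1 <- var_model(matrix(0.5, 1, 1), matrix(1, 1, 1), fs = 2)
  sp1 <- var_spectrum(m1, 0)
  expect_equal(Re(sp1$S[1, 1, 1]), 4, tolerance = 1e-12)

  # bivariate: Hermitian PSD everywhere and S = H Sigma H* identity
  m <- pair_var_model(0.3)
  freqs <- gc_freq_grid(m$fs, 64)
  sp <- var_spectrum(m, freqs)
  for (i in c(1, 20, 64)) {
    S_i <- sp$S[, , i]
    expect_equal(S_i, Conj(t(S_i)), tolerance = 1e-12)
    expect_gte(min(Re(eigen(S_i, only.values = TRUE)$values)), -1e-12)
    H_i <- sp$H[, , i]
    expect_equal(S_i, H_i %*% m$sigma %*% Conj(t(H_i)), tolerance = 1e-10)
  }
  expect_error(var_spectrum(m, m$fs), "within")
})

test_that("the parametric spectrum agrees with an independent Welch estimate", {
  m <- strong_var2()
  set.seed(43)
  x <- simulate_var(m, 1e5)
  np <- welch_cross_spectrum(x, seg_len = 256, fs = m$fs)
  par <- var_spectrum(m, np$freqs)
  # broadband agreement of the diagonal power spectra (true model vs Welch)
  for (ch in 1:2) {
    rel <- mean(abs(Re(par$S[ch, ch, ]) - Re(np$S[ch, ch, ]))) /
      mean(Re(par$S[ch, ch, ]))
    expect_lt(rel, 0.1)
  }
})

test_that("spectral GC is zero without coupling, positive with it, and symmetric under relabeling", {
  freqs <- gc_freq_grid(1 / 0.535, 129)

  # uncoupled, diagonal covariance: exactly zero in both directions
  m0 <- var_model(diag(2) * 0.4, diag(2), fs = 1 / 0.535)
  expect_true(all(spectral_gc(m0, freqs, from = 1, to = 2) == 0))
  expect_true(all(spectral_gc(m0, freqs, from = 2, to = 1) == 0))

  # unidirectional VAR(1) coupling 2 -> 1: positive forward, zero reverse
  A <- rbind(c(0.4, 0.5), c(0, 0.4))
  m1 <- var_model(A, diag(2), fs = 1 / 0.535)
  I_fwd <- spectral_gc(m1, freqs, from = 2, to = 1)
  I_rev <- spectral_gc(m1, freqs, from = 1, to = 2)
  expect_true(all(I_fwd > 0))
  expect_true(all(I_rev == 0))
  expect_equal(attr(I_fwd, "n_clamped"), 0L)

  # relabeling the channels leaves the directed value unchanged
  set.seed(44)
  x <- simulate_var(m1, 4000)
  f12 <- fit_var(x, 1, fs = m1$fs)
  f21 <- fit_var(x[, 2:1], 1, fs = m1$fs)
  expect_equal(spectral_gc(f12, freqs, from = 2, to = 1),
               spectral_gc(f21, freqs, from = 1, to = 2),
               tolerance = 1e-10)
})

test_that("band integration averages the spectrum and validates its band", {
  freqs <- seq(0, 1, length.out = 101)
  expect_equal(band_gc(freqs, rep(0.37, 101), 0.1, 0.8), 0.37)
  # ramp from 0 at f1 to 1 at f2: mean 0.5
  ramp <- pmax(pmin((freqs - 0.2) / 0.6, 1), 0)
  expect_equal(band_gc(freqs, ramp, 0.2, 0.8), 0.5, tolerance = 1e-10)
  expect_error(band_gc(freqs, ramp, 0.5, 1.2), "outside")
  expect_error(band_gc(freqs, ramp, 0.8, 0.2))
})

test_that("full-band GC matches the reduced-model variance-ratio oracle", {
  m <- pair_var_model(0.2)
  set.seed(45)
  x <- simulate_var(m, 1e5)
  fit <- fit_var(x, 6, fs = m$fs)
  freqs <- gc_freq_grid(m$fs)
  F_band <- band_gc(freqs, spectral_gc(fit, freqs, from = 1, to = 2),
                    0, m$fs / 2)
  F_td <- time_domain_gc_oracle(x, 6, from = 1, to = 2)
  expect_gt(F_td, 0.02)            # the effect is real at this coupling
  expect_lt(abs(F_band - F_td) / F_td, 0.05)
})

test_that("null TGC concentrates near zero and declines with sample size", {
  m0 <- var_model(diag(2) * 0.4, diag(2), fs = 1 / 0.535)
  freqs <- gc_freq_grid(m0$fs, 257)
  med <- vapply(c(500, 2000, 8000), function(T_n) {
    vals <- vapply(1:12, function(r) {
      set.seed(1000 + 7 * T_n + r)
      x <- simulate_var(m0, T_n)
      fit <- fit_var(x, 6, fs = m0$fs)
      band_gc(freqs, spectral_gc(fit, freqs, from = 1, to = 2),
              0.05, 0.9)
    }, numeric(1))
    stats::median(vals)
  }, numeric(1))
  expect_true(all(diff(med) < 0))
  expect_lt(med[3], 0.005)
})

test_that("order selection honors its contract on degenerate candidate sets", {
  m <- pair_var_model(0.2)
  b <- simulate_bold(m, 2, 400, seed = 46)
  expect_equal(as.integer(select_order(b$series, b$run, candidates = 4,
                                       fs = m$fs)), 4L)
  expect_error(select_order(b$series, b$run, candidates = 50, fs = m$fs),
               "infeasible")
  sel <- select_order(b$series, b$run, candidates = 2:10, fs = m$fs)
  expect_true(sel %in% 2:10)
  expect_named(attr(sel, "criterion"))
})

test_that("the per-subject connectivity table has the documented shape", {
  cfg <- small_cohort_config(seed = 47)
  cohort <- generate_cohort(cfg)
  ss <- simulate_subject_series(cohort, 1)
  conns <- stream_connections(visual_stream_atlas())
  tbl <- pairwise_connectivity(ss$series, ss$run, conns, order = 2,
                               fs = 1 / cfg$tr_seconds)
  expect_equal(nrow(tbl), 36L)   # 12 fc + 24 directed tgc
  expect_equal(sum(tbl$metric == "fc"), 12L)
  expect_equal(sum(tbl$metric == "tgc"), 24L)
  expect_true(all(tbl$value[tbl$metric == "tgc"] >= 0))
  expect_true(all(abs(tbl$value[tbl$metric == "fc"]) <= 1))

  expect_error(
    pairwise_connectivity(ss$series[, 1:3], ss$run, conns, order = 2,
                          fs = 1 / cfg$tr_seconds),
    "missing ROI")
  bad <- data.frame(roi_a = "L SOG", roi_b = "L SOG", connection = "x")
  expect_error(
    pairwise_connectivity(ss$series, ss$run, bad, order = 2,
                          fs = 1 / cfg$tr_seconds),
    "self-pair")
  expect_error(
    pairwise_connectivity(ss$series, ss$run, conns[1, ], order = 2,
                          fs = 1 / cfg$tr_seconds, band = c(0.05, 2)),
    "Nyquist")
})

test_that("directionality is recovered on unidirectionally coupled simulations", {
  m <- pair_var_model(0.18)
  hits <- vapply(1:25, function(s) {
    b <- simulate_bold(m, 4, 860, seed = 500 + s)
    freqs <- gc_freq_grid(m$fs, 257)
    fit1 <- fit_var(b$series[b$run == 1, ], 6, fs = m$fs)
    I_f <- spectral_gc(fit1, freqs, from = 1, to = 2)
    I_r <- spectral_gc(fit1, freqs, from = 2, to = 1)
    band_gc(freqs, I_f, 0.05, 0.9) > band_gc(freqs, I_r, 0.05, 0.9)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
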