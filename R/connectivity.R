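#' Pearson undirected functional connectivity
#'
#' Plain Pearson correlation between two ROI time series; symmetric and
#' invariant to positive affine transforms of either input.
#'
#' @param x,y Numeric vectors of equal length (>= 3), non-constant.
#' @return Correlation in \[-1, 1\].
#' @export
pearson_fc <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12)
    stop("degenerate signal: constant input to pearson_fc")
  stats::cor(x, y)
}

#' Fit a VAR(p) by multivariate least squares
#'
#' Ordinary least squares of each channel on p lags of all channels, after
#' demeaning each channel over the segment. The innovation covariance is the
#' residual cross-product divided by the number of usable equations, T - p.
#'
#' @param x Numeric matrix (T x d), one contiguous segment.
#' @param order Lag order p >= 1; requires T > 10 * p.
#' @param fs Sampling rate (Hz) stored on the fitted model.
#' @return A [var_model()] with estimated lag matrices and covariance.
#' @export
fit_var <- function(x, order, fs = 1) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- ncol(x)
  p <- as.integer(order)
  stopifnot(p >= 1, d >= 1)
  if (n <= 10 * p)
    stop(sprintf("segment too short for VAR(%d): T = %d (need > %d)",
                 p, n, 10L * p))
  if (any(apply(x, 2, stats::sd) < 1e-12))
    stop("degenerate signal: constant channel in fit_var")
  x <- sweep(x, 2, colMeans(x))

  # design: columns ordered (lag 1, ch 1..d), (lag 2, ch 1..d), ...
  Y <- x[(p + 1):n, , drop = FALSE]
  X <- do.call(cbind, lapply(1:p, function(k)
    x[(p + 1 - k):(n - k), , drop = FALSE]))
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X))
    stop("ill-conditioned regressor matrix in fit_var (rank deficient)")
  B <- qr.coef(qr_x, Y)                          # (d*p) x d
  res <- Y - X %*% B
  sigma <- crossprod(res) / (n - p)
  coeffs <- lapply(1:p, function(k)
    t(B[((k - 1) * d + 1):(k * d), , drop = FALSE]))
  var_model(coeffs, sigma, fs = fs)
}

#' Default frequency grid up to Nyquist
#'
#' @param fs Sampling rate in Hz.
#' @param n Number of equally spaced points on \[0, fs/2\] (default 513).
#' @return Numeric vector of frequencies (Hz).
#' @export
gc_freq_grid <- function(fs, n = 513L) {
  seq(0, fs / 2, length.out = n)
}

#' Parametric VAR spectral decomposition
#'
#' Transfer function and spectral matrix of a VAR model on a frequency grid:
#' \deqn{H(f) = \left(I - \sum_k A_k e^{-i 2 \pi f k / f_s}\right)^{-1},
#'       \quad S(f) = H(f) \Sigma H(f)^*.}
#'
#' @param model A `var_model`.
#' @param freqs Frequencies in Hz, within \[0, fs/2\].
#' @return A list with `freqs`, `H` and `S` (complex d x d x nf arrays).
#' @export
var_spectrum <- function(model, freqs) {
  stopifnot(inherits(model, "var_model"))
  fs <- model$fs
  if (any(freqs < -1e-12 | freqs > fs / 2 + 1e-9))
    stop("frequencies must lie within [0, fs/2]")
  d <- model$dim
  p <- model$order
  nf <- length(freqs)
  H <- array(complex(real = 0), dim = c(d, d, nf))
  S <- H
  if (d == 2L) {
    # vectorized closed-form 2x2 inversion across the whole grid
    a11 <- rep(1 + 0i, nf); a12 <- rep(0i, nf)
    a21 <- rep(0i, nf);     a22 <- rep(1 + 0i, nf)
    if (p > 0) for (k in 1:p) {
      z <- exp(-2i * pi * freqs * k / fs)
      A <- model$coeffs[[k]]
      a11 <- a11 - A[1, 1] * z; a12 <- a12 - A[1, 2] * z
      a21 <- a21 - A[2, 1] * z; a22 <- a22 - A[2, 2] * z
    }
    det <- a11 * a22 - a12 * a21
    if (any(Mod(det) < 1e-14))
      stop(sprintf("singular characteristic matrix at f = %.5g Hz",
                   freqs[which.min(Mod(det))]))
    h11 <- a22 / det; h12 <- -a12 / det
    h21 <- -a21 / det; h22 <- a11 / det
    H[1, 1, ] <- h11; H[1, 2, ] <- h12
    H[2, 1, ] <- h21; H[2, 2, ] <- h22
    Sg <- model$sigma
    # S_ij = sum_kl H_ik Sigma_kl conj(H_jl)
    for (i in 1:2) for (j in 1:2) {
      Hi <- rbind(H[i, 1, ], H[i, 2, ])
      Hj <- rbind(H[j, 1, ], H[j, 2, ])
      S[i, j, ] <- (Sg[1, 1] * Hi[1, ] + Sg[2, 1] * Hi[2, ]) * Conj(Hj[1, ]) +
        (Sg[1, 2] * Hi[1, ] + Sg[2, 2] * Hi[2, ]) * Conj(Hj[2, ])
    }
  } else {
    I_d <- diag(d)
    for (i in seq_len(nf)) {
      A_f <- I_d
      if (p > 0) {
        z <- exp(-2i * pi * freqs[i] * (1:p) / fs)
        for (k in 1:p) A_f <- A_f - model$coeffs[[k]] * z[k]
      }
      Hf <- tryCatch(solve(A_f),
                     error = function(e)
                       stop(sprintf(
                         "singular characteristic matrix at f = %.5g Hz",
                         freqs[i])))
      H[, , i] <- Hf
      S[, , i] <- Hf %*% model$sigma %*% Conj(t(Hf))
    }
  }
  list(freqs = freqs, H = H, S = S)
}

#' Geweke frequency-domain Granger causality
#'
#' Spectral Granger causality from channel `from` to channel `to` of a fitted
#' bivariate VAR:
#' \deqn{I_{2 \to 1}(f) = \ln \frac{S_{11}(f)}
#'   {S_{11}(f) - (\Sigma_{22} - \Sigma_{12}^2 / \Sigma_{11}) |H_{12}(f)|^2}}
#' where channel 1 is the target, channel 2 the source, and
#' \eqn{\Sigma_{22} - \Sigma_{12}^2 / \Sigma_{11}} is the partial innovation
#' variance of the source. Nonpositive log arguments arising from
#' finite-sample degeneracy are clamped to 0; the number of clamped grid
#' points is reported in the `n_clamped` attribute.
#'
#' @param model Bivariate `var_model`.
#' @param freqs Frequency grid (Hz) within \[0, fs/2\].
#' @param from,to Source and target channel indices (default 2 -> 1).
#' @param spectrum Optional precomputed [var_spectrum()] of `model` on
#'   `freqs` (avoids recomputation when both directions are needed).
#' @return Numeric vector of nonnegative spectral GC values on `freqs`, with
#'   attribute `n_clamped`.
#' @export
spectral_gc <- function(model, freqs, from = 2L, to = 1L, spectrum = NULL) {
  stopifnot(model$dim == 2, from != to, from %in% 1:2, to %in% 1:2)
  sp <- if (is.null(spectrum)) var_spectrum(model, freqs) else spectrum
  Sig <- model$sigma
  if (Sig[to, to] <= 0) stop("target innovation variance must be positive")
  partial <- Sig[from, from] - Sig[to, from]^2 / Sig[to, to]
  s_tt <- Re(sp$S[to, to, ])
  h_tf <- Mod(sp$H[to, from, ])^2
  den <- s_tt - partial * h_tf
  ok <- den > 0 & s_tt > 0 & s_tt / den >= 1
  out <- numeric(length(freqs))
  out[ok] <- log(s_tt[ok] / den[ok])
  attr(out, "n_clamped") <- sum(!ok)
  out
}

#' Band-integrated (time-domain-equivalent) Granger causality
#'
#' Averages spectral GC over a frequency band by trapezoidal quadrature:
#' \deqn{F = \frac{1}{f_2 - f_1} \int_{f_1}^{f_2} I(f) \, df.}
#'
#' @param freqs Frequency grid (Hz) on which `gc` is tabulated.
#' @param gc Spectral GC values from [spectral_gc()].
#' @param f1,f2 Band edges (Hz), `f1 < f2`, both within the grid range.
#' @return Scalar nonnegative band GC.
#' @export
band_gc <- function(freqs, gc, f1, f2) {
  stopifnot(length(freqs) == length(gc), f1 < f2)
  eps <- 1e-9
  if (f1 < min(freqs) - eps || f2 > max(freqs) + eps)
    stop(sprintf("band [%g, %g] outside tabulated grid [%g, %g]",
                 f1, f2, min(freqs), max(freqs)))
  inner <- freqs > f1 & freqs < f2
  fgrid <- c(f1, freqs[inner], f2)
  vals <- c(stats::approx(freqs, gc, xout = f1, rule = 2)$y,
            gc[inner],
            stats::approx(freqs, gc, xout = f2, rule = 2)$y)
  area <- sum(diff(fgrid) * (utils::head(vals, -1) + utils::tail(vals, -1)) / 2)
  max(area / (f2 - f1), 0)
}

#' Welch segment-averaged cross-spectral estimate
#'
#' Nonparametric cross-spectral matrix by averaging windowed cross-
#' periodograms over 50\%-overlapping Hamming-windowed segments, pooled
#' across runs. Scaled so that white noise with covariance \eqn{\Sigma}
#' has expected spectrum \eqn{\Sigma} (the same convention as
#' [var_spectrum()]).
#'
#' @param x Numeric matrix (T x d).
#' @param run Optional run index per row; segments never straddle runs.
#' @param seg_len Segment length (default 256, shortened to the largest
#'   run if needed).
#' @param fs Sampling rate (Hz).
#' @return List with `freqs` (one-sided, Hz) and `S` (complex d x d x nf).
#' @export
welch_cross_spectrum <- function(x, run = NULL, seg_len = 256L, fs = 1) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- ncol(x)
  if (is.null(run)) run <- rep(1L, n)
  run_lens <- table(run)
  seg_len <- min(seg_len, max(run_lens))
  step <- max(1L, seg_len %/% 2L)
  w <- 0.54 - 0.46 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))
  norm <- sum(w^2)
  nf <- seg_len %/% 2L + 1L
  acc <- array(complex(real = 0), dim = c(d, d, nf))
  n_seg <- 0L
  for (r in unique(run)) {
    xr <- x[run == r, , drop = FALSE]
    starts <- seq(1L, nrow(xr) - seg_len + 1L, by = step)
    for (s in starts) {
      seg <- xr[s:(s + seg_len - 1L), , drop = FALSE]
      seg <- sweep(seg, 2, colMeans(seg)) * w
      X <- stats::mvfft(seg)[1:nf, , drop = FALSE]
      for (i in 1:d) for (j in 1:d)
        acc[i, j, ] <- acc[i, j, ] + X[, i] * Conj(X[, j]) / norm
      n_seg <- n_seg + 1L
    }
  }
  if (n_seg == 0L) stop("runs too short for the requested segment length")
  list(freqs = (0:(nf - 1L)) * fs / seg_len, S = acc / n_seg)
}

#' Select the VAR model order by spectral difference
#'
#' For each candidate order p, the squared Frobenius distance
#' \deqn{D(p) = \sum_r \sum_f \| S_{\mathrm{VAR}}^{(r)}(f; p) -
#'   S_{\mathrm{Welch}}^{(-r)}(f) \|_F^2}
#' between the parametric spectrum of a VAR(p) fitted on run r and the
#' Welch segment-averaged spectrum of the remaining runs is accumulated
#' over runs, and the order minimizing D is returned (ties toward the
#' smaller order). Holding out the run under comparison keeps the
#' criterion honest: an overfitted parametric spectrum chases the sampling
#' noise of its own periodogram, which the held-out target does not share,
#' so D turns back up beyond the true order. A single-run input is split
#' into two half-run folds.
#'
#' @param x Numeric matrix (T x d) of the channel pair.
#' @param run Optional run index per row.
#' @param candidates Candidate orders (default 2:20).
#' @param fs Sampling rate (Hz).
#' @param seg_len Welch segment length (default 256).
#' @return The selected order (integer) with attribute `criterion`, the named
#'   vector of D(p).
#' @export
select_order <- function(x, run = NULL, candidates = 2:20, fs = 1,
                         seg_len = 256L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (is.null(run)) run <- rep(1L, n)
  if (length(unique(run)) == 1L)   # split a single run into two folds
    run <- rep(1:2, c(n %/% 2L, n - n %/% 2L))
  stopifnot(length(candidates) >= 1)
  candidates <- sort(unique(as.integer(candidates)))
  min_run <- min(table(run))
  feasible <- candidates[10L * candidates < min_run]
  if (length(feasible) == 0)
    stop("all candidate orders are infeasible for runs of length ", min_run)

  ids <- unique(run)
  targets <- lapply(ids, function(r)
    welch_cross_spectrum(x[run != r, , drop = FALSE], run[run != r],
                         seg_len = seg_len, fs = fs))
  crit <- vapply(feasible, function(p) {
    total <- 0
    for (k in seq_along(ids)) {
      m <- fit_var(x[run == ids[k], , drop = FALSE], p, fs = fs)
      S_par <- var_spectrum(m, targets[[k]]$freqs)$S
      total <- total + sum(Mod(S_par - targets[[k]]$S)^2)
    }
    total
  }, numeric(1))
  names(crit) <- feasible
  sel <- feasible[which.min(crit)]
  structure(as.integer(sel), criterion = crit)
}

# Fit a VAR(p) per run and average spectral matrices, transfer functions and
# innovation covariances across runs with run lengths as weights. Returns
# list(S, H, sigma, models).
average_run_spectra <- function(x, run, order, fs, freqs) {
  x <- as.matrix(x)
  ids <- unique(run)
  wts <- vapply(ids, function(r) sum(run == r), numeric(1))
  wts <- wts / sum(wts)
  d <- ncol(x)
  nf <- length(freqs)
  S <- array(complex(real = 0), dim = c(d, d, nf))
  H <- S
  sigma <- matrix(0, d, d)
  models <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    m <- fit_var(x[run == ids[k], , drop = FALSE], order, fs = fs)
    sp <- var_spectrum(m, freqs)
    S <- S + wts[k] * sp$S
    H <- H + wts[k] * sp$H
    sigma <- sigma + wts[k] * m$sigma
    models[[k]] <- m
  }
  list(S = S, H = H, sigma = sigma, models = models, weights = wts)
}

#' Per-subject pairwise connectivity over the stream connections
#'
#' For every connection, computes one undirected FC value (Pearson, per run,
#' averaged with run lengths as weights) and two directed band-integrated GC
#' values (one per direction). GC spectra are computed per run from per-run
#' bivariate VAR fits, averaged across runs with run lengths as weights, and
#' then integrated over the analysis band.
#'
#' @param series Numeric matrix or data frame with one named column per ROI.
#' @param run Integer run index per row (default: a single run).
#' @param connections Connection table from [stream_connections()], or any
#'   data frame with `roi_a`, `roi_b` columns.
#' @param order VAR model order (default 6).
#' @param fs Sampling rate (Hz).
#' @param band Length-2 analysis band in Hz (default `c(0.05, 0.9)`).
#' @param n_freq Number of frequency-grid points (default 513).
#' @return Long data frame with columns `connection`, `roi_a`, `roi_b`,
#'   `subsystem` (if present in `connections`), `metric` (`"fc"` or
#'   `"tgc"`), `direction` (`"undirected"`, `"a->b"`, `"b->a"`) and `value`.
#' @export
pairwise_connectivity <- function(series, run = NULL, connections,
                                  order = 6L, fs = 1 / 0.535,
                                  band = c(0.05, 0.9), n_freq = 513L) {
  series <- as.matrix(as.data.frame(series))
  if (is.null(run)) run <- rep(1L, nrow(series))
  stopifnot(length(run) == nrow(series), band[1] < band[2])
  missing_rois <- setdiff(unique(c(connections$roi_a, connections$roi_b)),
                          colnames(series))
  if (length(missing_rois))
    stop("series is missing ROI column(s): ",
         paste(missing_rois, collapse = ", "))
  if (any(connections$roi_a == connections$roi_b))
    stop("self-pair connection requested (roi_a == roi_b)")
  freqs <- gc_freq_grid(fs, n_freq)
  if (band[2] > fs / 2 + 1e-9)
    stop("analysis band exceeds the Nyquist frequency fs/2")

  run_lens <- vapply(unique(run), function(r) sum(run == r), numeric(1))
  wts <- run_lens / sum(run_lens)
  has_sub <- "subsystem" %in% names(connections)
  out <- vector("list", nrow(connections))
  for (i in seq_len(nrow(connections))) {
    a <- connections$roi_a[i]
    b <- connections$roi_b[i]
    x <- series[, c(a, b), drop = FALSE]
    fc_runs <- vapply(unique(run), function(r)
      pearson_fc(x[run == r, 1], x[run == r, 2]), numeric(1))
    fc <- sum(wts * fc_runs)

    I_ab <- numeric(length(freqs))   # a -> b: source channel 1, target 2
    I_ba <- numeric(length(freqs))
    for (k in seq_along(unique(run))) {
      r <- unique(run)[k]
      m <- fit_var(x[run == r, , drop = FALSE], order, fs = fs)
      sp <- var_spectrum(m, freqs)
      I_ab <- I_ab + wts[k] *
        spectral_gc(m, freqs, from = 1L, to = 2L, spectrum = sp)
      I_ba <- I_ba + wts[k] *
        spectral_gc(m, freqs, from = 2L, to = 1L, spectrum = sp)
    }
    lab <- connection_label(a, b)
    sub <- if (has_sub) connections$subsystem[i] else NA_character_
    out[[i]] <- data.frame(
      connection = lab, roi_a = a, roi_b = b, subsystem = sub,
      metric = c("fc", "tgc", "tgc"),
      direction = c("undirected", "a->b", "b->a"),
      value = c(fc,
                band_gc(freqs, I_ab, band[1], band[2]),
                band_gc(freqs, I_ba, band[1], band[2])),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (!has_sub) res$subsystem <- NULL
  res
}
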