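#' Vector autoregressive model
#'
#' Container for a stationary VAR(p) process
#' \deqn{x_t = A_1 x_{t-1} + \dots + A_p x_{t-p} + \epsilon_t,
#'       \quad \epsilon_t \sim N(0, \Sigma).}
#' Stationarity is enforced at construction: the spectral radius of the
#' companion matrix must be below 1.
#'
#' @param coeffs List of p square lag matrices (all d x d), or a single
#'   matrix for p = 1, or an empty list for pure noise.
#' @param sigma Innovation covariance (d x d, symmetric positive definite).
#' @param fs Sampling rate in Hz.
#' @return An object of class `var_model`.
#' @export
var_model <- function(coeffs, sigma, fs = 1) {
  if (is.matrix(coeffs)) coeffs <- list(coeffs)
  d <- nrow(sigma)
  stopifnot(is.list(coeffs), ncol(sigma) == d, fs > 0)
  for (a in coeffs) stopifnot(is.matrix(a), dim(a) == c(d, d))
  if (max(abs(sigma - t(sigma))) > 1e-8 * max(1, max(abs(sigma))))
    stop("sigma must be symmetric")
  if (min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("sigma must be positive definite")
  m <- structure(list(coeffs = coeffs, sigma = sigma, fs = fs,
                      order = length(coeffs), dim = d),
                 class = "var_model")
  rho <- companion_radius(m)
  if (rho >= 1)
    stop(sprintf("non-stationary VAR: companion spectral radius %.4f >= 1",
                 rho))
  m
}

#' Companion-matrix spectral radius of a VAR
#'
#' @param model A `var_model` (or a bare list of lag matrices).
#' @return The largest eigenvalue modulus of the companion matrix; 0 for an
#'   empty (pure-noise) model.
#' @export
companion_radius <- function(model) {
  coeffs <- if (inherits(model, "var_model")) model$coeffs else model
  p <- length(coeffs)
  if (p == 0) return(0)
  d <- nrow(coeffs[[1]])
  comp <- matrix(0, d * p, d * p)
  comp[1:d, ] <- do.call(cbind, coeffs)
  if (p > 1) comp[(d + 1):(d * p), 1:(d * (p - 1))] <- diag(d * (p - 1))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' @export
print.var_model <- function(x, ...) {
  cat(sprintf("VAR(%d) model, %d channels, fs = %.4g Hz\n",
              x$order, x$dim, x$fs))
  cat(sprintf("  companion spectral radius: %.4f\n", companion_radius(x)))
  invisible(x)
}

#' Simulate one realization of a VAR process
#'
#' Draws Gaussian innovations with the model's covariance and runs the lag
#' recursion after a burn-in (discarded) so the output is approximately a
#' draw from the stationary distribution.
#'
#' @param model A `var_model`.
#' @param n Number of samples to return.
#' @param burn Burn-in samples discarded before recording (default 200).
#' @return An `n` x d numeric matrix.
#' @export
simulate_var <- function(model, n, burn = 200L) {
  stopifnot(inherits(model, "var_model"), n >= 1)
  d <- model$dim
  p <- model$order
  total <- n + burn + p
  eps <- matrix(stats::rnorm(total * d), total, d) %*% chol(model$sigma)
  if (p == 0) return(eps[(burn + 1):(burn + n), , drop = FALSE])
  x <- matrix(0, total, d)
  A <- model$coeffs
  for (t in (p + 1):total) {
    acc <- eps[t, ]
    for (k in 1:p) acc <- acc + A[[k]] %*% x[t - k, ]
    x[t, ] <- acc
  }
  x[(total - n + 1):total, , drop = FALSE]
}

#' Simulate multi-run BOLD-like ROI series from a VAR model
#'
#' Produces `n_runs` independent stationary realizations of the model
#' (independent initial conditions and innovations per run), mirroring an
#' fMRI session of several functional runs.
#'
#' @param model A stationary `var_model`.
#' @param n_runs Number of runs.
#' @param samples_per_run Samples per run; must exceed the model order.
#' @param seed Integer seed for reproducibility (optional).
#' @return A list with `series` (the stacked (n_runs * samples_per_run) x d
#'   matrix) and `run` (integer run index per row).
#' @export
simulate_bold <- function(model, n_runs, samples_per_run, seed = NULL) {
  stopifnot(n_runs >= 1, samples_per_run > model$order)
  if (!is.null(seed)) set.seed(as.integer(seed %% .Machine$integer.max))
  runs <- lapply(seq_len(n_runs), function(r)
    simulate_var(model, samples_per_run))
  list(series = do.call(rbind, runs),
       run = rep(seq_len(n_runs), each = samples_per_run))
}
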