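# Independent oracles used to cross-check the implementation paths.

# Geweke time-domain GC by refitting the reduced (single-channel) model:
# ln(sigma^2_reduced / sigma^2_full) for the influence `from` -> `to`.
time_domain_gc_oracle <- function(x, order, from = 1, to = 2) {
  full <- fit_var(x, order)
  reduced <- fit_var(x[, to, drop = FALSE], order)
  log(reduced$sigma[1, 1] / full$sigma[to, to])
}

# Exact Mann-Whitney p-value by full enumeration of group assignments.
enumeration_wilcox_p <- function(a, b,
                                 alternative = c("two.sided", "less",
                                                 "greater")) {
  alternative <- match.arg(alternative)
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  m <- length(a)
  n <- length(b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(m + n, m)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  switch(alternative,
         less = mean(u_all <= u_obs),
         greater = mean(u_all >= u_obs),
         two.sided = min(1, 2 * min(mean(u_all <= u_obs),
                                    mean(u_all >= u_obs))))
}

# Brute-force count of lattice voxels inside a sphere: voxel centres on an
# isotropic grid of spacing `step` mm, centre on a voxel centre.
lattice_sphere_count <- function(radius, step) {
  half <- ceiling(radius / step)
  g <- expand.grid(i = -half:half, j = -half:half, k = -half:half)
  sum((g$i^2 + g$j^2 + g$k^2) * step^2 <= radius^2 + 1e-9)
}

# Small stationary VAR(2) with a pronounced spectral peak, used for
# parameter-recovery and order-selection checks.
strong_var2 <- function(fs = 1 / 0.535) {
  var_model(list(rbind(c(1.2, 0), c(0.3, 1.0)),
                 rbind(c(-0.5, 0), c(0, -0.4))),
            diag(2), fs = fs)
}

# A scaled-down cohort configuration for simulation-heavy tests.
small_cohort_config <- function(seed, ...) {
  cohort_config(n_gamers = 10L, n_nongamers = 8L, n_runs = 2L,
                samples_per_run = 200L, seed = seed, ...)
}
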