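---
title: "Directed and undirected connectivity of the dual visual streams: methods"
author: "dvsconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed and undirected connectivity of the dual visual streams: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis in one paragraph

`dvsconn` compares functional and structural connectivity of the dorsal
(DVS) and ventral (VVS) visual streams, plus the primary visual-stream
connections out of the calcarine (VS), between two participant groups —
habitual action video game players and non-players — and relates
connectivity to sensorimotor response time. Fourteen spherical regions of
interest in MNI space define twelve stream connections. Per connection the
pipeline computes one undirected functional connectivity value (Pearson
correlation of the ROI BOLD series) and two directed values (band-integrated
Geweke frequency-domain Granger causality, one per direction) for each
subject, compares groups with Wilcoxon rank-sum tests Holm-corrected within
each subsystem, and correlates the designated left dorsal connection
(L SOG → L SPL) with response time by Spearman rank correlation. A
calibrated synthetic cohort generator supplies data with the statistical
structure the analysis assumes, so every stage is exercised end-to-end
without external imaging data.

## Directed connectivity model

Each channel pair is modelled as a bivariate vector autoregression of
order $p$,

$$x_t = \sum_{k=1}^{p} A_k\, x_{t-k} + \epsilon_t,
  \qquad \epsilon_t \sim \mathcal N(0, \Sigma),$$

fitted by ordinary least squares on the lagged regressors after demeaning
each run segment, with the innovation covariance estimated from the
residual cross-products divided by the number of usable equations,
$T - p$. The transfer function and parametric spectral matrix are

$$H(f) = \Big(I - \sum_k A_k e^{-i 2 \pi f k / f_s}\Big)^{-1},
  \qquad S(f) = H(f)\, \Sigma\, H(f)^{*},$$

and the spectral Granger causality from channel 2 (source) to channel 1
(target) is

$$I_{2 \to 1}(f) = \ln \frac{S_{11}(f)}
  {S_{11}(f) - \left(\Sigma_{22} - \Sigma_{12}^2 / \Sigma_{11}\right)
   |H_{12}(f)|^2},$$

where $\Sigma_{22} - \Sigma_{12}^2/\Sigma_{11}$ is the partial innovation
variance of the source. The time-domain-equivalent (band) value is the
bandwidth-normalized integral

$$F_{2 \to 1} = \frac{1}{f_2 - f_1} \int_{f_1}^{f_2} I_{2 \to 1}(f)\, df,$$

evaluated by trapezoidal quadrature. The analysis band is 0.05–0.9 Hz at a
sampling rate of $1/\mathrm{TR} = 1/0.535\,\mathrm{s} \approx 1.87$ Hz
(Nyquist 0.93 Hz), on a 513-point frequency grid over $[0, f_s/2]$.

Assumptions worth stating plainly: the BOLD series is treated as a
realization of a stationary linear Gaussian process within each run; no
hemodynamic deconvolution is attempted, so "directed influence" means
lagged linear predictability of the measured signals at this TR; and the
causality is *pairwise* (bivariate) — no conditioning on other regions.

### Multi-run handling

Each functional run is fitted separately and the per-run GC spectra (and
per-run Pearson correlations) are averaged with run lengths as weights
before band integration. Concatenating runs would create spurious lagged
relations across run boundaries; averaging spectra avoids that at the cost
of slightly higher variance per fit.

### Numerical safeguards

The log argument in $I_{2\to1}$ is theoretically positive but can dip to
or below zero under finite-sample degeneracy; such grid points are clamped
to zero and counted (`n_clamped` attribute) rather than raised as errors.
Rank-deficient lag regressors raise a conditioning error. Band edges are
linearly interpolated onto the grid. Ties in the order-selection criterion
break toward the smaller order.

## Model-order selection

The order is chosen from candidates 2–20 by minimizing a spectral
difference between the fitted parametric spectrum and a nonparametric
Welch estimate (50%-overlapping Hamming-windowed segments of 256 samples,
cross-periodograms averaged; scaled so white noise with covariance
$\Sigma$ has expected spectrum $\Sigma$, matching the parametric
convention):

$$D(p) = \sum_r \sum_f \big\| S_{\mathrm{VAR}}^{(r)}(f; p) -
  S_{\mathrm{Welch}}^{(-r)}(f) \big\|_F^2 .$$

The comparison is deliberately *held out*: the VAR fitted on run $r$ is
compared against the Welch spectrum of the remaining runs. An in-sample
version of the same criterion is monotonically decreasing in $p$ — a
higher-order VAR chases the sampling noise of the very periodogram it is
scored against, so the minimizer saturates at the largest candidate. With
the held-out target, overfitting raises $D$ and the criterion turns back
up past the generating order. On synthetic cohorts at the study's sizing
(4 × 860 samples) the criterion recovers a generating order of 6 modally
(39/50 seeds) and a generating order of 2 modally (27/50 seeds); per-subject
selections scatter by one or two orders around the mode, which is why the
pipeline fixes the analysis order at the cohort-modal value (six) rather
than selecting per subject. A single-run input is split into two half-run
folds.

## Group statistics

Group differences use the Wilcoxon rank-sum test: exact enumeration when
the pooled sample is at most 12 without ties, otherwise the normal
approximation with tie and continuity corrections. Two-sided throughout —
sidedness is configurable, but the conservative default is used
everywhere. Multiplicity is controlled per subsystem family by
Holm–Bonferroni: the four undirected tests of a subsystem form one family;
for directed values both directions of every connection enter the family
(eight directed tests for the DVS). Brain–behavior association is Spearman
rank correlation with midranks and a two-sided t-approximate p-value; the
ordinary least-squares line reported alongside is for display only.
Subject exclusion is metric-local: a subject missing one measurement is
dropped from that test only, with the drop count logged.

One documented inconsistency: the source material labels the significant
directed connection L SOG–L SPL in the text but R SOG–R SPL in one figure
caption; the pipeline designates **L SOG → L SPL** throughout.

## The synthetic cohort generator

The generator emulates the study conditions the analysis assumes:

| parameter | default | meaning |
|---|---|---|
| `n_gamers`, `n_nongamers` | 28, 19 | group sizes |
| `n_runs`, `samples_per_run` | 4, 860 | 3440 volumes per subject |
| `tr_seconds` | 0.535 | sampling interval (s) |
| `coupling_nongamer`, `coupling_gamer` | 0.15, 0.21 | group-mean lag-1 cross-coefficient, L SOG → L SPL |
| `coupling_sd` | 0.075 | between-subject coupling SD |
| `rt_mean_nongamer`, `rt_gap` | 620 ms, 190 ms | response-time baseline and group gap |
| `behavior_link_strength` | 8 ms/SD | RT decrease per SD of coupling |
| `rt_noise_sd` | 30 ms | residual RT noise |
| `fa_shift`, `qa_shift` | 0.05, 0.06 | gamer shifts of the structural metrics |

Design choices, and why:

* **Generative class.** Per-subject BOLD-like series come from a bivariate
  VAR(6) for the designated pair — the model class the GC analysis
  presumes — with own-lag coefficients 0.25 (lag 1) and 0.20 (lag 6) on
  both channels, so the generating order matches the analysis order. The
  directed influence is a single lag-1 cross-coefficient drawn per subject
  as $c_i \sim \mathcal N(\mu_{\mathrm{group}}, s_c)$. The remaining 12
  atlas regions are independent AR(1) channels (coefficient 0.3), keeping
  the full 14-ROI table shape at negligible cost. The lag structure is
  triangular, so the system is stationary for any coupling value; the
  stationarity gate (companion spectral radius < 1) is still enforced on
  every emitted system.
* **Instantaneous component.** Innovations of the pair are correlated,
  $\Sigma_{12} = 0.5\,c_i$. Coupled cortical regions share common input,
  so undirected correlation should exceed what the lagged path alone
  produces; without this term the Pearson FC of a realistic lag-1 coupling
  is so weak (r ≈ 0.06) that its estimation noise at T = 3440 swamps the
  between-subject signal and the FC brain–behavior correlation attenuates
  well below its directed counterpart.
* **Response-time model.** $RT_i = \mu_{NG} - \Delta\cdot
  1[\mathrm{gamer}] - \beta\,(c_i - \mu_{\mathrm{group}})/s_c +
  \varepsilon_i$ — the simplest monotone-decreasing link consistent with a
  negative brain–behavior correlation. Standardizing the coupling against
  the group's nominal mean keeps the expected group gap exactly at
  `rt_gap`.
* **Calibration.** The free defaults (coupling means and SD, link
  strength, RT noise) were calibrated once so that, at packaged defaults,
  the cohort-averaged Spearman correlation between the designated
  connection and response time sits near −0.45 (directed) and −0.41
  (undirected) with a ~190 ms group gap, and then frozen. A single
  cohort's rank correlation at n = 44 has a sampling SD of roughly 0.12
  even when the population value is exactly on target — this noise floor
  is a property of the estimator and sample size, not of the generator —
  so calibration summaries (`cohort_calibration()`) average over replicate
  cohorts.
* **Seed discipline.** One base seed expands into per-subject,
  per-purpose substreams by a counter scheme (`seed + i·100003 +
  purpose·10007`), so adding subjects or purposes never perturbs existing
  draws. Couplings remain iid Gaussian: a variance-stabilized quantile
  design was considered and rejected because it breaks exchangeability and
  with it the null behavior of rank tests (uniform p-values under equal
  couplings), which the test suite verifies.
* **Exclusion pattern.** Completeness flags default to one gamer without
  tractography, one nongamer without fMRI, and one subject per group
  without response time, reproducing effective sample sizes of 46
  (functional), 44 (functional brain–behavior), 46 (structural) and 44
  (structural brain–behavior).
* **Structural metrics.** FA and QA are scalar per (subject, connection),
  drawn around fixed baselines (FA 0.45 ± 0.05, QA 0.35 ± 0.08) with the
  gamer shift applied to FA on L SOG–L IPL and to QA on L SOG–L IPL,
  R SOG–R SPL and R SOG–R IPL — the dorsal connections where elevation is
  expected. FA is clipped into (0, 1) with a warning if a shift pushes it
  outside. Per-group RT distributions are calibrated, not copied from any
  source: only the gap is externally specified.

### What the generator does *not* emulate

No hemodynamic response convolution, physiological noise, motion
artifacts, scanner drift (beyond what detrending would remove), spatial
correlation between ROIs other than the designated pair, or volumetric
data by default. Passing tests therefore demonstrate that the *pipeline*
recovers the structure it assumes from data of realistic size and noise —
not that real BOLD data satisfy those assumptions.

## ROI geometry

Spherical masks include a voxel iff its centre lies within the radius of
the MNI centre (voxel-centre convention; the common alternative,
any-overlap, grows masks by a shell of boundary voxels). The default grid
is the 2 mm isotropic MNI152 grid (91 × 109 × 91), configurable via any
invertible affine, since the acquisition grid for extraction is not fixed
by the protocol. Extraction order per run segment is fixed: voxel-average
→ remove least-squares linear trend → z-normalize. Detrending before
normalization keeps the variance bookkeeping of the trend removal out of
the normalization; the output is invariant to positive affine rescaling of
voxel intensities. A 6 mm sphere on the 2 mm grid contains exactly 123
voxels (the integer lattice count), which the tests pin against a
brute-force oracle.

## Problem sizes used by the test suite

Simulation-heavy properties run at deliberately chosen sizes: the Geweke
variance-ratio identity at T = 10^5 (agreement within 5%); directionality
recovery and order selection at the study sizing of 4 × 860 samples (40
and 50 seeds); null-uniformity of downstream rank tests on scaled-down
cohorts (10 + 8 subjects, 2 × 200 samples, 60 replicates) and on the
structural table at full size (300 replicates); family-wise error control
with 500 label permutations; generator calibration as a mean over 5
replicate cohorts. These sizes give Monte-Carlo error comfortably inside
each asserted tolerance.

## Known limitations

* Pairwise GC only; common-input effects from unmodelled regions are not
  conditioned away.
* The VAR order is fixed cohort-wide at six after modal selection;
  per-subject selection is noisy by one or two orders.
* FC values enter group tests as raw correlations (no Fisher z); with
  n ≥ 18 per group the rank test is insensitive to that choice.
* The Welch target uses fixed segmentation (256 samples, Hamming, 50%
  overlap); very short runs fall back to shorter segments.
* Real-data p-values depend on the deposited cohort and are outside what
  synthetic data can reproduce; only self-contained printed constants and
  calibrated stochastic targets are asserted.
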