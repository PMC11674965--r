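# dvsconn

Connectivity analysis of the dorsal and ventral visual streams, comparing
two participant groups (habitual action video game players vs.
non-players) and relating connectivity to sensorimotor response time.
The package implements the full statistical pipeline — undirected and
directed functional connectivity, rank-based group comparisons with
family-wise correction, brain–behavior correlation, and structural
anisotropy comparisons — together with a calibrated synthetic cohort
generator, so the whole analysis runs end-to-end without any imaging data.

It is written for researchers who want a tested, reproducible
reimplementation of this kind of dual-stream connectivity analysis: the
statistical engine accepts any per-subject ROI time-series and FA/QA
tables in the documented CSV layouts.

## What it computes

Fourteen spherical ROIs in MNI space (superior/inferior occipital and
parietal regions, inferior temporal and fusiform regions, calcarine)
define twelve connections across three subsystems (DVS, VVS, VS). Per
subject and connection:

* **FC** — Pearson correlation between the two ROI BOLD series, averaged
  over runs with run lengths as weights.
* **TGC** — band-integrated Geweke frequency-domain Granger causality in
  each direction. A bivariate VAR(p) is fitted per run by least squares;
  with transfer function `H(f) = (I − Σₖ Aₖ e^{−i2πfk/fs})⁻¹` and
  innovation covariance Σ, the spectral causality from source 2 to
  target 1 is

  `I₂→₁(f) = ln [ S₁₁(f) / (S₁₁(f) − (Σ₂₂ − Σ₁₂²/Σ₁₁)|H₁₂(f)|²) ]`,

  integrated over 0.05–0.9 Hz and normalized by the bandwidth
  (`F = (1/(f₂−f₁)) ∫ I df`). The sampling rate is 1/TR = 1/0.535 s ≈
  1.87 Hz. The VAR order (default 6) is selected from candidates 2–20 by
  a held-out spectral-difference criterion against a Welch estimate.

Groups are compared per connection with Wilcoxon rank-sum tests,
Holm-corrected within each subsystem family; brain–behavior association
uses Spearman rank correlation against response time; FA/QA structural
metrics go through the identical engine. The synthetic generator
reproduces the study conditions: 28 + 19 subjects, 4 runs × 860 volumes,
a directed coupling difference on L SOG → L SPL, a ~190 ms group
response-time gap, and a negative monotone coupling–RT link.

## Worked example

```r
library(dvsconn)

cohort <- generate_cohort(cohort_config(seed = 1))
tbl <- designated_pair_connectivity(cohort)   # FC + directed TGC, L SOG--L SPL

subj <- cohort$subjects
rts <- setNames(subj$response_time_ms, subj$subject_id)
rts[!(subj$fmri_complete & subj$rt_complete)] <- NA
brain_behavior(tbl, rts, "L SOG--L SPL", "tgc", "a->b")[c("rho", "p", "n")]
```

Running the numbered drivers under `analysis/` executes the full
workflow (`01_simulate` → `05_report`), writing tables and a markdown
report under `results/`. With the default seed the run prints, among
other things:

```
group mean RT: gamers 433 ms, nongamers 619 ms (gap 186 ms)
FC L SOG--L SPL (undirected): p_raw 0.0017, Holm p* 0.0068
TGC L SOG--L SPL (a->b): p_raw 0.0016, Holm p* 0.0125
FC  vs RT: rho = -0.436, p = 0.0031, n = 44
TGC vs RT: rho = -0.433, p = 0.0033, n = 44
subjects retained for structural analysis: 46
QA L SOG--L IPL: gamer median 0.399 vs nongamer 0.349, Holm p* 0.0439
```

Read: the designated left dorsal connection carries a significant group
difference in both undirected and directed connectivity, both measures
correlate negatively with response time over the 44-subject
brain–behavior subset (stronger coupling, faster responses), and the
structural metrics are elevated in the gamer group on the designated
dorsal connections. Per-seed values fluctuate — a rank correlation at
n = 44 has a sampling SD of about 0.12 — which is why calibration
summaries average over replicate cohorts
(see `cohort_calibration()`).

## Layout

* `R/` — atlas and ROI geometry, VAR simulation/fitting, spectral GC,
  group statistics, structural metrics, cohort generator, pipeline
  orchestration (`run_synth()` / `run_analyze()` / `run_report()`).
* `analysis/` — numbered narrative drivers over the package functions.
* `vignettes/dual-stream-connectivity.Rmd` — the methods vignette: model
  assumptions, parameter meanings and defaults, generator design and
  calibration, numerical choices, limitations.
* `inst/extdata/` — the 14-ROI atlas table, per-connection tracking
  parameters (reference metadata), default YAML configuration.
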