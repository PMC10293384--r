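# megslow

Source-space resting-state MEG analysis for longitudinal cohorts, built for
studying the neurophysiological progression markers of Parkinson's disease:
**spectral slowing** and **amplitude-envelope functional connectivity** on a
90-region parcellation (78 cortical + 12 subcortical regions).

## What it computes

For each subject-visit recording (a 90-region × samples source time-series
matrix), the pipeline derives:

* **Relative band power** per region in the five canonical bands — delta
  (0.5–4 Hz), theta (4–8 Hz), alpha1 (8–10 Hz), alpha2 (10–13 Hz), beta
  (13–30 Hz) — from Hann-tapered periodograms of 4096-sample epochs
  (13.11 s at 312.5 Hz, 0.076 Hz resolution), relative to total 0.5–30 Hz
  power, so the five values sum to 1 per region.
* **Peak frequency**: the dominant spectral frequency within 4–13 Hz.
* **AEC-c**, the corrected amplitude envelope correlation: per band and
  epoch, each signal pair is symmetrically orthogonalized (removing
  zero-lag leakage from field spread), the amplitude envelopes (analytic
  signal magnitudes) are correlated in both directions, averaged, and
  rescaled as `(r + 1) / 2` — values lie in [0, 1] with **0.5 meaning no
  coupling**. All 4005 region pairs form a 90 × 90 adjacency matrix,
  reduced to a per-region mean-connectivity profile.
* **Statistics**: connection-level permutation tests with
  Benjamini–Hochberg FDR across the 4005 connections; linear mixed models
  (subject random intercept) for baseline group differences
  (Bonferroni 0.05/6), a group × location (cortical/subcortical)
  interaction, longitudinal change over visits (categorical visit dummies),
  and associations between spectral measures and clinical scores (CAMCOG,
  UPDRS-III).

A synthetic-cohort generator (`simulate_cohort()`, `simulate_roi_signal()`,
`plant_envelope_coupling()`) reproduces the statistical structure the
analysis assumes — 1/f spectra with a drifting alpha-range peak, planted
band-limited envelope coupling, three-visit designs with dropout, clinical
scores driven by the spectral state — so the whole pipeline is testable
without access to patient recordings.

## Worked example

```r
library(megslow)

atlas <- load_atlas()                      # 90 regions, 78 cortical + 12 subcortical
bands <- canonical_bands()

# a synthetic subject-visit recording: 90 regions, 10 epochs of 4096 samples
design <- cohort_design(n_controls = 0, n_de_novo = 1, n_treated = 0,
                        dropout_probability = 0, seed = 5,
                        signal = list(sample_rate = 312.5, epoch_length = 2048L,
                                      n_epochs = 4L, one_over_f_exponent = 1,
                                      peak_power_ratio = 4, peak_width = 0.5))
sim <- simulate_cohort(design, mode = "signals")
rec <- sim$recordings[[1]]

es <- epoch(rec, 2048L)                    # broadband epochs
ss <- epoch_spectra(es)                    # per-region spectra, 0.5-30 Hz
rp <- relative_band_power(ss)              # region x band, rows sum to 1
pf <- peak_frequency(ss)                   # per-region peak, 4-13 Hz
summarize_regions(rp, atlas)
#>   measure cortical_mean subcortical_mean
#> 1   delta     0.2257281        0.2401626
#> 2   theta     0.1364701        0.1332008
#> 3  alpha1     0.1236361        0.1239078
#> 4  alpha2     0.1408609        0.1228460
#> 5    beta     0.3733049        0.3798828

round(mean(pf), 2)                         # region-mean peak frequency (Hz)
#> [1] 9.61

aec <- aec_matrix(bandpass(es, bands$alpha2))  # 90 x 90 AEC-c adjacency
round(mean(roi_profile(aec)), 3)           # whole-brain mean connectivity
#> [1] 0.484
```

The subject's true state (a de novo patient at baseline) has relative band
powers delta 0.218, theta 0.145, alpha1 0.116, alpha2 0.144, beta 0.378 and
a 9.04 Hz peak: the estimated region-mean band powers land within about 0.01
of the planted values, and the mean AEC-c of this uncoupled recording sits
near the 0.5 no-coupling calibration point (here 0.484 on short 4-epoch
recordings; 200-pair calibration runs centre on 0.50, see below). The
region-mean peak (9.61 Hz) sits above the 9.04 Hz truth — the documented
interaction between per-band power tilting and the spectral argmax near band
edges (see the methods vignette).

Longitudinal statistics run on the cohort table:

```r
sim <- simulate_cohort(cohort_design(seed = 42))          # 16 HC + 61 patients
tab <- assemble_analysis_table(sim$cohort, sim$measures)
fit_progression_model(tab, "rp_alpha2_cortical")[2:3, 1:5]
#>      term estimate conf.low conf.high  p.value
#>  visitFU1  -0.0186  -0.0247   -0.0124 2.77e-08
#>  visitFU2  -0.0368  -0.0471   -0.0265 6.81e-10
```

The planted per-visit alpha2 decline of −0.02 (so −0.02 at FU1, −0.04 at
FU2) is recovered within the 95% confidence intervals.

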