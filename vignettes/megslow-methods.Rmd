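---
title: "Methods: spectral slowing and envelope connectivity in longitudinal MEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral slowing and envelope connectivity in longitudinal MEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## What the package computes

`megslow` implements a source-space resting-state MEG analysis for
longitudinal cohorts, built around two neurophysiological progression
markers of Parkinson's disease:

* **spectral slowing** — a shift of oscillatory power toward lower
  frequencies (more delta/theta, less alpha2/beta relative power, and a
  lower dominant peak frequency), quantified per region and summarized over
  the 78 cortical and 12 subcortical regions of a 90-region AAL-style
  parcellation; and
* **amplitude-envelope functional connectivity** — the corrected amplitude
  envelope correlation (AEC-c) between every pair of regions, a 90 x 90
  adjacency per frequency band, reduced to one mean-connectivity value per
  region.

The statistical layer mirrors a longitudinal clinical study: baseline
three-group comparisons, a group-by-location interaction model, longitudinal
mixed models with visit dummies, connection-level permutation tests with FDR
correction, and mixed-model associations between spectral measures and
clinical scores (CAMCOG for cognition, UPDRS-III for motor impairment).

Because patient recordings of this kind are not publicly deposited, the
package ships a synthetic-cohort generator that reproduces the statistical
structure the analysis assumes. Every stage is therefore testable end to
end, and all empirical claims in this vignette are computed by the test
suite or the acceptance script — nothing is quoted from external data.

## Preprocessing model

The pipeline's entry point is a `roi_recording`: a 90 x samples matrix of
source-projected region time series with a sampling-rate header. Everything
upstream (beamforming, coregistration, artifact screening) is out of scope.

* **Downsampling** (`downsample()`): integer decimation preceded by a
  zero-phase anti-alias low-pass (raised-cosine roll-off between 0.9 and 1.0
  times the new Nyquist). The canonical use is bringing 1250 Hz recordings
  to the common 312.5 Hz analysis rate (factor 4). Factors that would push
  the rate to 60 Hz or below are rejected, since the analysis range ends at
  30 Hz.
* **Epoching** (`epoch()`): consecutive non-overlapping windows of 4096
  samples (13.11 s at 312.5 Hz). Where an observer would select artifact-free
  epochs by eye, the generator's data carry no artifacts, so the first
  `n_epochs` (default 10) windows are used; visual selection is deliberately
  not modelled because it is irreproducible.
* **Band filtering** (`bandpass()`): the five canonical bands — delta
  0.5–4, theta 4–8, alpha1 8–10, alpha2 10–13, beta 13–30 Hz; the gamma band
  is excluded and the analysis range ends at 30 Hz. Filtering is a
  frequency-domain amplitude mask applied per epoch: exactly zero phase,
  with raised-cosine transitions whose −6 dB points sit on the band edges
  and whose width is half the band's lower edge, capped at 2 Hz. We chose
  spectral masking over a forward-backward FIR because the delta band's
  0.25 Hz transition at 312.5 Hz would demand a filter longer than the
  4096-sample epoch itself; masking keeps the envelope timing that AEC
  depends on and imposes no group delay. The mask is exactly zero outside
  its transitions, so band leakage between non-adjacent bands is nil by
  construction.

Band edges are used with two conventions, on purpose: the *filter* treats
`low`/`high` as −6 dB points; *spectral bin assignment* treats bands as
half-open intervals `[low, high)` so that the five bands tile 0.5–30 Hz and
relative powers sum to exactly 1.

## Spectral measures

`epoch_spectra()` estimates one power spectrum per region: a single
Hann-tapered periodogram per 4096-sample epoch (no Welch sub-windowing, so
the grid spacing stays at `fs / 4096` = 0.076 Hz), averaged over epochs and
restricted to 0.5–30 Hz. The Hann taper controls sidelobe leakage at the
cost of spreading a pure tone over about three bins; tests therefore assert
tone concentration within ±2 bins rather than in a single bin.

* `normalize_spectrum()` divides each region's spectrum by its 0.5–30 Hz
  area (unit-area spectra depend only on spectral shape).
* `relative_band_power()` computes band power relative to total 0.5–30 Hz
  power; identical for raw and unit-area input.
* `peak_frequency()` returns the frequency of the maximum-power bin within
  the closed 4–13 Hz range, at the native 0.076 Hz resolution. Ties break
  toward the lower frequency — a deterministic convention that matters only
  on measure-zero inputs (a flat spectrum returns the lowest in-range grid
  point). The argmax is identical for raw and normalized spectra, so the
  choice of input does not affect per-region peaks; both reductions
  (per-subject peaks, group-mean spectra) are exposed.
* `summarize_regions()` takes unweighted means over the cortical (1–78) and
  subcortical (79–90) index sets, after epoch averaging.

## Connectivity: AEC-c

Instantaneous field spread mixes one source into many region signals and
inflates zero-lag amplitude correlations. The AEC-c removes this by pairwise
symmetric orthogonalization: per epoch, each band-filtered signal is
regressed on the other (zero lag, demeaned, no intercept) and the residual
is used in place of the leaked signal. Envelopes are magnitudes of the
analytic signal of the whole epoch; 5% of samples at each end are discarded
before correlating, to suppress transform edge effects. The two directed
envelope correlations are averaged and rescaled as `(r + 1) / 2`, giving a
value in [0, 1] with **0.5 = no coupling**. Averaging the two directions
before or after the affine rescale is equivalent (the map is linear); the
package averages first, then rescales, then averages over epochs.

We interpret "symmetric orthogonalization" as the pairwise two-direction
procedure, not the multivariate joint-whitening variant: the adjacency is a
pairwise object and the pairwise form is the one the AEC-c lineage computes.

The test suite pins this definition three ways: a brute-force reference
implementation (independent code path: `lm()` residuals, half-spectrum
analytic signal) agrees with `aec_matrix()` to 1e-10; independent
white-noise pairs average to 0.5 (within [0.48, 0.52] over 200 pairs of
10 x 4096-sample epochs); and instantaneous mixing `y = a*x + noise` up to
`a = 0.8` does not inflate AEC-c above the uncoupled baseline.

## Synthetic data: what it emulates, and what it does not

`simulate_roi_signal()` spectrally shapes white Gaussian noise: a `1/f^k`
background plus a Gaussian oscillatory bump at the (alpha-range) peak
frequency, optionally reshaped by per-band multiplicative tilts.
`band_tilts_for_targets()` inverts the tilts so the expected relative band
powers hit given targets exactly — this is how cohort ground truth stays
exact under drifting band powers. One caveat is documented and tested
coarsely: piecewise-constant band tilts introduce steps at band edges, which
can displace the within-4–13 Hz argmax when the bump sits near an edge; the
planted *slowing* remains visible in estimated peaks, but peak ground truth
is recovered with ~1 Hz accuracy in signals mode, while band-power ground
truth is recovered tightly.

`plant_envelope_coupling()` multiplies two independent band-limited carriers
by slow (< 1 Hz) log-normal amplitude modulators sharing a common component.
The mixing weight for a requested coupling strength is found numerically —
a seeded lookup of measured leakage-free envelope correlation against
mixing weight, cached per band and sampling rate — because the
envelope-correlation of modulated carriers has no convenient closed form.
Coupling is band-local (out-of-band content is untouched) and leaves phase
metrics unconstrained, matching what an amplitude-based measure sees.

`simulate_cohort()` reproduces the study structure: 16 controls (first
visit only), 17 de novo and 44 treated patients over BL/FU1/FU2;
monotone missing-at-random dropout at 0.25 per transition (chosen to mirror
a decline of roughly 61 to 39 to 35 patients); patient baseline offsets
(+0.03 theta, −0.03 alpha2 relative power; −0.5 Hz peak) and per-visit
progression (−0.5 Hz peak; +0.0125 delta, +0.0125 theta, −0.02 alpha2,
−0.005 beta per visit, summing to zero so powers stay normalized). Clinical
scores are noisy linear functions of the true spectral state — CAMCOG =
60 + 4 × peak frequency, UPDRS-III = 38 − 2.8 × peak frequency, with
subject-level random intercepts — so at a 9.5 Hz baseline peak the scores
sit near the plausible 96–98 (CAMCOG) and 11–14 (UPDRS-III) ranges, and
slowing drags cognition down and motor scores up. LEDD starts near 500 mg
for treated patients (0 for drug-naive de novo patients at baseline) and
rises 350 mg per visit.

Two generator modes keep the statistical simulations honest *and*
computable:

* `mode = "signals"` builds full 90-region recordings from the signal model
  (used to validate the signal-to-measure path);
* `mode = "measures"` (default) emits the derived measure columns directly
  as ground truth plus estimation noise — 0.1 Hz SD for peak frequency
  (about one spectral grid step, the argmax estimator's resolution-limited
  error on epoch-averaged spectra) and 0.01 for relative band powers and
  AEC-c summaries (the scale of 10-epoch averaging error). Statistical
  recovery studies over 100 cohorts run in seconds this way; simulating a
  hundred full-signal cohorts (tens of billions of samples) would add
  nothing to the statistical layer being tested.

Similarly, `simulate_connectivity_cohort()` generates subject-level AEC-c
matrices parametrically for permutation-test calibration: edge values are
0.5 plus subject offsets (SD 0.01) and edge noise (SD 0.021 — the SD
measured from this package's own signal-level null, i.e. AEC-c of
independent white-noise pairs averaged over 10 epochs of 4096 samples).
Planted effects are anchored to the signal pipeline at run time through
`measure_coupling_aecc()`, which maps a generator coupling strength to the
AEC-c the pipeline actually measures.

What the generator does **not** emulate: inter-regional leakage (the
orthogonalization is instead exercised directly by mixing tests), sensor
noise and artifacts, spatially structured connectivity, non-Gaussian score
distributions, and informative dropout. Passing tests therefore demonstrate
correctness of the estimators and calibration of the statistics under the
stated model, not robustness to everything real data can do.

## Statistical layer

* **Mixed models** are fitted with `lme4`/`lmerTest`: REML, a subject
  random intercept only, Satterthwaite degrees of freedom for p-values, and
  t-based Wald 95% confidence intervals. Singular fits (boundary
  random-intercept variance) are reported with a warning and flagged in the
  result metadata, never silently accepted. Covariates that are constant in
  the data at hand are dropped and recorded. The baseline three-group model
  has one row per subject, where the random intercept is unidentifiable and
  the mixed model reduces exactly to OLS — so it is fitted with `lm()`; a
  test verifies the reduction on data with zero between-subject variance.
* **Multiplicity**: Bonferroni 0.05/6 is applied where the study design
  applies it (baseline comparisons and longitudinal change; six comparisons
  per band family), clinical associations use 0.05, and the
  connection-level analysis uses Benjamini–Hochberg FDR across the 4005
  unique connections.
* **Permutation tests** (`permutation_connection_test()`): the statistic is
  the per-connection difference of group means — the simplest exchangeable
  statistic for a two-group comparison; the null is built by label exchange
  (unpaired) or within-subject condition swaps (paired, used for
  between-visit comparisons restricted to subjects observed at both
  visits), two-sided with the `(b + 1)/(N + 1)` correction. One design
  choice deserves emphasis: per-connection permutation p-values are bounded
  below by `1/(N + 1)`, so with thousands of connections a BH threshold of
  order `0.05/4005` is unattainable at any practical `N` (even 50,000
  permutations give a minimum q of about 0.08). Since connections are
  exchangeable under the null, the package pools the permutation null
  across connections by default, refining the granularity to
  `1/(N * 4005 + 1)`; `null_pooling = FALSE` selects the literal
  per-connection variant. Calibration (mean proportion of q ≤ 0.05 flags at
  most 0.05 under the global null) and power (a single edge planted at
  coupling strength 0.6 detected in ≥ 90% of runs at N = 2000) are both
  exercised in the acceptance suite.

## Problem sizes and numerical conventions

The test and acceptance suites run at deliberately chosen sizes: 200 pairs
for null calibration, 100 realizations per mixing level for leakage
robustness, 100 synthetic cohorts (about 60 patients each) for
parameter-recovery coverage, 100 repetitions of 20-vs-20 permutation tests
at N = 2000 (a calibration-preserving scale-down of the production
N = 50,000 default), and 3 regions x 2 epochs x 512 samples for exact
oracle equivalence. Degenerate inputs have defined behaviour throughout:
constant series cannot be orthogonalized (error), degenerate envelopes
yield NA entries with a warning and are excluded from epoch averages with
counts reported, zero-power spectra cannot be normalized, ties at the
spectral argmax resolve to the lower frequency, and double band-filtering
is rejected.

There is no shell entry point: the package's functions are the interface,
composed in scripts such as `scripts/acceptance.R`; a wrapper binary would
add nothing to reproducibility here.

## Known limitations

* The region labels and ordering of the packaged atlas are a standard
  AAL-style convention (cortical 1–78, subcortical 79–90), not a
  reproduction of any specific study's supplementary table; downstream
  mathematics depends only on the count and the partition.
* The generator's distributional choices are artifact conventions tested
  for self-consistency; coverage statements are about the generator's
  model class.
* Peak-frequency ground truth in signals mode interacts with band tilting
  near band edges (see above).
* Group-level spectra are unweighted means over subjects; no parametric
  separation of the 1/f background from the oscillatory bump is attempted.
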