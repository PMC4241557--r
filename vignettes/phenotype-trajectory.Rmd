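---
title: "Measuring and tracking the electrical phenotype of developing dopaminergic neurons"
author: "ephystraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and tracking the electrical phenotype of developing dopaminergic neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ephystraj)
```

## The problem and the model

Substantia nigra pars compacta (SNc) dopaminergic neurons acquire their
mature electrical behaviour — regular intrinsic pacemaking — over the first
postnatal weeks, passing through bursting and irregular firing on the way.
`ephystraj` implements the full analysis chain for quantifying that
maturation from whole-cell current-clamp recordings:

1. **Feature extraction.** Sixteen parameters per neuron: mean interspike
   interval (ISI~avg~, s) and its coefficient of variation (CV~ISI~, %,
   sample SD/mean) from at least 40 s of spontaneous firing; six action
   potential (AP) waveform metrics from the spike-triggered average
   (threshold, amplitude, half-width, 10–90% rise and decay slopes, AHP
   amplitude); passive properties R~in~, C~m~ and
   $\tau_m = R_{in} C_m$ from a mono-exponential fit of small
   hyperpolarizing pulses; sag amplitude and post-inhibitory rebound delay
   from a large hyperpolarizing pulse ending near −85 mV; and frequency–
   current gains at the start (GS) and end (GE) of 1 s depolarizing pulses,
   with the spike-frequency-adaptation index SFA = GS/GE.
2. **Pattern classification.** CV~ISI~ < 20% = regular, 20–80% = irregular,
   > 80% = bursting; boundary values go to the middle class.
3. **Stage statistics.** For every parameter, a one-way ANOVA across the 15
   postnatal stage bins with Tukey HSD (Tukey–Kramer for unbalanced
   groups), coded into four significance levels and stacked into the
   105-cell stage-pair table.
4. **Multivariate trajectory.** The 8 spontaneous-activity parameters are
   divided by the absolute value of their population mean, clustered with
   Ward agglomeration, and decomposed by PCA on the population (divisor-n)
   covariance matrix. Per-stage means of the factor loadings (F1, F2) trace
   the developmental trajectory; per-stage SDs define variability ellipses
   with area $A = \pi \cdot \mathrm{SD}(PC1) \cdot \mathrm{SD}(PC2)$.
5. **Perturbation emulation.** Apamin (fractional AHP block), low-dose TTX
   (scaling of AP amplitude and slopes) and dynamic-clamp leak injection
   ($g = 1/R_{target} - 1/R_{in}$, reversal −65 mV) are emulated at the
   generator-parameter level and quantified as supplementary-projection
   shifts in the reference PCA space.

Because no recordings are deposited with the source study, the package
ships a **synthetic cohort generator** calibrated to the published
stage-wise means and SDs of all 16 parameters
(`inst/extdata/table1_calibration.csv`). Every analysis stage is validated
end-to-end against the generator's ground truth.

## What the generator emulates — and what it does not

Each neuron is drawn per stage from truncated normal distributions whose
*truncated* mean and SD are moment-matched to the calibration (so clipped
tails never bias the realized stage means). Spontaneous firing is a
gamma-renewal process for regular/irregular regimes (CV = $1/\sqrt{k}$
gives closed-form CV control) and an alternating burst/pause renewal
process for bursters; the burst solver picks spikes-per-burst, pause mean
and pause jitter so the composite ISI distribution matches the target mean
and CV, drawing pauses from a shifted gamma so that the moments are exact
even for very skewed pause distributions. APs are analytic, piecewise
smooth templates: a quadratic depolarizing foot makes the
5%-of-peak-dV/dt criterion land exactly at the nominal threshold, the
10–90% bands are built so their chord slope equals the nominal rise/decay
slope, and the caps absorb the slack so half-width is a free
parameter (when the requested half-width is shorter than the symmetric
solution allows, the band above 30% of amplitude is steepened and the
sub-band slope recomputed so the 10–90% chord is untouched). Two
feasibility rules guard the construction: the template keeps dV/dt
continuous at every measured level (a slope corner at the 50% or 90%
crossing would bias its interpolated time), and limb combinations so
concave that the sub-band slope would fall below the 5%-of-peak dV/dt
level are rejected — the cohort sampler simply redraws such joint
parameter draws. Passive
responses are ideal RC exponentials; the sag is phenomenological (descent
to a trough, exponential relaxation to −85 mV) because only its amplitude
and the rebound delay are measured downstream.

Deliberate simplifications, and what they mean for the tests: parameters
are sampled **independently** within a stage (the calibration provides only
marginal statistics), there is no conductance-based dynamics, no synaptic
input, and noise is white Gaussian (0.3 mV default) rather than
recording-system noise. Passing round-trip tests therefore demonstrates
that the *measurement* chain is unbiased and that the *statistical* and
*multivariate* layers behave as specified — not that real recordings would
produce identical numbers. One consequence is documented honestly below:
without within-stage parameter covariance the irregular/regular boundary
is softer than in real data, and the automatic dendrogram cut typically
finds two classes (bursting vs the rest) rather than the three reported on
the real cohort; the three-class solution (`k = 3`) remains regime-aligned
and age-ordered.

## Parameters that matter

| parameter | default | why |
|---|---|---|
| sampling step | 0.05 ms (20 kHz) | AP slope metrics need the finer of the two acquisition rates |
| spike detector | dV/dt > 10 mV/ms, confirm V > −20 mV, 2 ms refractory, 0.25 ms smoothed derivative | robust on slow dopaminergic APs; smoothing keeps 0.3 mV noise (slope SD ≈ 8.5 mV/ms at 20 kHz) far below threshold |
| ISI window | ≥ 40 s of spontaneous firing | inclusion rule of the analysis; shorter spans raise an error |
| AP averaging window | 10 ms before / 60 ms after the peak | covers foot and AHP trough of the slowest APs |
| CV definition | sample (n−1) SD | small-n recordings |
| gain pulses | 1 s, ≥ 3 retained pulses, ≥ 6 spikes each | 4 spikes are the formal minimum, but only ≥ 6 make the first-three/last-three AP windows disjoint, which protects GE on slow, strongly adapting trains |
| saturation rule | spike count below the previous pulse, or terminal silent gap > max(200 ms, 2 × largest ISI) | a fixed 200 ms rule alone would misclassify every train slower than 5 Hz |
| normalization | divide by \|population mean\| | one convention for the cluster heat map and the PCA; exposed as `none`/`mean`/`zscore` |
| covariance divisor | n (population) | eigenvector directions are divisor-independent; exposed as a switch |
| automatic cut | largest gap between consecutive merge ΔSSE among the top min(n−1, 10) merges | simple and reproducible; `k` override available since no canonical rule exists |
| AHP→CV coupling κ | 4 | a 75% AHP block converts a regular-range CV into a bursting-range CV; an explicit artifact of the emulation, not a measured constant |
| TTX sodium scale | 0.8 | placeholder magnitude for 20 nM TTX; configurable |

## Numerical choices

Level crossings (half-height, 10/90% band edges, the 5% dV/dt threshold
crossing) are linearly interpolated between samples, which makes the
extracted metrics essentially exact on noiseless templates and halves
discretization error when the sampling step halves. Mean band slopes are
computed as the chord between the interpolated 10% and 90% crossings — the
time average of dV/dt over the band — rather than averaging per-sample
derivatives, which removes boundary-sample bias. The passive fit uses
`nls` with a `scaleOffset` control so zero-noise (perfect-fit) traces
converge cleanly; C~m~ is always reported as $\tau_m/R_{in}$, never fitted
independently. Ward clustering runs on squared Euclidean distances through
the Lance–Williams recurrence; merge heights are reported as the increase
in within-cluster sum of squares, verified against exhaustive-search
agglomeration for n ≤ 6. Eigenvectors are signed so the largest-magnitude
loading is positive; central-object ties break to the lowest neuron id;
degenerate cases (identical groups in the ANOVA, flat dendrograms,
rank-deficient PCA) return defined results with warnings instead of
failing.

Driven (frequency–current) trains are rendered with a compact variant of
the neuron's AP template (2 ms AHP recovery): during sustained
depolarization the membrane never returns to the spontaneous inter-spike
baseline, and the compact support also sets an intrinsic maximum firing
rate which the generator uses as its depolarization-block emulation. The
generator picks each neuron's current range so that at least three pulses
fall in the linear (non-blocked) regime.

## Problem sizes used by the validation suite

The validation functions (and `scripts/acceptance.R`) use: 50 noiseless
neurons per firing regime with 500 s spontaneous traces at 20 kHz for the
round-trip contract; 100 seeded null cohorts (15 stages × 20) for the
type-I calibration of the stacking table; 100 random n ≤ 6 matrices for
the Ward oracle; one full-size calibrated cohort (271 neurons, the
calibration's CV~ISI~ group sizes, 120 s traces) for the structural
checks; and ten half-size cohorts for the variability-narrowing
replication. The 271-neuron default mirrors the calibration's printed
group sizes; the source cohort's exact per-stage composition is not
recoverable from published information.

## A short example

```{r example, eval = FALSE}
plan <- default_stage_plan(scale = 1/3)
sim <- simulate_feature_cohort(plan, seed = 1, duration_s = 120,
                               protocols = "spontaneous")
snm <- spontaneous_matrix(sim$features)
pm <- pca_covariance(snm)
traj <- stage_trajectory(pm)
sd_age_correlation(traj)     # variability narrows with age: r < 0
```

## Known limitations

* No within-stage parameter covariance (marginals only): cluster
  separations between the irregular and regular phases are weaker than on
  real data (see above).
* HDF5 trace input is not available in this build; traces are delimited
  text.
* The pharmacology emulation acts on generator parameters, not on membrane
  mechanisms; dose–response behaviour is out of scope.
* Firing above the compact template's rate ceiling is treated as
  depolarization block rather than rendered as overlapping APs.
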