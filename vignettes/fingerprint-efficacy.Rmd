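---
title: "Fingerprint-efficacy modeling with chromeff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fingerprint-efficacy modeling with chromeff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromeff)
```

## The problem

Herbal-medicine quality control often rests on two kinds of evidence: a
chromatographic *fingerprint* (the full HPLC intensity-versus-retention-time
profile of an extract) and a panel of *bioactivities* (radical-scavenging
EC50s, FRAP, cellular antioxidant activity, enzyme-inhibition rates).
Spectrum-effect — or fingerprint-efficacy — modeling connects the two: which
of the peaks shared by all samples of a botanical material actually carry
its activity?  chromeff implements that workflow end to end for cohorts such
as wild versus cultivated *Chrysanthemum* flowers: fingerprint processing,
assay statistics, a linear latent-variable model (PLSR with VIP screening),
a nonlinear confirmation model (a back-propagation network trained by
Levenberg-Marquardt, read out through Garson contribution ratios), and a
consensus marker selection.  A separate branch covers the untargeted
cell-metabolomics stage: feature-table preprocessing, OPLS-DA with
permutation testing, volcano statistics and hierarchical clustering.

Because raw data of this kind are rarely released, the package ships seeded
generators for every input, each returning its ground truth.  All tests and
the acceptance suite run against those generators.

## Fingerprint stage

Peaks are symmetric Gaussians for the generator and local maxima above a
height and a topographic-prominence threshold for the detector; bounds sit
at flanking minima and areas are trapezoidal.  Matching across samples is a
greedy, height-ordered agglomeration on retention time with a running-mean
consensus (deterministic; tolerance default 0.2 min against a per-sample
retention jitter of 0.05 min).  The reference trace is the pointwise median
chromatogram ("simulative median"), and the similarity index is the cosine
(congruence) coefficient on the shared grid — invariant to positive scaling;
a correlation mode is available.  Which of the two the original similarity
software used is not documented, so cosine is the default and the choice is
exposed.  No similarity acceptance threshold is enforced; the index is
reported only.  *Common peaks* are the matched columns observed in every
sample; missing peaks are `NA`, never zero.

## Assay statistics

Closed forms: scavenging `100(1 - B/A)`, inhibition `[1 - (As - An)/Ac]·100`
(one implementation for glucosidase and lipase), CAA unit
`1 - ∫SA/∫CA` with trapezoids on the recorded 5-minute grid, and calibration
inversion `(y - b)/a`.  Values outside [0, 100]% are reported as computed
with a warning — the formulas permit them, and silent clamping would hide
assay problems.  EC50 comes from a four-parameter logistic fit by nonlinear
least squares with the EC50 on the log scale, started from the
linear-interpolation crossing of the half-maximal response; non-convergence
is flagged on the result, not thrown, and an interpolation-only mode exists.
A note on precision: with 8 single wells and all four parameters free, the
median EC50 error under 2% response noise is ~8-10% — the asymptote
uncertainty leaks into the EC50.  With triplicate wells (standard plate
practice, and what the acceptance suite simulates) it drops below 4%.

The activity matrix builder harmonises orientation before modeling: for
endpoints where lower is better (EC50s) the default is the reciprocal
(`1/EC50`), negation is available, and the declared orientation is stored on
the matrix.  How the original analyses jointly modeled lower-better and
higher-better endpoints is not stated anywhere we know of; the reciprocal
keeps all columns "larger = more active" on a ratio scale.

## The chemometric core

PLSR is NIPALS with X- and Y-deflation, unit-variance scaling by default
(the de-facto standard of the commercial software used in this field),
per-component and cumulative R²X/R²Y, and a sign convention (first element
of each weight vector non-negative) that makes results reproducible to the
bit.  For a single response NIPALS converges in one pass per component and
the full-component coefficients equal ordinary least squares — this is one
of the acceptance properties.  If the power iteration stalls on
near-degenerate late components the component is flagged and a warning
raised rather than failing: the extracted subspace is still usable, and a
hard error would break cross-validation on small folds.

VIP is `sqrt(p · Σ_a SSY_a (w_aj/‖w_a‖)² / Σ_a SSY_a)`; the mean squared
VIP is 1 by construction, so VIP > 1 means "more than an average share of
the explained response variance".  Q² is sevenfold cross-validation with a
seeded, deterministic fold assignment, training-fold re-scaling, and
`Q² = 1 - PRESS/SS`; the pipeline picks the smallest component count
attaining the maximal Q².

OPLS-DA codes two classes as centred ±1, removes class-orthogonal
variation, and reports S-plot covariance/correlation pairs and a
single-component VIP.  The permutation test refits the model under seeded
relabelings and uses the add-one estimator
`p = (1 + #[permuted ≥ observed])/(1 + n)`, so 200 permutations bound p
below by 1/201; under label exchange the rejection rate at α = 0.05 is
calibrated (an acceptance property).  Volcano statistics are Welch t-tests
with group-2/group-1 fold changes, Benjamini-Hochberg adjustment (raw p is
used for the selection flag, mirroring common practice; adjusted p is
reported), and the VIP gate.  The internal OPLS-DA for volcano uses
unit-variance scaling: on raw (unlogged) intensity tables pareto scaling
lets high-abundance features swamp the VIP spectrum.

## The neural model

A single hidden layer (tanh; identity available for linear sanity checks),
linear output, inputs and targets standardised on the training split.  The
weight update is the damped Gauss-Newton step
`x_{k+1} = x_k - (JᵀJ + μI)⁻¹ Jᵀe` with the classical μ schedule (start
1e-3, ÷10 on an accepted step, ×10 on a rejected one), a seeded random
70/15/15 train/validation/test split, early stopping on validation MSE, and
best-validation weights returned.  The analytic Jacobian is verified
against central differences; accepted-step training MSE is non-increasing
by construction.  Reported MSEs are on the standardised scale.

Contribution ratios use Garson's weight-partition algorithm (absolute
input-hidden shares per hidden neuron, weighted by absolute hidden-output
weights, normalised to 100%); the signed connection-weight (Olden) method is
available.  On 16-sample cohorts a single trained network's Garson ranking
is unstable, so the pipeline trains a small ensemble (default 5 seeded
restarts) and averages the ratios — a standard stabilisation for
contribution analyses.  The hidden-layer default is ⌈(inputs+outputs)/2⌉.

## Marker consensus

A peak is a marker when its VIP exceeds 1.0 *and* its contribution ratio
ranks in the top `top_k`.  The delicate part is `top_k`.  Taking it equal to
the VIP-passing count sounds natural but fails in small cohorts: with 16
samples, one or two non-causal peaks exceed VIP 1 by sampling accident in
about half of simulated cohorts, and because the network sees the same
sample, the same peaks also rank high in contribution — the intersection
cannot remove them.  The default is therefore a spectrum cut: sort the
combined evidence (VIP × contribution), and cut at the largest logarithmic
gap within the VIP-passing peaks.  True markers form a high plateau well
separated from the chance tail, so the cut lands at the plateau edge; an
explicit `top_k` overrides it.

## Metabolomics preprocessing

The chain is fixed: (1) remove features whose zero-fraction *exceeds* 50%
(strict: exactly half is kept) — by default only when that holds in *every*
group, so a feature well measured in one group survives; the "any group"
reading of the ambiguous rule is a flag.  (2) Replace remaining zeros by
half the feature's minimum positive value.  (3) Keep features with an
identification score ≥ 36 on the 0-60 vendor scale (the score is consumed,
never computed).  Every rule logs in/removed/retained counts, and the
counts are conserved.

## What the generators emulate — and what they do not

`simulate_cohort` builds two classes with many-peak/low-abundance versus
fewer-peak/high-abundance structure, a shared common-peak set with
class-dependent log-normal areas (log-normality is an assumption, not a
documented fact), per-sample retention jitter, and Gaussian detector noise
over a linear baseline.  Causal weights default to 1/sd(area) per causal
peak so every causal peak contributes a comparable share of response
variance; with constant weights the most abundant causal peak dominates and
the others are unrecoverable at any assay precision.
`simulate_bioactivity` produces a panel with one total-capacity endpoint
(exactly the weighted sum of causal areas — the generator contract used by
the tests) plus two assays dominated by each causal compound, with
log-normal assay-to-assay multipliers and noise expressed as a fraction of
each endpoint's signal standard deviation (default 5%; the benchmark
cohorts use 2%).  This reflects a panel whose assays respond to different
constituents; it is the structure under which marker recovery at n = 16 is
statistically possible at all — with a dense equal-weight panel every causal
peak's correlation with the response is capped at 1/√3, which chance
correlations at n = 16 regularly beat.

Not emulated: peak tailing/fronting, co-elution beyond what random retention
times produce, inter-peak biological correlation, raw LC-MS spectra,
batch/drift effects.  A green recovery test therefore establishes that the
pipeline is correct and well calibrated on resolvable, independent peaks —
not that 16 real samples always identify three markers.

## Numerical choices and limitations

Seeds: every generator and every stochastic step (CV folds, splits,
permutations, restarts) takes an explicit seed and restores the caller's
RNG state.  Ties: peak matching is height-ordered; contribution ties break
by peak order; hierarchical clustering (Ward on Euclidean distances via the
standard agglomeration) merges lowest indices first.  Degenerate inputs:
constant columns error under unit-variance scaling (named), are skipped
with NA importance in `volcano`, and all-zero features must be filtered
before imputation.  The pipeline models the simulated peak-area truth table
(restricted to common peaks); the detection/matching/similarity stage runs
on the chromatograms and is reported alongside, so detector settings do not
silently change the model input.  Known limitations: two classes only in
OPLS-DA; no sparse/kernel PLS; no plate-layout handling; no KEGG/pathway
stage.
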