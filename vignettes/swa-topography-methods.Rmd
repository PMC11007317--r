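---
title: "Slow-wave activity topography and behavior: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slow-wave activity topography and behavior: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swatopo)
```

## The scientific problem

Slow-wave activity (SWA) — EEG spectral power in the low delta range,
0.8–4.6 Hz, during NREM sleep — is the standard physiological marker of
sleep depth. Its topographic distribution over the scalp is highly stable
within a person and differs between people, which makes the *relative* SWA
map (each electrode divided by the mean over all electrodes) a candidate
neural trait. `swatopo` implements the full chain needed to relate such
maps to a per-subject behavioral score — here, prosocial preference measured
as the contribution-minus-belief score of a one-shot public goods game — and
to correct the resulting electrode-wise correlation map for multiple
comparisons with a suprathreshold cluster permutation test.

The pipeline is:

1. band-pass filter the overnight recording (0.5–40 Hz), re-reference to the
   average of the good channels;
2. cut the signal into 30-s epochs aligned to a visually scored hypnogram;
3. per-epoch spectra (5-s Hanning subepochs, no overlap), SWA and 20–40 Hz
   band power, moving-average artifact screening;
4. average SWA over artifact-free N2/N3 epochs, interpolate bad channels on
   the map, normalize to the electrode mean, log-transform;
5. correlate each electrode with the score, form suprathreshold clusters
   among neighbours, and compare observed cluster sizes against a
   permutation distribution of maximal cluster sizes;
6. describe significant clusters via cluster-mean correlations, partial
   correlations against sleep/demographic covariates, and per-sleep-cycle
   analyses.

A reference-free current source density (CSD) variant replaces step 1's
potentials with a spherical-spline surface Laplacian and feeds the same
spectral path.

## Spectral estimation choices

Each 30-s epoch is split into six 5-s subepochs, giving 0.2 Hz bins so that
the SWA band edges 0.8 and 4.6 Hz are bin centres (band power sums bins with
`low <= f <= high`, inclusive). Subepochs are demeaned, Hanning-windowed
(periodic window) and scaled by the window power `sum(w^2)`, which makes two
identities exact: a sinusoid of amplitude $A$ at a bin centre contributes
total power $A^2/2$, and the bin sum equals the (window-corrected) time
domain mean square — Parseval. The 0 Hz bin carries the squared subepoch
mean plus the residual windowed DC power; band powers for any band starting
above 0 Hz are therefore unaffected by the signal's offset. Band power is a
bin *sum*, not a density integral; the distinction cancels after
normalization to the electrode mean, which is the only scale the statistics
ever see. The log transform uses the natural base — Pearson correlations
downstream are invariant to that choice.

## Artifact screening

An epoch is discarded when its power, averaged over good channels, exceeds
`factor` times a centred moving average in either the SWA band
(`factor_swa = 2`) or the 20–40 Hz band (`factor_hf = 2.5`); the moving
average spans 15 epochs (edges shrunk) and is computed *within stage class*
(NREM vs REM/wake), so the large physiological power step at stage
transitions is not mistaken for an artifact. The thresholds and window are
configurable; a per-epoch report (power, threshold, flag) is written so a
human can review and override — the screening is semiautomatic by design.
Whether screening should aggregate over channels or run per channel is a
genuinely open choice; the aggregate was chosen because isolated
single-channel noise is better handled by the bad-channel mechanism, which
excludes a channel from the average reference and interpolates it at the map
level (values, not signals — maps are what the statistics consume).

## Filtering

The band-pass is a Hamming-windowed linear-phase FIR with group-delay
compensation, i.e. zero-phase: slow waves must not be phase-shifted, and a
zero-phase FIR has no passband phase distortion by construction. Transition
widths are 0.5 Hz at the low edge and 2 Hz at the high edge; the narrower
one sets the filter order (~3.3/Δf cycles). Edges are reflection-padded
during the FFT convolution.

## Surface Laplacian (CSD)

The CSD operator is the spherical-spline surface Laplacian: spline order
`m = 4`, Tikhonov regularization `lambda = 1e-5`, 50 Legendre terms, all
configurable. The implementation solves the bordered spline system once per
montage and applies a precomputed linear operator to every sample, so the
transform is exactly linear, invariant to adding a constant across channels
(reference-free) and zero for spatially constant fields. On a full-sphere
test montage the operator reproduces the analytic surface-harmonic
Laplacian (orders 1–4) to better than 2% with `lambda = 0`; on a scalp cap,
edge electrodes are extrapolated by the spline and carry larger error for
high spatial orders, a limitation shared by every cap-only Laplacian. The
default `lambda` trades a little harmonic accuracy for robustness to
measurement noise.

## Sleep parameters and cycles

Sleep parameters follow the standard definitions: total sleep time is the
count of non-wake in-bed epochs times 0.5 min; sleep efficiency is TST over
time in bed; wake after sleep onset counts wake epochs strictly between
sleep onset and the last sleep epoch (terminal wake is not WASO); stage
percentages are relative to TST. Cycles follow the Feinberg–Floyd lineage:
a cycle is a maximal NREM period with at least 15 min of N2/N3-containing
sleep followed by a REM period of at least 5 min, the REM minimum being
waived for the first cycle; a short REM run does not close a cycle and is
merged forward; trailing NREM without REM forms a final cycle. All four
durations are configurable since the operationalization varies across the
literature. Per-cycle maps renormalize SWA to the electrode mean *within*
the cycle, so the cycle-specific global SWA decline across the night cancels.

## The cluster permutation test

Electrode-wise Pearson correlations are thresholded two-sidedly at
`r_crit = t / sqrt(t^2 + n - 2)` with `t` the 0.975 t-quantile on `n - 2`
degrees of freedom. Suprathreshold neighbours (3-D electrode distance ≤
40 mm; 4–10 neighbours per electrode on the built-in 59-channel montage) of
equal sign form clusters. The null distribution of the maximal cluster size
— over both signs, making the correction family-wise over the whole map —
is built by permuting the score vector against the fixed SWA matrix (5000
random permutations by default, seeded; exhaustive enumeration whenever
`n! <= 40320`). Cluster p-values use the add-one estimator
`(1 + #{null >= size}) / (1 + P)`, which is valid under exchangeability and
never exactly zero.

With discrete cluster sizes, the raw 95th-percentile order statistic of the
null does not control the family-wise error under ties, so the critical
cluster size is realized as the smallest size whose add-one p-value is at
most 0.05 — the exact achievable 95th-percentile threshold. "Significant"
(`size >= critical`) and `p <= 0.05` therefore coincide. The test is
slightly conservative: the realized family-wise error sits at the largest
achievable level below 5%, typically 3–5% on 59-electrode maps, never above.

Partial correlations project both variables on an intercept plus the
covariates and correlate the residuals (`df = n - 2 - k`); gender enters as
a single binary indicator. Pooled-cycle analyses average the per-subject
cluster means over cycles 2–4 before correlating.

## The synthetic-data generator

No public recording is required to run or validate the pipeline; the
generator reproduces the statistical structure the analysis assumes, at two
tiers.

**Topography tier** (fast; feeds the statistics directly). Per subject, a
zero-mean Gaussian field on the montage with squared-exponential spatial
correlation, plus a subject-level latent factor loading only on the planted
six-electrode right temporoparietal cluster (C6, CP4, CP6, FT8, P4, P6).
Maps are exponentiated, renormalized to electrode-mean 1 and re-logged, so
every relative map has mean exactly 1 before the log by construction. The
behavioral score is `rho * standardized cluster mean + sqrt(1 - rho^2) *
noise`, computed from the *renormalized* maps so that `effect_rho` (default
0.49) refers to the exact quantity the analysis correlates. Two generator
constants were fixed from the reported statistical geometry of real
relative-SWA maps rather than guessed freely: the spatial length scale is
40 mm, which puts the permutation critical cluster size at 5–6 electrodes —
a six-electrode cluster must be declarable significant at the 95th
percentile, and stronger smoothing (70 mm) would push critical sizes to
8–10 and make that impossible; and the cluster factor loading is 2 field
standard deviations, which makes each planted electrode individually
suprathreshold in most samples (correlation of an electrode with the cluster
mean ≈ 0.92), matching the observation that whole clusters, not isolated
electrodes, carry such effects. `map_log_sd = 0.25` spans relative SWA of
roughly 50–180% of the electrode mean, the range real subject maps cover.

**Signal tier** (slow; exercises the full chain). Per channel, `1/f`
background noise plus a band-limited 0.8–2 Hz oscillation during N2/N3
whose amplitude is a stage factor (N3 80 µV > N2 40 µV at unit gain) times
a per-channel gain derived from the topography tier, so SWA *power* scales
with the square of the gain. A configurable fraction of epochs (2% by
default) receives a broadband high-power artifact for the screening to
find. Hypnograms are built cycle-wise (N1 entry, N2/N3 blocks with N3
declining and REM growing across the night, brief awakenings), with stage
fractions defaulting to N1 8%, N2 46%, N3 25%, REM 21% of sleep — typical
young-adult values.

What the generator does **not** emulate: spindles, K-complexes and other
phasic NREM events; real electrode-noise spatial structure; volume
conduction from focal cortical sources; non-Gaussian map tails. Passing
tests therefore demonstrate that the statistical machinery is correct and
calibrated under the assumed data-generating process, not that any
particular real-data effect exists.

Behavioral records round the latent score to integer points and realize it
as a contribution/belief pair inside [0, 20]; rounding and clipping
attenuate the realized correlation slightly, which the test suite measures
rather than corrects.

## Problem sizes and numerical conventions

Statistical validation runs at the study's scale — 54 subjects, 59
electrodes — with 2000 permutations per test and 1000 replicate datasets for
the family-wise error calibration, sizes at which the binomial Monte-Carlo
error (~0.7 percentage points) is small against the 5% target. Signal-chain
integration tests use reduced montages (12 channels), 100 Hz sampling and
~70-minute nights, which exercise every code path at a fraction of the
cost; the operator-level spectral and CSD checks are exact-identity tests
and do not depend on problem size. Epoch indices are 0-based with half-open
intervals throughout; all TSV/JSON writers emit 17 significant digits so a
written value re-reads bit-identically; every stochastic function takes an
explicit integer seed and is bit-reproducible given it.

## Known limitations

- EDF output quantizes to the 16-bit grid (0.01 µV resolution at typical
  amplitudes); write-then-read is idempotent but not the identity on
  arbitrary doubles.
- The cap-edge CSD bias discussed above.
- The cluster test's conservatism under heavy ties is inherent to discrete
  cluster sizes; a cluster-mass statistic would reduce the discreteness but
  is deliberately out of scope.
- Sleep staging itself is an input (one token per 30-s epoch); no scorer is
  provided.
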