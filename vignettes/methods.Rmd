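---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`pvscgn` chains six quantitative methods used to characterize subpopulations
of striatal PV-expressing interneurons — stereological counting, spatial
statistics on anatomical contours, spike-train features, spike–field phase
locking, oscillation-cycle–normalized firing times, and cluster-number
inference — plus synthetic-data generators that provide ground truth for all
of them. This vignette explains each model, its assumptions, the tunable
parameters with their defaults and units, the numerical choices, and the
places where the design was genuinely open and a decision had to be made.
It states no empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## Stereology

The optical disector is a 3-D counting probe: within a 420 × 320 µm frame, a
cell is counted when the top of its nucleus first comes into focus inside a
10 µm counting depth that starts below a 2 µm guard zone (which protects
against sectioning artifacts at the cut surface). The rule
`top ∈ (guard, guard + depth]` is half-open: a nucleus already in focus at
the top of the disector belongs to the neighbouring section and is excluded.
Counting is complete within the probe volume, so density is exact division,
`Nv = count / volume`; nuclei are represented only by their top-depth
coordinate, which is all the rule needs.

The Cavalieri estimator integrates systematic sections:
`V(ref) = a(p) · t · ΣP` with `a(p)` the area per grid point and `t` the
section spacing; unbiasedness requires a random grid offset and random
section phase, which the synthetic point-grid generator provides. Precision
is summarized by the Gundersen–Jensen coefficient of error. Commercial
stereology software implements several CE variants without documenting which
is in use; we compute the m = 1 (smooth section-area sequence) form with a
point-counting noise term of `ΣP`:
`CE = sqrt((3(A − ΣP) − 4B + C)/240 + ΣP) / ΣP` where `A = ΣP_i²`,
`B = ΣP_i P_{i+1}`, `C = ΣP_i P_{i+2}`. For a smooth solid this is dominated
by the `1/sqrt(ΣP)` noise floor, matching the rule of thumb that ~1000
points give CE ≈ 0.03.

Internal canonical units are µm and µm³; densities are reported per mm³
(conversion factor 10⁹ at the reporting boundary).

## Contour-normalized topography

The striatum's irregular outline makes raw coordinates incomparable across
coronal planes. Each neuron is therefore located relative to the borders its
own axis-aligned rays actually hit: a horizontal and a vertical line through
the neuron are intersected with the plane's contour polygon, the *first*
crossing on each side defines that neuron's medial/lateral (ventral/dorsal)
border, and the position within the chord maps linearly to [−1, 1] with 0
equidistant from both borders. Because the first crossings move with the
neuron, the definition of "medial border" adapts to position, which is the
point of the construction for non-convex outlines.

Design choices that the range-only definition leaves open:

* **Sign convention** — +1 is lateral and +1 is dorsal; the contour carries
  `lateral_dir`/`dorsal_dir` metadata so pre-reflected hemispheres pool
  naturally.
* **Boundary points** — a neuron exactly on the contour (a measure-zero
  event) is rejected rather than assigned ±1, avoiding a 0/0 in the chord
  mapping.
* **Geometry kernel** — crossings use a half-open vertex rule so a ray
  through a polygon vertex is counted once; simplicity of contours is
  checked with an O(m²) segment-intersection scan (contours are small).

Per-plane inference: Wilcoxon signed-rank against 0 for a one-population
bias, Mann-Whitney for two populations, both skipped with an explicit record
when a plane holds ≤ 5 neurons (positional means are too unstable below
that), and Benjamini–Hochberg FDR across the planes of one analysis. The
cross-plane variability statistic for plane *s* with mean *m_s* is
`d_s = mean_{s'≠s} |m_s − m_{s'}|` — the mean of absolute pairwise
differences. The sentence defining this statistic can also be read as
`|mean_{s'≠s}(m_s − m_{s'})|`; both readings agree that a consistent shared
bias scores low and a gradient scores high, the absolute-differences form is
the stricter (it cannot cancel opposing drifts), so it is the default and
the signed form ships behind `mode = "abs_mean"`.

## Spike-train features

Epochs must be ≥ 60 s for population analyses (shorter epochs are flagged at
construction). ISI histograms use 100 log-spaced bins from 1 ms to 10 s —
binning is not prescribed anywhere authoritative, so it is configurable;
log-spacing matches the decades-wide ISI range of striatal interneurons, and
out-of-range ISIs accumulate in the boundary bins so percent counts always
sum to 100. Firing-pattern homogeneity of a population is the distribution
of Spearman correlations between ISI histograms of within-population pairs.

`CV2_i = 2|ISI_{i+1} − ISI_i|/(ISI_{i+1} + ISI_i)` is the standard local
(rate-adaptation-proof) variability measure; for a Poisson train
`CV2 = 2|1 − 2U|` with `U` uniform, giving the closed forms the tests check:
`E[CV2] = 1`, `P(CV2 < 0.2) = 0.1`, `P(CV2 > 1.85) = 0.075`, so the
unsmoothed low/high ratio tends to 4/3. The reported CV2 *ratio* feature is
add-one smoothed (`(n_lo + 1)/(n_hi + 1)`) because perfectly regular trains
have an empty denominator and clustering needs finite features; the raw
ratio is reported alongside. ISI percentiles use linear interpolation
between order statistics (R quantile type 7), logged base 10.

Waveform D1/D2 segmentation measures baseline from the pre-trigger window
and takes departure/return thresholds of k = 3 baseline SDs with 3
consecutive in-band samples required for a sustained return (both
configurable); for a noiseless waveform the threshold degrades gracefully to
machine epsilon so exact triangular test pulses split exactly. A waveform
that never returns to baseline yields a flagged `NA` D2 rather than a
fabricated value, mirroring the exclusion of such cells from waveform-length
comparisons.

## Spike–field phase locking

The filterbank has 107 bands with geometrically spaced centers from 1 to
80 Hz. The literal reading of band edges "± 1.5× the center frequency" is
impossible (a negative lower edge), so edges are proportional,
`[c/1.5, 1.5c]`: widths then increase with frequency and adjacent bands
overlap, which is what the construction requires; the factor is
configurable. Filtering is Butterworth order 2 (inside the quoted 1–3
range) applied forward–backward, so it is neutral-phase with doubled
effective order. Phase comes from the FFT analytic signal under the cosine
convention (0° at oscillation peaks, 180° at troughs). Spike phases are read
at the nearest sample (≤ 30 µs error at the 16.6 kHz acquisition rate this
models); circular interpolation is available.

Both the IIR filter and the FFT Hilbert transform produce edge transients;
all filtering and analytic-signal steps therefore mirror-pad the record
(odd reflection, 2/low seconds) and crop afterwards. Without this, transient
cycles can masquerade as oscillation peaks at the record edges.

Locking per band is the vector length `R = |mean(exp(iθ))|` and the Rayleigh
test `Z = nR²` with the standard finite-n series correction; only neurons
with ≥ 40 spikes in the epoch are tested (below that the test is
underpowered and the profile is returned untested). Phase histograms use 20
bins.

Slow oscillations are not sinusoids: bands whose passband spans the
fundamental and part of its harmonic content inherit a non-uniform
instantaneous-phase distribution, so even spikes fired at random times look
phase-locked. For bands centered below 5 Hz, spike phases are therefore
remapped through the empirical CDF of the *signal's own* phase samples from
the same epoch and band, `θ' = 2πF(θ) − π` — a monotone transform that is
the identity when the signal's phases are already uniform. The alternative
(correcting with a surrogate spike-phase distribution) was considered and
rejected: the non-uniformity to remove is a property of the oscillation
waveform, not of the spiking. The acceptance suite measures both sides: on a
skewed 1 Hz wave the uncorrected Rayleigh false-positive rate is far above
nominal and the corrected rate is restored to ~5%.

Three gamma ranges are in use in different analyses (30–80 Hz for
figures/profiles, 27–45 Hz in the SWA state definition, 30–48 Hz as the
clustering feature); all three ship as named presets (`gamma_band()`).

## Peak-aligned firing times

The LFP is inverted so that peaks proxy the synchronized up states of nearby
projection neurons, then filtered at 0.4–1.6 Hz (zero-phase Butterworth
order 2). Cycles are delimited trough-to-trough as crossings of odd
multiples of π on the unwrapped Hilbert phase — a phase-interval definition,
deliberately not amplitude minima, so low-amplitude cycles segment
identically. Durations outside the filter's corner periods
(1/1.6 s = 0.625 s to 1/0.4 s = 2.5 s) cannot be genuine passband cycles and
are discarded; the gate is computed from the corners, not stored as
constants. Spikes inside a retained peak map to normalized time
`2(t − start)/duration − 1` over 100 equal right-closed bins (a spike
exactly at a trough belongs to the peak beginning there), making firing
times comparable across cycles of different durations. Group comparisons use
the per-neuron median normalized firing time (Kruskal-Wallis + Dunn), with a
control comparison of peak durations/amplitudes between groups so that
field-recording biases cannot masquerade as spike-timing differences.

## Cluster-number inference

Features are clustered with Ward's method on squared Euclidean distances
(`hclust(method = "ward.D")` on `dist()²`). For real mixed-unit features the
columns are z-scored first (otherwise firing rate, in spikes/s, dominates
log-ISI features numerically); raw-scale linkage is available behind the
`standardize` flag and is the right mode when all columns already share one
scale — the synthetic Gaussian-cluster validation runs in raw mode for
exactly that reason (z-scoring a matrix whose columns contain 5-SD-separated
clusters shrinks and distorts that separation, because between-cluster
variance inflates each column's SD).

The number of significant clusters follows Thorndike's idea: genuine cluster
structure shows up as a large difference (gap) between successive
within-cluster distances — here the Ward merge-height sequence, whose
increments are the within-cluster variance increase of each merge. The null
distribution of gaps comes from surrogate data sets in which every feature
column is independently permuted across rows (10000 surrogates in the full
analysis; ≥ 100 enforced), which destroys between-column structure while
preserving every marginal. The open question is how to compare observed
gaps with surrogate gaps. Comparing the k-th largest observed gap against
the null of the k-th largest surrogate gap looks natural but is
anticonservative *as a family*: under a column-exchangeable null the
probability that at least one of the ~n gap ranks exceeds its own 95th
percentile approaches certainty (measured at 0.82 for n = 60). The default
is therefore the max-gap null: every observed gap is compared against the
null distribution of the *largest* surrogate gap,
`p = (1 + #{max surrogate gap ≥ observed}) / (n_surrogates + 1)`, which
controls the family-wise error at α by the exchangeability of the real data
with its own surrogates (measured ~5%); the per-rank mode remains available
as `null_type = "rank"`. The gap with the smallest p-value below α (ties
broken toward the larger gap) sets the dendrogram threshold at the midpoint
of its two heights; if no gap is significant the result is zero significant
clusters — an explicit, allowed outcome, and the price of family-wise
control is some conservatism near the detection boundary.

Cluster composition is evaluated against molecular identities that are
withheld from clustering; purity is the fraction of rows matching their
cluster's majority identity.

Two feature-set presets exist for slow-wave-activity recordings (7
parameters including the CV of ISIs, and a 6-parameter variant without it —
both appear in the source material's two listings, so both ship, with the
7-parameter set as default) and one 6-parameter set for the activated brain
state.

## Synthetic data: what it emulates, and what it does not

Generators are deterministic under a fixed seed and carry their ground-truth
parameters in a `truth` attribute.

* **Contours** are superellipses (exponent 2.5, ~3000 × 2200 µm) with
  rostro-caudal size drift over 13 planes and an optional medial notch that
  makes the polygon non-convex, exercising the first-crossing logic.
* **Neuron placement** draws target normalized coordinates from Beta
  distributions affinely mapped to [−1, 1] (mean = the requested bias,
  concentration 4), then inverts the ray parametrization by coordinate-wise
  fixed-point iteration, so realized normalized positions equal their
  targets and the *realized* mean bias is the nominal one. Beta was chosen
  because its support matches the normalized scale exactly.
* **Field signals** sum a ~1 Hz slow wave, a spindle-band component
  amplitude-modulated by the slow phase, a gamma component, and 1/f noise;
  default fs is 1 kHz (desk-scale; 16.6 kHz matches the modeled acquisition
  rate). Slow-wave skew is produced by waveshaping the sinusoid through a
  monotone exponential nonlinearity — period preserved, up/down symmetry
  broken — which is what makes the band-filtered phase distribution
  non-uniform and motivates the ECDF correction.
* **Locked trains** are inhomogeneous Poisson processes with intensity
  ∝ exp(κ cos(θ(t) − µ)) (thinning algorithm), normalized to a target mean
  rate, so the expected recovered vector length is the Bessel ratio
  I₁(κ)/I₀(κ).
* **Peak-timed trains** place per-cycle Poisson numbers of spikes at
  truncated-Gaussian normalized times (µ*, σ*).
* **Feature clusters** sit on a randomly rotated regular simplex with unit
  within-cluster SD and exact mutual center distances; identity labels agree
  with the generating cluster at a controllable rate.

What passing on these generators does *not* show: real recordings have
non-stationary states, electrode drift, spike-sorting contamination,
correlated neurons, and anatomical contours with histological distortions —
none of which are emulated. The validation demonstrates correctness and
calibration of the estimators, not robustness to those artifacts.

## Problem sizes and numerical tolerances

The test suite and acceptance script run at desk scale, chosen so each
stochastic check has adequate resolution: signals at 250 Hz for 60–300 s;
vector-length recovery at n ≥ 2000 spikes (tolerance ±0.05 around the
Bessel ratio); Rayleigh size at n = 40 over 1000 replicates; the ECDF
correction over 500 replicates; cluster recovery over 20 seeds with 1000
surrogates each (10000 surrogates is the full-analysis default, which only
sharpens the p-value floor); stereological recovery over 100 seeded slabs
(unbiasedness judged within 2 standard errors) and a grid fine enough for
the Cavalieri estimate to sit within 5% of the analytic ellipsoid volume;
and CV2 closed forms at 5000 ISIs averaged over 10 trains. Exact arithmetic
(duration gate, filterbank construction, total numbers, disector rule) is
asserted exactly; floating-point-degenerate cases (a periodic train on a
non-dyadic grid) are asserted at 1e-9.

## Known limitations

* The ECDF correction assumes the spike epoch and the phase-distribution
  epoch coincide; applying it across epochs with different waveform shape
  would mis-correct.
* Peak segmentation trusts the Hilbert phase of the slow band; recordings
  dominated by broadband artifacts would need artifact rejection upstream.
* The surrogate null preserves column marginals but destroys all
  between-column dependence; features that are dependent for reasons other
  than cluster structure (e.g. mathematically coupled statistics computed
  from the same ISIs) make the null slightly conservative.
* Ward linkage with squared Euclidean distances assumes roughly spherical,
  similarly sized clusters; strongly elongated clusters can split before
  they separate.
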