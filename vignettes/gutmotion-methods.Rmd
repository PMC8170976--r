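---
title: "Methods: spatiotemporal motility mapping and enteric biomarker quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatiotemporal motility mapping and enteric biomarker quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutmotion)
```

## Scope and model

`gutmotion` implements the analysis layer of a gut-first Parkinson phenotyping
study in the A30P α-synuclein mouse model: ex vivo gastrointestinal motility
mapping, an nCounter-style miRNA differential-expression workflow with
proteomics overlap and counter-regulation pairing, immunofluorescence
quantification, and the shared two-group statistics. Wet-lab steps (dissection,
staining, mass-spectrometry acquisition) and external knowledge bases (target
prediction, pathway analysis) are out of scope; the pipeline consumes diameter
traces or frame stacks, count/intensity tables, a user-supplied miRNA→protein
target map, and images.

## The motility signal

The central object is a **diameter trace**: a loci × frames matrix of gut
diameters (mm), observed at 30 equally spaced loci along a 2 cm segment at
25 frames/s, oral end at locus 0. Traces come either from `track_edges()` on a
frame stack (per-column intensity profiles, a stack-wide Otsu threshold, and
the outermost above-threshold rows as the two gut borders) or directly from
TSV files.

`baseline_correct()` removes slow whole-gut movements per locus with a
**moving median**, chosen over a moving mean because the median is robust
against the deep contraction troughs that would otherwise bias the baseline
toward them. The window must sit *between* two timescales: longer than the
longest cycle period (so contractions do not leak into the baseline) and
shorter than the drift timescale (so drift is tracked). Defaults are 20 s for
small-intestine-like signals (cycle periods ≈ 0.4–1.5 s) and 300 s for
colonic signals (periods ≈ 69–104 s). For wide windows the median is evaluated
on a decimated grid (≤ ~1000 support points per window) and interpolated,
which is exact for the low-frequency component it estimates. The signed
amplitude is `trace − baseline`: dilatations positive, contractions negative,
and `baseline + amplitude` reconstructs the input to machine precision.
`normalize_map()` divides each locus by its initial diameter, taken as the
mean over the first second rather than frame 0 to damp noise.

## Cycle detection and endpoints

`detect_cycles()` runs a Schmitt-trigger state machine on the amplitude of
each locus: a contraction onset is the linearly interpolated zero crossing
between the last passage above `+h/2` and the next passage below `−h/2`,
where `h` is the hysteresis band width. The default `h = 0.075` mm is the
midpoint of the 0.05–0.1 mm range used in the original recordings; any signal
confined to the band is ignored by construction, which is the entire point of
the dual threshold. Only full onset-to-onset cycles enter the interval lists;
partial cycles at the trace boundaries are discarded.

The three endpoints are:

* **contraction rate** — the median over loci of per-locus onset counts
  (robust to a dead locus at a segment edge), rescaled to per minute or per
  10 minutes;
* **mean interval** — per-locus mean cycle duration, then the unweighted mean
  over loci with at least one full cycle. The per-locus-then-grand mean was
  chosen over pooling all cycles because each locus is analyzed separately
  upstream; the two differ when cycle counts vary across loci;
* **wave velocity** — onsets are chained across adjacent loci (the
  adjacent-locus lag must stay below half the local mean interval, preventing
  distinct waves from being concatenated); each wave spanning ≥ 10 loci gets a
  least-squares fit of onset time against locus position, and the velocity is
  the inverse slope (mm/s, aboral positive, retrograde negative). Waves with
  slopes below the timing resolution across the segment are flagged
  synchronous and excluded with a warning. The automated fit replaces manual
  cursor alignment; `min_loci = 10` guards against spurious two-point fits.

Missing endpoints are reported as `NA`, never fabricated zeros: a flat trace
has rate 0 but undefined interval and velocity.

Whether the hysteresis applies to raw (mm) or normalized amplitude is an open
choice; raw mm is used because the band itself is quoted in mm.

## The synthetic-data generator

Every stage is verified against `simulate_trace()` and friends, since the raw
recordings behind the original cohort are not redistributable. The waveform of
one cycle is a raised-cosine contraction trough of depth `amplitude` occupying
`duty` (default 40%) of the period, followed by a raised-cosine dilatation
bump over the remainder with peak `duty/(1−duty)·amplitude`, making the
waveform zero-mean. The dilatation phase is not cosmetic: the Schmitt trigger
requires the signal to rise above `+h/2` before each onset, and a cycle
defined as "one contraction and one dilatation" provides exactly that. Real
waveforms are unknown (unpublished acquisition internals); a smooth
single-trough shape with one zero-crossing pair per cycle is the simplest
signal consistent with the published description. Drift is a slow sinusoid
plus an optional linear ramp, spanning both drift archetypes.

Noise is additive on the diameter. Two regimes matter:

* **SI-like** (fast cycles, 60 s recordings): Gaussian noise with sd 0.02 mm,
  comfortably below the band. With ≈ 20 near-zero frames per cycle the
  probability that white noise traverses the full band within one cycle is
  negligible.
* **LI-like** (slow cycles, 600 s recordings): sd 0.01 mm and drift 0.15 mm
  over a 2400 s sinusoid. A 70 s cycle has > 1000 near-zero frames, so
  frame-independent Gaussian noise at 0.02 mm would cross any 0.075 mm band
  with near certainty per cycle — an adversarial model for slow, smooth
  colonic recordings, whose effective noise after optical averaging is
  smaller and strongly autocorrelated. The bound follows from the
  single-frame tail probability times the quiescent frame count.

Noise can also be drawn bounded-uniform (`noise_dist = "uniform"`, with
`noise_sd` as the half-range): hysteresis suppression is a *guarantee* only
for bounded noise strictly inside the band, and the noise-rejection checks
use that regime.

What the generator does **not** emulate: non-stationary cycle frequencies,
segmentation-vs-peristalsis pattern mixtures, whole-segment translation in
the organ bath, and optical artifacts other than a dark frame. Passing the
recovery tests therefore demonstrates correctness of the detection and
endpoint arithmetic under realistic signal geometry, not robustness to every
failure mode of real video.

Generator amplitudes (0.4 mm) are plausible rather than fitted: no real
contraction amplitudes are published for this preparation.

## miRNA and protein workflow

`normalize_counts()` rescales each sample so the geometric mean of its
housekeeping features (Actb, B2m, Gapdh, Rpl19 by default) equals the
across-sample average of those geometric means — the platform-standard
geometric variant, with an arithmetic option behind a flag. The operation is
idempotent and exactly inverts per-sample scalings.

`expression_filter()` flags features whose **mean normalized count across all
samples** is ≥ 100. A per-sample reading ("at least 100 counts in every
sample") was the alternative; the mean interpretation was chosen because a
single failed sample should not silence an otherwise robust miRNA, and the
choice is recorded in the DE table's metadata.

`differential_expression()` applies a two-sided equal-variance Student's t to
`log2(count + 1)` per expressed feature — the log stabilizes count variance
and the pseudo-count avoids log 0 — with linear-scale fold changes
(case/WT). The study-matching significance flag uses the *unadjusted* p ≤
0.05 (the volcano guide line); a Benjamini–Hochberg FDR column is emitted
alongside for modern use but does not drive the flag. Features with zero
within-group variance in both groups and unequal means get a missing p-value
and a flag rather than a fabricated value. Protein intensity tables run
through the same machinery with `min_count = 0`; pre-tested tables (p-values
included) can skip DE entirely and feed the overlap and pairing steps
directly.

`counter_regulation_pairs()` intersects significant-up miRNAs with
significant-down proteins through a user-supplied two-column target map
(`inst/extdata/mirna_target_map.tsv` ships the published Nefl/Vamp2/Calb2
targeting lists as an example); tallies are distinct counts of pairs, miRNAs
and proteins. Only housekeeping normalization is implemented; no
positive-control normalization precedes it.

## Image quantification

`binarize_and_area()` thresholds a single channel (Otsu by default — the
original description says only "converted to binary pictures" — with a fixed
threshold available for audits) and reports percent-positive pixels over the
section or within a binary mask (e.g. marker area within a Tuj1-positive
ganglionic mask, the area-fraction reading of "signals per neuronal area").
`count_cells()` counts connected components above a minimum area; no
watershed splitting is attempted, so touching objects merge — documented
behaviour matching simple manual counting. `live_dead_counts()` counts the
calcein channel as live and propidium iodide as dead, with double-positives
conservatively counted dead. `percent_reduction()` and `marker_ratio()`
reproduce the published count arithmetic (reductions to two decimals, ratios
optionally normalized to a control).

## Statistics layer

`two_group_test()` is the equal-variance Student's t (Welch behind a flag)
with Cohen's d on the pooled standard deviation,
`d = (m₁−m₂)/√(((n₁−1)s₁²+(n₂−1)s₂²)/(n₁+n₂−2))`, and star labels at
p ≤ 0.05/0.01/0.001. The Shapiro–Wilk gate records normality per group
(n ≥ 3) and warns on failures but never switches the test — the original
analysis describes no fallback. Tests are two-sided throughout.
`two_way_anova()` uses the standard decomposition; with one observation per
cell the additive model is fitted and the interaction reported missing.
`compare_cohorts()` applies the two-group machinery endpoint-wise with
pairwise exclusion of missing values.

## Numerical choices and problem sizes

Onset times are linearly interpolated between frames; intervals are exact
differences of onset times. Integer onset counts quantize the rate: with a
60 s trace and ~40 cycles the median across loci moves in 0.5-count steps
(1.25%), so drift-invariance comparisons use 120 s traces where the quantum
is below 1%. The verification suite uses 20 seeded 60 s SI-like simulations
for parameter recovery, 100 seeds for noise rejection, 200 simulated panels
for DE sensitivity/false-positive calibration, and 200 null simulations for
type-I calibration of the t and ANOVA layers — sizes at which binomial noise
on a 5% rate is a percent or two.

## Known limitations

* Baseline correction acts on corrected diameters; whether the original
  acquisition corrected dot positions or diameters is unknowable from the
  published description.
* Wave association is greedy nearest-onset chaining; crossing waves (rare in
  these preparations) could be mis-assembled.
* The velocity of a wave that never spans 10 consecutive loci is not
  estimated.
* Otsu thresholds assume a bimodal intensity histogram; dim, low-contrast
  stains should use the fixed-threshold mode.
* Type-I calibration bands at 200 simulations are ±1.3 binomial standard
  deviations wide; occasional excursions are expected sampling noise, not
  miscalibration.
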