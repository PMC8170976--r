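# gutmotion

Analysis pipeline for **gut-first phenotyping of Parkinson mouse models**: the
A30P α-synuclein mouse shows retarded gastrointestinal motility and molecular
dysregulation in the enteric nervous system months before any motor symptom,
and this package implements the quantitative layer of that phenotype — for
physiologists analyzing ex vivo gut recordings and for molecular biologists
running nCounter-style miRNA panels and proteomics overlap analysis against
them.

## What it computes

**Motility.** A gut-segment recording becomes a diameter trace `D[i, t]`
(30 loci over 2 cm, 25 frames/s). A per-locus moving median estimates the slow
baseline `B`, leaving the signed amplitude `A = D − B` (dilatations positive,
contractions negative), optionally normalized to each locus's initial
diameter. Contraction onsets are detected per locus by a Schmitt trigger: an
onset is the interpolated zero crossing between the last passage above `+h/2`
and the next below `−h/2`, with hysteresis `h = 0.075` mm suppressing
noise-induced false triggers. From the onsets:

* contraction rate = median over loci of onset counts, per min (SI) or per
  10 min (LI);
* mean interval = per-locus mean full-cycle (onset-to-onset) duration,
  averaged over loci;
* wave velocity = inverse slope of onset time vs locus position, fitted per
  propagating wave (aboral positive).

**Omics.** Housekeeping (geometric-mean) normalization of miRNA counts, the
≥ 100 mean-count expression filter, per-feature Student's t on
`log2(count + 1)` with linear fold changes and a volcano table, overlap
partitions and integer proportions of significant-protein sets, and
counter-regulation pairing (significant-up miRNA × significant-down protein
through a user-supplied target map).

**Images.** Otsu/fixed-threshold percent-positive area (whole section or
within a ganglionic mask), connected-component cell counts, live/dead counts,
percent reductions and marker/PGP9.5 ratios.

**Statistics.** Shapiro–Wilk gate (recorded, never switching the test),
equal-variance Student's t, Cohen's d on the pooled SD
`d = (m₁−m₂)/s_p`, `s_p = √(((n₁−1)s₁² + (n₂−1)s₂²)/(n₁+n₂−2))`, two-way
ANOVA, and endpoint-wise cohort comparison tables with `*`/`**`/`***` stars.

A synthetic-data module (`simulate_trace`, `render_frames`,
`simulate_cohort`, `simulate_count_matrix`, `simulate_if_image`) generates
seeded inputs with known ground truth for every stage.

## Worked example

```r
library(gutmotion)

# a small-intestine-like recording: 40 contractions/min propagating at 15 mm/s,
# 0.4 mm deep, over 0.5 mm slow drift and 0.02 mm noise
p <- wave_params(frequency = 40, amplitude = 0.4, velocity = 15,
                 drift_amplitude = 0.5, drift_period = 120, seed = 1)
tr  <- simulate_trace(p)
map <- normalize_map(baseline_correct(tr, window_s = 20))
unlist(summarize_motility(map))
#>  contraction_rate    mean_interval_s      velocity_mm_s       n_waves_used
#>              "40" "1.49435870207861" "14.9710740428995"               "40"
#>     n_synchronous   reporting_window      hysteresis_mm
#>               "0"          "per_min"            "0.075"
```

The detector recovers the generator's truth: 40 contractions/min (rate), a
1.494 s mean cycle (true 1.5 s = one contraction plus one dilatation), and
14.97 mm/s wave velocity (true 15) from 40 assembled waves.

Effect size from published group summaries — small-intestine contraction
rates of 40.7 ± 2.6 (n = 6 WT) vs 35.7 ± 3.6 (n = 7 case):

```r
cohens_d_summary(6, 40.7, 2.6, 7, 35.7, 3.6)
#> [1] 1.570045
```

A simulated 578-miRNA panel (166 robustly expressed, 45 spiked 2-fold up in
the case group, n = 5 vs 6):

```r
cm <- normalize_counts(simulate_count_matrix(spike_design(seed = 439)))
de <- differential_expression(cm)         # >= 100-count filter, t-test, BH
c(expressed = sum(de$expressed), significant = sum(de$significant))
#> expressed significant
#>       166          53
```

166 features pass the expression filter; 53 reach p ≤ 0.05 (the 45 spiked
features plus the expected ~5% false positives among the 121 nulls).

## Analysis workflow

Numbered drivers under `analysis/` rerun the study-shaped analyses end to end
and write tables/figures under `results/`:

1. `01_simulate_motility.R` — SI and LI cohorts (6 WT vs 7 case) at the
   published group means; traces as TSV + sidecar JSON.
2. `02_motility_metrics.R` — maps, heatmaps, endpoint summaries, WT-vs-case
   comparison table (t, Cohen's d, stars).
3. `03_omics.R` — miRNA DE + volcano, protein overlap proportions
   (7%/14%, partition 61/134/13), counter-regulation pairing against the
   bundled Nefl/Vamp2/Calb2 target map.
4. `04_image_quant.R` — IF area quantification, masked marker area, cell
   counts, live/dead reductions, marker ratios.

Run them in order from the repository root: `Rscript analysis/01_simulate_motility.R` etc.

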