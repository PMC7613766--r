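# cooccupy

Genome-wide co-occupancy analysis of a sequence-specific transcription
factor and its accessory corepressor partners from ChIP-seq peak calls and
binned signal tracks.

## The problem

In myeloid leukemia models, the transcription repressor GFI1 recruits an
LSD1/CoREST corepressor complex to chromatin; accessory DNA-binding
components such as the HMG-box protein HMG20B stabilize the complex. The
genomic signature of this arrangement is quantitative and positional:

* the three factors' peak summits co-locate within ~100 bp, and peak
  strengths (MACS2 *pileup*) correlate across factors;
* the GFI1 consensus motif sits **at** the anchor factor's summit but
  **8–10 bp to one side** of the accessory factors' summits, with the two
  accessory factors sharing the same side at each site (a bimodal motif
  positional curve);
* after knockdown of the accessory factor, histone acetylation (H3K27Ac)
  rises and the LSD1:GFI1 signal ratio falls — but only at the strongest
  peaks, visible when peaks are ranked and split into ten equal strength
  cohorts;
* genes nearest the strongest peaks are preferentially up-regulated,
  detectable by preranked gene-set enrichment of per-cohort gene sets.

`cooccupy` implements this analysis chain for computational biologists
working with ChIP-seq peak calls: reading MACS2 narrowPeak/xls peaks,
blacklist filtering at the published thresholds (pileup ≥ 50, fold
enrichment ≥ 5), strength-decile cohorts, summit matching and anchored
triple distance statistics (one-way ANOVA with Tukey HSD), CentriMo-style
motif positional-probability curves with apex/width metrics, windowed
signal aggregation with GFI1-anchored normalization, and a preranked GSEA
engine (weighted Kolmogorov–Smirnov running sum, gene-set permutation
null). A synthetic-data generator plants all of these structures with known
parameters so every estimator can be validated by parameter recovery.

## Core statistics

* **Summit matching.** For reference peak *a* and candidate set *B* on the
  same chromosome, the match is `argmin_b |summit_b − summit_a|` subject to
  `|d| ≤ 100` bp; triples around strong anchors satisfy all three pairwise
  constraints, and signed distances obey `d(H→L) = d(H→G) − d(L→G)`.
* **Positional curve.** `P(o) = #{summits with a motif centered at
  summit+o} / #summits` for `o ∈ [−250, 250]`, smoothed by a 5-bp moving
  average; the enriched width is the contiguous run above
  `background + 2·SD` containing the maximum, and apexes are per-side modes.
* **Anchored ratio.** The knockdown LSD1 window signal is rescaled by the
  global factor `Σ GFI1_NTC / Σ GFI1_KD` ("assume constant GFI1 signal"),
  then `ratio = (LSD1+ε)/(GFI1+ε)` per peak and condition and the cohort
  mean of `ratio_KD / ratio_NTC` is tested across cohorts.
* **Enrichment score.** Walking the ranked list, hits add
  `|s_i|^p / Σ_hits |s|^p`, misses subtract `1/(N − N_hits)`; ES is the
  signed maximum deviation, NES the ES over the mean same-sign null |ES|
  from size-matched random gene sets, with the standard NES-ratio FDR.

## Worked example

```r
library(cooccupy)

cfg <- sim_config(seed = 42, n_sites = 800, n_control_sites = 300,
                  chrom_lengths = c(chrA = 3e6, chrB = 3e6), n_genes = 600)
sim <- simulate_cooccupancy(cfg)

## co-localization of the two accessory factors around strong anchor peaks
thr <- quantile(sim$peaks$gfi1$pileup, 0.8)
triple_analysis(sim$peaks$gfi1, sim$peaks$hmg20b, sim$peaks$lsd1,
                gfi1_min_pileup = thr)
#> triple_analysis: 143 anchored triples
#>   corr(signed H->G, L->G): r = 0.973 (p = 1.35e-91)
#>  pair     mean       sem median iqr   n
#>   H-G 8.867133 0.2869906      9   4 143
#>   L-G 8.902098 0.2937872      9   4 143
#>   H-L 1.783217 0.1105754      2   2 143
```

The two accessory factors are ~9 bp from the anchor but ~1.8 bp from each
other, and their signed anchor distances correlate at r = 0.97: they sit
together on one side of the anchor, not independently around it.

```r
occ <- scan_consensus(sim$genome$sequence, cfg$motif)
curve_metrics(positional_curve(occ,
  data.frame(chrom = sim$peaks$hmg20b$chrom,
             summit = sim$peaks$hmg20b$summit)))
#> curve_metrics: enriched width 43 bp; apex offset(s) -9, 9; bimodal TRUE
```

The accessory-factor curve is bimodal with apexes at ±9 bp, recovering the
planted modal offset.

```r
co <- assign_cohorts(sim$peaks$hmg20b, 10)
w <- function(f, cond) window_signal(sim$tracks[[f]][[cond]],
                                     sim$peaks$hmg20b, 300)
fac <- gfi1_anchor_factor(w("gfi1", "kd"), w("gfi1", "ntc"))
rr <- lsd1_gfi1_ratio(apply_anchor(w("lsd1", "kd"), fac), w("lsd1", "ntc"),
                      apply_anchor(w("gfi1", "kd"), fac), w("gfi1", "ntc"), co)
round(rr$summary$mean, 2)
#>  [1] 0.35 0.36 0.36 0.37 0.99 1.01 1.00 1.00 1.00 1.01
```

The LSD1:GFI1 ratio drops to ~0.35 in the four strongest cohorts (where the
generator planted the coupling) and stays at 1.0 elsewhere.

```r
mp <- map_nearest_gene(sim$peaks$hmg20b, sim$genes)
sets <- build_cohort_gene_sets(co, mp, "promoter")
res <- run_gsea(sim$ranked, sets, n_perm = 300, seed = 7)
res[res$set %in% c("cohort01", "cohort10"), ]
#> gsea_result: 2 gene set(s)
#>       set size    es   nes       p    q
#>  cohort01   22 0.868 2.520 0.00433 0.00
#>  cohort10   15 0.421 1.122 0.34300 0.73
```

Only the strongest cohort's promoter gene set is enriched at the top of the
knockdown expression ranking.

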