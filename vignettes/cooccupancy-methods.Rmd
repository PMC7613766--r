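---
title: "Methods: co-occupancy analysis and its synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-occupancy analysis and its synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cooccupy)
```

# The biological model being measured

A sequence-specific repressor (GFI1-like, "the anchor") binds its DNA
consensus; an HMG-box accessory protein (HMG20B-like) and the demethylase
scaffold it recruits (LSD1-like) bind DNA next to the anchor, on one side or
the other of the motif. This package quantifies the genomic fingerprints of
that arrangement from ChIP-seq peak calls and binned coverage:

1. **Co-location**: summits of the three factors fall within 100 bp of one
   another and their peak strengths correlate.
2. **Side structure**: relative to accessory-factor summits the motif is
   offset by a modal ~9 bp with both accessory factors on the *same* side
   per site, so the motif positional curve around accessory summits is
   bimodal while the anchor-summit curve peaks at zero; signed
   accessory-to-anchor distances are strongly correlated while distances
   within the accessory pair carry no side information.
3. **Strength-gated function**: only the strongest peaks repress — baseline
   acetylation/accessibility is inversely related to peak strength there,
   and knockdown of the accessory factor raises H3K27Ac (strongest three
   decile cohorts) and lowers the LSD1:GFI1 signal ratio (strongest four
   cohorts), with cohort-level LSD1 loss tracking accessory-factor loss.
4. **Expression consequence**: genes nearest the strongest peaks are
   up-regulated after knockdown, so per-cohort gene sets enrich at the top
   of a knockdown expression ranking.

# Analysis operations

## Peaks

Internal coordinates are 0-based half-open; MACS2 xls input (1-based,
inclusive) is converted at the boundary, and the ENCODE narrowPeak summit
offset (column 10) is resolved against `start`, with `-1` mapping to the
interval midpoint. narrowPeak has no fold-enrichment column, so fold
enrichment is `Inf` there (never filters) unless a sidecar xls supplies it.
`filter_peaks()` applies `pileup >= 50` and `fold enrichment >= 5` by
default and removes any peak sharing even one base with a blacklist
interval — blacklists mark artifact *regions*, so the whole peak interval is
tested, not just the summit.

`assign_cohorts()` sorts by pileup (ties: fold enrichment, chromosome,
start — fixed so runs are reproducible), keeps `floor(N/K)` peaks per cohort
and discards the `N mod K` weakest. With 18,385 peaks and ten cohorts this
gives 1,838 per cohort with 5 discarded; distributing the remainder would
give mixed sizes of 1,838/1,839, and equal sizes are what per-cohort SEMs
and ANOVA assume, so floor-and-discard is used.

Summit annotation uses strand-aware windows: promoter `[TSS-1000, TSS+100)`
and TTS `[TES-100, TES+1000)`, with precedence promoter > 5'UTR > 3'UTR >
exon > intron > TTS > intergenic. Whole-gene structure is optional; without
exons the gene-body categories collapse. These windows are conventional
annotator defaults — the annotation categories, not the window edges, carry
the analysis.

## Co-localization

`match_summits()` takes, per reference peak, the nearest candidate summit on
the same chromosome within 100 bp; equidistant candidates resolve toward the
smaller coordinate (documented, fixed). Matching is deliberately not forced
one-to-one: no deduplication rule is imposed on many-to-one matches.
`triple_analysis()` anchors on strong anchor peaks (default pileup ≥ 300, a
dataset-specific threshold; on synthetic data a strength quantile is the
natural floor) and requires all three pairwise separations ≤ 100 bp.
Correlations are Pearson (Spearman reported alongside) on **signed**
distances — the side structure lives in the sign — while distance means,
SEMs and the one-way ANOVA + Tukey HSD use **absolute** distances,
matching how inter-summit distances are summarized. The triangle identity
`d(H→L) = d(H→G) − d(L→G)` holds for every triple by construction and is
asserted in tests.

## Motif positional curves

The IUPAC consensus is scanned on both strands (reverse strand via the
reverse complement); occurrences are anchored at their center
(`start + floor(len/2)`) and strand is collapsed, which keeps curves
symmetric. The curve is the per-offset fraction of summits with at least
one occurrence centered there; probabilities are fractions of summits and
never exceed one. Smoothing is a centered 5-bp moving average; the
background is the mean smoothed probability over the `|o| ∈ [200, 250]`
flanks and the enrichment threshold is background + 2 flank SDs (both are
calibration knobs surfaced as arguments). The enriched width is the maximal
contiguous run above threshold containing the global maximum. The apex on
each side of zero is that side's maximum within the region; the curve is
called bimodal when both side apexes reach 70% of the global maximum *and*
the curve dips below half the lower apex between them. The valley condition
is needed because a smoothed central delta has plateau maxima at ±1–2 bp on
both sides and would otherwise be called bimodal.

Enriched-region *widths* depend on the upstream motif-discovery machinery
in published analyses, so widths are matched qualitatively (anchor curve
strictly narrower than accessory curves), not numerically; the apex offsets
are the quantitative target (modal 8–10 bp per side).

## Windowed signal and cohort statistics

`window_signal()` averages track bins whose *center* lies in
`[summit−h, summit+h)` (half-open, like everything else here); windows
narrower than one bin fall back to the summit's bin, and a window wholly off
the chromosome is an error. The analyses use h = 1000 bp for acetylation
fold changes and h = 300 bp for factor ratios.

Fold changes use a pseudocount of ε = 0.5 signal units (the source analyses
are silent on this; 0.5 is small against the tracked signals and surfaced
as an argument) and are summarized per cohort as mean ± SEM **on the FC
scale**, matching the axis of such figures; a log2 option exists. Cohort
comparisons use one-way ANOVA with Tukey HSD and no additional correction
layer — Tukey already adjusts the all-pairs family, and the reported
contrasts ("each of the top three cohorts versus each of the bottom five")
are a subset of that family.

The anchoring factor is a *single global scalar*, `Σ NTC / Σ KD` of the
anchor factor's window signals over all peaks. Per-peak anchoring would
divide out the very biological signal under study (localized partner loss),
whereas one scalar only removes a shared between-condition scale.

## Preranked enrichment

The ES is the classic weighted Kolmogorov–Smirnov running sum with hit
weight exponent p = 1 (p = 0 gives the unweighted form). Because the input
is a preranked list, the null is **gene-set permutation**: size-matched
random draws from the ranked universe, the standard choice in preranked
mode. NES divides ES by the mean same-sign null |ES|; the nominal p is
one-sided against the same-sign null with the +1 continuity correction; the
FDR q follows the NES-ratio procedure with monotonicity in |NES| enforced.
Score ties are broken by gene identifier so the ranking is strict and
deterministic. Nearest-TSS mapping replaces regulatory-domain tools
deliberately: enhancers do not necessarily regulate the nearest gene, so
conclusions are drawn at cohort level (which set enriches), never per gene.

# The synthetic generator

`sim_config()` holds every tunable; `simulate_cooccupancy()` chains the
stages. Each stage derives its own RNG substream from the single seed, so a
config is byte-reproducible and stages can be rerun independently.

**What it emulates.** Sites are placed on a slot lattice (pitch 1.5× the
2 kb minimum spacing, jitter ±spacing/4) so that ±1 kb windows never
overlap. Each non-control site gets one motif instance written into the
genome, centered on the anchor summit. The accessory offset model is: side
`s` uniform on {−1, +1} per site; shared distance `d = 9 + N(0, 3)` bp
truncated at zero; each accessory factor adds independent integer jitter
from {−2, …, +2}. These three numbers (modal 9 bp, sd 3 bp, ±2 bp jitter)
are the minimal parameterization that yields bimodal apexes in the 8–10 bp
band, a signed-distance correlation near 1, and accessory-pair distances
far below accessory-to-anchor distances. Strengths are lognormal
(meanlog = log 70, sdlog = 0.8) tied by a Gaussian copula with pairwise
latent correlation 0.9; this places roughly a fifth to a quarter of peaks
above the "strong" thresholds and a few percent above the strongest anchor
floor, mirroring the quantile structure of the real peak universes. Factor
presence probabilities (1.0 / 0.91 / 0.95 for the reference, anchor and
scaffold factors) mirror the published strong-peak overlap percentages.

Tracks are Gaussian bumps (sd 75 bp, bin 10 bp) with height equal to
strength, truncated at 8 sd, with optional per-bin Poisson noise on the
expected counts. Knockdown multiplies bump heights by per-site retention:
the depleted factor retains U(0.25, 0.45) everywhere; the scaffold factor's
retention equals the depleted factor's at the strongest 40% of sites
(cohorts 1–4) and 1 elsewhere; the anchor's biological retention is 1. A
global ×0.7 condition scale on the three factors' knockdown tracks emulates
a shared depth difference — exactly what anchored normalization exists to
remove, and what makes the anchoring factor (≈ 1/0.7) testable.
Acetylation/accessibility bumps have baseline 50/30 units, reduced as
`(q70/strength)^0.5` above the 70th strength percentile (the planted
inverse relation) and multiplied by 2 after knockdown at those same sites
(cohorts 1–3). The control factor gets its own motif-free sites, strengths
from the same lognormal, acetylation *level* rising with its strength but
no knockdown response — a specificity control.

Genes: 60% receive a TSS within 1 kb of a site, 40% are placed ≥ 1.5 kb
from every site; two exons of 200 bp bracket an intron so all annotation
categories exist. Baseline expression is lognormal FPKM with the 0.25-FPKM
expressed-gene filter applied to the ranked-list builder. The nearest gene
of each strongest-decile site is planted responsive with expression score
effect 2 over N(0, 1) noise — enough to rank the top-cohort set first
without making every responsive gene extreme. The published knockdown data
give no quantitative per-cohort retention or gain values, so those
magnitudes are qualitative mimics chosen once; what the tests validate is
*which cohorts* respond, not the magnitudes.

**What it does not emulate.** No reads (no FASTQ/BAM), no fragment-length
or GC/duplication biases, no irregular peak shapes or width variation, no
chromatin-domain structure, no correlated backgrounds between tracks, and
uniform base composition outside planted motifs. Passing tests therefore
demonstrate that the estimators recover planted parameters under the
package's idealized signal model — not that they are robust to the full
messiness of real ChIP-seq.

# Numerical choices and degenerate inputs

* All tie-breaks are fixed and documented: nearest-summit ties toward the
  smaller coordinate, strength-sort ties by (fold enrichment, chromosome,
  start), nearest-gene and ranking ties by gene identifier, curve-maximum
  ties toward the offset closest to zero.
* Empty results are values, not errors, where the quantity is well defined
  (no triples → empty result without statistics; empty cohort gene set →
  retained and flagged); violated preconditions are errors (empty peak set
  into `select_top()`, window off the chromosome, empty ranked-list
  intersection).
* The anchoring self-consistency bound (cohort ratios = 1 within 1e-6 in a
  noise-free run) is limited only by float accumulation over window sums.
* Problem sizes used by the test suite and acceptance script — 800–5,000
  sites on 6–17 Mb genomes, 300–500 permutations — were chosen as the
  smallest sizes at which the planted structure dominates sampling noise
  by a comfortable margin; all run in seconds on one CPU.

# Known limitations

* Annotation treats the first/last exon as UTRs when no CDS is available;
  peak classes depend on those window conventions.
* `overlap_fractions()` and `match_summits()` are summit-based; interval
  overlap without nearby summits is invisible to them.
* The FDR of the enrichment engine is the classic NES-ratio estimate: at
  very small set counts it is coarse (q snaps to few distinct values).
* The generator's strength/retention coupling is piecewise by strength
  quantile, a deliberately sharp version of what is presumably a smooth
  biological relationship.
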