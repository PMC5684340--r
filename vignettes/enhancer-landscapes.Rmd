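---
title: "Stimulus-regulated enhancer landscapes: models and design choices"
author: "EnhancerScape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stimulus-regulated enhancer landscapes: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

EnhancerScape analyses how a stimulus changes a cell's enhancer
repertoire, starting from per-sample peak calls and fragment placements
for the enhancer marks H3K27ac (active) and H3K4me1 (candidate), the
promoter mark H3K4me3, optionally the chromatin reader BRD4, and matched
input chromatin, in a two-condition × two-replicate design. Five
statistical components sit on top of standard interval algebra:

* a co-occupancy rule defining enhancers,
* an empirical-Bayes moderated two-group test on log2 ChIP/input
  enrichment,
* a rank-curve (ROSE-style) super-enhancer cutoff with gained/lost
  classification,
* distance-rule integration with gene expression, and
* a random-placement permutation test for lncRNA–enhancer overlap.

## Enhancer definition

All H3K27ac peaks are merged into disjoint regions (coverage union;
abutting half-open intervals are joined). A merged region is *supported*
by a sample if at least one of that sample's peaks overlaps it by one
base or more. Candidate enhancers are H3K27ac merged regions with
support ≥ 2 of 4 that overlap (≥ 1 bp) an H3K4me1 merged region with
support ≥ 2 of 4. Support may come from any two samples, whether or not
they share a condition: a region present only after treatment is still
supported by its two treated replicates, which is what lets de-novo
gained enhancers enter the catalog. The enhancer footprint is the
H3K27ac region, because all downstream quantification is H3K27ac-based;
the H3K4me1 region only gates membership. Regions overlapping promoter
windows (TSS ± 1000 bp), annotated exons, or H3K4me3 peaks are then
excluded as likely promoters.

## Enrichment and the moderated test

For enhancer *i* and ChIP sample *s*, fragments overlapping the enhancer
are counted once each (a paired-end fragment is one interval), scaled to
one million total fragments per library, and summarized as

\[ E_{is} = \log_2\frac{\mathrm{Count^{ChIP}}_{is} + 1}
                        {\mathrm{Count^{input}}_{is} + 1}. \]

The +1 pseudocounts keep E finite at empty regions. Columns are quantile
normalized (every sample is forced to the per-rank means of the sorted
columns; fractional midranks from ties interpolate between adjacent
reference values), which removes sample-level distributional differences
— including any residual library-scale effects — while preserving
within-sample rank order.

The two-group test is the standard empirical-Bayes moderated t: per
enhancer, residual variance \(s^2\) on \(d = n_1 + n_2 - 2\) df is
shrunk towards a prior \(s_0^2\) with weight \(d_0\),
\(\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)\), and
\(\tilde t = \mathrm{logFC} / (\tilde s \sqrt{1/n_1 + 1/n_2})\) is
referred to a t distribution on \(d + d_0\) df. The prior is estimated
by moment matching on \(\log s^2\): the excess of its variance over
\(\psi'(d/2)\) is inverted through the trigamma function (Newton
iteration) to give \(d_0\), and the mean gives \(s_0^2\). When the
moment estimate is non-finite (no excess variance across features) the
limit \(d_0 = \infty\) — one shared variance — is used. With \(d_0 = 0\)
the statistic reduces exactly to the ordinary pooled t, which the test
suite checks against an independent implementation; with estimated
priors it agrees with limma to 10 decimals, which the suite uses as an
external oracle only.

"Fold change ≥ 2" is interpreted as a difference of ≥ 1 between mean
normalized log2 enrichments. The enrichment is already a log2 ratio, so
a ratio-of-ratios reading would be ill-defined near zero; a one-unit
difference of log2 enrichment is the natural fold-2 statement on this
scale. The unaffected background band is |linear fold| ≤ 1.05, i.e.
|logFC| ≤ log2(1.05), labelled `unaffected_background`; everything
neither differential nor background is `other`.

De-novo thresholds (treated > 1.5 with control < 1.1 for gained, the
mirror image for lost) are applied to the mean **log2** enrichment — the
quantity the rest of the analysis calls the "ChIP enrichment signal".
The linear reading (thresholds on \(2^E\)) is available through
`classifyDeNovo(scale = "linear")`; log2 is the default because 1.5 and
1.1 sit naturally inside the observed log2 enrichment range (≈ 0–5)
whereas on the linear scale nearly every active enhancer would exceed
them. Enhancers with undefined statistics (zero variance under
\(d_0 = 0\)) are classified `other` and excluded from BH adjustment.

## Super-enhancers

Enhancers within 12.5 kb (end-to-start) are stitched; the stitched
span's signal is the mean of per-replicate per-million-scaled fragment
counts of H3K27ac minus the same quantity for the matched inputs,
floored at zero (rpm). No TSS exclusion is applied during stitching: the
catalog is already promoter-filtered, and the BRD4-peak mode runs the
same way for symmetry. After sorting signals ascending and scaling both
rank and signal to [0, 1], the cutoff is the index maximizing
\(x_i - y_i\) — the tangency point of a slope-one line with the curve —
with ties broken to the highest-signal index, so a perfectly linear or
flat curve yields zero super-enhancers (the conservative choice).
Regions strictly above the cutoff signal are SEs.

Differential SEs are evaluated on the union of SE spans from the two
conditions, merging overlapping spans and recomputing signal on the
merged span so each locus is classified exactly once. The fold change is
\((\mathrm{signal_{trt}} + \varepsilon)/(\mathrm{signal_{ctrl}} +
\varepsilon)\) with \(\varepsilon = 0.1\) rpm guarding empty spans;
gained means fc ≥ 2, lost fc ≤ 0.5. Swapping conditions maps gained to
lost exactly up to the ε asymmetry (< 1 % at realistic signals).

## Expression integration

Normalized expression ("A.U.") is TMM-scaled counts per million: the
package's own trimmed-mean-of-M-values implementation (30 % log-ratio
trim, 5 % intensity trim, inverse-asymptotic-variance weights, reference
column by 75th-percentile proximity to the mean, factors centred to
multiply to one) reproduces edgeR to numerical precision; edgeR is kept
as a test oracle. Defining A.U. this way makes the 100 A.U. expression
floor scale-free. The two-sample expression design supports no
replicate-based significance testing, so DE genes follow the
coverage/fold rule exactly as stated: normalized coverage ≥ 10 in either
condition and linear fold ≥ 1.5 in either direction. Normalized (not
raw) counts are used for the coverage floor so the rule is invariant to
sequencing depth.

Two distance rules link regions to genes. Differential enhancers are
assigned to every gene whose TSS lies within ±250 kb of the enhancer
boundaries (a gene may have many enhancers and vice versa). SEs and TEs
are mapped ROSE-style to the single closest *expressed* gene (> 100
A.U. in at least one condition) within ±50 kb of the region centre,
measured centre-to-TSS — the TSS side is chosen for consistency with the
±250 kb rule, and `mapNearestGenesRose()` documents the tie-break
(equidistant genes resolve to the lexicographically lower gene_id, so
results are deterministic). Genes claimed by both an SE and a TE count
as SE genes; expressed genes claimed by neither are "no enhancer" genes.

The contribution summary totals A.U. of SE-associated genes per
condition and splits the percent change into per-class percentage
points, \(100 (\sum T_k - \sum C_k)/\sum C\), which sum to the total by
construction — an exact conservation the tests assert. Gene-level log2
fold changes use a 1 A.U. pseudocount.

## lncRNA–enhancer overlap test

The null hypothesis is positional independence: both sets are re-placed
uniformly at random across the genome, preserving each element's
length — the stricter and standard null — with chromosomes chosen with
probability proportional to the number of valid start positions and
elements placed independently (same-set overlaps allowed, as the
simplest reading of random placement). Each simulation records the
number of enhancers overlapping ≥ 1 lncRNA; the enhancer-side count is
the primary statistic and the lncRNA-side count is reported alongside.
The add-one empirical p-value \((1 + \#\{K_{null} \ge K_{obs}\})/(1 +
N)\) can never be zero and equals 1/10001 < 10⁻⁴ when no null
simulation reaches the observed count at the conventional 10,000
simulations. The implementation linearizes coordinates with guard gaps,
merges the placed lncRNAs, and tests all enhancers with one
`findInterval` pass, so genome-scale runs (tens of thousands of
elements × 10⁴ simulations) take minutes. Genome layouts are Seqinfo
objects; chromosome lengths are 32-bit integers, so a multi-gigabase
genome is represented as its chromosomes rather than one concatenated
sequence.

## The synthetic-data generator

`simulateExperiment()` emulates the statistical structure the analysis
assumes, with planted truth for every downstream stage. Defaults are the
study conditions used throughout the tests:

* **Genome**: two 50 Mb chromosomes — large enough that ±250 kb windows
  and 12.5 kb stitching see no edge effects, small enough for
  seconds-scale runs.
* **Counts**: fragments are 300 bp spans; input tracks are uniform
  background at 20 expected fragments per 2 kb region (the Poisson
  floor), ChIP tracks add planted extras so a baseline enhancer has
  log2 enrichment ≈ 2 (background rate 20, signal rate 60). Noise is
  Poisson by default — the minimal model for per-region fragment
  counts — with a negative-binomial option of stated dispersion.
* **Classes**: fractions 0.15/0.15/0.5/0.1/0.1 for
  up/down/unaffected/de-novo gained/lost; the planted effect size is
  2 log2 units, and de-novo enhancers move between enrichment ≈ 0.8
  (below the 1.1 threshold, and below peak-calling presence) and
  0.8 + effect. Because extra fragments ride on a background whose
  effective rate includes fragment-length edge effects, realized
  enrichment is compressed by ≈ 0.2 log2 units relative to nominal;
  all planted classes keep comfortable margins to their thresholds.
* **Clusters**: nine 5-enhancer clusters with constituents 2–8 kb apart
  and a 10× signal multiplier, planted gained/lost/unchanged in equal
  thirds with a 4× signal ratio. Cluster constituents inherit their
  cluster's direction in the truth table; the class-fraction invariant
  is asserted on singletons.
* **Peaks**: every enhancer gets a peak (± ≤ 200 bp jitter) in both
  replicates of each condition where its enrichment is high enough;
  spurious single-sample peaks and promoter/exon/H3K4me3 decoy
  candidates exercise the support and exclusion filters.
* **Expression**: each singleton enhancer and each cluster gets a
  linked gene 5–30 kb downstream (TSS-side geometry keeps promoters and
  exons clear of the enhancer); linked genes inherit ±1 log2 fold
  change (linear fold 2, above the 1.5 DE rule); distal genes on the
  chromosome tails provide the "no enhancer" class, with alternating
  strands.
* **lncRNAs**: lengths uniform 0.5–5 kb; a planted fraction (default
  0.3) is centred on enhancers, the rest placed uniformly with
  rejection against enhancer overlap. `simulateNullOverlap()` places
  all of them uniformly for calibration.

What the generator does **not** emulate: sequence content and
mappability, GC or copy-number bias, peak-caller behaviour (peaks are
planted, not called), replicate-specific batch effects beyond
independent sampling noise, correlated fragment placement, or realistic
gene density. Passing tests therefore demonstrate that the statistical
machinery recovers planted structure under its own model assumptions,
not that those assumptions hold for any particular real dataset.

## Problem sizes and determinism

The test suite and the acceptance script size their simulations for
minutes-scale runs: 500 enhancers × 2×2 samples for recovery (5 seeds),
two null simulations for calibration of the moderated test, 1000
replicate experiments at 199 permutations each for overlap-test
calibration, and one genome-scale permutation run (42,076 × 466
elements, 10,000 simulations). All randomness flows through explicit
seed arguments (`withSeed()` restores the caller's RNG state), so every
output — including written files, via `runPipeline()` — is reproducible
bit for bit under a fixed seed.

## Known limitations

* The moderated test assumes approximately normal enrichment values;
  at very low counts the log2 ratio is granular and the test is
  slightly conservative (observed null rejection ≈ 0.03–0.06 at
  α = 0.05 in the calibration runs).
* The overlap null ignores chromatin context: no GC/mappability
  matching or exclusion zones (bedtools-shuffle-style nulls are out of
  scope).
* One fragment may count towards two overlapping regions; regions in
  the final catalog are disjoint, so this affects only user-supplied
  overlapping query sets.
* The ±50 kb nearest-gene rule measures centre-to-TSS; gene-body
  distance is not offered.
* Amplification efficiency in the qPCR formulas is fixed at perfect
  doubling, as the formulas assume; standard-curve correction is out of
  scope.
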