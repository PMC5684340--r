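# EnhancerScape

Differential enhancer and super-enhancer landscape analysis from
histone-mark ChIP-seq, for regulatory genomicists studying how a stimulus
rewires the enhancer repertoire of a cell type (the motivating setting is
agonist-treated vascular smooth muscle cells profiled with H3K27ac,
H3K4me1, H3K4me3 and BRD4 in a two-condition, two-replicate design).

The package implements the full computational pipeline downstream of peak
calling:

1. **Enhancer definition.** Merged H3K27ac regions supported by peaks in
   at least 2 of 4 samples that overlap an H3K4me1 region with the same
   support, minus anything overlapping promoters (TSS ± 1 kb), exons, or
   H3K4me3 peaks.
2. **Differential enrichment.** Per enhancer *i* and ChIP sample *s*,
   enrichment is `E[i,s] = log2((Count_ChIP + 1) / (Count_input + 1))`
   with counts scaled to 1 million total fragments. After quantile
   normalization, a two-group empirical-Bayes moderated t-test shrinks
   per-enhancer variances s² towards a moment-matched prior (d₀, s₀²):
   `s̃² = (d₀s₀² + ds²)/(d₀ + d)`, `t = logFC / (s̃·√(1/n₁+1/n₂))` on
   d + d₀ df. Enhancers with |logFC| ≥ 1 (linear fold 2) at BH q < 0.05
   are up/down; de-novo gained enhancers additionally have treated
   enrichment > 1.5 with control < 1.1 (lost: the mirror image).
3. **Super-enhancers.** ROSE-style: enhancers within 12.5 kb are
   stitched, ranked by background-subtracted signal (rpm, ChIP − input,
   floored at 0), and split at the point where a slope-one line is
   tangent to the unit-scaled rank curve. Regions that are SE in either
   condition are classified gained (signal fold change ≥ 2) or lost
   (≤ 0.5) with an ε = 0.1 rpm pseudo-signal.
4. **Expression integration.** TMM-normalized counts per million
   ("A.U."), TPM, the coverage ≥ 10 & fold ≥ 1.5 DE-gene rule, enhancer →
   gene assignment by a ±250 kb TSS window, ROSE-style nearest-gene
   mapping (±50 kb from the region centre, 100 A.U. expression floor, SE
   priority over TE), cumulative expression-contribution summaries, and
   nearest-gene-rank correlations.
5. **lncRNA–enhancer overlap.** A random-placement permutation test:
   both element sets are re-placed uniformly across the genome (lengths
   preserved) and the enhancer-side overlap count is compared to the
   observed one via the add-one empirical p-value
   `p = (1 + #{K_null ≥ K_obs}) / (1 + N_sims)`.
6. **qPCR utilities.** 2^−ΔΔCt fold change and dilution-adjusted percent
   input.

A seeded synthetic-data generator (`simConfig()`/`simulateExperiment()`)
plants all of this structure — enhancer classes, SE clusters, linked gene
expression, overlapping lncRNAs — so the entire pipeline is testable with
known truth and no external data.

## Worked example

```r
library(EnhancerScape)

sim <- simConfig(seed = 42, chromLengths = c(chr1 = 2e7, chr2 = 2e7),
                 nEnhancers = 200, nSeClusters = 4, nGenes = 260,
                 nLncrnas = 40, includeBrd4 = FALSE,
                 nSpuriousPeaks = 20, nDecoys = 12)
res <- runPipeline("demo_out", "all", sim = sim, seed = 42, nSims = 2000)

table(S4Vectors::mcols(res$diffEnhancers)$class)
#>        de_novo_gained          de_novo_lost                  down
#>                    17                    18                    32
#>                 other unaffected_background                    up
#>                    85                    15                    33

res$rankings$treated
#> RoseRanking (treated): 184 stitched regions, 4 SEs (cutoff 1059.175 rpm)

table(S4Vectors::mcols(res$diffSE)$class)
#>    gained      lost unchanged
#>         1         2         1

res$overlap
#> OverlapTestResult: 12/200 enhancers overlap a lncRNA (40 lncRNAs)
#>   null: 2000 simulations, mean 1.00, sd 1.00
#>   add-one empirical p = 0.0004998
```

The class table counts enhancers whose H3K27ac enrichment rose (`up`,
including the 17 `de_novo_gained` that appear only after treatment) or
fell at fold ≥ 2 and q < 0.05; the four stitched regions above the
rank-curve cutoff are the planted enhancer clusters, and the 2 000-fold
random placement shows the planted lncRNA–enhancer overlap (12 of 200
enhancers) would essentially never arise by chance (p ≈ 5 × 10⁻⁴).
`demo_out/` then contains the enhancer BED, differential tables, SE
rankings, expression integration TSVs and a run manifest; rerunning with
the same seed reproduces every file byte for byte.

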