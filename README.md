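# ampdep

Collateral dependency screening for cancer genomic amplifications.

High-copy focal amplifications drag whole chromosomal segments along with
the driver oncogene, and cancer cells can become selectively dependent on
those coamplified passenger genes. `ampdep` is an R package for finding,
confirming, and prioritizing such amplification-associated dependencies by
integrating three gene × cell-line data layers — copy number, CRISPR
knockout gene effects, and expression — plus tumor survival data. It is
aimed at computational cancer biologists working with DepMap-style exports
(and matched tumor cohorts), and ships a synthetic-data generator with a
ground-truth manifest so every stage can be tested for parameter recovery.

## The method in brief

- Stored relative copy number is `RCN = log2(copies/ploidy + 1)`; absolute
  copies are recovered as `ACN = ploidy × (2^RCN − 1)`. High-copy
  amplification is called at `RCN ≥ 2` (equivalently `ACN ≥ 6` in diploids;
  the screen partition uses the absolute rule).
- The amplicon around a reference gene is the set of genes whose copy-number
  profiles correlate with the reference at Pearson `r ≥ 0.7` across the
  panel.
- For each amplicon, every gene's knockout effect is compared between
  amplified and non-amplified lines with a two-tailed pooled Student
  *t*-test; genome-wide Benjamini–Hochberg correction yields FDR *q*-values.
  Hits are genes with `q < 0.05` and a negative effect difference.
- Hits are confirmed positionally (hypergeometric overlap against
  chromosome-band gene sets, `p = P(X ≥ k)` with
  `X ~ Hypergeom(N, K, n)`) and by preranked GSEA of the coamplified set
  (weighted running-sum ES, gene-label permutation null, meandiv NES).
- Amplified vs amplification-free tumors are compared with Kaplan–Meier
  curves, the log-rank test, and O/E hazard ratios; targets are prioritized
  by subcellular accessibility and ligandability (−3…3) and assessed for
  whether mRNA expression predicts the dependency.

## Worked example

Generate the reference synthetic dataset (2,000 genes × 200 lines, one
20-gene amplicon amplified in 30% of lines, five planted dependencies at
Δ = −0.5) and run the core stages:

```r
library(ampdep)

b <- simulate_bundle(sim_config())
calls <- call_amplifications(b$rcn, b$samples, b$truth$reference_gene,
                             mode = "absolute")
calls
#> <amplification_calls G1010 [absolute]: 65/200 samples amplified>

amplicon <- find_coamplified(b$rcn, b$truth$reference_gene)
amplicon
#> <amplicon G1010: 20 coamplified genes at r >= 0.7>

screen <- screen_amplicon(b$effects, calls, amplicon)
head(screen_hits(screen)[, c("gene_id", "delta", "t_statistic", "q_value")])
#>   gene_id      delta t_statistic      q_value
#> 1   G1017 -0.5608388   -18.59150 5.307805e-42
#> 2   G1008 -0.5170322   -17.59583 2.405072e-39
#> 3   G1011 -0.4665714   -16.45236 4.442911e-36
#> 4   G1014 -0.4717605   -16.01348 7.163007e-35
#> 5   G1004 -0.4641103   -15.33277 6.826939e-33
```

All five hits are the planted dependencies: each is ~0.5 gene-effect units
more essential in amplified lines, at vanishing FDR. The positional overlap
puts the planted band first, and the coamplified set is strongly enriched at
the top of the dependency ranking:

```r
hits <- screen_hits(screen)
head(overlap_analysis(hits$gene_id, b$positional_sets, screen$gene_id), 1)
#>   set_name   K k gene_ratio      p_value      q_value    N n
#> 1 band_011 100 5       0.05 2.837444e-07 5.674889e-06 2000 5

preranked_gsea(rank_for_gsea(screen),
               setdiff(amplicon$coamplified$gene, amplicon$reference_gene),
               n_perm = 10000, seed = 1)
#> <gsea target: ES=0.999 NES=2.019 p=0 FDR=0 (19 hits, 10000 perms)>
```

`prioritize_targets()` then orders hits by accessibility (membrane/secreted
first) and ligandability, `lineage_confirmation()` re-tests them per tumor
type, and `classify_biomarker()` separates genes whose expression tracks
copy number (usable mRNA biomarkers) from dosage-buffered,
copy-number-only dependencies. `run_pipeline()` chains everything —
including survival comparisons — into one output directory with a
machine-readable `summary.json`; `inst/scripts/ampdep.R` wraps it for the
shell.

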