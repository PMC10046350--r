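---
title: "Screening collateral dependencies of cancer genomic amplifications"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening collateral dependencies of cancer genomic amplifications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampdep)
```

## The problem and the model

Focal genomic amplifications recurrently raise the copy number of whole
chromosomal segments, not single oncogenes. Cancer cells carrying such an
amplicon can become selectively dependent not only on the driver but on
*passenger* genes amplified alongside it — collateral dependencies that are
attractive therapeutic targets precisely because the amplification is already
measured in molecular diagnostics. `ampdep` implements, as a reusable and
tested pipeline, the integration of three gene-by-cell-line data layers that
exposes these dependencies:

1. **Copy number.** Gene-level values are stored relative to each line's
   ploidy as $\mathrm{RCN} = \log_2(\mathrm{copies}/\mathrm{ploidy} + 1)$.
   Absolute copies are recovered with the ploidy-aware inverse
   $\mathrm{ACN} = \mathrm{ploidy}\times(2^{\mathrm{RCN}} - 1)$, so a stored
   value of 2 in a diploid line is 6 copies. High-copy amplification is
   called at $\mathrm{RCN} \ge 2$ (relative mode) or
   $\mathrm{ACN} \ge 6$ copies (absolute mode); the two rules coincide at
   ploidy 2, and the screen partition uses the absolute rule.
2. **Coamplicons.** The amplicon around a reference oncogene is defined
   empirically: every gene whose copy-number profile has Pearson
   $r \ge 0.7$ with the reference gene's across the panel is coamplified.
   The threshold is applied to the signed $r$; anti-correlated genes never
   qualify.
3. **CRISPR gene effects.** Knockout fitness scores are centered so that 0
   means non-essential and negative means loss of viability. For each
   amplicon, every gene is tested between amplified and non-amplified lines
   with a two-tailed pooled-variance Student $t$-test, and the genome-wide
   family of p-values is corrected by Benjamini–Hochberg. A collateral
   dependency is a gene with $q < 0.05$ and a negative effect difference.

Two enrichment views confirm that hits concentrate where the amplicon lies:
a hypergeometric overlap of the hit list against positional (chromosome-band)
gene sets, and a preranked GSEA of the coamplified set against the ranked
screen. Downstream, hits are prioritized for druggability, re-confirmed per
lineage, and assessed for whether mRNA expression could serve as a dependency
biomarker; amplified tumors are compared against amplification-free tumors by
Kaplan–Meier/log-rank survival analysis.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `rcn_threshold` | 2 | relative-mode amplification call (log2 units) |
| `acn_threshold` | 6 | absolute-mode call, in copies; screen partition |
| `r_threshold` | 0.7 | coamplification bar (Pearson r, signed) |
| `q_threshold` | 0.05 | FDR bar for screen hits and enrichment |
| similarity tiers | 0.4 / 0.7 | weak < 0.4 ≤ moderate < 0.7 ≤ high |
| `gsea_perms`, `gsea_weight` | 10000, 1 | gene-label permutations; weighted statistic |
| `min_amplified` | 3 | smallest amplified arm a screen will accept |

The similarity tiers classify, per lineage, how well cell-line amplification
frequencies track tumor frequencies; lineages with degenerate frequency
vectors (amplification rare) are reported `not_evaluable` rather than forced
into a tier.

## Design choices where the design was open

* **Student, not Welch.** The screen uses the pooled-variance Student test
  (`t.test(var.equal = TRUE)` semantics), vectorized in closed form for
  genome-wide throughput; Welch is available behind a flag. The scalar and
  vectorized paths share one implementation and are tested against
  `stats::t.test` to 1e-12.
* **BH family.** Correction is genome-wide within one amplicon's screen, not
  pooled across amplicons and not restricted to coamplified genes; a tally
  utility pools hit counts across screens afterwards.
* **GSEA rank statistic.** Ordering "by q-value" alone is unsigned, so the
  preranked list uses $-\log_{10}(\max(q, 10^{-300}))\cdot\mathrm{sign}(-\Delta)$:
  strong dependencies top the list, protective genes sink. Ties break by p,
  then $|\Delta|$, then gene id — a total, reproducible order.
* **GSEA null and normalization.** Gene-label permutation (random same-size
  sets), the standard null for preranked mode; NES divides ES by the mean of
  same-sign permutation scores ("meandiv"); the single-set FDR is the
  same-sign permutation-NES tail. Near-exact magnitude ties between the
  positive and negative running-sum extremes (possible at weight 0) resolve
  to the positive deviation within a 1e-9 tolerance.
* **Hazard ratios from the log-rank table.** HR is the O/E ratio
  $(O_1/E_1)/(O_2/E_2)$ rather than a Cox fit, keeping the survival module
  self-contained; values can differ slightly from a semi-parametric estimate.
* **Prioritization as an explicit rule.** Tier 1 = membrane/secreted
  (accessible to antibodies and small molecules), tier 2 = everything else;
  within a tier, q ascending, then ligandability (−3…3 scale) descending with
  missing scores last, then gene id. A ligandability ≥ 0 earns a `druggable`
  badge that never affects rank.
* **Biomarker rule.** Expression is called a usable dependency biomarker only
  when copy number drives expression (q < 0.05 and r ≥ 0.4) *and* expression
  predicts dependency (q < 0.05 and r ≤ −0.4); the 0.4 magnitude echoes the
  moderate-correlation tier and is configurable. A screen hit failing either
  arm is `copy_number_only` — the dissociation seen for dosage-buffered genes.
* **Default ploidy 2.** Samples missing ploidy are treated as diploid with a
  warning, the neutral assumption given the relative-copy-number encoding.
* **Missing values.** Correlations drop incomplete pairs pairwise; t-tests
  drop values listwise per gene and skip genes whose groups fall below 2.

## What the synthetic generator emulates

The generator (`sim_config()`, `simulate_bundle()`) builds fixtures with the
statistical structure the analysis assumes, plus a ground-truth manifest for
parameter-recovery tests. Its defaults are the reference study conditions
used throughout the test suite: 2,000 genes × 200 lines in 4 lineages,
ploidies drawn from {2, 3}, one contiguous 20-gene amplicon amplified in 30%
of lines at 8–16 absolute copies, five planted dependencies at
$\Delta = -0.5$ against effect noise 0.2, three of the five dosage-expressed
(slope 1 per RCN unit), and a 400-tumor survival cohort with baseline hazard
$\ln 2$ and hazard ratio 2 for amplified tumors.

Choices behind the defaults:

* **Copy noise 0.3 copies**, truncated at zero, keeps unamplified lines far
  from the calling bar (≥ 10 standard deviations).
* **Amplicon boundary.** Flank genes are amplified with probability halving
  per gene of distance, starting at 1/4 for the nearest neighbor, and flank
  segments draw their own amplitude. This yields boundary genes whose
  profiles correlate only partially with the reference (expected r ≈ 0.4),
  exercising the coamplification filter with a clear margin below 0.7; with a
  1/2 starting probability and a shared amplitude the nearest flank gene's
  expected r sits within sampling error of the bar at n = 200, which would
  make truth-set recovery a coin flip rather than a property.
* **Noise scales are artifact choices** — no public noise magnitudes exist
  for these data types; effect noise 0.2 approximates the spread of
  non-essential Chronos scores, expression noise 0.5 and lineage offsets 0.5
  (log2 units) give within-lineage correlations that are strong for dosage
  genes yet null for buffered ones.
* **Survival.** Event times are exponential; censoring is administrative at
  `censor_time`; an amplification-independent other-cause hazard makes the
  OS and DSS endpoints differ (other-cause deaths count for OS, censor DSS).
* **What is not emulated:** structural-variant breakpoints, subclonality,
  sgRNA-level counts (gene effects are drawn directly, as the pipeline
  consumes them), copy-number bias in the screen, or realistic expression
  distributions. Passing recovery tests therefore shows the *inference
  machinery* is correct under its stated model, not that real DepMap/TCGA
  data satisfy that model.

Identical seed and config give bit-identical bundles; every simulator stage
derives its own sub-seed so stages can be rerun independently.

## Numerical notes and degenerate inputs

* `rcn_to_acn`/`acn_to_rcn` are exact inverses to machine precision.
* Zero pooled variance with equal means gives $p = 1$ by convention; with
  unequal means the gene is reported infinitely significant; genes constant
  across all lines are skipped and listed.
* A zero-variance reference copy-number vector makes coamplification
  undefined and errors; degenerate frequency vectors make similarity
  `not_evaluable`.
* Hypergeometric p-values are upper tails, $P(X \ge k)$, so zero overlap is
  never evidence ($p = 1$).
* Results tables and matrices are serialized with round-trip-exact numeric
  formatting, which is what makes pipeline reruns byte-identical.

## Problem sizes used by the checks

The bundled checks run the reference fixture (2,000 × 200) for screen,
enrichment, and pipeline recovery; oracle equivalence is exhaustive for the
hypergeometric test to universe size 15 and for GSEA nominal p at list
length 8; null calibration uses 10 label permutations of the full screen and
200 simulated cohorts for log-rank uniformity. The full pipeline on the
reference fixture, including 10,000 GSEA permutations, completes in well
under a minute on one CPU.

## Known limitations

* The O/E hazard ratio is biased toward 1 relative to Cox under heavy
  censoring; tests constrain it only to 30% on uncensored exponential arms.
* The single-set GSEA FDR reduces to a permutation tail; with many sets a
  pooled Subramanian-style FDR would be preferable.
* Coamplification uses all samples, not lineage subsets; lineage-restricted
  amplicon structure is not modelled.
* The prioritization rule is a codification of what is, in practice, expert
  triage; it guarantees a deterministic order, not biological primacy.
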