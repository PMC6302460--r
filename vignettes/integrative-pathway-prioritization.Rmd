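---
title: "Integrative pathway prioritization from proteomic and phosphoproteomic data"
author: "intePath maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative pathway prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## Overview

Shotgun proteomics of tumor cohorts measures two complementary layers of
the same biology: protein abundance and site-level phosphorylation. Either
layer alone supports pathway analysis, but each carries its own technical
and biological noise, so single-layer pathway rankings are prone to both
false positives and false negatives. intePath implements an integrative
workflow: differential-abundance calling per layer, combination of the two
layers into method-specific inputs, pathway scoring by three engines of
increasing structural awareness, and a rank-based evaluation harness that
measures how well each method/input combination recovers a curated list of
disease-relevant *target pathways* (positive controls).

```{r quick, eval = FALSE}
library(intePath)
study <- simulateStudy(simConfig(seed = 11))
res <- runPipeline(study$protein, study$phospho, study$collection,
                   mode = "intersection", nPerm = 200, nBoot = 200,
                   seed = 11)
res$report$summary
```

## The statistical workflow

### Differential abundance

Both layers are features-by-samples matrices of log-scale abundances.
Missing values are treated as low-abundance censoring (a value that was
not observed was most plausibly below the detection floor) and imputed
with the minimum observed value, per feature by default
(`imputeMin(scope = "per_feature")`); the stricter matrix-wide minimum is
available via `scope = "global"`. Phosphosites (`GENE_S123` ids) are
collapsed to one row per gene before testing; the default rule keeps the
site with the largest absolute tumor-minus-normal mean difference,
preserving the strongest regulatory signal where sites disagree, with
per-sample averaging as the alternative. Whether to test sites first and
collapse afterwards is a genuinely open choice; collapse-first is the
default because it makes the phosphoprotein table directly comparable to
the protein table, and the site-level route remains available by calling
`differentialTest()` before `collapseSites()`.

Each feature is tested with the classical pooled-variance two-sample
t-test (Welch via `varEqual = FALSE`), and p-values are
Benjamini-Hochberg adjusted across all features of the layer; a feature is
differentially expressed (DE) when adjusted p < 0.05. The fold change is
the difference of group means on the log scale, so fold changes from the
two layers can be summed meaningfully and signs survive. Degenerate rows
with zero variance in both groups cannot be tested: equal means give
p = 1, perfectly separated means give p = 0, and both are flagged in a
`degenerate` column rather than silently propagated.

### Layer integration

`integrateTables()` builds the method-facing input under five modes.
The *intersection* mode takes genes DE in both layers with the sum of
their two log fold changes — the stringent integration that filters
layer-specific noise. The *union* mode (a supported negative control;
noisy by construction) takes genes DE in either layer, with the single
available fold change for singly-DE genes and the sum for doubly-DE ones;
summing rather than averaging keeps it consistent with the intersection
mode. The *full profile* is the summed fold change over every gene
quantified in both layers, sorted descending (ties broken
lexicographically by gene symbol, then stably, for determinism) — the
ranked list consumed by running-sum enrichment. Single-layer modes pass
one layer through unchanged. Protein tables that still carry isoform rows
are collapsed to gene keys by largest absolute fold change
(`collapseGenes()`) before integration.

### Three scoring engines

**Over-representation (ORA).** Each pathway is scored by the
hypergeometric upper tail: with a background of N quantified genes, m of
them in the pathway, n DE genes and k of those in the pathway, p =
P(X >= k), computed by summing exact point masses in log space. The
background universe is the set of quantified genes (the both-layer overlap
for integrated modes, the layer's genes for single-layer modes);
restricting it to pathway-annotated genes is deliberately not the default,
since the quantified universe is the defensible choice for proteomics.

**Running-sum enrichment (GSEA-style).** Walking the ranked profile, the
running sum gains `|s|^p / sum(|s|^p over members)` at member genes and
loses `1/(L-k)` at non-members; the enrichment score ES is the signed
maximum deviation from zero. The exponent defaults to 1 (score-weighted);
0 gives the pure Kolmogorov-Smirnov statistic. The null reshuffles member
labels over the list (`nPerm` = 2000 by default); a gene-label null is
the only option here because the integrated input is a single gene-score
vector, not a sample matrix. The permutation p-value is the add-one
two-sided exceedance of |ES|: the signed-max statistic picks its own
direction, and conditioning the null on the observed sign makes p behave
like Uniform(0, 0.5) under the null — we verified a doubled type-I rate
empirically — so the two-sided count is used to keep the null calibrated.
NES divides ES by the mean absolute same-sign null score. Pathways with
fewer than 3 members in the list are skipped (logged); if every member
score is zero the weights fall back to the unweighted form with a warning.

**Topology-based scoring (SPIA-style).** Pathway topologies are signed
directed graphs; relation types map to weights (+1 activation-like, -1
inhibition-like, configurable). The influence matrix is
`B[i, j] = beta(j -> i) / Nds(j)` with `Nds(j)` the out-degree of j. Gene
perturbation factors solve `PF = dE + B %*% PF` exactly; the net
accumulation `Acc = PF - dE` isolates the propagated part and
`tA = sum(Acc)` summarizes the pathway. Two independent evidence channels
— the hypergeometric pNDE for the DE count and a bootstrap pPERT for tA
(DE-count fold changes drawn without replacement from the pool of all
measured combined fold changes, placed on random members, null centered
at its median, two-sided add-one tail) — combine as
`pG = c - c*log(c)` with `c = pNDE * pPERT`, the tail probability of a
product of two independent uniforms. When `I - B` is singular (e.g. a
feedback loop with unit gain) or its reciprocal condition number falls
below 1e-10, the pathway is flagged and scored on pNDE alone
(pPERT = 1) rather than dropped, so ranking lengths stay stable across
runs; pathways without topology degrade the same way.

### Rank evaluation

Each method's table is ordered by ascending p-value — raw rather than
adjusted, which is order-preserving under Benjamini-Hochberg anyway —
with deterministic tie-breaks (ORA: overlap k descending, then id; GSEA:
|NES| descending, then id; topology: |tA| descending, then id). Raw ranks
are normalized as `ceiling(100 * r / N)`, mapping rank 1 to a value >= 1
and rank N to exactly 100 regardless of collection size; ceiling is the
only rounding that respects that stated range. Target-pathway reports
give five-number summaries of the normalized target ranks per
method/mode; `topKOverlap()` intersects top-K lists across methods, and
`subtypeCompare()` produces all Venn region counts of per-subtype top-K
sets plus per-target ranks. Subtype runs contrast each subtype's tumors
against the shared normal samples (subtype-vs-rest is a trivial variant
the user can build by relabeling).

## The synthetic study

Because real tumor cohorts and a fixed pathway-database release are not
reproducible inputs, every claim the package tests is exercised on
simulated data with known ground truth (`simulateStudy()`).

What the generator emulates: log-scale abundances with per-gene baselines
Normal(mu0, 1); perturbed genes shifted by +/- delta in tumor samples,
with the sign propagated along the pathway topology from the pathway's
first member (breadth-first, member-order tie-breaks; unreached genes stay
positive) so topology scoring has coherent signal to find; the planted
signal split between the layers (fraction lambda to protein, the rest to
phospho, an `overlapFrac` fraction shifted in both); several phosphosites
per gene with fixed site offsets; low-abundance censoring below the
global tau-quantile of each matrix (the MNAR mechanism that justifies
minimum imputation); optional subtype labels with subtype-specific
planted pathways; and — central to the integration question —
*layer-specific decoy pathways*: a `decoyFrac` fraction of pathways per
layer whose members shift by delta in that layer only. Decoys model
pathway-coherent single-omics noise, the reason single-layer pathway
rankings produce false positives; cross-layer integration is exactly the
filter that removes them. Genes claimed by more than one perturbed
pathway keep their first assignment (global planted, then
subtype-planted, then decoys), deterministically.

Defaults (chosen once as a realistic desk-scale study, and kept): 200
pathways of 15-40 genes over a 3000-gene universe; 1.5 expected edges per
gene with activation:inhibition drawn 0.8:0.2; 5 planted pathways;
delta = 2 against unit noise (a clearly detectable but not overwhelming
effect at n = 20 + 20); lambda = 0.5 (signal evenly split);
overlapFrac = 0.3 — some cross-layer redundancy is biologically expected
and, with zero overlap, the DE intersection would be empty by
construction and integration could carry no signal at all;
decoyFrac = 0.1 per layer with decoy magnitude tied to delta (so the
delta = 0 null stays a clean null); 1-4 sites per gene; tau = 0.05
missingness. A balanced 20 vs 20 design replaces the heavily unbalanced
cohort sizes of real tumor/normal studies because a handful of controls
gives the t-test almost no power at this scale; the unbalanced design
remains one `simConfig()` call away.

What the generator does *not* emulate: realistic mass-spectrometry
intensity distributions, batch effects or multiplexing structure,
correlated noise between genes, kinase-substrate coupling between the
layers, or identifier ambiguity. Passing tests therefore demonstrate the
statistical machinery under an idealized signal model, not performance on
real cohort data.

## Numerical and design choices

- Hypergeometric tails are summed in log space (log point masses +
  log-sum-exp), exact to ~1e-13 against direct term summation.
- The enrichment-score permutation loop runs in C++ on R's own RNG, so
  `set.seed()` reproduces results bit-for-bit; the pure-R
  `enrichmentScore()` is the reference implementation the C++ path is
  tested against. On an exact peak/trough tie the positive side wins, in
  both implementations.
- The propagation system is solved by LU decomposition, not iteration;
  iteration to a 1e-10 fixpoint is used as an independent oracle in the
  test suite.
- All ranking tie-breaks are total orders, so every output is
  reproducible byte-for-byte under a fixed seed.
- Pipelines drop features that are missing in every sample (logged)
  before per-feature imputation, which would otherwise have nothing to
  impute from.

## Simulation-study scale

The packaged studies run at 200 pathways x 3000 genes with 200
permutations/bootstraps per pathway (500 for the null-calibration study),
over fixed seed sets of 20 (null calibration) and 50 (planted recovery,
integration-mode comparison, subtype specificity). These sizes are the
package's chosen reference scale: large enough for stable pooled medians
and rates, small enough to re-run routinely. The default `nPerm`/`nBoot`
of 2000 is recommended for real analyses.

## Known limitations

- Running-sum enrichment inherits the signed-max statistic's tie
  convention; antisymmetry under list reversal holds only up to exact
  peak/trough ties.
- Under the decoy noise model, the whole-profile enrichment scorer gains
  little from integration: decoy genes keep signal-scale summed fold
  changes, so only the overlap fraction of planted genes (at ~2*delta)
  separates planted pathways from decoys, and both layers' decoys appear
  in the integrated profile. The DE-intersection methods (ORA and
  topology scoring) filter decoys entirely and benefit strongly. The
  package reports this honestly rather than adjusting the noise model to
  flatter the enrichment scorer.
- Topologies arrive as flat signed edge lists; converting pathway-database
  exports (e.g. KGML) to that format is left to the user.
- Gene identifiers are bare case-sensitive symbols with no aliasing.
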