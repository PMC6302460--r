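# intePath

Integrative pathway prioritization from paired proteomic and
phosphoproteomic tumor/normal data.

Mass-spectrometry studies of tumors quantify both protein abundance and
site-level phosphorylation. Pathway analysis on either layer alone is
noisy; intePath implements and evaluates the integrative alternative:
call differential abundance per layer, combine the layers, score pathways
with three engines, and benchmark every method/input combination by how
highly it ranks literature-curated *target pathways* (positive controls).
A synthetic-data generator with planted, topology-aware pathway signal
makes the whole workflow testable end to end.

## The methods

With a background of `N` quantified genes, `m` in the pathway, `n`
differentially expressed (DE; pooled-variance t-test, Benjamini–Hochberg
adjusted p < 0.05) and `k` of those in the pathway:

- **ORA** — hypergeometric over-representation,
  `p = P(X ≥ k), X ~ Hypergeom(N, m, n)`, on a DE gene list (the
  intersection of the two layers' DE genes with summed log fold changes,
  in the integrated mode).
- **GSEA-style enrichment** — a Kolmogorov–Smirnov running sum over the
  full ranked profile of summed log fold changes: `+|s|^p/Σ|s|^p` at
  member genes, `−1/(L−k)` elsewhere; ES is the signed maximum deviation,
  with a gene-label permutation null (n = 2000 by default) and add-one
  two-sided p-values.
- **SPIA-style topology scoring** — perturbation propagation
  `PF = ΔE + B·PF` with influence matrix `B[i,j] = β(j→i)/N_ds(j)`; net
  accumulation `tA = Σ(PF − ΔE)` gets a bootstrap p-value (`pPERT`),
  combined with the over-representation evidence (`pNDE`) as
  `pG = c − c·ln c`, `c = pNDE·pPERT`.

Rankings are normalized to 1–100 (`ceiling(100·r/N)`, lower is better)
so collections of different sizes are comparable. Integration modes:
`intersection` (the stringent default), `union` (a supported negative
control), `protein_only`, `phospho_only`.

## Worked example

```r
library(intePath)

# a synthetic 200-pathway study with 5 planted pathways, signal split
# between the layers, and layer-specific decoy pathways as noise
study <- simulateStudy(simConfig(seed = 11))

res <- runPipeline(study$protein, study$phospho, study$collection,
                   mode = "intersection", nPerm = 200, nBoot = 200,
                   seed = 11)
res$report$summary
#>   ranking min q1 median q3 max n_missing
#> 1     ora   1  1      2  2   3         0
#> 2    gsea   1  3      4  7  30         0
#> 3    spia   1  1      2  2   3         0
```

The summary gives the five-number spread of the normalized ranks of the
five planted (target) pathways under each method: over-representation and
topology scoring place them at median rank 2 of 100, the running-sum
scorer at 4 — the planted signal is recovered at the top of the ranking
by all three engines. `topKOverlap(res$rankings, 50)` lists the pathways
all methods agree on; `runSubtypeAnalysis()` repeats the workflow per
tumor subtype against the shared normals and compares top-20 lists.

A thin command-line wrapper is installed with the package:

```sh
Rscript inst/scripts/intepath simulate --seed 3 --out data/
Rscript inst/scripts/intepath run --protein data/protein.tsv \
    --phospho data/phospho.tsv --annotations data/samples.tsv \
    --gmt data/pathways.gmt --edges data/edges.tsv \
    --targets data/targets.txt --seed 3 --out run/
```

The twelve literature-curated breast-cancer target pathways ship as
`inst/extdata/targets_breast.txt` (`readTargets()`).

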