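# teaheterosis

Analysis toolkit for **volatile heterosis** (hybrid vigor of aroma
compounds) and **expression-level dominance** in two-parent / two-hybrid
plant designs, built around the tea plant (*Camellia sinensis*) cross
HD × TGY and its F1 hybrids JGY and HGY. It is aimed at breeders and
transcriptomics analysts who have (a) GC-MS volatile concentrations and
(b) a replicated FPKM-like expression matrix for the four genotypes, and
want the standard quantitative readouts of hybrid vigor.

## What it computes

**Heterosis indices.** For a trait with hybrid value F1 and parental values
P1, P2:

- mid-parent heterosis MPV (%) = (F1 − MP)/MP × 100, MP = (P1 + P2)/2
- over-high-parent heterosis OPV (%) = (F1 − HP)/HP × 100, HP = max(P1, P2)

with internal-standard GC-MS semi-quantification
(`quantify_internal_standard()`), compound-class sums (`class_sum()`), and
compact letter displays from pairwise Welch t-tests (`letter_groups()`).

**Expression-level dominance.** Each gene gets six pairwise calls among
{parent1, parent2, hybrid1, hybrid2} — *higher* means Welch p < 0.05 on
log2(x + 0.1) **and** fold change ≥ 2 — and is assigned to one of ten
classes: C1–C4 additive (hybrids between the parents), C5–C6 higher-parent
dominance, C7–C8 lower-parent dominance, C9/C10 up-/down-regulated
overdominance (`classify_matrix()`, `summarize_patterns()`).

**Co-expression screening.** A deterministic batch self-organizing map
(default 2×4 grid) clusters z-scored genotype-mean profiles of the
F1-upregulated genes; transcription factors sharing a module with anchor
pathway genes are candidate regulators, ranked by Pearson correlation with
exact small-n p-values (`train_som()`, `co_module_candidates()`,
`correlation_p()`).

**Enrichment.** Generic over-representation analysis of a gene set against
GMT term maps: upper-tail hypergeometric p-values with Benjamini–Hochberg
FDR (`ora()`).

**Synthetic ground truth.** `generate_expression()` and
`generate_volatile_table()` simulate the full design with genes planted in
known classes and traits with known MPV/OPV, so every stage is testable
end to end.

## Worked example

Heterosis of the published volatile class sums for the HD × TGY cross
(shipped in `inst/extdata/`):

```r
library(teaheterosis)
sums <- read.delim(system.file("extdata", "tea_volatile_class_sums.tsv",
                               package = "teaheterosis"))
ht <- volatile_heterosis_table(sums[, c("class", "genotype", "value")],
                               hybrids = c("HGY", "JGY"),
                               parents = c("TGY", "HD"))
ht$MPV <- round(ht$MPV, 1); ht$OPV <- round(ht$OPV, 1)
print(ht, row.names = FALSE)
#>  hybrid         class      F1      MP     HP   MPV  OPV
#>     HGY           GLV  432.93 342.425 400.67  26.4  8.1
#>     HGY   monoterpene 1500.79 841.565 916.70  78.3 63.7
#>     HGY sesquiterpene   42.58  19.230  22.28 121.4 91.1
#>     JGY           GLV  584.62 342.425 400.67  70.7 45.9
#>     JGY   monoterpene 1555.90 841.565 916.70  84.9 69.7
#>     JGY sesquiterpene   24.98  19.230  22.28  29.9 12.1
```

Every MPV and OPV is positive: both hybrids out-produce the mid-parent and
the better parent for all three volatile classes — e.g. HGY accumulates 78.3%
more monoterpenes than the parental average and 63.7% more than its better
parent.

Classification of a simulated 1000-gene matrix with known planted classes:

```r
lm <- generate_expression(simulation_config(n_genes = 1000, seed = 42))
asg <- classify_matrix(lm$matrix)
summarize_patterns(asg)$category_fractions
#>                 category count pct_of_all pct_of_classified pct_of_non_additive
#>                 additive   320         32                40                  NA
#>  higher-parent dominance   160         16                20            33.33333
#>   lower-parent dominance   160         16                20            33.33333
#>         up-overdominance    80          8                10            16.66667
#>       down-overdominance    80          8                10            16.66667
#>             unclassified   200         20                NA                  NA
```

which recovers 100% of the planted categories at the default noise level
(CV 0.05, fold 4).

## Analysis workflow

The `analysis/` directory holds the numbered drivers of the full study —
simulate the design, compute the volatile heterosis table, classify and
summarize expression patterns, screen TFs by SOM co-modules, and run
enrichment — each writing its tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_volatile_heterosis.R
Rscript analysis/03_classify_patterns.R
Rscript analysis/04_som_screening.R
Rscript analysis/05_enrichment.R
```

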