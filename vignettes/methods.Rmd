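---
title: "Methods: volatile heterosis and expression-level dominance in hybrid tea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: volatile heterosis and expression-level dominance in hybrid tea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teaheterosis)
```

# The scientific setting

Heterosis (hybrid vigor) is the phenomenon in which an F1 hybrid outperforms
its parents. In aroma breeding of tea (*Camellia sinensis*), the traits of
interest are the concentrations of green leaf volatiles (GLVs, C6
aldehydes/alcohols/esters from the lipoxygenase pathway) and of mono- and
sesquiterpenes (from the MEP/MVA isoprenoid pathways), measured by GC-MS,
and the transcriptome-wide distribution of gene expression between two
parents and two F1 hybrids. This package implements the quantitative
machinery for such a 2-parent / 2-hybrid design: heterosis indices for
measured traits, a statistical classifier of per-gene expression inheritance
modes, SOM-based co-expression screening of transcription factors, and
over-representation analysis — together with a synthetic-data generator
whose ground truth exercises every stage.

# Heterosis indices

For a trait with hybrid value $F_1$ and parental values $P_1, P_2$:

* mid-parent heterosis, $\mathrm{MPV}\,(\%) = \dfrac{F_1 - \mathrm{MP}}{\mathrm{MP}} \times 100$
  with $\mathrm{MP} = (P_1 + P_2)/2$;
* over-high-parent heterosis, $\mathrm{OPV}\,(\%) = \dfrac{F_1 - \mathrm{HP}}{\mathrm{HP}} \times 100$
  with $\mathrm{HP} = \max(P_1, P_2)$.

Because $(F_1 - x)/x$ decreases in $x$ and $\mathrm{HP} \ge \mathrm{MP}$ for
positive traits, $\mathrm{MPV} \ge \mathrm{OPV}$ always; the suite checks
this on fuzzed inputs. Indices operate on trait means; replicate SDs are
carried for reporting but not propagated into the percentages, which is how
such tables are conventionally printed.

Volatile concentrations come from internal-standard semi-quantification:
`quantify_internal_standard()` scales the target/standard peak-area ratio by
the spiked standard mass (default 1.5 µg, i.e. 15 µL of a 100 ppm ethyl
decanoate solution) per gram of sample. `class_sum()` totals per-compound
mean concentrations within a compound class, and `letter_groups()` produces
a compact letter display from pairwise two-sided Welch t-tests using the
insert-and-absorb algorithm, scanning groups by decreasing mean. Raw
p-values are thresholded at $\alpha = 0.05$ by default (a Bonferroni flag
exists) because printed volatile tables conventionally letter on raw
pairwise significance.

# Expression-level dominance classification

Each gene is measured in four genotype groups (parent1, parent2, hybrid1,
hybrid2) with at least two replicates each. For every ordered pair of
groups, the gene gets a call in {higher, lower, similar}: *higher* requires
a two-sided Welch t-test on $\log_2(x + c)$ with $p < \alpha$ **and** a
pseudocounted mean fold change $\ge$ `fc_min`. Defaults are $\alpha = 0.05$,
`fc_min` $= 2$, pseudocount $c = 0.1$ (FPKM-scale zeros are common; $c$ is
configurable and should scale with the expression units). The p-value is
pluggable, so calls can instead be driven by a count-model test (e.g. a
DESeq-style analysis) with only the fold gate applied on top.

The six calls jointly decide the cluster, in this order:

1. both hybrids higher than both parents → C9 (up-regulated overdominance);
2. both hybrids lower than both parents → C10 (down-regulated overdominance);
3. parents differ, both hybrids similar to the high parent and different
   from the low parent → C5/C6 (higher-parent dominance; C5 when parent1 is
   the high parent, C6 when parent2 is);
4. the mirror case on the low parent → C7/C8 (lower-parent dominance);
5. parents differ and each hybrid is strictly between them → C1–C4
   (additive; C1/C3 when the hybrids also differ from each other, C2/C4
   when they are statistically equal, with the pair member chosen by which
   parent is high);
6. anything else → unclassified. In particular, hybrids with conflicting
   evidence (one overdominant, one additive) are unclassified, because every
   mode is defined jointly over both hybrids.

Zero-variance groups arise in noise-free synthetic data; there the test is
degenerate and the classifier sets $p = 0$ when the means differ and $p = 1$
when they are equal, which preserves the intuitive calls. On such data the
classifier provably reduces to a pure mean-ordering rule, and the suite
checks it against an independent ordering oracle over an exhaustive grid of
all $4^4$ mean combinations.

`summarize_patterns()` reports counts and percentages at cluster and
category level against three denominators — all genes, classified genes
(C1–C10) and non-additive genes (C5–C10) — because published summaries mix
these bases and the choice materially changes the percentages.

# Synthetic data: what it emulates and what it does not

`generate_expression()` plants each gene in one of the ten classes (or
"none") at configurable proportions. Group means are geometric ladders of
the baseline with ratio `effect_fold` (e.g. C5 is $(f, 1, f, f) \times$
baseline in role order parent1, parent2, hybrid1, hybrid2; C1 uses
$f^3, 1, f^2, f$ so each adjacent pair of the additive ordering is separated
by a full fold). Replicates are log-normal around the group means with a
fixed coefficient of variation, the natural noise model for positive,
right-skewed expression and concentration data: the CV is interpretable and
values stay positive. All draws flow from one seeded generator, so output is
bit-reproducible.

Defaults are chosen to mirror a realistic bulk RNA-seq validation setting:
3 replicates (the common design), baseline 50 expression units, effect fold
4, CV 0.05 between biological replicates of a clonal plant, and 2000 genes
for the recovery study (10 seeds run in well under a minute). Real data
differ in ways the generator does not model: gene-specific dispersion,
correlated genes, library-size artifacts, and mean–variance coupling of
count data. Passing recovery tests therefore demonstrates that the decision
rules are implemented correctly and have the stated power under the stated
noise, not that any particular recovery rate will hold on real FPKM
matrices.

# SOM co-expression modules

Genes up-regulated in the F1 generation (categories C5, C6, C9 by default)
are clustered on a small self-organizing map (default 2×4 = 8 modules) of
z-scored 4-dimensional genotype-mean profiles. The implementation is a batch
SOM: each epoch assigns every gene to its best-matching unit and replaces
each codebook vector by the neighborhood-weighted mean of the data, with a
Gaussian neighborhood whose radius decays linearly to zero, so the final
epochs are a k-means refinement and training is deterministic.

Two numerical choices matter and were settled by their failure modes:

* **Initialization** is farthest-point sampling: the first codebook vector
  is an input profile drawn with the run seed, each further one the profile
  farthest from those already chosen. Uniform random sampling routinely
  seeds two units inside one cluster and none in another, and the folded map
  cannot always recover — on an 8-prototype benchmark it merged clusters for
  roughly a third of seeds. Maximin seeding removes that failure while
  remaining data-driven and seeded.
* **Initial radius** defaults to 0.6 grid units, giving adjacent units about
  a quarter of the central weight at the start. A large initial radius (the
  usual choice when the goal is topographic ordering of a big map) smooths
  all codebooks toward the grand mean early in training and can fold
  well-separated clusters onto one unit of a small grid. Module discovery on
  an 8-unit grid prioritizes cluster fidelity over global topography, so the
  gentler default is appropriate; it is a parameter, not a constant.

Ties in best-matching-unit assignment break to the lowest unit index.
Transcription-factor screening is a set operation: for each anchor gene,
the TFs (an input id list — TF annotation is upstream of this package)
assigned to the anchor's module. Correlations between anchor and TF
profiles use the 4 genotype means, and `correlation_p()` converts Pearson's
$r$ to a two-sided p-value via $t = r\sqrt{n-2}/\sqrt{1-r^2}$ with $n-2$
degrees of freedom, exact at these tiny $n$ (e.g. $r = 0.978$, $n = 4$
gives $p = 0.022$).

# Over-representation analysis

`ora()` tests a query gene set against user-supplied term→gene maps (GMT
format) with the upper-tail hypergeometric probability
$P(X \ge k)$ for $X \sim \mathrm{Hypergeom}(N, K, q)$, equivalent to
one-sided Fisher's exact test, and adjusts across all tested terms with
Benjamini–Hochberg. The "gene ratio" column is the overlap count, matching
the integer layout of published GO tables. Terms below `min_term_size`
(default 2) are skipped to avoid degenerate tails; no annotation database is
shipped or assumed.

# qPCR utility

`delta_delta_ct()` implements relative quantification:
$\Delta\Delta C_T = (C_{T,\mathrm{target}} - C_{T,\mathrm{ref}})_\mathrm{test}
- (C_{T,\mathrm{target}} - C_{T,\mathrm{ref}})_\mathrm{calibrator}$ and the
relative expression $2^{-\Delta\Delta C_T}$.

# Design choices on genuinely open points

* **Pairwise test.** The classifier thresholds raw $p < 0.05$ with fold
  change $\ge 2$; BH-adjusted q-values and other fold cutoffs are options
  rather than defaults, and externally computed p-values plug in directly.
* **C1–C4 sub-enumeration.** Only the additive *category* is fixed by the
  definitions; the split into four clusters (hybrids ordered vs equal ×
  which parent is high) is one defensible enumeration that yields exactly
  ten classes, and category-level results are insensitive to it.
* **Three denominators** in pattern summaries, as above.
* **Published class sums as inputs.** Where a published table prints both
  per-compound means and class sums, the printed sums are treated as the
  authoritative trait values for heterosis (per-compound rows are rounded,
  so recomputed sums can drift by a few units).

# Problem sizes and determinism

The validation suite runs entirely on synthetic data: 2000-gene matrices
across 10 seeds for recovery, exhaustive $4^4$ mean grids for the
zero-noise oracle, 240 profiles for SOM purity, backgrounds up to 60 genes
for exact hypergeometric enumeration, and $10^4$ fuzzed triples for the
MPV/OPV inequality. Every stochastic component takes an explicit integer
seed and restores the caller's RNG state, so identical inputs and seeds give
byte-identical outputs, including the TSV/JSON artifacts of
`run_pipeline()`.

# Known limitations

* The classifier assumes independent replicate groups and tests each gene
  marginally; it does not borrow strength across genes the way count models
  do, and with 2–3 replicates its power comes from the fold-change gate as
  much as the t-test.
* SOM module identity (unit numbering) is meaningful only within one run;
  compare memberships, not labels, across configurations.
* ORA treats genes as exchangeable draws; term overlap and gene length
  biases are out of scope.
* The generator plants clean single-class signals; it does not emulate
  partially penetrant or mixed inheritance modes.
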