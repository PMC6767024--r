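#!/usr/bin/env Rscript
# Simulate the study design: a 4-genotype x 3-replicate expression matrix
# with genes planted in the ten dominance/additivity classes, a volatile
# table with known heterosis, and a term map with a planted enriched term.
# Writes everything under results/simulated/ for the later stages.

suppressPackageStartupMessages(library(teaheterosis))
out <- "results/simulated"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 2024

cfg <- simulation_config(n_genes = 2000, effect_fold = 4, replicate_cv = 0.05,
                         n_replicates = 3, seed = seed)
lm <- generate_expression(cfg)
write_expression(lm$matrix, file.path(out, "expression.tsv"),
                 file.path(out, "sample_sheet.tsv"))
write_tsv(data.frame(gene_id = names(lm$truth), class = unname(lm$truth)),
          file.path(out, "truth.tsv"))
cat(sprintf("simulated %d genes x %d samples; planted classes:\n",
            length(lm$matrix$gene_ids), length(lm$matrix$sample_ids)))
print(table(lm$truth))

vt <- generate_volatile_table(
  list(GLV = c(parent1 = 400, parent2 = 280, hybrid1 = 430, hybrid2 = 580),
       monoterpene = c(parent1 = 770, parent2 = 920, hybrid1 = 1500, hybrid2 = 1560),
       sesquiterpene = c(parent1 = 22, parent2 = 16, hybrid1 = 43, hybrid2 = 25)),
  cv = 0.1, n_replicates = 3, seed = seed, n_compounds = 3)
write_tsv(vt, file.path(out, "volatiles.tsv"))
cat(sprintf("simulated volatile table: %d rows\n", nrow(vt)))
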