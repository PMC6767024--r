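#!/usr/bin/env Rscript
# SOM co-module screening: cluster the F1-upregulated genes (higher-parent
# dominance and up-overdominance patterns) on a 2x4 grid of z-scored
# genotype-mean profiles, list transcription factors sharing a module with
# anchor pathway genes, and correlate anchor and TF profiles.

suppressPackageStartupMessages(library(teaheterosis))
em <- read_expression("results/simulated/expression.tsv",
                      "results/simulated/sample_sheet.tsv")
truth <- read.delim("results/simulated/truth.tsv")

# role-play the screening inputs: two C9 genes as pathway anchors, a set of
# C5/C6/C9 genes as the TF list (TF identity is an input, not an annotation)
up <- truth$gene_id[truth$class %in% c("C5", "C6", "C9")]
anchors <- truth$gene_id[truth$class == "C9"][1:2]
tf_ids <- setdiff(up, anchors)[1:40]

res <- run_pipeline(em, "results/som", config = run_config(seed = 2024),
                    anchors = anchors, tf_ids = tf_ids)
cat(sprintf("modules occupied: %d of %d units\n",
            sum(res$modules$counts > 0), length(res$modules$counts)))
for (a in anchors)
  cat(sprintf("anchor %s shares its module with %d of %d TFs\n",
              a, length(res$candidates[[a]]), length(tf_ids)))
if (!is.null(res$correlations)) {
  long <- correlation_long(res$correlations)
  sig <- long[long$p < 0.05, ]
  cat(sprintf("significant anchor/TF profile correlations (n=4): %d of %d pairs\n",
              nrow(sig), nrow(long)))
}
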