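#!/usr/bin/env Rscript
# Stage 1 — synthetic study generation.
#
# Emulates two independent RNA-seq studies of spleen gene expression under a
# binary stress condition: 300 genes per study, 15 and 10 birds per group
# (a pooled 50-individual dataset), 19 planted condition-responsive genes
# shared by both studies (|log2 fold change| 4, alternating direction, NB
# dispersion 0.05). Writes the count matrices, condition sidecars and the
# planted truth under results/data/.

suppressPackageStartupMessages(library(stressnet))

master_seed <- 20260923L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

design <- two_study_design(
  n_genes = 300,
  n_samples_per_group = c(15, 10),
  de_gene_ids = paste0("gene", 1:19),
  log2_fold_change = 4,
  nb_dispersion = 0.05,
  seed = master_seed
)
sim <- simulate_two_study_counts(design)

for (s in 1:2) {
  cm <- sim[[paste0("study", s)]]
  write_count_matrix(cm,
                     file.path(out, sprintf("study%d_counts.tsv", s)),
                     file.path(out, sprintf("study%d_samples.tsv", s)))
  cat(sprintf("study %d: %d genes x %d samples (%d planted DE)\n",
              s, nrow(cm$counts), ncol(cm$counts), length(sim$truth)))
}
writeLines(sim$truth, file.path(out, "planted_genes.txt"))
cat("planted truth written to", file.path(out, "planted_genes.txt"), "\n")
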