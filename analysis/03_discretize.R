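#!/usr/bin/env Rscript
# Stage 3 — pooled quantile discretization.
#
# Expression of the shared genes is pooled across all 50 samples of both
# studies, cut into low/medium/high at the tertiles of each gene's pooled
# log-CPM vector, and the binary stress condition is appended as one extra
# variable.

suppressPackageStartupMessages(library(stressnet))

data_dir <- "results/data"
out <- "results"
shared <- readLines(file.path(out, "shared_genes.txt"))

studies <- lapply(1:2, function(s) {
  cm <- read_count_matrix(file.path(data_dir, sprintf("study%d_counts.tsv", s)),
                          file.path(data_dir, sprintf("study%d_samples.tsv", s)))
  filter_low_counts(cm, min_cpm = 1, min_samples = 2)
})

ds <- build_discrete_dataset(lapply(studies, log_cpm, prior_count = 0.5),
                             shared, n_bins = 3)
ds <- append_condition(ds, unlist(lapply(studies, `[[`, "condition")))
write_discrete_dataset(ds, file.path(out, "discrete_dataset.tsv"),
                       file.path(out, "discrete_dataset.json"))
cat(sprintf("discrete dataset: %d variables x %d samples (incl. condition)\n",
            length(ds$variables), ncol(ds$data)))
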