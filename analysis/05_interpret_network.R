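#!/usr/bin/env Rscript
# Stage 5 — interpretation of the final network.
#
# Two complementary views of which genes sit closest to the stress
# condition: the Markov blanket of the condition node (parents, children,
# spouses) and the condition's community under divisive edge-betweenness
# clustering with the modularity cut.

suppressPackageStartupMessages(library(stressnet))

out <- "results"
ds_nodes <- read_discrete_dataset(file.path(out, "discrete_dataset.tsv"),
                                  file.path(out, "discrete_dataset.json"))$variables
network <- read_edge_list(file.path(out, "final_network.tsv"),
                          nodes = ds_nodes)

blanket <- markov_blanket(network, "condition")
cat("Markov blanket of the condition:",
    paste(blanket$blanket, collapse = ", "), "\n")
cat("  children:", paste(blanket$children, collapse = ", "), "\n")
cat("  parents: ", paste(blanket$parents, collapse = ", "), "\n")
cat("  spouses: ", paste(blanket$spouses, collapse = ", "), "\n")

linked <- unique(c(network$edges[, 1], network$edges[, 2]))
gn <- girvan_newman(ugraph(linked, network$edges))
cat(sprintf("communities: %d (modularity %.4f)\n",
            gn$n_communities, gn$modularity))
comm <- if ("condition" %in% names(gn$membership)) {
  condition_community(gn, "condition")
} else character(0)
cat("condition community:", paste(comm, collapse = ", "), "\n")

ann <- data.frame(node = ds_nodes,
                  community = ifelse(ds_nodes %in% names(gn$membership),
                                     gn$membership[ds_nodes], NA),
                  in_blanket = ds_nodes %in% blanket$blanket)
write.table(ann, file.path(out, "node_annotation.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(target = "condition", parents = blanket$parents,
       children = blanket$children, spouses = blanket$spouses,
       blanket = blanket$blanket, n_communities = gn$n_communities,
       modularity = gn$modularity, community_of_target = comm),
  file.path(out, "interpretation.json"), auto_unbox = FALSE, digits = NA)
cat("annotation written to", file.path(out, "node_annotation.tsv"), "\n")
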