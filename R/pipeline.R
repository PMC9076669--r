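#' Pipeline configuration
#'
#' Collects every stage's knobs. Full-scale defaults are 3 expression bins,
#' top 100 networks per run, 1000 runs in 10 groups of 100, and an arc-weight
#' threshold of 50; `n_runs`, `group_size` and the search budget are scaled
#' down for desk-scale runs.
#'
#' @param min_cpm,min_samples low-count filter (see [filter_low_counts()]).
#' @param prior_count log-CPM pseudo-count.
#' @param alpha,max_n DE selection cutoffs (see [top_genes()]).
#' @param n_bins expression categories (see [discretize_quantile()]).
#' @param search a [search_config()].
#' @param n_runs ensemble size.
#' @param group_size networks per consensus group (`n_runs` divisible by it).
#' @param threshold arc-weight selection threshold on the group scale.
#' @param rule cross-group combination rule (see [select_arcs()]).
#' @param majority_fraction within-run consensus threshold. The pipeline
#'   default is 0.3 rather than a strict majority: BDe scoring gives
#'   Markov-equivalent structures identical scores, so a reversible arc's
#'   two directions each hover near half of a run's top networks and a
#'   strict 0.5 cut can drop the adjacency entirely; 0.3 keeps it in at
#'   least one direction and leaves the decision to the grouped cross-run
#'   weighting, which is the step that actually aggregates evidence.
#' @param target_node node whose blanket/community is interpreted.
#' @param master_seed integer master seed for all stages.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(min_cpm = 1, min_samples = 2, prior_count = 0.5,
                            alpha = 0.05, max_n = NULL, n_bins = 3,
                            search = search_config(),
                            n_runs = 1000, group_size = 100, threshold = 50,
                            rule = "mean", majority_fraction = 0.3,
                            target_node = "condition", master_seed = 1L) {
  if (n_runs %% group_size != 0) stop("n_runs must be divisible by group_size")
  if (threshold <= 0 || threshold > group_size) {
    stop("threshold must be in (0, group_size]")
  }
  structure(list(min_cpm = min_cpm, min_samples = min_samples,
                 prior_count = prior_count, alpha = alpha, max_n = max_n,
                 n_bins = n_bins, search = search, n_runs = n_runs,
                 group_size = group_size, threshold = threshold, rule = rule,
                 majority_fraction = majority_fraction,
                 target_node = target_node,
                 master_seed = as.integer(master_seed)),
            class = "pipeline_config")
}

#' Run the full pipeline on a list of count studies
#'
#' Stages: per-study DE selection (filter, log-CPM, moderated t, top genes)
#' -> cross-study intersection -> pooled quantile discretization -> binary
#' condition appended -> ensemble structure learning -> grouped arc weights
#' -> final-arc selection -> Markov blanket and communities of the target
#' node. Every stage writes its artifact under `out_dir` and the choices
#' actually applied are recorded in `manifest.json`.
#'
#' @param studies list of [count_matrix()] objects (>= 1).
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory (created if needed); `NULL` to skip all
#'   file artifacts.
#' @return list with `gene_stats` (per study), `selected` (per-study gene
#'   lists), `genes` (intersection), `dataset`, `ensemble`, `weights`,
#'   `network`, `blanket`, `communities`, `community_of_target`.
#' @export
run_pipeline <- function(studies, cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"), length(studies) >= 1)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(fn, ...) if (!is.null(out_dir)) fn(...)

  # stage 1-2: per-study DE statistics and top-gene lists
  filtered <- lapply(studies, filter_low_counts,
                     min_cpm = cfg$min_cpm, min_samples = cfg$min_samples)
  logmats <- lapply(filtered, log_cpm, prior_count = cfg$prior_count)
  stats <- lapply(seq_along(filtered), function(i) {
    fit_moderated_t(logmats[[i]], filtered[[i]]$condition)
  })
  selected <- lapply(stats, top_genes, alpha = cfg$alpha, max_n = cfg$max_n)
  for (i in seq_along(stats)) {
    emit(write.table, stats[[i]],
         file.path(out_dir, sprintf("gene_stats_study%d.tsv", i)),
         sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # stage 3: intersection across studies, in study-1 order
  genes <- Reduce(intersect_gene_lists, selected)
  if (length(genes) < 2) {
    stop("pipeline stage 'intersect': fewer than 2 genes shared across ",
         "studies; nothing to learn on")
  }
  emit(writeLines, genes, file.path(out_dir, "shared_genes.txt"))

  # stage 4: pooled discretization + condition variable
  ds <- build_discrete_dataset(logmats, genes, n_bins = cfg$n_bins)
  cond <- unlist(lapply(filtered, `[[`, "condition"))
  ds <- append_condition(ds, cond)
  emit(write_discrete_dataset, ds,
       file.path(out_dir, "discrete_dataset.tsv"),
       file.path(out_dir, "discrete_dataset.json"))

  # stage 5: ensemble structure learning
  ensemble <- run_ensemble(ds, cfg$search, cfg$n_runs,
                           derive_seed(cfg$master_seed, 1000L),
                           cfg$majority_fraction)

  # stage 6: grouped arc weights
  weights <- group_and_weight(ensemble, cfg$group_size)
  emit(write_arc_weights, weights, file.path(out_dir, "arc_weights.tsv"))

  # stage 7: final network
  network <- select_arcs(weights, cfg$threshold, nodes = ds$variables,
                         rule = cfg$rule)
  emit(write_edge_list, network, file.path(out_dir, "final_network.tsv"))
  emit(write_graphml, network, file.path(out_dir, "final_network.graphml"))
  emit(writeLines, network$isolated, file.path(out_dir, "isolated_nodes.txt"))

  # stage 8: interpretation
  blanket <- if (cfg$target_node %in% network$all_nodes) {
    markov_blanket(network, cfg$target_node)
  } else NULL
  communities <- if (length(network$nodes) > 0) {
    girvan_newman(skeleton(network))
  } else NULL
  comm_target <- if (!is.null(communities) &&
                     cfg$target_node %in% names(communities$membership)) {
    condition_community(communities, cfg$target_node)
  } else character(0)
  if (!is.null(out_dir)) {
    ann <- data.frame(
      node = network$all_nodes,
      community = if (is.null(communities)) NA_integer_ else
        unname(communities$membership[network$all_nodes]),
      in_blanket = network$all_nodes %in% (blanket$blanket %||% character(0)))
    write.table(ann, file.path(out_dir, "node_annotation.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(target = cfg$target_node,
           parents = blanket$parents, children = blanket$children,
           spouses = blanket$spouses, blanket = blanket$blanket,
           n_communities = communities$n_communities,
           modularity = communities$modularity,
           community_of_target = comm_target),
      file.path(out_dir, "interpretation.json"), auto_unbox = FALSE,
      digits = NA, null = "null")
    manifest <- list(
      master_seed = cfg$master_seed,
      n_studies = length(studies),
      de = list(min_cpm = cfg$min_cpm, min_samples = cfg$min_samples,
                prior_count = cfg$prior_count, alpha = cfg$alpha,
                max_n = cfg$max_n,
                n_selected = vapply(selected, length, integer(1)),
                prior_df = vapply(stats, attr, numeric(1), "prior_df")),
      n_shared_genes = length(genes),
      n_bins = cfg$n_bins,
      search = unclass(cfg$search),
      ensemble = list(n_runs = cfg$n_runs, group_size = cfg$group_size,
                      threshold = cfg$threshold, rule = cfg$rule,
                      majority_fraction = cfg$majority_fraction),
      ambiguity_resolutions = list(
        normalization = "library-size CPM (no TMM)",
        discretization = "pooled across studies, type-7 quantiles, ties down",
        consensus_rule = paste0(cfg$rule, " weight >= ", cfg$threshold),
        condition_constraints = "none"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  }
  list(gene_stats = stats, selected = selected, genes = genes, dataset = ds,
       ensemble = ensemble, weights = weights, network = network,
       blanket = blanket, communities = communities,
       community_of_target = comm_target)
}
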