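#' Run an ensemble of annealed searches
#'
#' Each run uses its own sub-seed derived from `master_seed` and is reduced
#' to a single consensus graph by [consensus_of_top()]. At full scale this
#' is 1000 runs; the scale is fully configurable.
#'
#' @param data a [discrete_dataset()].
#' @param cfg a [search_config()] (its `seed` field is ignored; run seeds are
#'   derived).
#' @param n_runs number of independent searches (>= 1).
#' @param master_seed integer master seed.
#' @param majority_fraction passed to [consensus_of_top()].
#' @return list of `digraph` consensus networks, in run order.
#' @export
run_ensemble <- function(data, cfg, n_runs, master_seed,
                         majority_fraction = 0.5) {
  stopifnot(n_runs >= 1)
  lapply(seq_len(n_runs), function(i) {
    run_cfg <- cfg
    run_cfg$seed <- derive_seed(master_seed, i)
    consensus_of_top(simulated_annealing_search(data, run_cfg),
                     majority_fraction)
  })
}

#' Group consensus networks and count arc occurrences
#'
#' Splits the ensemble, in run order, into consecutive groups of
#' `group_size` networks. Within each group every arc seen in any member is
#' scored by the number of member networks containing it (the full-scale
#' setting, groups of 100, gives weights between 1 and 100).
#'
#' @param networks list of `digraph` objects (length divisible by
#'   `group_size`).
#' @param group_size networks per group.
#' @return list of `arc_weights` objects: `group`, and `arcs` (data frame
#'   `parent`, `child`, `weight`).
#' @export
group_and_weight <- function(networks, group_size) {
  n <- length(networks)
  if (n == 0 || n %% group_size != 0) {
    stop("number of networks (", n, ") not divisible by group size (",
         group_size, ")")
  }
  lapply(seq_len(n / group_size), function(gi) {
    members <- networks[((gi - 1) * group_size + 1):(gi * group_size)]
    counts <- list()
    for (net in members) {
      e <- net$edges
      if (nrow(e) == 0) next
      for (k in paste(e[, 1], e[, 2], sep = "\r")) {
        counts[[k]] <- (counts[[k]] %||% 0L) + 1L
      }
    }
    if (length(counts) == 0) {
      arcs <- data.frame(parent = character(0), child = character(0),
                         weight = integer(0), stringsAsFactors = FALSE)
    } else {
      pc <- do.call(rbind, strsplit(names(counts), "\r", fixed = TRUE))
      arcs <- data.frame(parent = pc[, 1], child = pc[, 2],
                         weight = unname(unlist(counts)),
                         stringsAsFactors = FALSE)
      arcs <- arcs[order(arcs$parent, arcs$child), , drop = FALSE]
      rownames(arcs) <- NULL
    }
    structure(list(group = gi, group_size = group_size, arcs = arcs),
              class = "arc_weights")
  })
}

#' Select the final network from grouped arc weights
#'
#' The default rule averages each arc's weight across all groups (an arc
#' absent from a group contributes 0 there) and keeps arcs whose mean weight
#' is `>= threshold` — the inclusive rule, so a mean exactly at the
#' threshold is selected. The alternative `rule = "groups"` keeps arcs
#' reaching `>= threshold` in at least `groups_required` groups. If both
#' directions of an edge survive, only the direction with the higher mean
#' weight is kept (ties go to the lexicographically smaller parent, with a
#' message). Variables left without any selected arc are excluded from the
#' network's node list but reported as isolated.
#'
#' @param matrices list of `arc_weights` from [group_and_weight()].
#' @param threshold selection threshold on the group-scale weight (full
#'   scale: 50 of 100).
#' @param nodes full variable roster (so isolated nodes can be reported);
#'   defaults to the nodes seen in any arc.
#' @param rule `"mean"` (default) or `"groups"`.
#' @param groups_required for `rule = "groups"`: minimum number of
#'   qualifying groups (default: majority of groups).
#' @return object of class `final_network`: `nodes` (non-isolated), `arcs`
#'   (data frame `parent`, `child`, `mean_weight`), `all_nodes`, `isolated`,
#'   and the selection `rule` used.
#' @export
select_arcs <- function(matrices, threshold, nodes = NULL,
                        rule = c("mean", "groups"), groups_required = NULL) {
  rule <- match.arg(rule)
  stopifnot(length(matrices) >= 1, threshold > 0)
  n_groups <- length(matrices)
  if (is.null(groups_required)) groups_required <- ceiling(n_groups / 2)

  long <- do.call(rbind, lapply(matrices, function(aw) aw$arcs))
  if (is.null(long) || nrow(long) == 0) {
    tab <- data.frame(parent = character(0), child = character(0),
                      mean_weight = numeric(0), n_groups_hit = integer(0))
  } else {
    key <- paste(long$parent, long$child, sep = "\r")
    mean_w <- tapply(long$weight, key, sum) / n_groups
    hits <- tapply(long$weight, key, function(w) sum(w >= threshold))
    pc <- do.call(rbind, strsplit(names(mean_w), "\r", fixed = TRUE))
    tab <- data.frame(parent = pc[, 1], child = pc[, 2],
                      mean_weight = as.numeric(mean_w),
                      n_groups_hit = as.integer(hits),
                      stringsAsFactors = FALSE)
  }
  sel <- if (rule == "mean") tab$mean_weight >= threshold else
    tab$n_groups_hit >= groups_required
  tab <- tab[sel, , drop = FALSE]

  # keep one direction per edge: higher mean weight wins, lexicographically
  # smaller parent on ties
  if (nrow(tab) > 1) {
    und <- ifelse(tab$parent < tab$child,
                  paste(tab$parent, tab$child, sep = "\r"),
                  paste(tab$child, tab$parent, sep = "\r"))
    drop <- logical(nrow(tab))
    for (k in unique(und[duplicated(und)])) {
      idx <- which(und == k)
      ord <- order(-tab$mean_weight[idx], tab$parent[idx])
      drop[idx[ord[-1]]] <- TRUE
      if (tab$mean_weight[idx[ord[1]]] == tab$mean_weight[idx[ord[2]]]) {
        message("bidirectional tie for edge ", sub("\r", "--", k),
                "; kept ", tab$parent[idx[ord[1]]], " -> ",
                tab$child[idx[ord[1]]])
      }
    }
    tab <- tab[!drop, , drop = FALSE]
  }
  rownames(tab) <- NULL

  linked <- unique(c(tab$parent, tab$child))
  if (is.null(nodes)) nodes <- linked
  structure(list(nodes = intersect(nodes, linked),
                 arcs = tab[, c("parent", "child", "mean_weight")],
                 all_nodes = nodes,
                 isolated = setdiff(nodes, linked),
                 rule = rule, threshold = threshold),
            class = "final_network")
}

#' @export
print.final_network <- function(x, ...) {
  cat("final_network:", length(x$nodes), "linked nodes (of",
      length(x$all_nodes), "),", nrow(x$arcs), "arcs; rule:", x$rule,
      ">=", x$threshold, "\n")
  invisible(x)
}
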