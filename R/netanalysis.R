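#' Simple undirected graph
#'
#' @param nodes node names.
#' @param edges two-column character matrix of endpoints; stored with
#'   endpoints sorted within each edge, duplicates and self-loops rejected.
#' @return object of class `ugraph`.
#' @export
ugraph <- function(nodes, edges = empty_edges()) {
  edges <- as_edge_matrix(edges)
  if (nrow(edges) > 0) {
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
    if (!all(edges %in% nodes)) stop("edge endpoint not among nodes")
    edges <- t(apply(edges, 1, sort))
    colnames(edges) <- c("a", "b")
    edges <- unique(edges)
  } else {
    colnames(edges) <- c("a", "b")
  }
  structure(list(nodes = as.character(nodes), edges = edges),
            class = "ugraph")
}

#' Undirected skeleton of a directed network
#' @param x a `digraph`, `final_network` or `dag`.
#' @return a [ugraph()] over the same nodes (for a `final_network`, the
#'   linked nodes).
#' @export
skeleton <- function(x) {
  if (inherits(x, "final_network")) {
    return(ugraph(x$nodes, as.matrix(x$arcs[, c("parent", "child")])))
  }
  ugraph(x$nodes, x$edges)
}

adjacency_list <- function(g) {
  adj <- setNames(vector("list", length(g$nodes)), g$nodes)
  for (i in seq_len(nrow(g$edges))) {
    a <- g$edges[i, 1]; b <- g$edges[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

#' Shortest-path edge betweenness
#'
#' For every edge, the number of shortest paths between unordered node pairs
#' that traverse it, with ties split fractionally (Brandes' breadth-first
#' accumulation, run from every source and halved).
#'
#' @param g a [ugraph()].
#' @return named numeric vector, names `"a|b"` with sorted endpoints.
#' @export
edge_betweenness <- function(g) {
  stopifnot(inherits(g, "ugraph"))
  if (nrow(g$edges) == 0) return(setNames(numeric(0), character(0)))
  ekey <- paste(g$edges[, 1], g$edges[, 2], sep = "|")
  bc <- setNames(numeric(length(ekey)), ekey)
  adj <- adjacency_list(g)
  for (s in g$nodes) {
    # BFS from s: sigma = #shortest paths, preds on shortest paths
    dist <- setNames(rep(Inf, length(g$nodes)), g$nodes)
    sigma <- setNames(rep(0, length(g$nodes)), g$nodes)
    preds <- setNames(vector("list", length(g$nodes)), g$nodes)
    dist[s] <- 0; sigma[s] <- 1
    order_visited <- character(0)
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      order_visited <- c(order_visited, v)
      for (w in adj[[v]]) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- setNames(rep(0, length(g$nodes)), g$nodes)
    for (w in rev(order_visited)) {
      for (v in preds[[w]]) {
        contrib <- sigma[v] / sigma[w] * (1 + delta[w])
        k <- paste(sort(c(v, w)), collapse = "|")
        bc[k] <- bc[k] + contrib
        delta[v] <- delta[v] + contrib
      }
    }
  }
  bc / 2
}

connected_components <- function(g) {
  adj <- adjacency_list(g)
  comp <- setNames(rep(NA_integer_, length(g$nodes)), g$nodes)
  cid <- 0L
  for (s in g$nodes) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (is.na(comp[w])) { comp[w] <- cid; queue <- c(queue, w) }
    }
  }
  comp
}

#' Newman-Girvan modularity of a partition
#'
#' `Q = sum_c (e_cc - a_c^2)` where `e_cc` is the fraction of edges inside
#' community `c` and `a_c` the fraction of edge endpoints in `c`. A graph
#' with no edges has `Q = 0` by convention.
#'
#' @param g a [ugraph()].
#' @param membership named vector assigning every node a community id.
#' @return the modularity, in `[-1, 1]`.
#' @export
modularity_q <- function(g, membership) {
  stopifnot(inherits(g, "ugraph"))
  missing <- setdiff(g$nodes, names(membership))
  if (length(missing) > 0) {
    stop("node(s) missing from partition: ", paste(missing, collapse = ", "))
  }
  m <- nrow(g$edges)
  if (m == 0) return(0)
  comms <- unique(membership[g$nodes])
  q <- 0
  for (cc in comms) {
    inside <- names(membership)[membership == cc]
    e_cc <- sum(g$edges[, 1] %in% inside & g$edges[, 2] %in% inside) / m
    ends <- sum(g$edges[, 1] %in% inside) + sum(g$edges[, 2] %in% inside)
    a_c <- ends / (2 * m)
    q <- q + e_cc - a_c^2
  }
  q
}

#' Girvan-Newman divisive community detection
#'
#' Repeatedly removes a maximum-betweenness edge (recomputing betweenness
#' after each removal; ties broken by the lexicographically smallest edge),
#' recording the component structure along the way, and returns the
#' partition that maximizes modularity on the original graph. The full
#' removal sequence and per-step partitions are kept so the dendrogram can
#' be cut at a fixed community count instead.
#'
#' @param g a [ugraph()] with >= 1 node.
#' @return object of class `community_partition`: `membership`,
#'   `n_communities`, `modularity`, `removed_edges` (in removal order), and
#'   `steps` (per step: membership and modularity).
#' @export
girvan_newman <- function(g) {
  stopifnot(inherits(g, "ugraph"))
  if (length(g$nodes) == 0) stop("empty graph")
  work <- g
  removed <- character(0)
  memb <- connected_components(work)
  steps <- list(list(membership = memb, modularity = modularity_q(g, memb)))
  while (nrow(work$edges) > 0) {
    bc <- edge_betweenness(work)
    best <- names(bc)[bc == max(bc)]
    victim <- sort(best)[1]
    ab <- strsplit(victim, "|", fixed = TRUE)[[1]]
    keep <- !(work$edges[, 1] == ab[1] & work$edges[, 2] == ab[2])
    work$edges <- work$edges[keep, , drop = FALSE]
    removed <- c(removed, victim)
    memb <- connected_components(work)
    steps[[length(steps) + 1L]] <-
      list(membership = memb, modularity = modularity_q(g, memb))
  }
  qs <- vapply(steps, `[[`, numeric(1), "modularity")
  best_step <- which.max(qs)  # earliest maximum -> coarsest best partition
  best <- steps[[best_step]]
  structure(list(membership = best$membership,
                 n_communities = length(unique(best$membership)),
                 modularity = best$modularity,
                 removed_edges = removed,
                 steps = steps),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat("community_partition:", x$n_communities, "communities, Q =",
      round(x$modularity, 4), "\n")
  invisible(x)
}

#' Cut the divisive dendrogram at a fixed community count
#' @param cp a `community_partition` from [girvan_newman()].
#' @param k desired number of communities.
#' @return the membership of the first recorded step with >= k communities.
#' @export
cut_communities <- function(cp, k) {
  for (st in cp$steps) {
    if (length(unique(st$membership)) >= k) return(st$membership)
  }
  cp$steps[[length(cp$steps)]]$membership
}

#' Markov blanket of a node in a directed graph
#'
#' Parents (in-neighbors), children (out-neighbors) and spouses (other
#' parents of the children); the blanket is their union, never containing
#' the target. The purely graph-theoretic definition is applied, so it is
#' well defined even on cyclic consensus aggregates; the usual conditional
#' independence reading holds only for acyclic inputs.
#'
#' @param graph a `digraph`, `dag` or `final_network`.
#' @param target node name.
#' @return object of class `markov_blanket`: `target`, `parents`,
#'   `children`, `spouses`, `blanket`.
#' @export
markov_blanket <- function(graph, target) {
  if (inherits(graph, "final_network")) {
    graph <- digraph(graph$all_nodes,
                     as.matrix(graph$arcs[, c("parent", "child")]))
  }
  if (!target %in% graph$nodes) stop("unknown target node: ", target)
  e <- graph$edges
  parents <- sort(unique(e[e[, 2] == target, 1]))
  children <- sort(unique(e[e[, 1] == target, 2]))
  spouses <- sort(setdiff(unique(e[e[, 2] %in% children, 1]), target))
  structure(list(target = target, parents = parents, children = children,
                 spouses = spouses,
                 blanket = sort(unique(c(parents, children, spouses)))),
            class = "markov_blanket")
}

#' @export
print.markov_blanket <- function(x, ...) {
  cat("Markov blanket of", x$target, ":",
      paste(x$blanket, collapse = ", "), "\n")
  invisible(x)
}

#' Members of the target's community
#' @param cp a `community_partition`.
#' @param target node name present in the partition.
#' @return the target's community members, excluding the target itself.
#' @export
condition_community <- function(cp, target) {
  if (!target %in% names(cp$membership)) stop("unknown target node: ", target)
  members <- names(cp$membership)[cp$membership == cp$membership[target]]
  sort(setdiff(members, target))
}
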