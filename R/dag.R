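#' Directed acyclic graphs over named variables
#'
#' A `dag` is a list with `nodes` (ordered character vector) and `edges`
#' (two-column character matrix, columns `parent` and `child`). Edges are
#' unique ordered pairs, self-edges are forbidden, and the structure must be
#' acyclic.
#'
#' @param nodes character vector of variable names (unique).
#' @param edges two-column character matrix (or data frame) of parent/child
#'   pairs; may have zero rows.
#' @return an object of class `dag`.
#' @export
dag <- function(nodes, edges = empty_edges()) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node names")
  edges <- as_edge_matrix(edges)
  if (nrow(edges) > 0) {
    if (!all(edges %in% nodes)) stop("edge endpoint not among nodes")
    if (any(edges[, 1] == edges[, 2])) stop("self-edges are not allowed")
    if (anyDuplicated(paste(edges[, 1], edges[, 2], sep = "\r"))) {
      stop("duplicate edges")
    }
  }
  g <- structure(list(nodes = nodes, edges = edges), class = "dag")
  if (!is_acyclic(g)) stop("graph contains a directed cycle")
  g
}

empty_edges <- function() {
  matrix(character(0), ncol = 2, dimnames = list(NULL, c("parent", "child")))
}

as_edge_matrix <- function(edges) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (is.null(edges) || length(edges) == 0) return(empty_edges())
  edges <- matrix(as.character(edges), ncol = 2)
  colnames(edges) <- c("parent", "child")
  edges
}

#' @export
print.dag <- function(x, ...) {
  cat("dag:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Topological sort of a directed graph
#'
#' Kahn's algorithm; returns `NULL` when the edge set contains a directed
#' cycle, which doubles as the acyclicity check.
#'
#' @param nodes character vector of node names.
#' @param edges two-column parent/child character matrix.
#' @return node names in a topological order, or `NULL` if cyclic.
#' @export
topological_sort <- function(nodes, edges) {
  edges <- as_edge_matrix(edges)
  indeg <- setNames(integer(length(nodes)), nodes)
  if (nrow(edges) > 0) {
    tb <- table(edges[, 2])
    indeg[names(tb)] <- as.integer(tb)
  }
  out <- split(edges[, 2], factor(edges[, 1], levels = nodes))
  order <- character(0)
  queue <- nodes[indeg == 0]
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    for (w in out[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(order) < length(nodes)) NULL else order
}

#' Test a parent/child edge set for acyclicity
#' @param g a `dag`-shaped list (`nodes`, `edges`).
#' @return `TRUE` if acyclic.
#' @export
is_acyclic <- function(g) {
  !is.null(topological_sort(g$nodes, g$edges))
}

parents_of <- function(g, node) g$edges[g$edges[, 2] == node, 1]
children_of <- function(g, node) g$edges[g$edges[, 1] == node, 2]

has_edge <- function(g, parent, child) {
  any(g$edges[, 1] == parent & g$edges[, 2] == child)
}

add_edge <- function(g, parent, child) {
  g$edges <- rbind(g$edges, c(parent, child))
  g
}

drop_edge <- function(g, parent, child) {
  keep <- !(g$edges[, 1] == parent & g$edges[, 2] == child)
  g$edges <- g$edges[keep, , drop = FALSE]
  g
}

edge_key <- function(g) {
  if (nrow(g$edges) == 0) return("")
  paste(sort(paste(g$edges[, 1], g$edges[, 2], sep = ">")), collapse = ";")
}

#' Generate a random DAG
#'
#' Nodes are taken in a random topological order; each forward pair becomes an
#' edge independently with probability `edge_prob`, subject to a per-node
#' parent limit.
#'
#' @param n_nodes number of nodes (>= 1); named `V1..Vn`.
#' @param max_parents maximum in-degree.
#' @param edge_prob probability of each admissible edge.
#' @param seed integer seed; identical seeds give identical graphs.
#' @return a `dag`.
#' @export
random_dag <- function(n_nodes, max_parents, edge_prob, seed) {
  if (!is.numeric(n_nodes) || n_nodes < 1) stop("n_nodes must be >= 1")
  if (edge_prob < 0 || edge_prob > 1) stop("edge_prob must be in [0, 1]")
  n_nodes <- as.integer(n_nodes)
  nodes <- paste0("V", seq_len(n_nodes))
  set.seed(seed)
  ord <- sample(nodes)
  edges <- empty_edges()
  nparents <- setNames(integer(n_nodes), nodes)
  if (n_nodes >= 2) {
    for (j in 2:n_nodes) {
      for (i in 1:(j - 1)) {
        if (nparents[ord[j]] < max_parents && runif(1) < edge_prob) {
          edges <- rbind(edges, c(ord[i], ord[j]))
          nparents[ord[j]] <- nparents[ord[j]] + 1L
        }
      }
    }
  }
  dag(nodes, edges)
}

#' Enumerate the valid single-edge moves from a DAG
#'
#' Moves are edge additions, deletions and reversals that keep the graph a
#' simple DAG and respect `max_parents`. Used by [propose_move()] and by the
#' search tests as an exhaustive neighborhood oracle.
#'
#' @param g a `dag`.
#' @param max_parents per-node parent limit (`Inf` for none).
#' @return data frame with columns `type` (add/delete/reverse), `parent`, `child`.
#' @export
dag_neighborhood <- function(g, max_parents = Inf) {
  moves <- list()
  npar <- setNames(integer(length(g$nodes)), g$nodes)
  if (nrow(g$edges) > 0) {
    tb <- table(g$edges[, 2])
    npar[names(tb)] <- as.integer(tb)
  }
  for (u in g$nodes) for (v in g$nodes) {
    if (u == v) next
    if (has_edge(g, u, v)) {
      moves[[length(moves) + 1L]] <- c("delete", u, v)
      # reversal: v -> u must not close a cycle or overflow u's parents
      g2 <- add_edge(drop_edge(g, u, v), v, u)
      if (npar[u] + 1L <= max_parents && is_acyclic(g2)) {
        moves[[length(moves) + 1L]] <- c("reverse", u, v)
      }
    } else if (!has_edge(g, v, u)) {
      if (npar[v] + 1L <= max_parents && is_acyclic(add_edge(g, u, v))) {
        moves[[length(moves) + 1L]] <- c("add", u, v)
      }
    }
  }
  if (length(moves) == 0) {
    return(data.frame(type = character(0), parent = character(0),
                      child = character(0), stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, moves)
  data.frame(type = m[, 1], parent = m[, 2], child = m[, 3],
             stringsAsFactors = FALSE)
}

#' Propose a random local move
#'
#' Draws uniformly among the valid single-edge moves (addition, deletion,
#' reversal) and applies it. Uses the current R random stream.
#'
#' @param g a `dag`.
#' @param max_parents per-node parent limit (`Inf` for none).
#' @return the neighboring `dag`, or `NULL` if no valid move exists.
#' @export
propose_move <- function(g, max_parents = Inf) {
  nb <- dag_neighborhood(g, max_parents)
  if (nrow(nb) == 0) return(NULL)
  mv <- nb[sample.int(nrow(nb), 1L), ]
  apply_move(g, mv$type, mv$parent, mv$child)
}

apply_move <- function(g, type, parent, child) {
  switch(type,
    add = add_edge(g, parent, child),
    delete = drop_edge(g, parent, child),
    reverse = add_edge(drop_edge(g, parent, child), child, parent),
    stop("unknown move type: ", type))
}

#' Enumerate every labeled DAG on a small node set
#'
#' Each unordered node pair independently takes one of three states (no edge,
#' forward, backward); cyclic orientations are filtered out. Counts follow
#' Robinson's sequence (1, 3, 25, 543 for n = 1..4). Refuses n > 4.
#'
#' @param n number of nodes (<= 4).
#' @param nodes optional node names (default `V1..Vn`).
#' @return list of `dag` objects, each labeled DAG exactly once.
#' @export
enumerate_all_dags <- function(n, nodes = paste0("V", seq_len(n))) {
  if (n > 4) stop("enumeration limited to n <= 4")
  if (n < 1) stop("n must be >= 1")
  if (n == 1) return(list(dag(nodes)))
  pairs <- t(combn(nodes, 2))
  npair <- nrow(pairs)
  states <- expand.grid(rep(list(0:2), npair))
  out <- list()
  for (i in seq_len(nrow(states))) {
    st <- as.integer(states[i, ])
    e <- empty_edges()
    for (k in seq_len(npair)) {
      if (st[k] == 1L) e <- rbind(e, pairs[k, ])
      if (st[k] == 2L) e <- rbind(e, rev(pairs[k, ]))
    }
    if (!is.null(topological_sort(nodes, e))) {
      out[[length(out) + 1L]] <- dag(nodes, e)
    }
  }
  out
}
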