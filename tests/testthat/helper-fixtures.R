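# shared fixtures and small oracles, all built in code

# two triangles joined by one bridge (7 edges)
barbell_graph <- function() {
  ugraph(LETTERS[1:6],
         rbind(c("A", "B"), c("A", "C"), c("B", "C"),
               c("C", "D"),
               c("D", "E"), c("D", "F"), c("E", "F")))
}

# 6-node, 6-edge ground truth used by the recovery tests
recovery_truth <- function() {
  dag(paste0("V", 1:6),
      rbind(c("V1", "V2"), c("V1", "V3"), c("V2", "V4"),
            c("V3", "V5"), c("V4", "V6"), c("V5", "V6")))
}

undirected_key <- function(parent, child) {
  vapply(seq_along(parent), function(i) {
    paste(sort(c(parent[i], child[i])), collapse = "|")
  }, character(1))
}

skeleton_f1 <- function(true_dag, arcs) {
  truth <- undirected_key(true_dag$edges[, 1], true_dag$edges[, 2])
  got <- if (nrow(arcs) > 0) undirected_key(arcs$parent, arcs$child) else
    character(0)
  tp <- length(intersect(truth, got))
  if (length(truth) + length(got) == 0) return(1)
  2 * tp / (length(truth) + length(got))
}

# Markov-equivalence signature: skeleton + unshielded colliders
equivalence_class_key <- function(g) {
  sk <- sort(undirected_key(g$edges[, 1], g$edges[, 2]))
  vstr <- character(0)
  for (v in g$nodes) {
    pars <- g$edges[g$edges[, 2] == v, 1]
    if (length(pars) >= 2) {
      for (pair in utils::combn(sort(pars), 2, simplify = FALSE)) {
        adjacent <- any(
          (g$edges[, 1] == pair[1] & g$edges[, 2] == pair[2]) |
          (g$edges[, 1] == pair[2] & g$edges[, 2] == pair[1]))
        if (!adjacent) {
          vstr <- c(vstr, paste(pair[1], v, pair[2], sep = "*"))
        }
      }
    }
  }
  paste(paste(sk, collapse = ";"), paste(sort(vstr), collapse = ";"),
        sep = " || ")
}

# brute-force edge betweenness: enumerate every shortest path of every pair
brute_edge_betweenness <- function(g) {
  ekey <- paste(g$edges[, 1], g$edges[, 2], sep = "|")
  bc <- setNames(numeric(length(ekey)), ekey)
  adj <- setNames(vector("list", length(g$nodes)), g$nodes)
  for (i in seq_len(nrow(g$edges))) {
    a <- g$edges[i, 1]; b <- g$edges[i, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  all_shortest <- function(s, t) {
    # BFS layers, then recursive path reconstruction
    dist <- setNames(rep(Inf, length(g$nodes)), g$nodes)
    dist[s] <- 0
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1; queue <- c(queue, w)
      }
    }
    if (is.infinite(dist[t])) return(list())
    paths <- function(v) {
      if (v == s) return(list(s))
      pre <- Filter(function(u) dist[u] == dist[v] - 1, adj[[v]])
      out <- list()
      for (u in pre) for (p in paths(u)) out[[length(out) + 1]] <- c(p, v)
      out
    }
    paths(t)
  }
  nodes <- g$nodes
  if (length(nodes) >= 2) {
    for (pair in utils::combn(nodes, 2, simplify = FALSE)) {
      ps <- all_shortest(pair[1], pair[2])
      if (length(ps) == 0) next
      for (p in ps) {
        for (k in seq_len(length(p) - 1)) {
          key <- paste(sort(c(p[k], p[k + 1])), collapse = "|")
          bc[key] <- bc[key] + 1 / length(ps)
        }
      }
    }
  }
  bc
}

# exact joint over a tiny ground-truth network, by enumeration
enumerate_joint <- function(bn) {
  ord <- topological_sort(bn$nodes, bn$edges)
  states <- expand.grid(lapply(bn$arities[bn$nodes], function(a) 0:(a - 1)))
  names(states) <- bn$nodes
  probs <- rep(1, nrow(states))
  for (v in bn$nodes) {
    pars <- bn$edges[bn$edges[, 2] == v, 1]
    if (length(pars) == 0) {
      rows <- rep(1L, nrow(states))
    } else {
      idx <- rep(0L, nrow(states)); stride <- 1L
      for (p in pars) {
        idx <- idx + states[[p]] * stride
        stride <- stride * bn$arities[[p]]
      }
      rows <- idx + 1L
    }
    probs <- probs * bn$cpts[[v]][cbind(rows, states[[v]] + 1L)]
  }
  cbind(states, prob = probs)
}
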