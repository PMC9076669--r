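#' Configuration of the simulated-annealing structure search
#'
#' Defaults follow a conventional annealing schedule: start hot relative to
#' the score scale, cool geometrically, and reheat when the chain stalls.
#' All knobs are exposed because none of them is canonical.
#'
#' @param n_proposals number of proposed moves (full scale 250e6; desk scale
#'   around 1e5).
#' @param top_n number of distinct best-scoring structures to track.
#' @param ess BDeu equivalent sample size.
#' @param t0 initial temperature, in score (nat) units.
#' @param cooling geometric cooling factor in (0, 1).
#' @param steps_per_level proposals between cooling steps; `NULL` (default)
#'   resolves to `n_proposals / 100`, so the temperature profile — hot start,
#'   cold finish — is the same at any proposal budget. A fixed value (e.g.
#'   2500) reproduces a budget-independent schedule instead.
#' @param reanneal_after reset the temperature after this many consecutive
#'   rejections.
#' @param max_parents per-node parent limit (`NULL` = unrestricted).
#' @param seed integer seed for the run.
#' @return object of class `search_config`.
#' @export
search_config <- function(n_proposals = 1e5, top_n = 100, ess = 1,
                          t0 = 1e4, cooling = 0.9, steps_per_level = NULL,
                          reanneal_after = 5000, max_parents = NULL,
                          seed = 1L) {
  stopifnot(n_proposals >= 0, top_n >= 1, ess > 0,
            cooling > 0, cooling < 1,
            is.null(steps_per_level) || steps_per_level > 0)
  structure(list(n_proposals = n_proposals, top_n = top_n, ess = ess,
                 t0 = t0, cooling = cooling,
                 steps_per_level = steps_per_level,
                 reanneal_after = reanneal_after,
                 max_parents = max_parents, seed = as.integer(seed)),
            class = "search_config")
}

#' Simulated-annealing search for high-scoring network structures
#'
#' Starts from the empty graph and performs `n_proposals` local moves (edge
#' addition, deletion, reversal, drawn uniformly among the valid moves). A
#' move with score change `delta >= 0` is always accepted, otherwise accepted
#' with probability `exp(delta / T)`; `T` follows the configured geometric
#' cooling with reannealing when acceptance stalls. Setting `t0 = 0` gives
#' the zero-temperature (pure hill-climbing) variant. The `top_n` distinct
#' structures visited, ranked by BDeu score, are returned.
#'
#' @param data a [discrete_dataset()] with >= 2 variables.
#' @param cfg a [search_config()].
#' @param track_trajectory if `TRUE`, also return the accepted-state score
#'   sequence (for diagnostics; memory-proportional to acceptances).
#' @return list of scored networks, each `list(dag, log_score)`, descending
#'   score; attributes `n_accepted` and (optionally) `trajectory`.
#' @export
simulated_annealing_search <- function(data, cfg, track_trajectory = FALSE) {
  stopifnot(inherits(data, "discrete_dataset"), inherits(cfg, "search_config"))
  if (length(data$variables) < 2) stop("need >= 2 variables")
  maxp <- if (is.null(cfg$max_parents)) length(data$variables) - 1L else
    as.integer(cfg$max_parents)
  spl <- if (is.null(cfg$steps_per_level)) {
    max(100, cfg$n_proposals %/% 100)
  } else cfg$steps_per_level
  set.seed(cfg$seed)
  res <- .sa_search_cpp(data$data, unname(data$arities),
                        as.double(cfg$n_proposals), as.integer(cfg$top_n),
                        cfg$ess, cfg$t0, cfg$cooling,
                        as.double(spl),
                        as.double(cfg$reanneal_after), maxp,
                        track_trajectory)
  nets <- lapply(seq_along(res$edges), function(i) {
    em <- res$edges[[i]]
    edges <- if (nrow(em) == 0) empty_edges() else
      cbind(data$variables[em[, 1]], data$variables[em[, 2]])
    list(dag = dag(data$variables, edges), log_score = res$scores[i])
  })
  attr(nets, "n_accepted") <- res$n_accepted
  if (track_trajectory) attr(nets, "trajectory") <- res$trajectory
  nets
}

#' Majority consensus of a run's top networks
#'
#' An arc enters the consensus iff it appears in strictly more than
#' `majority_fraction` of the supplied networks; each retained arc carries
#' its within-list frequency as a confidence. The result is a directed graph
#' that need not be acyclic.
#'
#' @param top list of scored networks from [simulated_annealing_search()].
#' @param majority_fraction inclusion threshold in (0, 1].
#' @return object of class `digraph`: `nodes`, `edges`, and per-edge
#'   `confidence`.
#' @export
consensus_of_top <- function(top, majority_fraction = 0.5) {
  stopifnot(length(top) > 0, majority_fraction > 0, majority_fraction <= 1)
  nodes <- top[[1]]$dag$nodes
  counts <- list()
  for (net in top) {
    e <- net$dag$edges
    if (nrow(e) == 0) next
    for (k in paste(e[, 1], e[, 2], sep = "\r")) {
      counts[[k]] <- (counts[[k]] %||% 0L) + 1L
    }
  }
  freq <- unlist(counts) / length(top)
  keep <- which(freq > majority_fraction)
  if (length(keep) == 0) {
    edges <- empty_edges()
    conf <- numeric(0)
  } else {
    pc <- do.call(rbind, strsplit(names(freq)[keep], "\r", fixed = TRUE))
    edges <- as_edge_matrix(pc)
    conf <- unname(freq[keep])
  }
  digraph(nodes, edges, confidence = conf)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' General directed graph (cycles allowed)
#'
#' @param nodes node names.
#' @param edges two-column parent/child matrix.
#' @param ... per-edge attribute vectors (e.g. `confidence`, `weight`).
#' @return object of class `digraph`.
#' @export
digraph <- function(nodes, edges = empty_edges(), ...) {
  edges <- as_edge_matrix(edges)
  if (nrow(edges) > 0 && !all(edges %in% nodes)) {
    stop("edge endpoint not among nodes")
  }
  structure(c(list(nodes = as.character(nodes), edges = edges), list(...)),
            class = "digraph")
}

#' @export
print.digraph <- function(x, ...) {
  cat("digraph:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}
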