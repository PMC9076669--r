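#' Ground-truth categorical Bayesian networks
#'
#' Attaches random conditional probability tables to a DAG. Each CPT row
#' (one per joint parent configuration) is drawn from a symmetric Dirichlet
#' with the given concentration; small concentrations give near-deterministic
#' rows, which is how the search tests build strong-dependence data.
#'
#' Parent configurations are indexed mixed-radix with the first listed parent
#' varying fastest: for parent states `s1..sk` and arities `a1..ak`,
#' `row = 1 + s1 + a1*(s2 + a2*(s3 + ...))`.
#'
#' @param g a `dag`.
#' @param arities named integer vector, one arity (>= 2) per node.
#' @param concentration positive Dirichlet concentration.
#' @param seed integer seed.
#' @return object of class `ground_truth_bn`: the dag plus `arities` and
#'   `cpts` (per node, a `q x r` matrix of row distributions).
#' @export
random_cpts <- function(g, arities, concentration, seed) {
  if (!is.numeric(concentration) || concentration <= 0) {
    stop("concentration must be > 0")
  }
  arities <- arities[g$nodes]
  if (any(is.na(arities)) || any(arities < 2)) stop("all arities must be >= 2")
  set.seed(seed)
  cpts <- list()
  for (v in g$nodes) {
    pars <- parents_of(g, v)
    q <- prod(arities[pars])
    r <- arities[[v]]
    cpts[[v]] <- t(vapply(seq_len(q), function(i) rdirichlet_sym(r, concentration),
                          numeric(r)))
  }
  structure(list(nodes = g$nodes, edges = g$edges, arities = arities,
                 cpts = cpts), class = c("ground_truth_bn", "dag"))
}

# one symmetric Dirichlet draw; log-space Marsaglia boost keeps tiny
# concentrations from underflowing to all-zero rows
rdirichlet_sym <- function(k, alpha) {
  if (alpha >= 0.1) {
    x <- rgamma(k, shape = alpha)
    if (sum(x) > 0) return(x / sum(x))
  }
  lg <- log(rgamma(k, shape = alpha + 1)) + log(runif(k)) / alpha
  w <- exp(lg - max(lg))
  w / sum(w)
}

parent_config_index <- function(states_mat, arities) {
  # states_mat: samples x k matrix of 0-based parent states, column order =
  # parent list order (first parent varies fastest)
  if (ncol(states_mat) == 0) return(rep(1L, nrow(states_mat)))
  idx <- rep(0L, nrow(states_mat))
  stride <- 1L
  for (j in seq_len(ncol(states_mat))) {
    idx <- idx + states_mat[, j] * stride
    stride <- stride * arities[j]
  }
  idx + 1L
}

#' Ancestral sampling from a ground-truth Bayesian network
#'
#' Nodes are visited in a topological order; each sample draws every node's
#' state from the CPT row selected by its parents' already-sampled states.
#'
#' @param bn a `ground_truth_bn` from [random_cpts()].
#' @param n_samples number of samples (>= 1).
#' @param seed integer seed.
#' @return a [discrete_dataset()] with `|nodes|` variables and `n_samples`
#'   samples.
#' @export
sample_discrete <- function(bn, n_samples, seed) {
  stopifnot(inherits(bn, "ground_truth_bn"), n_samples >= 1)
  set.seed(seed)
  ord <- topological_sort(bn$nodes, bn$edges)
  data <- matrix(NA_integer_, nrow = length(bn$nodes), ncol = n_samples,
                 dimnames = list(bn$nodes, paste0("s", seq_len(n_samples))))
  for (v in ord) {
    pars <- parents_of(bn, v)
    r <- bn$arities[[v]]
    if (length(pars) == 0) {
      rows <- rep(1L, n_samples)
    } else {
      rows <- parent_config_index(t(data[pars, , drop = FALSE]), bn$arities[pars])
    }
    u <- runif(n_samples)
    cum <- t(apply(bn$cpts[[v]], 1, cumsum))
    data[v, ] <- vapply(seq_len(n_samples), function(s) {
      sum(u[s] > cum[rows[s], ]) }, integer(1))
  }
  discrete_dataset(
    variables = bn$nodes,
    arities = bn$arities,
    data = data,
    labels = lapply(bn$arities, function(a) as.character(seq_len(a) - 1L))
  )
}

#' Design of a paired two-study RNA-seq simulation
#'
#' Describes two independent negative-binomial count studies that share a set
#' of planted condition-responsive genes: in each study a planted gene's
#' group means differ by `2^log2_fold_change`, all other genes are null.
#' Planted directions alternate (up, down, up, ...) across the planted set
#' so the groups keep comparable library sizes — the counts carry no global
#' composition bias, matching the plain library-size normalization used
#' downstream. The negative binomial is parameterized by mean and dispersion
#' `phi` with variance `mu + phi * mu^2` (the usual RNA-seq convention).
#'
#' @param n_genes total genes per study.
#' @param n_samples_per_group length-2 integer vector: per-group sample size
#'   in study 1 and study 2 (>= 2 each).
#' @param de_gene_ids character vector of planted gene ids (subset of
#'   `gene1..geneN`).
#' @param log2_fold_change planted effect size (stress vs non-stress).
#' @param nb_dispersion negative-binomial dispersion (> 0).
#' @param baseline_log_mean_range interval for per-gene baseline log-mean
#'   (natural log scale; default log of 5 to 500 counts).
#' @param seed integer master seed; each study is generated from its own
#'   derived sub-stream.
#' @return object of class `two_study_design`.
#' @export
two_study_design <- function(n_genes, n_samples_per_group, de_gene_ids,
                             log2_fold_change, nb_dispersion,
                             baseline_log_mean_range = log(c(5, 500)),
                             seed = 1L) {
  genes <- paste0("gene", seq_len(n_genes))
  if (!all(de_gene_ids %in% genes)) stop("de_gene_ids must be a subset of the gene set")
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (length(n_samples_per_group) == 1) {
    n_samples_per_group <- rep(n_samples_per_group, 2)
  }
  if (any(n_samples_per_group < 2)) stop("need >= 2 samples per group")
  structure(list(n_genes = n_genes, genes = genes,
                 n_samples_per_group = n_samples_per_group,
                 de_gene_ids = de_gene_ids,
                 log2_fold_change = log2_fold_change,
                 nb_dispersion = nb_dispersion,
                 baseline_log_mean_range = baseline_log_mean_range,
                 seed = seed),
            class = "two_study_design")
}

#' Simulate paired two-study count matrices with planted DE genes
#'
#' @param design a [two_study_design()].
#' @return list with `study1`, `study2` ([count_matrix()] objects) and
#'   `truth` (the planted gene ids).
#' @export
simulate_two_study_counts <- function(design) {
  stopifnot(inherits(design, "two_study_design"))
  studies <- lapply(1:2, function(s) {
    simulate_one_study(design, study = s,
                       seed = derive_seed(design$seed, s))
  })
  list(study1 = studies[[1]], study2 = studies[[2]],
       truth = design$de_gene_ids,
       truth_sign = setNames(de_sign(design)[match(design$de_gene_ids,
                                                   design$genes)],
                             design$de_gene_ids))
}

# per-gene planted effect direction: +1/-1 alternating over the planted set
# (0 for null genes); deterministic so both studies agree
de_sign <- function(design) {
  s <- numeric(design$n_genes)
  idx <- match(design$de_gene_ids, design$genes)
  if (length(idx) > 0) s[idx] <- rep_len(c(1, -1), length(idx))
  s
}

#' @details Planted effects alternate in direction (first planted gene up in
#'   stress, second down, and so on), so the two groups keep comparable
#'   library sizes and the counts carry no global composition bias --
#'   matching the plain library-size normalization used downstream. The
#'   per-gene direction is deterministic (`de_sign` on the returned design).
simulate_one_study <- function(design, study, seed) {
  set.seed(seed)
  n <- design$n_samples_per_group
  ng <- n[study]
  base_mu <- exp(runif(design$n_genes,
                       design$baseline_log_mean_range[1],
                       design$baseline_log_mean_range[2]))
  # centred planting: group means mu * 2^(-+lfc/2) and mu * 2^(+-lfc/2) keep
  # the ratio at 2^lfc while alternating directions balance the expected
  # library mass of the two groups
  sign <- de_sign(design)
  half <- design$log2_fold_change / 2
  mu_ns <- base_mu * 2^(-half * sign)
  mu_st <- base_mu * 2^(half * sign)
  size <- 1 / design$nb_dispersion
  counts_ns <- matrix(rnbinom(design$n_genes * ng, mu = rep(mu_ns, ng),
                              size = size), ncol = ng)
  counts_st <- matrix(rnbinom(design$n_genes * ng, mu = rep(mu_st, ng),
                              size = size), ncol = ng)
  counts <- cbind(counts_ns, counts_st)
  samples <- paste0("st", study, "_s", seq_len(2 * ng))
  dimnames(counts) <- list(design$genes, samples)
  count_matrix(counts,
               condition = rep(c("non-stress", "stress"), each = ng),
               study = rep(paste0("study", study), 2 * ng))
}

#' Construct a strong-dependence ground-truth network
#'
#' Root nodes get uniform marginals; a child's CPT row puts mass
#' `1 - noise` on a target state that changes with every parent
#' (`target = (s1 + sum_{k >= 2} [s_k = arity_k - 1]) mod r`), the rest
#' spread evenly. Every edge then carries strong, identifiable signal --
#' including into colliders, whose children remain pairwise dependent on
#' each parent -- which is what the structure-recovery tests need from
#' their generative truth.
#'
#' @param g a `dag`.
#' @param arities named per-node state counts (>= 2).
#' @param noise probability mass off the target state (in `[0, 1)`).
#' @return a `ground_truth_bn`.
#' @export
strong_dependence_bn <- function(g, arities, noise = 0.05) {
  stopifnot(noise >= 0, noise < 1)
  arities <- arities[g$nodes]
  if (any(is.na(arities)) || any(arities < 2)) stop("all arities must be >= 2")
  cpts <- list()
  for (v in g$nodes) {
    pars <- parents_of(g, v)
    r <- arities[[v]]
    if (length(pars) == 0) {
      cpts[[v]] <- matrix(1 / r, nrow = 1, ncol = r)
      next
    }
    confs <- as.matrix(expand.grid(lapply(arities[pars], function(a)
      0:(a - 1)))) # first parent varies fastest, matching the row indexing
    q <- nrow(confs)
    m <- matrix(noise / (r - 1), nrow = q, ncol = r)
    for (j in seq_len(q)) {
      extra <- if (ncol(confs) > 1) {
        sum(confs[j, -1] == arities[pars][-1] - 1L)
      } else 0L
      target <- (confs[j, 1] + extra) %% r
      m[j, target + 1L] <- 1 - noise
    }
    cpts[[v]] <- m
  }
  structure(list(nodes = g$nodes, edges = g$edges, arities = arities,
                 cpts = cpts), class = c("ground_truth_bn", "dag"))
}
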