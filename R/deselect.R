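#' Gene-by-sample count matrix with condition labels
#'
#' @param counts nonnegative integer matrix, genes in rows (rownames = gene
#'   ids), samples in columns (colnames = sample ids).
#' @param condition per-sample labels, `"non-stress"` or `"stress"`.
#' @param study optional per-sample study id.
#' @return object of class `count_matrix`.
#' @export
count_matrix <- function(counts, condition, study = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers")
  }
  condition <- as.character(condition)
  if (length(condition) != ncol(counts)) stop("condition length != sample count")
  if (!all(condition %in% c("non-stress", "stress"))) {
    stop("condition labels must be 'non-stress' or 'stress'")
  }
  structure(list(counts = counts, condition = condition, study = study),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples (",
      sum(x$condition == "non-stress"), "non-stress /",
      sum(x$condition == "stress"), "stress )\n")
  invisible(x)
}

#' Remove genes without minimal expression support
#'
#' Keeps genes whose counts-per-million exceed `min_cpm` in at least
#' `min_samples` samples. Library sizes are the column sums of the input
#' matrix. The sample set is unchanged; the result may have zero genes.
#'
#' @param cm a [count_matrix()].
#' @param min_cpm CPM threshold (strict `>`).
#' @param min_samples minimum number of samples exceeding the threshold.
#' @return the filtered [count_matrix()].
#' @export
filter_low_counts <- function(cm, min_cpm = 1, min_samples = 2) {
  stopifnot(inherits(cm, "count_matrix"))
  if (min_samples > ncol(cm$counts)) stop("min_samples exceeds sample count")
  lib <- colSums(cm$counts)
  cpm <- sweep(cm$counts, 2, pmax(lib, 1), "/") * 1e6
  keep <- rowSums(cpm > min_cpm) >= min_samples
  count_matrix(cm$counts[keep, , drop = FALSE], cm$condition, cm$study)
}

#' Log2 counts-per-million
#'
#' `log2((count + prior) / (library + 2 * prior) * 1e6)` with library sizes
#' taken as the column sums of the matrix being transformed.
#'
#' @param cm a [count_matrix()].
#' @param prior_count nonnegative pseudo-count stabilizing low counts.
#' @return real matrix of the same dimensions.
#' @export
log_cpm <- function(cm, prior_count = 0.5) {
  stopifnot(inherits(cm, "count_matrix"), prior_count >= 0)
  lib <- colSums(cm$counts)
  if (any(lib == 0)) stop("zero library size in sample(s): ",
                          paste(colnames(cm$counts)[lib == 0], collapse = ", "))
  log2(sweep(cm$counts + prior_count, 2, lib + 2 * prior_count, "/") * 1e6)
}

#' Empirical-Bayes moderated two-group t statistics
#'
#' Per gene, the two-group linear model gives the effect `beta` (stress minus
#' non-stress mean) and a pooled residual variance `s2` on `n - 2` df. A
#' scaled-F prior `(d0, s0^2)` is estimated from all genes by Smyth-style
#' moment matching (via [limma::fitFDist()]); the posterior variance
#' `s2_tilde = (d0*s0^2 + d*s2) / (d0 + d)` replaces `s2` in the t statistic,
#' whose null distribution gains `d0` degrees of freedom.
#'
#' With `prior_df = 0` the statistic reduces exactly to the ordinary
#' pooled-variance two-sample t.
#'
#' @param logmat genes x samples real matrix (e.g. from [log_cpm()]).
#' @param condition per-sample labels, `"non-stress"` / `"stress"`, >= 2
#'   samples per group.
#' @param prior_df `NULL` to estimate `d0` from the data, or a fixed
#'   nonnegative value (0 = no moderation, `Inf` = complete shrinkage).
#' @return data frame (one row per gene): `gene`, `log2fc`, `s2`, `s2_post`,
#'   `t`, `p`, `adj_p`, with the fitted prior in attributes `prior_df` and
#'   `prior_var`.
#' @export
fit_moderated_t <- function(logmat, condition, prior_df = NULL) {
  condition <- as.character(condition)
  stopifnot(ncol(logmat) == length(condition))
  g1 <- condition == "non-stress"
  g2 <- condition == "stress"
  n1 <- sum(g1); n2 <- sum(g2)
  if (n1 < 2 || n2 < 2) stop("need >= 2 samples per group")
  m1 <- rowMeans(logmat[, g1, drop = FALSE])
  m2 <- rowMeans(logmat[, g2, drop = FALSE])
  beta <- m2 - m1
  rss <- rowSums((logmat[, g1, drop = FALSE] - m1)^2) +
         rowSums((logmat[, g2, drop = FALSE] - m2)^2)
  d <- n1 + n2 - 2
  s2 <- rss / d
  if (is.null(prior_df)) {
    fit <- limma::fitFDist(s2, df1 = d)
    d0 <- fit$df2
    s02 <- fit$scale
    if (!is.finite(s02) || is.na(s02)) { d0 <- Inf; s02 <- mean(s2) }
  } else {
    d0 <- prior_df
    s02 <- if (d0 > 0) mean(s2) else 0
  }
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else {
    (d0 * s02 + d * s2) / (d0 + d)
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tstat <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, sign(beta) * Inf))
  df_total <- d + d0
  p <- 2 * pt(-abs(tstat), df = df_total)
  res <- data.frame(gene = rownames(logmat), log2fc = beta, s2 = s2,
                    s2_post = s2_post, t = tstat, p = p,
                    adj_p = adjust_bh(p), row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(res, "prior_df") <- d0
  attr(res, "prior_var") <- s02
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return adjusted values in `[0, 1]`, monotone over the sorted order.
#' @export
adjust_bh <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Select the top significant genes
#'
#' Genes with BH-adjusted p at or below `alpha`, ordered by ascending raw p,
#' optionally truncated.
#'
#' @param stats data frame from [fit_moderated_t()].
#' @param alpha adjusted-p cutoff.
#' @param max_n optional cap on the list length.
#' @return character vector of gene ids (possibly empty).
#' @export
top_genes <- function(stats, alpha = 0.05, max_n = NULL) {
  if (nrow(stats) == 0) stop("empty gene statistics")
  hits <- stats[stats$adj_p <= alpha, , drop = FALSE]
  hits <- hits[order(hits$p), , drop = FALSE]
  out <- hits$gene
  if (!is.null(max_n)) out <- head(out, max_n)
  out
}

#' Intersect two gene lists, preserving the first list's order
#' @param listA,listB character vectors of gene ids.
#' @return genes present in both, in `listA` order.
#' @export
intersect_gene_lists <- function(listA, listB) {
  listA[listA %in% listB]
}
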