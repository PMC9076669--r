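#' Categorical variables-by-samples dataset
#'
#' The container fed to structure learning: integer state codes (0-based) for
#' each variable and sample, with per-variable arities and ordered state
#' labels. The binary condition variable, when present, is named
#' `"condition"` with labels `"0"` / `"1"`.
#'
#' @param variables ordered variable names.
#' @param arities named (or positionally matched) integer state counts.
#' @param data integer matrix, variables x samples, codes in `[0, arity)`.
#' @param labels list of per-variable ordered state labels.
#' @param cutpoints optional list of per-variable discretization cutpoints.
#' @return object of class `discrete_dataset`.
#' @export
discrete_dataset <- function(variables, arities, data, labels = NULL,
                             cutpoints = NULL) {
  variables <- as.character(variables)
  arities <- setNames(as.integer(arities), variables)
  data <- as.matrix(data)
  storage.mode(data) <- "integer"
  stopifnot(nrow(data) == length(variables), all(arities >= 2))
  rownames(data) <- variables
  if (is.null(colnames(data)) && ncol(data) > 0) {
    colnames(data) <- paste0("s", seq_len(ncol(data)))
  }
  if (anyNA(data)) stop("missing values are not supported")
  for (v in variables) {
    if (any(data[v, ] < 0 | data[v, ] >= arities[[v]])) {
      stop("state codes of ", v, " outside [0, arity)")
    }
  }
  if (is.null(labels)) {
    labels <- lapply(arities, function(a) as.character(seq_len(a) - 1L))
  }
  structure(list(variables = variables, arities = arities, data = data,
                 labels = setNames(labels, variables),
                 cutpoints = cutpoints),
            class = "discrete_dataset")
}

#' @export
print.discrete_dataset <- function(x, ...) {
  cat("discrete_dataset:", length(x$variables), "variables x",
      ncol(x$data), "samples; arities:",
      paste(unique(x$arities), collapse = "/"), "\n")
  invisible(x)
}

#' Quantile discretization of one continuous vector
#'
#' Cutpoints sit at the `k/n_bins` empirical quantiles (type-7 linear
#' interpolation, `k = 1..n_bins-1`); value `v` falls in the largest bin `b`
#' with `v > cutpoint(b)`, so intervals are closed on the right at each
#' cutpoint and ties go to the lower bin. With all-distinct values and a
#' length divisible by `n_bins`, bins come out equal-sized.
#'
#' @param values real vector (length >= n_bins).
#' @param n_bins number of categories (>= 2; default 3 = low/medium/high).
#' @return list with `codes` (0-based integer bins) and `cutpoints`.
#' @export
discretize_quantile <- function(values, n_bins = 3) {
  stopifnot(n_bins >= 2, length(values) >= n_bins)
  if (length(unique(values)) < n_bins) {
    warning("fewer distinct values (", length(unique(values)),
            ") than bins (", n_bins, "); bins are degenerate")
  }
  cut_q <- quantile(values, probs = seq_len(n_bins - 1) / n_bins,
                    type = 7, names = FALSE)
  codes <- vapply(values, function(v) sum(v > cut_q), numeric(1))
  list(codes = as.integer(codes), cutpoints = cut_q)
}

#' Build the discrete expression dataset for the selected genes
#'
#' Pools the per-gene expression values across all samples of all supplied
#' studies, then applies [discretize_quantile()] to each pooled vector. All
#' studies must carry every selected gene and have disjoint sample ids.
#'
#' @param exprs one expression matrix (genes x samples) or a list of them,
#'   typically log-CPM from [log_cpm()].
#' @param genes selected gene ids.
#' @param n_bins number of expression categories (default 3).
#' @return a [discrete_dataset()] of `length(genes)` variables over the
#'   pooled samples, with labels low < medium < high for `n_bins = 3`.
#' @export
build_discrete_dataset <- function(exprs, genes, n_bins = 3) {
  if (!is.list(exprs)) exprs <- list(exprs)
  for (m in exprs) {
    missing <- setdiff(genes, rownames(m))
    if (length(missing) > 0) {
      stop("gene(s) absent from an input study: ",
           paste(missing, collapse = ", "))
    }
  }
  pooled <- do.call(cbind, lapply(exprs, function(m) m[genes, , drop = FALSE]))
  if (anyDuplicated(colnames(pooled))) stop("sample ids overlap across studies")
  lab <- if (n_bins == 3) c("low", "medium", "high") else
    paste0("bin", seq_len(n_bins) - 1L)
  codes <- matrix(NA_integer_, nrow = length(genes), ncol = ncol(pooled),
                  dimnames = list(genes, colnames(pooled)))
  cuts <- list()
  for (g in genes) {
    d <- discretize_quantile(pooled[g, ], n_bins)
    codes[g, ] <- d$codes
    cuts[[g]] <- d$cutpoints
  }
  discrete_dataset(genes, rep(n_bins, length(genes)), codes,
                   labels = rep(list(lab), length(genes)),
                   cutpoints = cuts)
}

#' Append the binary condition variable
#'
#' Adds one variable named `"condition"` (0 = non-stress, 1 = stress) aligned
#' with the dataset's sample order; gene variables are unchanged.
#'
#' @param ds a [discrete_dataset()].
#' @param labels per-sample condition, either 0/1 integers or
#'   `"non-stress"`/`"stress"` strings.
#' @return the extended [discrete_dataset()].
#' @export
append_condition <- function(ds, labels) {
  stopifnot(inherits(ds, "discrete_dataset"))
  if (length(labels) != ncol(ds$data)) {
    stop("condition labels length (", length(labels),
         ") != sample count (", ncol(ds$data), ")")
  }
  if (is.character(labels)) {
    if (!all(labels %in% c("non-stress", "stress"))) {
      stop("unknown condition labels")
    }
    labels <- as.integer(labels == "stress")
  }
  if (!all(labels %in% c(0L, 1L))) stop("condition must be binary 0/1")
  discrete_dataset(
    variables = c(ds$variables, "condition"),
    arities = c(ds$arities, condition = 2L),
    data = rbind(ds$data, condition = as.integer(labels)),
    labels = c(ds$labels, list(condition = c("0", "1"))),
    cutpoints = ds$cutpoints
  )
}

#' Drop the condition variable (inverse of [append_condition()])
#' @param ds a [discrete_dataset()] containing a `"condition"` variable.
#' @return the dataset without it.
#' @export
drop_condition <- function(ds) {
  keep <- ds$variables != "condition"
  discrete_dataset(ds$variables[keep], ds$arities[keep],
                   ds$data[keep, , drop = FALSE], ds$labels[keep],
                   ds$cutpoints)
}
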