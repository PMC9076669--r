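#' Read/write count matrices as TSV with a condition sidecar
#'
#' The count file has gene ids in the first column (`gene`) and one column
#' per sample; the sidecar maps `sample` to `condition`
#' (non-stress/stress) and optional `study`.
#'
#' @param cm a [count_matrix()].
#' @param counts_path,sidecar_path file paths.
#' @return `write_count_matrix` returns the paths invisibly;
#'   `read_count_matrix` returns a [count_matrix()].
#' @export
write_count_matrix <- function(cm, counts_path, sidecar_path) {
  df <- data.frame(gene = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- data.frame(sample = colnames(cm$counts), condition = cm$condition,
                     study = cm$study %||% NA_character_,
                     stringsAsFactors = FALSE)
  write.table(side, sidecar_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(counts_path, sidecar_path))
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(counts_path, sidecar_path) {
  df <- read.delim(counts_path, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (names(df)[1] != "gene") stop(counts_path, ": first column must be 'gene'")
  dup <- which(duplicated(df$gene))
  if (length(dup) > 0) {
    stop(counts_path, ": duplicated gene id '", df$gene[dup[1]],
         "' at line ", dup[1] + 1L)
  }
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df$gene
  side <- read.delim(sidecar_path, stringsAsFactors = FALSE)
  if (!all(c("sample", "condition") %in% names(side))) {
    stop(sidecar_path, ": needs 'sample' and 'condition' columns")
  }
  miss <- setdiff(colnames(counts), side$sample)
  if (length(miss) > 0) stop(sidecar_path, ": no condition for sample(s) ",
                             paste(miss, collapse = ", "))
  side <- side[match(colnames(counts), side$sample), ]
  study <- if ("study" %in% names(side) && !all(is.na(side$study)))
    side$study else NULL
  count_matrix(counts, side$condition, study)
}

#' Read/write a discrete dataset as TSV plus a JSON header
#'
#' The TSV holds integer state codes (variables as rows, samples as
#' columns); the JSON header carries arities, state labels and any
#' discretization cutpoints.
#'
#' @param ds a [discrete_dataset()].
#' @param tsv_path,json_path file paths.
#' @export
write_discrete_dataset <- function(ds, tsv_path, json_path) {
  df <- data.frame(variable = ds$variables, ds$data,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  hdr <- list(variables = ds$variables,
              arities = unname(ds$arities),
              labels = unname(ds$labels),
              cutpoints = ds$cutpoints)
  jsonlite::write_json(hdr, json_path, auto_unbox = FALSE, digits = NA)
  invisible(c(tsv_path, json_path))
}

#' @rdname write_discrete_dataset
#' @export
read_discrete_dataset <- function(tsv_path, json_path) {
  df <- read.delim(tsv_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "variable") {
    stop(tsv_path, ": first column must be 'variable'")
  }
  hdr <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  data <- as.matrix(df[, -1, drop = FALSE])
  rownames(data) <- df$variable
  if (!identical(df$variable, as.character(hdr$variables))) {
    stop(json_path, ": variable roster disagrees with ", tsv_path)
  }
  cuts <- hdr$cutpoints
  if (length(cuts) == 0) cuts <- NULL
  discrete_dataset(hdr$variables, hdr$arities, data,
                   labels = as.list(hdr$labels), cutpoints = cuts)
}

#' Read/write directed networks as edge-list TSV
#'
#' Columns `parent`, `child` and one column per edge attribute
#' (e.g. `confidence` or `mean_weight`).
#'
#' @param g a `digraph` or `final_network`.
#' @param path file path.
#' @param nodes for reading: the full node roster (isolated nodes cannot be
#'   recovered from an edge list alone).
#' @export
write_edge_list <- function(g, path) {
  if (inherits(g, "final_network")) {
    df <- g$arcs
  } else {
    df <- data.frame(parent = g$edges[, 1], child = g$edges[, 2],
                     stringsAsFactors = FALSE)
    if (!is.null(g$confidence)) df$confidence <- g$confidence
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path, nodes = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("parent", "child") %in% names(df))) {
    stop(path, ": needs 'parent' and 'child' columns")
  }
  if (is.null(nodes)) nodes <- unique(c(df$parent, df$child))
  extra <- df[, setdiff(names(df), c("parent", "child")), drop = FALSE]
  do.call(digraph, c(list(nodes = nodes,
                          edges = cbind(df$parent, df$child)),
                     as.list(extra)))
}

#' Read/write a directed weighted network as GraphML (via igraph)
#'
#' @param g a `digraph` or `final_network` (arc mean weights become the
#'   `weight` edge attribute).
#' @param path file path.
#' @export
write_graphml <- function(g, path) {
  if (inherits(g, "final_network")) {
    ig <- igraph::graph_from_data_frame(
      data.frame(from = g$arcs$parent, to = g$arcs$child,
                 weight = g$arcs$mean_weight),
      directed = TRUE, vertices = g$all_nodes)
  } else {
    df <- data.frame(from = g$edges[, 1], to = g$edges[, 2])
    if (!is.null(g$confidence)) df$weight <- g$confidence
    ig <- igraph::graph_from_data_frame(df, directed = TRUE,
                                        vertices = g$nodes)
  }
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
read_graphml <- function(path) {
  ig <- igraph::read_graph(path, format = "graphml")
  nodes <- igraph::V(ig)$name
  el <- igraph::as_edgelist(ig)
  w <- igraph::E(ig)$weight
  if (is.null(w)) digraph(nodes, el) else digraph(nodes, el, weight = w)
}

#' Write grouped arc weights as a long-format TSV
#' @param matrices list of `arc_weights` from [group_and_weight()].
#' @param path file path; columns `group`, `parent`, `child`, `weight`.
#' @export
write_arc_weights <- function(matrices, path) {
  long <- do.call(rbind, lapply(matrices, function(aw) {
    if (nrow(aw$arcs) == 0) return(NULL)
    cbind(group = aw$group, aw$arcs)
  }))
  if (is.null(long)) {
    long <- data.frame(group = integer(0), parent = character(0),
                       child = character(0), weight = integer(0))
  }
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_arc_weights
#' @param group_size group size to restore on the `arc_weights` objects.
#' @export
read_arc_weights <- function(path, group_size) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  lapply(sort(unique(df$group)), function(gi) {
    arcs <- df[df$group == gi, c("parent", "child", "weight")]
    rownames(arcs) <- NULL
    structure(list(group = gi, group_size = group_size, arcs = arcs),
              class = "arc_weights")
  })
}
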