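# Readers for the plain-text network formats the package consumes.

read_two_cols <- function(path, sep, comment) {
  d <- utils::read.table(path, header = FALSE, sep = sep,
                         comment.char = comment, quote = "",
                         colClasses = "character",
                         stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop("expected two columns in ", path)
  d[, 1:2]
}

#' Read an edge list from delimited text
#'
#' Two columns (source, target), one edge per line; lines starting with
#' the comment character are skipped.
#'
#' @param path file path.
#' @param sep field delimiter (default tab).
#' @param comment comment character (default \code{"#"}).
#' @return two-column character matrix.
#' @export
read_edge_list <- function(path, sep = "\t", comment = "#") {
  d <- read_two_cols(path, sep, comment)
  m <- as.matrix(d)
  dimnames(m) <- list(NULL, c("from", "to"))
  m
}

#' Read node group attributes from delimited text
#'
#' Two columns: node id, group category.
#'
#' @inheritParams read_edge_list
#' @return named character vector (node id -> category) suitable for
#'   \code{\link{group_partition}}.
#' @export
read_node_groups <- function(path, sep = "\t", comment = "#") {
  d <- read_two_cols(path, sep, comment)
  setNames(d[, 2L], d[, 1L])
}

#' Read a node-attributed network from GraphML
#'
#' Uses igraph to parse the file and extracts the edge list together
#' with a categorical node attribute.
#'
#' @param path GraphML file path.
#' @param attr name of the node attribute holding the group category.
#' @return list with \code{edges} (two-column character matrix of node
#'   names) and \code{groups} (named vector, node -> category).
#' @export
read_graphml_groups <- function(path, attr) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("reading GraphML requires the 'igraph' package")
  g <- igraph::read_graph(path, format = "graphml")
  if (!attr %in% igraph::vertex_attr_names(g))
    stop(sprintf("no node attribute '%s' in %s", attr, path))
  nm <- if ("name" %in% igraph::vertex_attr_names(g))
    igraph::V(g)$name else as.character(seq_len(igraph::vcount(g)))
  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- cbind(from = nm[el[, 1L]], to = nm[el[, 2L]])
  list(edges = edges,
       groups = setNames(as.character(igraph::vertex_attr(g, attr)), nm))
}

#' Write a network sample as edge-list and attribute files
#'
#' @param net a \code{\link{er_homophily}} / \code{\link{ba_homophily}}
#'   sample.
#' @param edges_path,attrs_path output paths (tab-delimited).
#' @return \code{invisible(net)}.
#' @export
write_network_sample <- function(net, edges_path, attrs_path) {
  stopifnot(inherits(net, "network_sample"))
  utils::write.table(net$edges, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(node = names(net$labels),
                                group = unname(net$labels)),
                     attrs_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(net)
}
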