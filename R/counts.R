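#' Count edges between group pairs
#'
#' Tallies the number of edges connecting each pair of groups. In the
#' undirected case the result is upper-triangular: an intra-group edge is
#' counted once in \code{counts[i, i]} and an inter-group edge once in
#' \code{counts[i, j]} with \code{i < j}. Self-loops are rejected; the
#' models and coefficients in this package have no self-loop term.
#'
#' @param edges two-column matrix or data frame of node ids (one edge per
#'   row). Node ids are matched against \code{names(partition$index)}.
#' @param partition a \code{\link{group_partition}} covering every endpoint.
#' @param directed logical; count ordered pairs when \code{TRUE}.
#' @param multigraph logical; if \code{FALSE} (default) duplicate edges —
#'   in the undirected case \code{(u,v)} and \code{(v,u)} are the same
#'   edge — are collapsed before counting.
#' @return an object of class \code{group_edge_counts}: list with
#'   \code{counts} (B x B integer matrix), \code{directed} and \code{total}
#'   (the edge count E).
#' @examples
#' p <- group_partition(c(u = "a", v = "a", w = "b", x = "b"))
#' e <- rbind(c("u", "v"), c("w", "x"), c("u", "w"), c("v", "x"))
#' count_group_edges(e, p)$counts
#' @export
count_group_edges <- function(edges, partition, directed = FALSE,
                              multigraph = FALSE) {
  stopifnot(inherits(partition, "group_partition"))
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop("'edges' must have two columns")
  mode(edges) <- "character"
  if (nrow(edges) > 0L && any(edges[, 1L] == edges[, 2L])) {
    bad <- edges[edges[, 1L] == edges[, 2L], 1L][1L]
    stop(sprintf("self-loop at node '%s'", bad))
  }
  gi <- partition$index[edges[, 1L]]
  gj <- partition$index[edges[, 2L]]
  if (anyNA(gi) || anyNA(gj)) {
    miss <- c(edges[, 1L][is.na(gi)], edges[, 2L][is.na(gj)])[1L]
    stop(sprintf("node '%s' has no group", miss))
  }
  if (!multigraph && nrow(edges) > 0L) {
    key <- if (directed) paste(edges[, 1L], edges[, 2L], sep = "\r")
           else paste(pmin(edges[, 1L], edges[, 2L]),
                      pmax(edges[, 1L], edges[, 2L]), sep = "\r")
    keep <- !duplicated(key)
    gi <- gi[keep]; gj <- gj[keep]
  }
  B <- n_groups(partition)
  if (!directed) {  # fold into upper triangle
    lo <- pmin(gi, gj); hi <- pmax(gi, gj)
    gi <- lo; gj <- hi
  }
  counts <- matrix(0L, B, B, dimnames = list(partition$levels,
                                             partition$levels))
  if (length(gi) > 0L) {
    tab <- table(factor(gi, levels = seq_len(B)),
                 factor(gj, levels = seq_len(B)))
    counts[] <- as.integer(tab)
  }
  structure(list(counts = counts, directed = directed,
                 total = sum(counts)),
            class = "group_edge_counts")
}

#' Assemble group-pair edge counts directly from a count matrix
#'
#' Convenience constructor when aggregate counts are already known (for
#' instance the published per-network count tables). For undirected counts
#' the matrix must be upper triangular (intra-group on the diagonal,
#' inter-group above it).
#'
#' @param counts B x B non-negative matrix of edge counts.
#' @param directed logical.
#' @return a \code{group_edge_counts} object.
#' @export
group_edge_counts <- function(counts, directed = FALSE) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("'counts' must be square")
  if (any(counts < 0)) stop("negative edge count")
  if (!directed && any(counts[lower.tri(counts)] != 0))
    stop("undirected counts must be upper triangular")
  structure(list(counts = counts, directed = directed,
                 total = sum(counts)),
            class = "group_edge_counts")
}

#' @export
print.group_edge_counts <- function(x, ...) {
  cat(sprintf("%s group edge counts, E = %s\n",
              if (x$directed) "Directed" else "Undirected",
              format(x$total, big.mark = ",")))
  print(x$counts)
  invisible(x)
}
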