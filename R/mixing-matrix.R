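#' Mixing matrix of a network
#'
#' The mixing matrix \eqn{e} holds the fraction of edges connecting each
#' pair of groups; its entries sum to 1. For undirected counts the matrix
#' is made symmetric with the half-weight convention
#' \eqn{e_{ij} = e_{ji} = E_{ij} / (2E)} for \eqn{i \ne j} and
#' \eqn{e_{ii} = E_{ii} / E}, so row sums \eqn{a_i} and column sums
#' \eqn{b_i} are the fractions of edge ends attached to group \eqn{i}.
#' For directed counts \eqn{e_{ij} = E_{ij} / E}.
#'
#' @param counts a \code{\link{group_edge_counts}} object (or a plain
#'   count matrix, interpreted through \code{\link{group_edge_counts}}).
#' @param directed logical, used only when \code{counts} is a plain matrix.
#' @return a numeric B x B matrix of class \code{mixing_matrix} with
#'   attributes \code{a} (row marginals), \code{b} (column marginals) and
#'   \code{adjusted} (logical).
#' @seealso \code{\link{adjust_mixing}}, \code{\link{assortativity_nominal}}
#' @export
mixing_matrix <- function(counts, directed = FALSE) {
  if (!inherits(counts, "group_edge_counts"))
    counts <- group_edge_counts(counts, directed = directed)
  E <- counts$total
  if (E == 0) stop("no edges")
  cm <- counts$counts
  if (counts$directed) {
    e <- cm / E
  } else {
    e <- (cm + t(cm)) / (2 * E)   # halves off-diagonals, keeps diagonal
  }
  new_mixing_matrix(e, adjusted = FALSE)
}

new_mixing_matrix <- function(e, adjusted = FALSE) {
  structure(e, a = rowSums(e), b = colSums(e), adjusted = adjusted,
            class = c("mixing_matrix", class(matrix())))
}

#' Adjust a mixing matrix for group sizes
#'
#' Divides each entry of the mixing matrix by the product of the group
#' fractions, \eqn{e^*_{ij} = e_{ij} / (f_i f_j)}, removing the "pool of
#' opportunities" advantage that larger groups have. By default the
#' adjusted matrix is renormalized to sum to 1 so that it remains a valid
#' mixing matrix and can be fed to \code{\link{assortativity_nominal}};
#' set \code{renormalize = FALSE} to inspect the raw rescaled entries.
#'
#' With equal group fractions the adjustment is a uniform rescaling and
#' (after renormalization) leaves the matrix unchanged.
#'
#' @param m a \code{\link{mixing_matrix}}.
#' @param fractions numeric vector of group fractions \eqn{f_i}, all
#'   positive, in the matrix's group order.
#' @param renormalize logical; divide by the grand sum (default).
#' @return a \code{mixing_matrix} with the \code{adjusted} attribute set.
#' @examples
#' e <- mixing_matrix(group_edge_counts(matrix(c(1, 0, 0, 1), 2, 2)))
#' adjust_mixing(e, c(0.2, 0.8))
#' @export
adjust_mixing <- function(m, fractions, renormalize = TRUE) {
  stopifnot(inherits(m, "mixing_matrix"))
  if (isTRUE(attr(m, "adjusted"))) stop("mixing matrix is already adjusted")
  f <- check_fractions(fractions, nrow(m))
  e <- unclass(m) / outer(f, f)
  attributes(e) <- attributes(unclass(m))[c("dim", "dimnames")]
  if (renormalize) e <- e / sum(e)
  new_mixing_matrix(e, adjusted = TRUE)
}

check_fractions <- function(fractions, B) {
  f <- as.numeric(fractions)
  if (length(f) == 1L && B == 2L) f <- c(f, 1 - f)
  if (length(f) != B)
    stop(sprintf("expected %d group fractions, got %d", B, length(f)))
  if (any(f <= 0)) stop("degenerate group")
  if (abs(sum(f) - 1) > 1e-8)
    stop("group fractions must sum to 1")
  f
}

#' @export
print.mixing_matrix <- function(x, digits = 4, ...) {
  cat(sprintf("%s mixing matrix (%d groups)\n",
              if (isTRUE(attr(x, "adjusted"))) "Adjusted" else "Observed",
              nrow(x)))
  m <- unclass(x)
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  print(round(m, digits))
  cat("marginals a:", paste(round(attr(x, "a"), digits), collapse = " "),
      "\n          b:", paste(round(attr(x, "b"), digits), collapse = " "),
      "\n")
  invisible(x)
}

#' Serialize a mixing matrix to JSON or TSV
#'
#' JSON output is an object with fields \code{groups}, \code{e} (row-major
#' matrix), \code{a}, \code{b} and \code{adjusted}; TSV output is a plain
#' labelled matrix dump.
#'
#' @param m a \code{\link{mixing_matrix}}.
#' @param path output file path.
#' @param format \code{"json"} or \code{"tsv"}.
#' @return \code{path}, invisibly.
#' @export
write_mixing_matrix <- function(m, path, format = c("json", "tsv")) {
  stopifnot(inherits(m, "mixing_matrix"))
  format <- match.arg(format)
  groups <- rownames(m)
  if (is.null(groups)) groups <- as.character(seq_len(nrow(m)))
  if (format == "json") {
    obj <- list(groups = groups,
                e = unname(apply(unclass(m), 1L, as.numeric,
                                 simplify = FALSE)),
                a = as.numeric(attr(m, "a")),
                b = as.numeric(attr(m, "b")),
                adjusted = isTRUE(attr(m, "adjusted")))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    d <- as.data.frame(unclass(m))
    names(d) <- groups
    utils::write.table(cbind(group = groups, d), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
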