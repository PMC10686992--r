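#' Nominal assortativity of a mixing matrix
#'
#' Computes the nominal (discrete) assortativity coefficient
#' \deqn{r = \frac{\sum_i e_{ii} - \sum_i a_i b_i}{1 - \sum_i a_i b_i},}
#' where \eqn{a_i = \sum_j e_{ij}} and \eqn{b_i = \sum_j e_{ji}} are the
#' fractions of edges that begin and end at nodes of group \eqn{i}. The
#' row-sum/column-sum accounting matters for asymmetric (directed)
#' mixing matrices; for symmetric matrices it reduces to the familiar
#' \eqn{\sum_i a_i^2} form. The coefficient is 1 exactly when all edges
#' are intra-group, 0 when \eqn{e_{ii} = a_i b_i} (no group preference),
#' and negative when inter-group edges dominate.
#'
#' @param m a \code{\link{mixing_matrix}} or a plain numeric matrix whose
#'   entries sum to 1.
#' @return an object of class \code{assortativity}: list with \code{r},
#'   \code{trace} (\eqn{\sum_i e_{ii}}), \code{expected_trace}
#'   (\eqn{\sum_i a_i b_i}) and \code{adjusted}.
#' @examples
#' e <- mixing_matrix(group_edge_counts(matrix(c(6, 2, 0, 2), 2, 2)))
#' assortativity_nominal(e)
#' @export
assortativity_nominal <- function(m) {
  if (!inherits(m, "mixing_matrix")) {
    m <- as.matrix(m)
    if (abs(sum(m) - 1) > 1e-8) stop("mixing matrix must sum to 1")
    m <- new_mixing_matrix(m, adjusted = FALSE)
  }
  a <- attr(m, "a"); b <- attr(m, "b")
  tr <- sum(diag(unclass(m)))
  ab <- sum(a * b)
  if (1 - ab <= .Machine$double.eps * 4)
    stop("assortativity undefined for a single group")
  structure(list(r = (tr - ab) / (1 - ab), trace = tr,
                 expected_trace = ab,
                 adjusted = isTRUE(attr(m, "adjusted"))),
            class = "assortativity")
}

#' Adjusted nominal assortativity
#'
#' Nominal assortativity of the group-size adjusted mixing matrix:
#' \code{assortativity_nominal(adjust_mixing(m, fractions))}. The
#' adjustment removes the group-size bias, so on networks generated with
#' fixed mixing tendencies the coefficient no longer depends on the
#' minority fraction.
#'
#' @inheritParams adjust_mixing
#' @return an \code{assortativity} object with \code{adjusted = TRUE}.
#' @export
assortativity_adjusted <- function(m, fractions) {
  assortativity_nominal(adjust_mixing(m, fractions))
}

#' @export
print.assortativity <- function(x, digits = 4, ...) {
  cat(sprintf("%s assortativity r = %.*f\n",
              if (x$adjusted) "Adjusted nominal" else "Nominal",
              digits, x$r))
  cat(sprintf("  intra-group edge fraction %.*f, expected %.*f\n",
              digits, x$trace, digits, x$expected_trace))
  invisible(x)
}

#' Assortativity straight from an edge list
#'
#' Composes \code{\link{group_partition}}, \code{\link{count_group_edges}},
#' \code{\link{mixing_matrix}} and (optionally) \code{\link{adjust_mixing}}.
#'
#' @param edges two-column matrix or data frame of node-id pairs.
#' @param groups named vector: node id -> group category.
#' @param adjusted logical; adjust for group sizes (fractions taken from
#'   the partition).
#' @param directed logical.
#' @return an \code{assortativity} object.
#' @examples
#' edges <- rbind(c("u0", "v0"), c("v0", "w1"), c("w1", "x1"))
#' groups <- c(u0 = "g0", v0 = "g0", w1 = "g1", x1 = "g1")
#' assortativity_network(edges, groups)$r  # 1/3
#' @export
assortativity_network <- function(edges, groups, adjusted = FALSE,
                                  directed = FALSE) {
  p <- group_partition(groups)
  m <- mixing_matrix(count_group_edges(edges, p, directed = directed))
  if (adjusted) assortativity_adjusted(m, p$fractions)
  else assortativity_nominal(m)
}

#' Both coefficients from two-group aggregate counts
#'
#' Convenience path for the published per-network count summaries: given
#' minority-minority, inter-group and majority-majority edge counts plus
#' the minority fraction, returns the nominal and the adjusted nominal
#' assortativity. The total edge count is \code{E00 + E01 + E11}.
#'
#' @param E00 intra-group edge count of the minority group.
#' @param E01 inter-group edge count.
#' @param E11 intra-group edge count of the majority group.
#' @param f0 minority fraction, in (0, 1).
#' @return named numeric vector \code{c(r = ..., r_adj = ...)}.
#' @examples
#' assortativity_counts(17468, 91738, 212846, 0.21)  # about (0.10, 0.14)
#' @export
assortativity_counts <- function(E00, E01, E11, f0) {
  if (any(c(E00, E01, E11) < 0)) stop("negative edge count")
  if (E00 + E01 + E11 == 0) stop("no edges")
  if (f0 <= 0 || f0 >= 1) stop("f0 must be in (0, 1)")
  cnt <- group_edge_counts(matrix(c(E00, 0, E01, E11), 2, 2),
                           directed = FALSE)
  m <- mixing_matrix(cnt)
  c(r = assortativity_nominal(m)$r,
    r_adj = assortativity_adjusted(m, c(f0, 1 - f0))$r)
}
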