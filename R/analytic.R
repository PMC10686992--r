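#' Expand homophily parameters to a row-stochastic matrix
#'
#' The mixing tendency \eqn{h_{ij}} is the intrinsic probability that a
#' node of group \eqn{i} connects to a node of group \eqn{j}; rows sum
#' to 1. A scalar \code{h} expands to \eqn{h_{ii} = h} with the
#' off-diagonal mass split evenly, \eqn{h_{ij} = (1-h)/(B-1)} — for two
#' groups this is the complement rule \eqn{h_{ij} = 1 - h_{ii}}. A
#' length-B vector gives the diagonal (each row's off-diagonal mass again
#' split evenly); a full matrix is validated as row-stochastic.
#'
#' @param h scalar, length-B vector of intra-group tendencies, or a B x B
#'   row-stochastic matrix with entries in \code{[0, 1]}.
#' @param B number of groups (ignored when \code{h} is a matrix).
#' @return a B x B numeric matrix with rows summing to 1.
#' @examples
#' homophily_matrix(0.8)            # 2 groups, complement rule
#' homophily_matrix(c(0.8, 0.2))    # asymmetric two-group mixing
#' @export
homophily_matrix <- function(h, B = 2L) {
  if (is.matrix(h)) {
    if (nrow(h) != ncol(h)) stop("'h' must be square")
    if (any(h < 0 | h > 1)) stop("homophily tendencies must be in [0, 1]")
    if (any(abs(rowSums(h) - 1) > 1e-8))
      stop("rows of 'h' must sum to 1")
    return(unname(h))
  }
  h <- as.numeric(h)
  if (any(h < 0 | h > 1)) stop("homophily tendencies must be in [0, 1]")
  if (length(h) == 1L) h <- rep(h, B)
  B <- length(h)
  if (B < 2L) stop("need at least two groups")
  hm <- matrix(0, B, B)
  diag(hm) <- h
  off <- (1 - h) / (B - 1)
  for (i in seq_len(B)) hm[i, -i] <- off[i]
  hm
}

#' Expected mixing matrix under the random homophily model
#'
#' Under random tie formation with group fractions \eqn{f} and mixing
#' tendencies \eqn{h}, the probability weight of an edge from group
#' \eqn{i} to group \eqn{j} is \eqn{p_{ij} = f_i f_j h_{ij}}, and the
#' expected mixing matrix is \eqn{e_{ij} = p_{ij} / \sum_{ij} p_{ij}}.
#' The ordered-pair (directed) accounting is retained, so the matrix is
#' asymmetric whenever \eqn{h_{ij} \ne h_{ji}} — this is what makes the
#' zero locus of the nominal coefficient exact under asymmetric mixing.
#'
#' @param fractions group fractions \eqn{f_i} (a scalar \code{f0} is
#'   completed to \code{c(f0, 1 - f0)}).
#' @param h homophily parameters, see \code{\link{homophily_matrix}}.
#' @return a \code{\link{mixing_matrix}}.
#' @examples
#' expected_mixing(0.5, 0.8)  # [[0.4, 0.1], [0.1, 0.4]]
#' @export
expected_mixing <- function(fractions, h) {
  f <- as.numeric(fractions)
  if (length(f) == 1L) f <- c(f, 1 - f)
  if (any(f <= 0) || abs(sum(f) - 1) > 1e-8)
    stop("group fractions must be positive and sum to 1")
  hm <- homophily_matrix(h, B = length(f))
  if (nrow(hm) != length(f))
    stop("dimension mismatch between fractions and h")
  p <- outer(f, f) * hm
  T <- sum(p)
  if (T <= 0) stop("degenerate model")
  new_mixing_matrix(p / T, adjusted = FALSE)
}

#' Closed-form nominal assortativity of the two-group homophily model
#'
#' Evaluates the expected nominal assortativity of a random network with
#' minority fraction \code{f0} and intra-group tendencies \code{h00}
#' (minority) and \code{h11} (majority), with the complement rule
#' \eqn{h_{01} = 1 - h_{00}}, \eqn{h_{10} = 1 - h_{11}}. Written out from
#' \eqn{p_{ij} = f_i f_j h_{ij}}:
#' the intra-group fraction is \eqn{(f_0^2 h_{00} + f_1^2 h_{11})/T} and
#' the expected trace uses row-sum times column-sum marginals. At equal
#' group sizes (\code{f0 = 0.5}) this reduces to \eqn{h_{00}+h_{11}-1};
#' as \code{f0} shrinks at fixed symmetric \code{h}, the coefficient is
#' dragged toward zero — the group-size bias this package adjusts for.
#'
#' All three arguments are vectorized (recycled to a common length).
#'
#' @param f0 minority fraction, in (0, 1).
#' @param h00 minority intra-group tendency, in \code{[0, 1]}.
#' @param h11 majority intra-group tendency, in \code{[0, 1]};
#'   defaults to \code{h00} (symmetric mixing).
#' @return numeric vector of coefficients.
#' @examples
#' analytic_r(0.5, 0.8)        # 0.6
#' analytic_r(0.1, 0.8, 0.2)   # 0: on the zero locus h00 = 1 - h11
#' @export
analytic_r <- function(f0, h00, h11 = h00) {
  k <- max(length(f0), length(h00), length(h11))
  f0 <- rep_len(f0, k); h00 <- rep_len(h00, k); h11 <- rep_len(h11, k)
  if (any(f0 <= 0 | f0 >= 1)) stop("f0 must be in (0, 1)")
  if (any(c(h00, h11) < 0 | c(h00, h11) > 1))
    stop("homophily tendencies must be in [0, 1]")
  f1 <- 1 - f0
  h01 <- 1 - h00; h10 <- 1 - h11
  T <- f0^2 * h00 + f1^2 * h11 + f0 * f1 * (h01 + h10)
  if (any(T <= 0)) stop("degenerate model")
  tr <- (f0^2 * h00 + f1^2 * h11) / T
  a0 <- (f0^2 * h00 + f0 * f1 * h01) / T   # row sums
  b0 <- (f0^2 * h00 + f0 * f1 * h10) / T   # column sums
  ab <- a0 * b0 + (1 - a0) * (1 - b0)
  (tr - ab) / (1 - ab)
}

#' Closed-form adjusted nominal assortativity
#'
#' The adjusted coefficient of the two-group homophily model is simply
#' \eqn{h_{00} + h_{11} - 1}, for every minority fraction: dividing the
#' expected mixing matrix by \eqn{f_i f_j} leaves only the tendencies, so
#' the group-size dependence cancels exactly. This is the closed form of
#' \code{assortativity_adjusted(expected_mixing(f0, h), f0)}.
#'
#' @inheritParams analytic_r
#' @return numeric vector of coefficients in \code{[-1, 1]}.
#' @examples
#' analytic_r_adj(0.8, 0.8)  # 0.6
#' analytic_r_adj(0.8, 0.2)  # 0: asymmetric mixing invisible to r_adj
#' @export
analytic_r_adj <- function(h00, h11 = h00) {
  k <- max(length(h00), length(h11))
  h00 <- rep_len(h00, k); h11 <- rep_len(h11, k)
  if (any(c(h00, h11) < 0 | c(h00, h11) > 1))
    stop("homophily tendencies must be in [0, 1]")
  h00 + h11 - 1
}

#' The zero locus of both assortativity coefficients
#'
#' For every minority fraction, both the nominal and the adjusted
#' coefficient vanish when \eqn{h_{00} = 1 - h_{11}}: a strongly
#' homophilic minority combined with a correspondingly heterophilic
#' majority is indistinguishable, to any single-valued coefficient, from
#' the absence of mixing preferences. Given \code{h00}, returns the
#' majority tendency on that locus.
#'
#' @param h00 minority intra-group tendency, in \code{[0, 1]}.
#' @return \code{1 - h00}.
#' @export
zero_locus <- function(h00) {
  if (any(h00 < 0 | h00 > 1)) stop("h00 must be in [0, 1]")
  1 - h00
}

#' Sweep the analytic coefficients over a parameter grid
#'
#' Evaluates the closed-form nominal or adjusted coefficient on the full
#' grid of minority fractions and mixing tendencies, in long format —
#' the analytic counterpart of the model's calibration curves and
#' heatmaps.
#'
#' @param f0 grid of minority fractions.
#' @param h00 grid of minority intra-group tendencies.
#' @param h11 grid of majority tendencies; \code{NULL} (default) means
#'   symmetric mixing \code{h11 = h00} (the two grids are then paired,
#'   not crossed).
#' @param measure \code{"nominal"} or \code{"adjusted"}.
#' @return data frame with columns \code{f0}, \code{h00}, \code{h11},
#'   \code{measure}, \code{value}.
#' @examples
#' head(assortativity_sweep(f0 = c(0.1, 0.5), h00 = c(0.2, 0.8)))
#' @export
assortativity_sweep <- function(f0 = seq(0.05, 0.5, by = 0.05),
                                h00 = seq(0, 1, by = 0.05),
                                h11 = NULL,
                                measure = c("nominal", "adjusted")) {
  measure <- match.arg(measure)
  g <- if (is.null(h11)) expand.grid(f0 = f0, h00 = h00)
       else expand.grid(f0 = f0, h00 = h00, h11 = h11)
  if (is.null(h11)) g$h11 <- g$h00
  g$measure <- measure
  g$value <- if (measure == "nominal")
    analytic_r(g$f0, g$h00, g$h11)
  else analytic_r_adj(g$h00, g$h11)
  g[, c("f0", "h00", "h11", "measure", "value")]
}
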