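#' Estimate asymmetric intra-group mixing tendencies from counts
#'
#' Inverts the two-group random homophily model to recover the minority
#' and majority intra-group tendencies from aggregate data. With
#' \eqn{e_{00} = E_{00}/E} and \eqn{e_{11} = E_{11}/E} the raw intra-group
#' edge fractions (note: normalized by \eqn{E}, not the half-weight
#' mixing-matrix entries), the model normalizer is
#' \deqn{\hat T = \frac{2 f_0 f_1}{1 - e_{00}(1 - f_1/f_0)
#'   - e_{11}(1 - f_0/f_1)},}
#' and the tendencies follow as
#' \eqn{\hat h_{00} = e_{00}\,\hat T / f_0^2} and
#' \eqn{\hat h_{11} = e_{11}\,\hat T / f_1^2}. On the expected edge
#' fractions of the model the inversion is exact. Estimates falling
#' outside \code{[0, 1]} are flagged, not clipped — an out-of-range value
#' is evidence that the random homophily model does not fit.
#'
#' @param E total edge count (> 0).
#' @param E00 minority intra-group edge count.
#' @param E11 majority intra-group edge count.
#' @param f0 minority fraction, in (0, 1).
#' @param model generative model assumed for the inversion; only
#'   \code{"er"} (random tie formation) is available.
#' @return an object of class \code{homophily_fit}; see
#'   \code{\link{homophily_fit}} for the fields and methods.
#' @examples
#' fit <- estimate_homophily(E = 1000, E00 = 400, E11 = 400, f0 = 0.5)
#' coef(fit)  # h00 = h11 = 0.8
#' @export
estimate_homophily <- function(E, E00, E11, f0, model = "er") {
  if (!identical(model, "er")) stop(sprintf("unsupported model: %s", model))
  if (E <= 0) stop("no edges")
  if (E00 < 0 || E11 < 0) stop("negative edge count")
  if (E00 + E11 > E) stop("intra-group counts exceed total edges")
  if (f0 <= 0 || f0 >= 1) stop("f0 must be in (0, 1)")
  f1 <- 1 - f0
  e00 <- E00 / E
  e11 <- E11 / E
  den <- 1 - e00 * (1 - f1 / f0) - e11 * (1 - f0 / f1)
  if (den <= 0) stop("counts inconsistent with ER-homophily model")
  T_hat <- 2 * f0 * f1 / den
  h <- c(h00 = e00 * T_hat / f0^2, h11 = e11 * T_hat / f1^2)
  new_homophily_fit(h, T_hat,
                    inputs = c(E = E, E00 = E00, E11 = E11, f0 = f0),
                    e_intra = c(e00 = e00, e11 = e11), n = NA_integer_)
}

new_homophily_fit <- function(h, T_hat, inputs, e_intra, n) {
  structure(list(coefficients = h, T = T_hat, inputs = inputs,
                 e_intra = e_intra, n = n, model = "er",
                 out_of_range = any(h < 0 | h > 1)),
            class = "homophily_fit")
}

#' Fit the homophily model to a two-group network
#'
#' Counts the network's group-pair edges, takes the minority fraction
#' from the node labels, and applies the analytical inversion of
#' \code{\link{estimate_homophily}}. The returned fit carries the
#' network's size, so \code{\link{simulate.homophily_fit}} can generate
#' replicate networks under the fitted tendencies.
#'
#' @param edges two-column matrix or data frame of node-id pairs.
#' @param groups named vector: node id -> group category; exactly two
#'   categories.
#' @param model only \code{"er"}.
#' @return an object of class \code{homophily_fit}: list with
#'   \code{coefficients} (\code{h00}, \code{h11}), \code{T} (estimated
#'   model normalizer \eqn{\sum_{ij} p_{ij}}), \code{inputs} (E, E00,
#'   E11, f0), \code{e_intra} (raw intra-group edge fractions), \code{n}
#'   (node count, \code{NA} for count-only fits), and
#'   \code{out_of_range} (TRUE when an estimate leaves \code{[0, 1]}).
#' @seealso \code{\link{estimate_homophily}} for the aggregate-count
#'   interface and the model equations.
#' @export
homophily_fit <- function(edges, groups, model = "er") {
  p <- group_partition(groups)
  if (n_groups(p) != 2L) stop("estimator defined for two groups")
  cnt <- count_group_edges(edges, p, directed = FALSE)
  fit <- estimate_homophily(E = cnt$total, E00 = cnt$counts[1L, 1L],
                            E11 = cnt$counts[2L, 2L],
                            f0 = p$fractions[1L], model = model)
  fit$n <- length(p$index)
  fit
}

#' @export
print.homophily_fit <- function(x, digits = 4, ...) {
  cat("Asymmetric homophily estimate (random homophily model)\n")
  cat(sprintf("  h00 (minority) = %.*f\n  h11 (majority) = %.*f\n",
              digits, x$coefficients[["h00"]],
              digits, x$coefficients[["h11"]]))
  if (x$out_of_range)
    cat("  warning: estimate outside [0, 1] - model misfit likely\n")
  invisible(x)
}

#' @export
coef.homophily_fit <- function(object, ...) object$coefficients

#' @export
summary.homophily_fit <- function(object, ...) {
  r_pair <- assortativity_counts(object$inputs[["E00"]],
                                 object$inputs[["E"]] -
                                   object$inputs[["E00"]] -
                                   object$inputs[["E11"]],
                                 object$inputs[["E11"]],
                                 object$inputs[["f0"]])
  structure(list(fit = object, r = r_pair[["r"]],
                 r_adj = r_pair[["r_adj"]],
                 r_model = analytic_r_adj(object$coefficients[["h00"]],
                                          object$coefficients[["h11"]])),
            class = "summary.homophily_fit")
}

#' @export
print.summary.homophily_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat(sprintf("  T (sum of p_ij)  = %.*f\n", digits, x$fit$T))
  cat(sprintf("  nominal r        = %.*f\n  adjusted r       = %.*f\n",
              digits, x$r, digits, x$r_adj))
  cat(sprintf("  h00 + h11 - 1    = %.*f\n", digits, x$r_model))
  cat(sprintf("  inputs: E = %d, E00 = %d, E11 = %d, f0 = %.4f\n",
              x$fit$inputs[["E"]], x$fit$inputs[["E00"]],
              x$fit$inputs[["E11"]], x$fit$inputs[["f0"]]))
  invisible(x)
}

#' Simulate replicate networks from a fitted homophily model
#'
#' Generates networks from the random homophily model at the fitted
#' tendencies, matching the fitted network's size and edge count (both
#' can be overridden, and must be supplied for count-only fits where the
#' node count is unknown).
#'
#' @param object a \code{\link{homophily_fit}}.
#' @param nsim number of replicate networks.
#' @param seed integer seed for the first replicate; replicate k uses
#'   \code{seed + k - 1}.
#' @param n nodes per replicate (default: the fitted network's size).
#' @param m_edges edges per replicate (default: the fitted E).
#' @param ... unused.
#' @return a list of \code{\link{er_homophily}} samples (a single sample
#'   when \code{nsim = 1}).
#' @export
simulate.homophily_fit <- function(object, nsim = 1, seed = NULL,
                                   n = object$n,
                                   m_edges = object$inputs[["E"]], ...) {
  if (is.na(n)) stop("node count unknown; supply 'n'")
  h <- pmin(pmax(object$coefficients, 0), 1)  # simulation needs valid probs
  seeds <- if (is.null(seed)) rep(list(NULL), nsim)
           else as.list(seed + seq_len(nsim) - 1L)
  out <- lapply(seeds, function(s)
    er_homophily(n = n, f0 = object$inputs[["f0"]],
                 h = c(h[["h00"]], h[["h11"]]),
                 m_edges = m_edges, seed = s))
  if (nsim == 1L) out[[1L]] else out
}
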