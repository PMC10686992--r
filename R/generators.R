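# Seeded generative models with tunable group mixing.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  force(code)
}

group_sizes_two <- function(n, f0) {
  if (n < 2L) stop("need at least two nodes")
  if (f0 <= 0 || f0 >= 1) stop("f0 must be in (0, 1)")
  n0 <- as.integer(round(n * f0))
  if (n0 < 1L || n - n0 < 1L) stop("each group needs at least one node")
  c(n0, n - n0)
}

#' Random network with tunable group mixing
#'
#' Generates a simple undirected two-group network in which the
#' probability weight of an edge between groups \eqn{i} and \eqn{j} is
#' \eqn{p_{ij} = f_i f_j h_{ij}}: an ordered candidate pair is drawn with
#' group-pair probability \eqn{f_i f_j} (source node uniform, target
#' group by the group fractions, target node uniform within that group)
#' and accepted with probability \eqn{h_{ij}}. A rejection consumes a
#' step but no edge; candidate pairs that would repeat an existing edge
#' or form a self-loop are redrawn without consuming acceptance
#' probability, so the realized mixing tracks \eqn{h} as long as the
#' graph stays sparse. Sampling continues until \code{m_edges} distinct
#' edges are placed.
#'
#' Nodes \code{1..n0} (with \code{n0 = round(n * f0)}) form group
#' \code{"0"} and the rest group \code{"1"}.
#'
#' @param n number of nodes.
#' @param f0 fraction of nodes in group 0, in (0, 1); conventionally the
#'   minority (\code{f0 <= 0.5}).
#' @param h mixing tendencies: scalar \code{h} (symmetric, complement
#'   rule for the off-diagonals), length-2 vector \code{c(h00, h11)}, or
#'   a full 2 x 2 row-stochastic matrix.
#' @param m_edges number of edges to place.
#' @param seed optional integer seed; the caller's RNG state is restored
#'   afterwards.
#' @return an object of class \code{network_sample}: list with
#'   \code{edges} (two-column integer matrix), \code{labels} (named
#'   vector of group labels \code{"0"}/\code{"1"}), \code{seed} and
#'   \code{spec} (the generating parameters).
#' @examples
#' net <- er_homophily(n = 100, f0 = 0.3, h = 0.8, m_edges = 400, seed = 1)
#' assortativity_network(net$edges, net$labels)$r
#' @export
er_homophily <- function(n, f0, h, m_edges, seed = NULL) {
  sizes <- group_sizes_two(n, f0)
  hm <- homophily_matrix(h, B = 2L)
  max_pairs <- choose(sizes[1], 2) + choose(sizes[2], 2) +
    prod(sizes)
  if (m_edges < 0 || m_edges > max_pairs)
    stop("m_edges exceeds the number of simple-graph edges")
  glab <- rep(c(0L, 1L), sizes)
  with_seed(seed, {
    edges <- matrix(0L, m_edges, 2L,
                    dimnames = list(NULL, c("from", "to")))
    seen <- new.env(hash = TRUE, parent = emptyenv())
    placed <- 0L
    proposals <- 0L
    cap <- max(2e5, 400 * m_edges)
    starts <- c(0L, sizes[1L])
    while (placed < m_edges) {
      if (proposals > cap)
        stop(sprintf(
          "unable to reach the requested edge count (%d of %d placed)",
          placed, m_edges))
      B <- max(256L, 2L * (m_edges - placed))
      src <- sample.int(n, B, replace = TRUE)
      tg <- sample.int(2L, B, replace = TRUE, prob = sizes / n)
      tgt <- starts[tg] + floor(runif(B) * sizes[tg]) + 1L
      for (k in 1:20) {            # redraw self-pairs within the group
        hit <- which(tgt == src)
        if (length(hit) == 0L) break
        tgt[hit] <- starts[tg[hit]] +
          floor(runif(length(hit)) * sizes[tg[hit]]) + 1L
      }
      ok <- tgt != src
      proposals <- proposals + B
      acc <- ok & runif(B) < hm[cbind(glab[src] + 1L, glab[tgt] + 1L)]
      if (!any(acc)) next
      s <- src[acc]; t <- tgt[acc]
      key <- as.character(pmin(s, t) * n + pmax(s, t))
      fresh <- !duplicated(key) &
        !vapply(key, exists, logical(1), envir = seen, inherits = FALSE)
      s <- s[fresh]; t <- t[fresh]; key <- key[fresh]
      if (length(s) == 0L) next
      take <- seq_len(min(length(s), m_edges - placed))
      for (kk in key[take]) assign(kk, TRUE, envir = seen)
      edges[placed + take, 1L] <- s[take]
      edges[placed + take, 2L] <- t[take]
      placed <- placed + length(take)
    }
    new_network_sample(edges, glab, seed,
                       spec = list(model = "er", n = n, f0 = f0, h = hm,
                                   m_edges = m_edges))
  })
}

#' Growing scale-free network with group mixing
#'
#' Preferential-attachment growth combined with homophily: starting from
#' a fully connected seed of \code{m_per_node + 1} nodes, each arriving
#' node of group \eqn{i} connects to \code{m_per_node} distinct existing
#' targets chosen with probability proportional to
#' \eqn{h_{ij} \times k_{target}} (mixing tendency times degree). Group
#' memberships are assigned by shuffling a fixed label vector with
#' \code{round(n * f0)} group-0 nodes. When fewer targets have positive
#' weight than requested (e.g. fully homophilous mixing before any
#' same-group node exists), only the positive-weight targets are used.
#'
#' @inheritParams er_homophily
#' @param m_per_node edges added per arriving node.
#' @return a \code{network_sample}; \code{spec$model} is \code{"ba"}.
#' @export
ba_homophily <- function(n, f0, h, m_per_node, seed = NULL) {
  sizes <- group_sizes_two(n, f0)
  hm <- homophily_matrix(h, B = 2L)
  m <- as.integer(m_per_node)
  if (m < 1L) stop("m_per_node must be at least 1")
  if (n <= m + 1L) stop("n must exceed m_per_node + 1")
  with_seed(seed, {
    glab <- sample(rep(c(0L, 1L), sizes))
    seedn <- m + 1L
    from <- integer(0); to <- integer(0)
    for (i in seq_len(seedn - 1L))            # seed clique
      for (j in (i + 1L):seedn) { from <- c(from, i); to <- c(to, j) }
    deg <- integer(n)
    deg[seq_len(seedn)] <- seedn - 1L
    for (v in (seedn + 1L):n) {
      existing <- seq_len(v - 1L)
      w <- hm[glab[v] + 1L, glab[existing] + 1L] * deg[existing]
      pos <- sum(w > 0)
      k <- min(m, pos)
      tgt <- if (k > 0L) {
        if (pos == 1L) existing[w > 0] else
          sample(existing, k, prob = w)
      } else sample(existing, 1L)             # keep the graph connected
      from <- c(from, rep(v, length(tgt))); to <- c(to, tgt)
      deg[tgt] <- deg[tgt] + 1L
      deg[v] <- deg[v] + length(tgt)
    }
    new_network_sample(cbind(from = from, to = to), glab, seed,
                       spec = list(model = "ba", n = n, f0 = f0, h = hm,
                                   m_per_node = m))
  })
}

new_network_sample <- function(edges, glab, seed, spec) {
  labels <- setNames(as.character(glab), as.character(seq_along(glab)))
  structure(list(edges = matrix(as.character(edges), ncol = 2L,
                                dimnames = dimnames(edges)),
                 labels = labels,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 spec = spec),
            class = "network_sample")
}

#' @export
print.network_sample <- function(x, ...) {
  cat(sprintf("network_sample: model %s, %d nodes, %d edges, f0 = %.3f%s\n",
              x$spec$model, x$spec$n, nrow(x$edges), x$spec$f0,
              if (is.na(x$seed)) "" else sprintf(", seed %d", x$seed)))
  invisible(x)
}

#' Ensemble of generated networks with per-run mixing statistics
#'
#' Generates \code{n_runs} independent networks from one generator
#' specification and computes, for each run, the nominal assortativity,
#' the adjusted assortativity, and the estimated intra-group tendencies.
#' Per-run seeds are derived from the master seed (\code{seed + run}),
#' so the whole table is reproducible.
#'
#' @inheritParams er_homophily
#' @param n_runs number of independent networks.
#' @param model \code{"er"} or \code{"ba"}.
#' @param m_edges edges per network (ER model); default \code{4 * n},
#'   i.e. mean degree 8.
#' @param m_per_node edges per arriving node (BA model).
#' @param seed master integer seed.
#' @return a data frame of class \code{mixing_ensemble} with one row per
#'   run: \code{run}, \code{seed}, \code{r}, \code{r_adj},
#'   \code{h00_hat}, \code{h11_hat}, \code{flagged}. Summarize with
#'   \code{\link{summary.mixing_ensemble}}.
#' @examples
#' ens <- mixing_ensemble(5, n = 100, f0 = 0.3, h = 0.8, m_edges = 300,
#'                        seed = 42)
#' summary(ens)
#' @export
mixing_ensemble <- function(n_runs, n, f0, h, model = c("er", "ba"),
                            m_edges = 4 * n, m_per_node = 4,
                            seed = NULL) {
  model <- match.arg(model)
  if (n_runs < 1L) stop("n_runs must be at least 1")
  seeds <- if (is.null(seed)) rep(NA_integer_, n_runs)
           else (as.integer(seed) + seq_len(n_runs)) %% .Machine$integer.max
  rows <- lapply(seq_len(n_runs), function(k) {
    s <- if (is.na(seeds[k])) NULL else seeds[k]
    net <- if (model == "er")
      er_homophily(n, f0, h, m_edges, seed = s)
    else ba_homophily(n, f0, h, m_per_node, seed = s)
    p <- group_partition(net$labels)
    cnt <- count_group_edges(net$edges, p)
    # keep the drawn source -> target orientation: the model defines its
    # mixing matrix over ordered pairs, and only that accounting makes the
    # asymmetric zero locus h00 = 1 - h11 land on r = 0
    m <- mixing_matrix(count_group_edges(net$edges, p, directed = TRUE))
    fit <- tryCatch(
      estimate_homophily(cnt$total, cnt$counts[1, 1], cnt$counts[2, 2],
                         p$fractions[1]),
      error = function(e) NULL)
    data.frame(run = k, seed = seeds[k],
               r = assortativity_nominal(m)$r,
               r_adj = assortativity_adjusted(m, p$fractions)$r,
               h00_hat = if (is.null(fit)) NA_real_ else coef(fit)[["h00"]],
               h11_hat = if (is.null(fit)) NA_real_ else coef(fit)[["h11"]],
               flagged = if (is.null(fit)) TRUE else fit$out_of_range)
  })
  out <- do.call(rbind, rows)
  attr(out, "spec") <- list(model = model, n = n, f0 = f0,
                            h = homophily_matrix(h, 2L),
                            m_edges = m_edges, m_per_node = m_per_node,
                            seed = seed)
  class(out) <- c("mixing_ensemble", "data.frame")
  out
}

#' Summarize an ensemble: means and standard errors
#'
#' @param object a \code{\link{mixing_ensemble}}.
#' @param ... unused.
#' @return data frame with one row per statistic (\code{r}, \code{r_adj},
#'   \code{h00_hat}, \code{h11_hat}): ensemble \code{mean}, standard
#'   error of the mean \code{se}, and \code{n_runs}.
#' @export
summary.mixing_ensemble <- function(object, ...) {
  stats <- c("r", "r_adj", "h00_hat", "h11_hat")
  do.call(rbind, lapply(stats, function(s) {
    x <- object[[s]]
    x <- x[!is.na(x)]
    data.frame(stat = s, mean = mean(x),
               se = stats::sd(x) / sqrt(length(x)),
               n_runs = length(x))
  }))
}
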