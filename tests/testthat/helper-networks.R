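# Small in-code network fixtures shared across tests.

# 4-node path u0 - v0 - w1 - x1: one intra edge per group, one across.
path_net <- function() {
  list(edges = rbind(c("u0", "v0"), c("v0", "w1"), c("w1", "x1")),
       groups = c(u0 = "g0", v0 = "g0", w1 = "g1", x1 = "g1"))
}

# complete bipartite K_{2,2} across the two groups
k22_net <- function() {
  list(edges = rbind(c("a1", "b1"), c("a1", "b2"),
                     c("a2", "b1"), c("a2", "b2")),
       groups = c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
}

# random simple labelled graph for property tests
random_net <- function(n, B, p_edge = 0.2) {
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < p_edge
  if (!any(keep)) keep[1] <- TRUE
  list(edges = matrix(as.character(pairs[keep, , drop = FALSE]), ncol = 2),
       groups = setNames(sample(letters[1:B], n, replace = TRUE),
                         as.character(1:n)))
}

# random normalized mixing matrix
random_mixing <- function(B, symmetric = FALSE) {
  e <- matrix(runif(B * B), B, B)
  if (symmetric) e <- (e + t(e)) / 2
  e / sum(e)
}
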