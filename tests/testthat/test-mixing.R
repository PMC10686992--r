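test_that("group partitions index categories minority-first with exact fractions", {
  p <- group_partition(c(a = "F", b = "F", c = "M", d = "M", e = "M",
                         f = "M", g = "M", h = "M", i = "M", j = "M"))
  expect_equal(p$levels, c("F", "M"))
  expect_equal(p$fractions, c(0.2, 0.8))
  expect_equal(unname(p$index[c("a", "c")]), c(1L, 2L))

  one <- group_partition(setNames(rep("x", 6), letters[1:6]))
  expect_equal(length(one$levels), 1L)
  expect_equal(one$fractions, 1)

  three <- group_partition(c(a = "X", b = "Y", c = "Z"))
  expect_equal(three$fractions, rep(1 / 3, 3))
  expect_equal(three$levels, c("X", "Y", "Z"))  # tie broken lexicographically

  # without minority ordering, levels are lexicographic
  p2 <- group_partition(c(a = "zmin", b = "amaj", c = "amaj"),
                        minority_first = FALSE)
  expect_equal(p2$levels, c("amaj", "zmin"))
  expect_equal(group_partition(c(a = "zmin", b = "amaj", c = "amaj"))$levels,
               c("zmin", "amaj"))
})

test_that("partition fractions always sum to one and are positive", {
  set.seed(71)
  for (k in 1:20) {
    n <- sample(2:40, 1)
    g <- setNames(sample(letters[1:sample(1:5, 1)], n, replace = TRUE),
                  paste0("v", 1:n))
    p <- group_partition(g)
    expect_lt(abs(sum(p$fractions) - 1), 1e-12)
    expect_true(all(p$fractions > 0))
    expect_equal(sum(p$sizes), n)
  }
})

test_that("degenerate partitions are rejected with informative errors", {
  expect_error(group_partition(character(0)), "empty partition")
  expect_error(group_partition(c("a", "b")), "named")
})

test_that("edge counting folds undirected pairs and respects direction", {
  p <- group_partition(c(u = "a", v = "a", w = "b", x = "b"))
  c1 <- count_group_edges(rbind(c("u", "v")), p)
  expect_equal(unname(c1$counts), matrix(c(1L, 0L, 0L, 0L), 2, 2))
  expect_equal(c1$total, 1L)

  e4 <- rbind(c("u", "v"), c("w", "x"), c("u", "w"), c("x", "v"))
  c4 <- count_group_edges(e4, p)
  expect_equal(unname(c4$counts), matrix(c(1L, 0L, 2L, 1L), 2, 2))
  expect_equal(c4$total, 4L)

  # directed: two group-a -> group-b arcs, none back
  cd <- count_group_edges(rbind(c("u", "w"), c("v", "x")), p,
                          directed = TRUE)
  expect_equal(unname(cd$counts), matrix(c(0L, 0L, 2L, 0L), 2, 2))
})

test_that("duplicate edges collapse unless multigraph counting is requested", {
  p <- group_partition(c(u = "a", v = "a", w = "b"))
  dup <- rbind(c("u", "v"), c("v", "u"), c("u", "v"))
  expect_equal(count_group_edges(dup, p)$total, 1L)
  expect_equal(count_group_edges(dup, p, multigraph = TRUE)$total, 3L)
  # directed mode treats (u,v) and (v,u) as distinct
  expect_equal(count_group_edges(dup, p, directed = TRUE)$total, 2L)
})

test_that("self-loops and unknown endpoints are rejected by name", {
  p <- group_partition(c(u = "a", v = "b"))
  expect_error(count_group_edges(rbind(c("u", "u")), p), "self-loop.*'u'")
  expect_error(count_group_edges(rbind(c("u", "zz")), p), "'zz' has no group")
})

test_that("mixing matrices use half-weight off-diagonals and clean marginals", {
  cnt <- group_edge_counts(matrix(c(7432, 0, 149069, 1381069), 2, 2))
  m <- mixing_matrix(cnt)
  E <- 1537570
  expect_equal(m[1, 1], 7432 / E)
  expect_equal(m[1, 2], 149069 / (2 * E))
  expect_equal(m[2, 1], m[1, 2])
  expect_equal(m[2, 2], 1381069 / E)
  expect_lt(abs(sum(m) - 1), 1e-12)
  expect_equal(attr(m, "a"), rowSums(unclass(m)))
  expect_equal(attr(m, "b"), colSums(unclass(m)))

  expect_equal(unclass(mixing_matrix(group_edge_counts(diag(c(1, 1)))))[1:4],
               c(0.5, 0, 0, 0.5))
  cross <- mixing_matrix(group_edge_counts(matrix(c(0, 0, 2, 0), 2, 2)))
  expect_equal(cross[1, 2], 0.5)
  expect_equal(cross[2, 1], 0.5)
  expect_error(mixing_matrix(group_edge_counts(matrix(0, 2, 2))), "no edges")
})

test_that("group-size adjustment matches the entrywise oracle and renormalizes", {
  cnt <- group_edge_counts(matrix(c(7432, 0, 149069, 1381069), 2, 2))
  m <- mixing_matrix(cnt)
  f <- c(0.06, 0.94)
  adj <- adjust_mixing(m, f)
  # oracle: divide entrywise by f_i f_j, then by the grand sum
  raw <- unclass(m) / outer(f, f)
  expect_equal(unclass(adj), raw / sum(raw), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(adj[1, 1], 0.3292304813, tolerance = 1e-9)
  expect_equal(adj[1, 2], 0.2107536356, tolerance = 1e-9)
  expect_equal(adj[2, 2], 0.2492622475, tolerance = 1e-9)
  expect_true(attr(adj, "adjusted"))
  expect_lt(abs(sum(adj) - 1), 1e-12)
  expect_equal(adj[1, 2], adj[2, 1])  # symmetry survives adjustment
})

test_that("adjustment is the identity at equal fractions and exposes raw values", {
  e <- mixing_matrix(group_edge_counts(matrix(c(3, 0, 2, 5), 2, 2)))
  expect_equal(unclass(adjust_mixing(e, c(0.5, 0.5))), unclass(e),
               tolerance = 1e-12, ignore_attr = TRUE)
  hand <- adjust_mixing(
    mixing_matrix(group_edge_counts(diag(c(1, 1)))), c(0.2, 0.8))
  expect_equal(diag(unclass(hand)), c(0.9411764706, 0.0588235294),
               tolerance = 1e-9)
  raw <- adjust_mixing(
    mixing_matrix(group_edge_counts(diag(c(1, 1)))), c(0.2, 0.8),
    renormalize = FALSE)
  expect_equal(diag(unclass(raw)), c(12.5, 0.78125))
  expect_error(adjust_mixing(e, c(0, 1)), "degenerate group")
  expect_error(adjust_mixing(adjust_mixing(e, c(0.3, 0.7)), c(0.3, 0.7)),
               "already adjusted")
})

test_that("counts, mixing and adjustment are equivariant under group relabeling", {
  set.seed(42)
  for (k in 1:10) {
    net <- random_net(12, 3)
    p <- group_partition(net$groups, minority_first = FALSE)
    m <- mixing_matrix(count_group_edges(net$edges, p))
    f <- p$fractions
    # rename categories so their lexicographic order reverses
    lv <- p$levels
    perm_names <- setNames(paste0(rev(lv), "_new"), lv)
    net2 <- net
    net2$groups <- setNames(unname(perm_names[net$groups]),
                            names(net$groups))
    p2 <- group_partition(net2$groups, minority_first = FALSE)
    m2 <- mixing_matrix(count_group_edges(net2$edges, p2))
    pos <- match(unname(perm_names[lv]), p2$levels)
    expect_equal(unclass(m2)[pos, pos], unclass(m), tolerance = 1e-12,
                 ignore_attr = TRUE)
    a2 <- adjust_mixing(m2, p2$fractions)
    a1 <- adjust_mixing(m, f)
    expect_equal(unclass(a2)[pos, pos], unclass(a1), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})
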