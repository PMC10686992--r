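test_that("expected mixing matrices follow p_ij = f_i f_j h_ij", {
  m <- expected_mixing(0.5, 0.8)
  expect_equal(unclass(m), matrix(c(0.4, 0.1, 0.1, 0.4), 2, 2),
               ignore_attr = TRUE)
  # asymmetric tendencies keep the ordered-pair accounting
  m2 <- expected_mixing(c(0.1, 0.9), c(0.8, 0.2))
  expect_equal(unclass(m2),
               matrix(c(0.008, 0.018, 0.072, 0.162), 2, 2,
                      byrow = TRUE) / 0.26,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_false(isTRUE(all.equal(m2[1, 2], m2[2, 1])))
  expect_lt(abs(sum(m2) - 1), 1e-12)
  # neutral mixing h = 0.5 gives the independence matrix for any f
  for (f0 in c(0.1, 0.37)) {
    e <- expected_mixing(f0, 0.5)
    expect_equal(unclass(e), outer(c(f0, 1 - f0), c(f0, 1 - f0)),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(assortativity_nominal(e)$r, 0, tolerance = 1e-12)
  }
  expect_no_error(expected_mixing(0.5, matrix(c(0, 1, 1, 0), 2, 2)))
  expect_error(expected_mixing(c(0.2, 0.9), 0.8), "sum to 1")
})

test_that("homophily parameter expansion is row-stochastic in every form", {
  expect_equal(homophily_matrix(0.8),
               matrix(c(0.8, 0.2, 0.2, 0.8), 2, 2))
  expect_equal(homophily_matrix(c(0.8, 0.2)),
               matrix(c(0.8, 0.2, 0.8, 0.2), 2, 2, byrow = TRUE))
  h3 <- homophily_matrix(0.7, B = 3)
  expect_equal(rowSums(h3), rep(1, 3))
  expect_equal(h3[1, 2], 0.15)
  expect_error(homophily_matrix(1.2), "\\[0, 1\\]")
  expect_error(homophily_matrix(matrix(c(0.5, 0.4, 0.2, 0.8), 2, 2)),
               "sum to 1")
})

test_that("closed-form coefficient matches its stated special values", {
  expect_equal(analytic_r(0.5, 0.8, 0.8), 0.6)
  expect_equal(analytic_r(0.1, 0.8, 0.2), 0, tolerance = 1e-14)
  expect_equal(analytic_r(0.1, 0.8, 0.8), 0.2806652807, tolerance = 1e-9)
  expect_error(analytic_r(0, 0.8), "f0")
  expect_error(analytic_r(0.5, 1.3), "\\[0, 1\\]")
})

test_that("closed form and mixing-matrix route agree on random parameters", {
  set.seed(2024)
  worst <- 0
  for (k in 1:1000) {
    f0 <- runif(1, 0.02, 0.98)
    h00 <- runif(1); h11 <- runif(1)
    direct <- analytic_r(f0, h00, h11)
    via_matrix <- assortativity_nominal(
      expected_mixing(f0, c(h00, h11)))$r
    worst <- max(worst, abs(direct - via_matrix))
  }
  expect_lt(worst, 1e-10)
})

test_that("equal group sizes reduce the coefficient to h00 + h11 - 1", {
  hs <- expand.grid(h00 = seq(0, 1, by = 0.1), h11 = seq(0, 1, by = 0.1))
  expect_equal(analytic_r(0.5, hs$h00, hs$h11), hs$h00 + hs$h11 - 1,
               tolerance = 1e-12)
})

test_that("the zero locus h00 = 1 - h11 kills the coefficient for every f0", {
  expect_equal(zero_locus(0.8), 0.2)
  expect_equal(zero_locus(0.5), 0.5)
  expect_equal(zero_locus(1), 0)
  grid <- expand.grid(f0 = seq(0.05, 0.95, length.out = 20),
                      x = seq(0.02, 0.98, length.out = 20))
  expect_lt(max(abs(analytic_r(grid$f0, grid$x, zero_locus(grid$x)))),
            1e-12)
})

test_that("the adjusted coefficient is h00 + h11 - 1, independent of f0", {
  expect_equal(analytic_r_adj(0.8, 0.2), 0)
  expect_equal(analytic_r_adj(0.8, 0.8), 0.6)
  expect_equal(analytic_r_adj(1, 1), 1)
  for (h00 in c(0.15, 0.6, 0.9)) for (h11 in c(0.2, 0.7)) {
    vals <- vapply(seq(0.03, 0.97, length.out = 15), function(f0)
      assortativity_adjusted(expected_mixing(f0, c(h00, h11)),
                             c(f0, 1 - f0))$r, numeric(1))
    expect_lt(max(abs(vals - (h00 + h11 - 1))), 1e-10)
  }
})

test_that("the nominal coefficient is monotone in h and in the minority size", {
  for (f0 in c(0.1, 0.3, 0.5)) {
    r <- analytic_r(f0, seq(0.05, 0.95, by = 0.05))
    expect_true(all(diff(r) > 0))
  }
  # bias: at fixed homophilic h, shrinking the minority drags r to zero
  for (h in c(0.6, 0.8, 0.95)) {
    r <- analytic_r(seq(0.02, 0.5, by = 0.02), h)
    expect_true(all(diff(r) > 0))
    expect_lt(analytic_r(1e-4, 0.8), 0.01)
  }
})

test_that("parameter sweeps tabulate the closed forms in long format", {
  sw <- assortativity_sweep(f0 = 0.5, h00 = c(0, 0.5, 1))
  expect_equal(sw$value, c(-1, 0, 1))
  expect_equal(names(sw), c("f0", "h00", "h11", "measure", "value"))
  adj <- assortativity_sweep(f0 = seq(0.05, 0.5, by = 0.05),
                             h00 = c(0.3, 0.8), h11 = c(0.2, 0.9),
                             measure = "adjusted")
  spread <- tapply(adj$value, paste(adj$h00, adj$h11),
                   function(v) diff(range(v)))
  expect_lt(max(spread), 1e-9)  # column-wise f0-independence
  nom <- assortativity_sweep(f0 = c(0.3, 0.5), h00 = c(0.2, 0.8))
  expect_equal(nrow(nom), 4L)
  expect_equal(nom$h11, nom$h00)  # symmetric pairing when h11 is NULL
})
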