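# Single-cell energy terms and the inter-vertex pair potential.

make_ring <- function(n, radius = 1) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  radius * cbind(cos(th), sin(th))
}

test_that("spring energy: rest length gives zero, stretch gives closed form", {
  p <- model_params()
  # ring with all bonds exactly at l0: regular n-gon with side l0
  n <- p$n_vertices
  R <- p$l0 / (2 * sin(pi / n))
  cell <- erythrosim:::ring_cell("healthy_discocyte", make_ring(n, R),
                                 p$A0_discocyte, p$l0, 50, FALSE)
  expect_equal(spring_energy(cell, p), 0, tolerance = 1e-10)
  # stretch a single bond by moving one vertex radially outward
  v <- cell$vertices
  # scaling the whole ring by (1+x) stretches every bond by fraction x
  x <- 0.02
  cell2 <- cell; cell2$vertices <- v * (1 + x)
  expected <- n * 0.5 * p$k_spring * x^2
  expect_equal(spring_energy(cell2, p), expected, tolerance = 1e-9)
})

test_that("spring energy of a perturbed ring equals a loop-sum oracle", {
  p <- model_params()
  set.seed(4)
  v <- make_ring(50, 4) + matrix(rnorm(100, 0, 0.05), 50, 2)
  cell <- erythrosim:::ring_cell("healthy_discocyte", v, p$A0_discocyte,
                                 p$l0, 50, FALSE)
  lens <- sqrt(rowSums((v[c(2:50, 1), ] - v)^2))
  oracle <- sum(0.5 * p$k_spring * (lens - p$l0)^2 / p$l0^2)
  expect_equal(spring_energy(cell, p), oracle, tolerance = 1e-12)
})

test_that("bending energy: regular polygon closed form and collinear joints", {
  p <- model_params()
  n <- 50
  cell <- erythrosim:::ring_cell("healthy_discocyte", make_ring(n, 4),
                                 p$A0_discocyte, p$l0, 50, FALSE)
  expect_equal(bending_energy(cell, p), n * 50 * (1 - cos(2 * pi / n)),
               tolerance = 1e-10)
  # a long thin rectangle-ish ring: collinear stretches contribute zero
  m <- 10
  side <- cbind(seq(0, 1, length.out = m), 0)
  top <- cbind(seq(1, 0, length.out = m), 0.05)
  v <- rbind(side, top)
  cellr <- erythrosim:::ring_cell("healthy_discocyte", v, 0.05, p$l0, 1,
                                  FALSE)
  # oracle: sum over joints of kb (1 - cos theta)
  nn <- nrow(v)
  ang <- 0
  for (i in seq_len(nn)) {
    a <- v[(i - 2 + nn) %% nn + 1, ]; b <- v[i, ]; cc <- v[i %% nn + 1, ]
    u <- b - a; w <- cc - b
    ang <- ang + 1 * (1 - sum(u * w) / sqrt(sum(u^2) * sum(w^2)))
  }
  expect_equal(bending_energy(cellr, p, k_bend = 1), ang, tolerance = 1e-12)
})

test_that("area energy follows the quadratic penalty and rejects crossings", {
  p <- model_params()
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  cell <- erythrosim:::ring_cell("healthy_discocyte", sq, 1, p$l0, 50, FALSE)
  expect_equal(area_energy(cell, p), 0, tolerance = 1e-12)
  # A = 1 but A0 = 1/(1+delta) style: set A0 so A = A0 (1 + delta)
  delta <- 0.1
  cell2 <- cell; cell2$A0 <- 1 / (1 + delta)
  expect_equal(area_energy(cell2, p), 0.5 * p$k_area * delta^2,
               tolerance = 1e-9)
  bowtie <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  cell3 <- cell; cell3$vertices <- bowtie
  expect_error(area_energy(cell3, p), "self-intersecting")
})

test_that("shoelace area of the unit square is 1", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(erythrosim:::cpp_polygon_area(sq), 1)
})

test_that("pair potential: zero at sigma for plain LJ, minimum depth, cutoff", {
  p <- model_params(eps_attr = 2)
  expect_equal(lj_potential(0.3, eps = 1, sigma = 0.3), 0, tolerance = 1e-12)
  # printed truncated-LJ value at the cutoff
  expect_equal(lj_potential(0.72, eps = 1, sigma = 0.3, r_cut = 0.721),
               4 * ((0.3 / 0.72)^12 - (0.3 / 0.72)^6), tolerance = 1e-12)
  expect_equal(4 * ((5 / 12)^12 - (5 / 12)^6), -0.0208, tolerance = 1e-2)
  # decomposed potential: minimum at 2^(1/6) sigma with depth -eps_attr
  # (the WCA core contributes exactly zero at its own cutoff there)
  rmin <- 2^(1 / 6) * p$sigma
  expect_equal(pair_potential(rmin, p), -p$eps_attr, tolerance = 1e-10)
  grid <- seq(0.25, p$r_cut - 1e-9, length.out = 400)
  expect_equal(min(pair_potential(grid, p)), -p$eps_attr, tolerance = 1e-3)
  # zero beyond the cutoff, continuous at it
  expect_equal(pair_potential(c(0.72, 0.8, 1.5), p), c(0, 0, 0))
  expect_lt(abs(pair_potential(p$r_cut - 1e-8, p)), 1e-5)
  expect_error(pair_potential(0, p), "singular")
})

test_that("repulsive core survives eps_attr = 0", {
  p <- model_params(eps_attr = 0)
  expect_gt(pair_potential(0.25, p), 1)
  expect_equal(pair_potential(0.5, p), 0)
})
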