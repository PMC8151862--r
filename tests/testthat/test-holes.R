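# Rasterization, hole labeling (periodic), characteristic size estimator,
# and the rank-based condition comparison.

grid_from_matrix <- function(m, res = 1, periodic = TRUE) {
  structure(list(occupied = m, resolution = res,
                 domain = c(ncol(m) * res, nrow(m) * res),
                 periodic = periodic),
            class = "occupancy_grid")
}

test_that("a single disk rasterizes to its area and an empty snapshot to
          free space", {
  p <- model_params(domain = c(30, 30))
  # a circle-limit cell is a disk of radius L0 / (2 pi)
  pc <- model_params(reduced_area_s = 1, domain = c(30, 30))
  cell <- make_discocyte(pc)
  cell$vertices <- sweep(cell$vertices, 2, c(15, 15), "+")
  snap <- snapshot(list(cell), c(30, 30))
  g <- rasterize(snap, 0.3, sigma = 0.3)
  measured <- sum(g$occupied) * 0.3^2
  # reference area of the same geometry (polygon + sigma/2 vertex disks)
  # from a 6x finer grid, and the ideal-disk area as a sanity anchor
  fine <- rasterize(snap, 0.05, sigma = 0.3)
  reference <- sum(fine$occupied) * 0.05^2
  expect_lt(abs(measured - reference) / reference, 0.03)
  R <- 24.5 / (2 * pi)
  expect_lt(abs(measured - pi * R^2) / (pi * R^2), 0.1)
})

test_that("hole labeling matches a flood-fill oracle on random grids,
          periodic and not", {
  set.seed(42)
  for (rep in 1:12) {
    occ <- matrix(rbinom(900, 1, 0.45), 30, 30)
    for (periodic in c(TRUE, FALSE)) {
      g <- grid_from_matrix(occ, periodic = periodic)
      hs <- label_holes(g)
      oracle <- flood_fill_labels(occ, periodic)
      expect_equal(sort(hs$pixels), sorted_component_sizes(oracle))
      # area conservation at grid level
      expect_equal(sum(hs$pixels) + sum(occ), length(occ))
    }
  }
})

test_that("a void straddling the periodic boundary is counted once", {
  occ <- matrix(1L, 9, 9)
  occ[4:6, c(1, 9)] <- 0L # two patches touching opposite vertical edges
  g <- grid_from_matrix(occ, periodic = TRUE)
  hs <- label_holes(g)
  expect_equal(length(hs$areas), 1)
  expect_equal(hs$pixels, 6L)
  gnp <- grid_from_matrix(occ, periodic = FALSE)
  expect_equal(length(label_holes(gnp)$areas), 2)
})

test_that("fully free grid is a single hole of the domain area", {
  g <- grid_from_matrix(matrix(0L, 12, 12), res = 0.5)
  hs <- label_holes(g)
  expect_equal(hs$areas, 12 * 12 * 0.25)
})

test_that("characteristic hole size estimators recover an exponential
          scale", {
  set.seed(7)
  a_star <- 40
  areas <- rexp(10000, 1 / a_star)
  hs <- structure(list(areas = areas, pixels = areas, labels = NULL,
                       connectivity = 4L, periodic_merged = TRUE,
                       resolution = 1, domain = c(1000, 1000)),
                  class = "hole_set")
  est <- characteristic_hole_size(hs, min_area_cutoff = 0)
  expect_lt(abs(est$characteristic_hole_size - a_star) / a_star, 0.03)
  est_m <- characteristic_hole_size(hs, min_area_cutoff = 0,
                                    estimator = "median_excess")
  expect_lt(abs(est_m$characteristic_hole_size - a_star) / a_star, 0.04)
  est_u <- characteristic_hole_size(hs, min_area_cutoff = 0,
                                    estimator = "mean_excess")
  expect_equal(est_u$characteristic_hole_size,
               mean(areas), tolerance = 1e-12)
  # censoring removes a single percolating void
  hs_p <- hs
  hs_p$areas <- c(areas[1:200], 2e5)
  est_c <- characteristic_hole_size(hs_p, min_area_cutoff = 0)
  expect_equal(est_c$n_censored, 1L)
  expect_lt(abs(est_c$characteristic_hole_size - a_star) / a_star, 0.2)
  # single hole above cutoff: degenerate, estimate = area - cutoff
  hs1 <- hs; hs1$areas <- c(5, 130)
  est1 <- characteristic_hole_size(hs1, min_area_cutoff = 100)
  expect_equal(est1$characteristic_hole_size, 30)
  expect_true(est1$degenerate)
  # all holes at the cutoff: zero, degenerate
  hs2 <- hs; hs2$areas <- rep(50, 4)
  est2 <- characteristic_hole_size(hs2, min_area_cutoff = 50)
  expect_equal(est2$characteristic_hole_size, 0)
  expect_true(est2$degenerate)
  expect_error(characteristic_hole_size(hs2, min_area_cutoff = 60),
               "cutoff")
})

test_that("rasterization occupied fraction is stable under refinement", {
  pc <- model_params(reduced_area_s = 1, domain = c(30, 30))
  cell <- make_discocyte(pc)
  cell$vertices <- sweep(cell$vertices, 2, c(15, 15), "+")
  snap <- snapshot(list(cell), c(30, 30))
  f1 <- mean(rasterize(snap, 0.3)$occupied)
  f2 <- mean(rasterize(snap, 0.15)$occupied)
  expect_lt(abs(f1 - f2) / f2, 0.01)
})

test_that("Kruskal-Wallis H matches the exact rank computation on a tiny
          example", {
  vals <- list(a = c(1.1, 2.3, 3.1), b = c(4.2, 5.0, 6.4))
  cmp <- compare_hole_conditions(vals)
  r <- rank(unlist(vals))
  N <- 6
  H <- 12 / (N * (N + 1)) * (3 * (mean(r[1:3]))^2 + 3 * (mean(r[4:6]))^2) -
    3 * (N + 1)
  expect_equal(unname(cmp$kruskal$statistic), H, tolerance = 1e-12)
})

test_that("Dunn-style z against the reference matches a hand computation", {
  vals <- list(ref = c(10, 12, 14, 11), other = c(20, 22, 25, 24))
  pw <- erythrosim:::dunn_vs_reference(vals, "ref")
  r <- rank(unlist(vals))
  rbar_ref <- mean(r[1:4]); rbar_oth <- mean(r[5:8])
  v0 <- 8 * 9 / 12 # no ties
  z_hand <- (rbar_oth - rbar_ref) / sqrt(v0 * (1 / 4 + 1 / 4))
  expect_equal(pw$z, z_hand, tolerance = 1e-12)
})

test_that("identical conditions are rarely declared significant and strongly
          separated ones always are", {
  set.seed(13)
  n_sig <- 0
  for (r in 1:40) {
    vals <- list(a = rnorm(5, 50, 5), b = rnorm(5, 50, 5),
                 c = rnorm(5, 50, 5))
    cmp <- compare_hole_conditions(vals)
    if (cmp$kruskal$p.value < 0.05) n_sig <- n_sig + 1
  }
  expect_lte(n_sig / 40, 0.1)
  sep <- list(a = rnorm(5, 50, 2), b = rnorm(5, 70, 2))
  cmp2 <- compare_hole_conditions(sep)
  expect_lt(cmp2$pairwise$p_adj[1], 0.01)
  expect_error(compare_hole_conditions(list(a = 1:2, b = 1:5)),
               "3 replicates")
})
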