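# Forces, Langevin integration, rigid-body dynamics, initialization and
# trajectory-level contracts.

test_that("forces equal minus the finite-difference energy gradient", {
  p <- model_params(domain = c(30, 30), hematocrit = 0.07, seed = 5,
                    eps_attr = 2)
  snap <- initialize_configuration(
    p, c(healthy_discocyte = 0.5, acanthocyte = 0.5))
  f <- total_forces(snap, p)
  pk <- erythrosim:::pack_snapshot(snap)
  cp <- erythrosim:::cpp_par(p)
  h <- 1e-6
  set.seed(8)
  idx <- sample(nrow(pk$coords), 25)
  for (i in idx) {
    for (j in 1:2) {
      cpl <- pk$coords; cpl[i, j] <- cpl[i, j] + h
      Ep <- erythrosim:::cpp_system_energy(cpl, pk$nv, pk$kb, pk$A0,
                                           pk$rigid, cp)
      cpl[i, j] <- cpl[i, j] - 2 * h
      Em <- erythrosim:::cpp_system_energy(cpl, pk$nv, pk$kb, pk$A0,
                                           pk$rigid, cp)
      fd <- -(Ep - Em) / (2 * h)
      expect_equal(f[i, j], fd,
                   tolerance = 1e-5 * max(1, abs(fd)) / max(1e-12, abs(fd)))
    }
  }
})

test_that("relaxed isolated discocyte feels (almost) no force and forces sum
          to zero", {
  p <- model_params(domain = c(50, 50))
  cell <- make_discocyte(p)
  cell$vertices <- sweep(cell$vertices, 2, c(25, 25), "+")
  snap <- snapshot(list(cell), c(50, 50))
  f <- total_forces(snap, p)
  expect_lt(max(abs(f)), 1e-2)
  # Newton's third law over a crowded periodic system
  p2 <- model_params(domain = c(30, 30), hematocrit = 0.2, seed = 9)
  snap2 <- initialize_configuration(p2, c(healthy_discocyte = 1))
  f2 <- total_forces(snap2, p2)
  expect_lt(max(abs(colSums(f2))), 1e-8 * nrow(f2))
})

test_that("energies are invariant under a global periodic translation", {
  p <- model_params(domain = c(30, 30), hematocrit = 0.15, seed = 2)
  snap <- initialize_configuration(
    p, c(healthy_discocyte = 0.6, acanthocyte = 0.4))
  e0 <- total_energy(snap, p)
  shifted <- snap
  for (i in seq_along(shifted$cells)) {
    shifted$cells[[i]]$vertices <-
      erythrosim:::wrap_coords(sweep(shifted$cells[[i]]$vertices, 2,
                                     c(7.3, 28.1), "+"), snap$domain)
  }
  e1 <- total_energy(shifted, p)
  expect_equal(e1, e0, tolerance = 1e-10 * max(1, abs(e0)))
})

test_that("zero temperature with zero forces leaves positions unchanged", {
  p <- model_params(domain = c(50, 50), kT = 0)
  cell <- make_discocyte(p)
  cell$vertices <- sweep(cell$vertices, 2, c(25, 25), "+")
  snap <- snapshot(list(cell), c(50, 50))
  # the relaxed cell is at a minimum: an athermal step must not move it
  # beyond the residual-gradient scale
  s2 <- langevin_step(snap, p, n_steps = 10)
  d <- max(abs(s2$cells[[1]]$vertices - snap$cells[[1]]$vertices))
  expect_lt(d, 1e-4)
})

test_that("athermal relaxation never increases the total energy", {
  p <- model_params(domain = c(30, 30), hematocrit = 0.15, kT = 0,
                    eps_attr = 2, seed = 4, n_steps = 400L)
  traj <- run_simulation(p, c(healthy_discocyte = 0.7, acanthocyte = 0.3),
                         n_save = 40)
  expect_true(all(diff(traj$energies) <= 1e-9))
})

test_that("free vertices diffuse with MSD = 4 D t", {
  # independent free walkers: 3-vertex rings with all couplings off
  p <- model_params(n_vertices = 3, k_spring = 0, k_bend_healthy = 0,
                    k_area = 0, eps_rep = 1e-300, eps_attr = 0,
                    domain = c(200, 200), dt = 0.01, kT = 1)
  n_cells <- 550
  th <- seq(0, 2 * pi, length.out = 4)[-4]
  set.seed(3)
  cells <- lapply(seq_len(n_cells), function(i) {
    # keep walkers far from the boundary so no re-centring shift occurs
    # over the run (rms displacement ~7 um)
    centre <- runif(2, 50, 150)
    erythrosim:::ring_cell("healthy_discocyte",
                           sweep(3 * cbind(cos(th), sin(th)), 2, centre,
                                 "+"),
                           1, p$l0, 0, FALSE)
  })
  snap <- snapshot(cells, p$domain)
  n_steps <- 2500L
  res <- erythrosim:::cpp_run_langevin(
    erythrosim:::pack_snapshot(snap)$coords, 3,
    rep(0, n_cells), rep(1, n_cells), rep(FALSE, n_cells),
    erythrosim:::cpp_par(p), n_steps = n_steps, save_every = 0L,
    kT = 1, gamma = 1, dt = p$dt, seed = 17, check_stability = FALSE)
  start <- erythrosim:::pack_snapshot(snap)$coords
  disp2 <- rowSums((res$final - start)^2)
  msd <- mean(disp2)
  expected <- 4 * 1 * n_steps * p$dt # D = kT / gamma = 1
  expect_lt(abs(msd - expected) / expected, 0.05)
})

test_that("rigid acanthocytes preserve shape to near machine precision", {
  p <- model_params(domain = c(40, 40), hematocrit = 0.1, seed = 6,
                    eps_attr = 2)
  snap <- initialize_configuration(p, c(acanthocyte = 1))
  s2 <- langevin_step(snap, p, n_steps = 1000, seed = 23)
  for (i in seq_along(snap$cells)) {
    v0 <- erythrosim:::unwrap_ring(snap$cells[[i]]$vertices, snap$domain)
    v1 <- erythrosim:::unwrap_ring(s2$cells[[i]]$vertices, snap$domain)
    d0 <- as.matrix(dist(v0))
    d1 <- as.matrix(dist(v1))
    expect_lt(max(abs(d1 - d0)) / max(d0), 1e-10)
  }
})

test_that("deformable cells keep perimeter and area within tolerance", {
  p <- model_params(domain = c(40, 40), hematocrit = 0.4, seed = 11,
                    n_steps = 4000L)
  traj <- run_simulation(p, c(healthy_discocyte = 0.8,
                              rigidified_discocyte = 0.2))
  fin <- traj$snapshots[[length(traj$snapshots)]]
  pers <- vapply(fin$cells, function(cl) {
    erythrosim:::ring_perimeter(erythrosim:::unwrap_ring(cl$vertices,
                                                         fin$domain))
  }, numeric(1))
  # ensemble drift below 1%; individual cells fluctuate thermally within
  # ~4 sd of the perimeter fluctuation (~0.45%)
  expect_lt(abs(mean(pers) - p$circumference_L0) / p$circumference_L0, 0.01)
  expect_lt(max(abs(pers - p$circumference_L0)) / p$circumference_L0, 0.03)
  for (cl in fin$cells) {
    v <- erythrosim:::unwrap_ring(cl$vertices, fin$domain)
    A <- abs(erythrosim:::cpp_polygon_area(v))
    expect_lt(abs(A - cl$A0) / cl$A0, 0.02)
  }
})

test_that("initialization meets composition, hematocrit and spacing
          contracts", {
  p <- model_params(domain = c(70, 70), seed = 31)
  snap <- initialize_configuration(
    p, c(healthy_discocyte = 0.8, acanthocyte = 0.2))
  kinds <- vapply(snap$cells, function(cl) cl$kind, character(1))
  n <- length(kinds)
  expect_equal(sum(kinds == "acanthocyte"), round(0.2 * n))
  # occupied area fraction (reference areas) in [0.48, 0.52]
  A <- sum(vapply(snap$cells, function(cl)
    abs(erythrosim:::cpp_polygon_area(
      erythrosim:::unwrap_ring(cl$vertices, snap$domain))), numeric(1)))
  expect_gte(A / (70 * 70), 0.48)
  expect_lte(A / (70 * 70), 0.52)
  # no inter-cell vertex pair closer than sigma: full periodic scan plus
  # a brute-force cross-check on a random subset
  pk <- erythrosim:::pack_snapshot(snap)
  w <- erythrosim:::wrap_coords(pk$coords, snap$domain)
  cellid <- rep(seq_len(n), each = 50)
  expect_gte(erythrosim:::cpp_min_intercell_dist(pk$coords, 50, 70, 70, 1),
             p$sigma)
  set.seed(1)
  ii <- sample(nrow(w), 150)
  for (i in ii) {
    d <- sqrt((w[, 1] - w[i, 1])^2 + (w[, 2] - w[i, 2])^2)
    d <- d[cellid != cellid[i]]
    expect_gte(min(d), p$sigma)
  }
})

test_that("identical seeds give identical trajectories and contacts grow
          with adhesion", {
  p <- model_params(domain = c(40, 40), n_steps = 1500L, seed = 19)
  t1 <- run_simulation(p, c(healthy_discocyte = 1))
  t2 <- run_simulation(p, c(healthy_discocyte = 1))
  expect_identical(t1$snapshots[[length(t1$snapshots)]]$cells,
                   t2$snapshots[[length(t2$snapshots)]]$cells)
})

test_that("without adhesion the final state is dominated by unbonded cells", {
  p <- model_params(domain = c(60, 60), hematocrit = 0.25, eps_attr = 0,
                    n_steps = 3000L, seed = 27)
  traj <- run_simulation(p, c(healthy_discocyte = 1))
  fin <- traj$snapshots[[length(traj$snapshots)]]
  ct <- cell_contacts(fin, p, r_contact = 0.4)
  # bonded pairs (within the adhesive minimum) should be rare
  expect_lt(mean(ct$n_contacts > 0), 0.3)
  singletons <- mean(tabulate(ct$cluster)[ct$cluster] == 1)
  expect_gt(singletons, 0.5)
})

test_that("stronger adhesion yields more contacts per cell", {
  base <- model_params(domain = c(50, 50), hematocrit = 0.45,
                       n_steps = 6000L)
  mean_contacts <- function(eps, seed) {
    p <- base; p$eps_attr <- eps; p$seed <- seed
    traj <- run_simulation(p, c(healthy_discocyte = 1), seed = seed)
    fin <- traj$snapshots[[length(traj$snapshots)]]
    mean(cell_contacts(fin, p)$n_contacts)
  }
  lo <- mean(vapply(1:2, function(s) mean_contacts(0.5, s), numeric(1)))
  hi <- mean(vapply(1:2, function(s) mean_contacts(3, s), numeric(1)))
  expect_gt(hi, lo)
})

test_that("snapshot text round-trip preserves the configuration", {
  p <- model_params(domain = c(30, 30), hematocrit = 0.1, seed = 3)
  snap <- initialize_configuration(
    p, c(healthy_discocyte = 0.5, acanthocyte = 0.5))
  path <- tempfile(fileext = ".tsv")
  write_snapshot(snap, path)
  back <- read_snapshot(path)
  expect_equal(length(back$cells), length(snap$cells))
  for (i in seq_along(snap$cells)) {
    expect_equal(back$cells[[i]]$vertices, unname(snap$cells[[i]]$vertices),
                 tolerance = 1e-6)
    expect_equal(back$cells[[i]]$kind, snap$cells[[i]]$kind)
    expect_equal(back$cells[[i]]$rigid, snap$cells[[i]]$rigid)
  }
  expect_equal(back$domain, snap$domain)
})
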