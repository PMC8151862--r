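# Snapshots, configuration initialization and the Langevin aggregation
# simulator.

#' Snapshot of all cells in a periodic domain
#'
#' A snapshot holds the cells of one time point; vertex coordinates are
#' wrapped into `[0, Lx) x [0, Ly)`. Rings crossing the periodic boundary
#' are re-assembled with [unwrap_ring()] when a continuous polygon is
#' needed.
#'
#' @param cells List of `ring_cell` objects.
#' @param domain `c(Lx, Ly)` in um.
#' @param time Simulation time.
#' @return An object of class `rbc_snapshot`.
#' @export
snapshot <- function(cells, domain, time = 0) {
  cells <- lapply(cells, function(cl) {
    cl$vertices <- wrap_coords(cl$vertices, domain)
    cl
  })
  structure(list(time = time, cells = cells, domain = domain,
                 periodic = TRUE),
            class = "rbc_snapshot")
}

#' @export
print.rbc_snapshot <- function(x, ...) {
  kinds <- vapply(x$cells, function(cl) cl$kind, character(1))
  cat(sprintf("rbc_snapshot: %d cells in %g x %g um periodic domain, t = %g\n",
              length(x$cells), x$domain[1], x$domain[2], x$time))
  print(table(kinds))
  invisible(x)
}

wrap_coords <- function(v, domain) {
  v[, 1] <- v[, 1] - domain[1] * floor(v[, 1] / domain[1])
  v[, 2] <- v[, 2] - domain[2] * floor(v[, 2] / domain[2])
  v
}

#' Unwrap a ring polygon across periodic boundaries
#'
#' Walks the ring and removes periodic jumps by the minimum-image rule, so
#' the returned polygon is spatially continuous (its centroid may lie
#' outside the domain).
#'
#' @param v `n x 2` matrix of wrapped ring vertices.
#' @param domain `c(Lx, Ly)`.
#' @return `n x 2` matrix of unwrapped vertices.
#' @export
unwrap_ring <- function(v, domain) {
  out <- v
  for (i in 2:nrow(v)) {
    d <- v[i, ] - v[i - 1, ]
    d <- d - domain * round(d / domain)
    out[i, ] <- out[i - 1, ] + d
  }
  out
}

# Pack a snapshot into the flat arrays the C++ core uses.  Coordinates are
# unwrapped per ring so each cell is a continuous polygon.
pack_snapshot <- function(snap) {
  nv <- nrow(snap$cells[[1]]$vertices)
  coords <- do.call(rbind, lapply(snap$cells, function(cl) {
    unwrap_ring(cl$vertices, snap$domain)
  }))
  kb <- vapply(snap$cells, function(cl) {
    if (is.null(cl$k_bend) || is.na(cl$k_bend)) 0 else cl$k_bend
  }, numeric(1))
  A0 <- vapply(snap$cells, function(cl) cl$A0, numeric(1))
  rigid <- vapply(snap$cells, function(cl) isTRUE(cl$rigid), logical(1))
  list(coords = coords, nv = nv, kb = kb, A0 = A0, rigid = rigid)
}

# Rebuild a snapshot from packed (wrapped) coordinates, reusing cell
# metadata from a template snapshot.
unpack_snapshot <- function(coords, template, time) {
  nv <- nrow(template$cells[[1]]$vertices)
  cells <- template$cells
  for (c in seq_along(cells)) {
    cells[[c]]$vertices <- coords[((c - 1) * nv + 1):(c * nv), , drop = FALSE]
  }
  snapshot(cells, template$domain, time = time)
}

# Per-step displacement cap for thermal runs: six standard deviations of
# the free-particle step, so free diffusion is statistically unaffected
# while rare force spikes inside the stiff excluded-volume core cannot
# destabilize the explicit Euler update.  Athermal runs are uncapped.
thermal_cap <- function(params) {
  if (params$kT > 0) 6 * sqrt(2 * params$kT * params$dt / params$gamma)
  else -1
}

# equilibrium distance of the widened packing core
pp_equilibrium <- function(params) {
  2^(1 / 6) * 1.2 * params$sigma
}

largest_remainder_counts <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

#' Initialize a cell configuration at a target hematocrit
#'
#' Places shrunken copies of the reference cells on a jittered lattice with
#' random orientations and inflates them stepwise back to full size, with a
#' short rigid-body, repulsion-only athermal relaxation after every growth
#' step (adhesion off). Growth increments are kept below the excluded-volume
#' gap, so membranes can never cross during packing; a final shape-frozen
#' relaxation at full size resolves the residual overlaps. The
#' number of cells is chosen so that the total reference cell area matches
#' `hematocrit * Lx * Ly`; per-kind counts use largest-remainder rounding,
#' so integer counts are exact.
#'
#' @param params A [model_params()] object.
#' @param composition Named fractions over
#'   `c("healthy_discocyte", "rigidified_discocyte", "acanthocyte")`
#'   summing to 1 (missing kinds are 0).
#' @param seed Integer seed (defaults to `params$seed`).
#' @param n_stages Number of growth stages from the initial scale to full
#'   size.
#' @param max_blocks,block_steps Relaxation budget at full size: up to
#'   `max_blocks` blocks of `block_steps` athermal steps; placement fails
#'   if vertex overlaps below `sigma` persist (infeasible packing).
#' @return An `rbc_snapshot` at time 0.
#' @export
initialize_configuration <- function(params,
                                     composition = c(healthy_discocyte = 1),
                                     seed = params$seed,
                                     n_stages = 40L,
                                     max_blocks = 40L,
                                     block_steps = 150L) {
  validate_model_params(params)
  stopifnot(abs(sum(composition) - 1) < 1e-8,
            all(names(composition) %in% cell_kinds))
  frac <- stats::setNames(numeric(3), cell_kinds)
  frac[names(composition)] <- composition

  templates <- list()
  areas <- stats::setNames(numeric(3), cell_kinds)
  for (k in cell_kinds) {
    if (frac[k] > 0) {
      templates[[k]] <- make_reference_cell(params, k)
      areas[k] <- abs(cpp_polygon_area(templates[[k]]$vertices))
    }
  }
  mean_area <- sum(frac * areas)
  Lx <- params$domain[1]; Ly <- params$domain[2]
  n_cells <- max(1L, round(params$hematocrit * Lx * Ly / mean_area))
  counts <- largest_remainder_counts(n_cells, frac)
  achieved <- sum(counts * areas) / (Lx * Ly)
  if (abs(achieved - params$hematocrit) > 0.02) {
    stop(sprintf("cannot meet hematocrit %.2f with this composition (got %.3f)",
                 params$hematocrit, achieved))
  }

  set.seed(seed)
  kinds <- sample(rep(cell_kinds, counts))
  nx <- max(1L, ceiling(sqrt(n_cells * Lx / Ly)))
  ny <- ceiling(n_cells / nx)
  sx <- Lx / nx; sy <- Ly / ny
  # hexagonal-like offset lattice: straight free-space corridors of a
  # square lattice would otherwise percolate into artificial giant voids
  sites <- expand.grid(ix = seq_len(nx) - 0.5, iy = seq_len(ny) - 0.5)
  sites$ix <- sites$ix + 0.5 * ((round(sites$iy + 0.5) %% 2))
  sites <- sites[sample(nrow(sites), n_cells), , drop = FALSE]

  tmpl <- lapply(kinds, function(k) templates[[k]]$vertices)
  r_bound <- max(vapply(tmpl, function(v) max(sqrt(rowSums(v^2))),
                        numeric(1)))
  # initial scale: shrunken cells cannot touch on the jittered lattice
  s0 <- min(1, 0.25 * min(sx, sy) / r_bound)
  angles <- stats::runif(n_cells, 0, 2 * pi)
  centres <- cbind(sites$ix * sx + stats::runif(n_cells, -0.25, 0.25) * sx,
                   sites$iy * sy + stats::runif(n_cells, -0.25, 0.25) * sy)

  nv <- params$n_vertices
  build_coords <- function(scale) {
    do.call(rbind, lapply(seq_len(n_cells), function(i) {
      a <- angles[i]
      R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
      sweep(scale * tmpl[[i]] %*% t(R), 2, centres[i, ], "+")
    }))
  }
  # recover centre and orientation of each (rigid) cell by Procrustes
  update_pose <- function(coords, scale) {
    for (i in seq_len(n_cells)) {
      v <- coords[((i - 1) * nv + 1):(i * nv), , drop = FALSE]
      cm <- colMeans(v)
      vc <- sweep(v, 2, cm)
      tp <- scale * tmpl[[i]]
      ang <- atan2(sum(tp[, 1] * vc[, 2] - tp[, 2] * vc[, 1]),
                   sum(tp[, 1] * vc[, 1] + tp[, 2] * vc[, 2]))
      centres[i, ] <<- cm
      angles[i] <<- ang
    }
  }

  # repulsion-only, with a slightly widened core so the jammed packing
  # leaves all physical pairs above sigma
  par_relax <- cpp_par(params, sigma_rep = 1.2 * params$sigma, eps_attr = 0)
  all_rigid <- rep(TRUE, n_cells)
  kb0 <- rep(0, n_cells)
  A0_tmpl <- vapply(tmpl, function(v) abs(cpp_polygon_area(v)), numeric(1))
  sites_xy <- cbind(sites$ix * sx, sites$iy * sy)
  relax_rigid <- function(coords, steps, kT = 0, rng_seed = seed,
                          k_tether = 25) {
    # packing is not physical dynamics: a 10x smaller friction lets the
    # slow rigid bodies break force arches within the step budget
    cpp_run_langevin(coords, nv, kb0, A0_tmpl, all_rigid, par_relax,
                     n_steps = steps, save_every = 0L, kT = kT,
                     gamma = params$gamma / 10, dt = 4 * params$dt,
                     seed = rng_seed, cap_disp = 0.02,
                     check_stability = FALSE, backtrack = FALSE,
                     tether_sites = sites_xy, k_tether = k_tether)$final
  }

  # Stepwise inflation with soft tethers to the lattice sites: the tether
  # keeps the packing homogeneous (untethered descent lets interlocking
  # shapes jam into clusters and leaves large voids). Each growth
  # increment is bounded by the currently available membrane clearance so
  # that rescaling can never sweep a membrane segment across another
  # cell's vertex (which would create a topologically locked crossing):
  # a vertex straddling a bond of length l0 at vertex-vertex distance d
  # has segment clearance sqrt(d^2 - (l0/2)^2).
  half_bond <- params$l0 / 2
  probe <- max(2 * half_bond, 2 * params$sigma)
  coords <- build_coords(s0)
  sc <- s0
  stage <- 0L
  max_stage <- 50L * n_stages
  while (sc < 1 && stage < max_stage) {
    stage <- stage + 1L
    dmin <- cpp_min_intercell_dist(coords, nv, Lx, Ly, probe)
    clearance <- sqrt(max(dmin^2 - half_bond^2, 0))
    if (clearance < 0.04) {
      coords <- relax_rigid(coords, 60L)
      if (stage %% 5 == 0) {
        coords <- relax_rigid(coords, 60L, kT = 0.5,
                              rng_seed = seed + 100L * stage)
      }
      next
    }
    dsc <- min(log(1 / s0) / n_stages, 0.4 * clearance / (2 * r_bound))
    update_pose(coords, sc)
    sc <- min(1, sc * exp(dsc))
    coords <- build_coords(sc)
    for (b in 1:6) {
      coords <- relax_rigid(coords, 60L)
      dmin <- cpp_min_intercell_dist(coords, nv, Lx, Ly, probe)
      if (dmin >= 0.95 * pp_equilibrium(params)) break
    }
  }
  if (sc < 1) {
    stop(sprintf(paste0("infeasible packing: growth stalled at scale %.3f ",
                        "(hematocrit %.2f)"), sc, params$hematocrit))
  }

  # full size: resolve residual overlaps with shapes frozen (cells are at
  # their relaxed template shapes, so an all-rigid settle is both valid
  # and unconditionally stable), thermal bursts break force arches
  ok <- FALSE
  for (b in seq_len(max_blocks)) {
    dmin <- cpp_min_intercell_dist(coords, nv, Lx, Ly, params$sigma * 1.01)
    if (dmin >= params$sigma) { ok <- TRUE; break }
    if (b %% 3 == 0) {
      coords <- relax_rigid(coords, 100L, kT = 0.3,
                            rng_seed = seed + 7000L + b, k_tether = 0)
    }
    coords <- relax_rigid(coords, block_steps, k_tether = 0)
  }
  if (!ok) {
    stop(sprintf(paste0("infeasible packing: vertex overlaps below sigma ",
                        "persist after growth relaxation (hematocrit %.2f)"),
                 params$hematocrit))
  }
  snap <- snapshot(lapply(seq_len(n_cells), function(i) {
    cl <- templates[[kinds[i]]]
    cl$vertices <- coords[((i - 1) * nv + 1):(i * nv), , drop = FALSE]
    cl
  }), params$domain, time = 0)
  snap
}

#' Total potential energy of a snapshot
#'
#' Bonded (spring, bending, area) energies of deformable cells plus all
#' pair interactions. Internal elastic terms of rigid cells are constant
#' under rigid-body motion and are defined as zero.
#'
#' @param snap An `rbc_snapshot`.
#' @param params A [model_params()] object.
#' @return Energy in kT.
#' @export
total_energy <- function(snap, params) {
  pk <- pack_snapshot(snap)
  cpp_system_energy(pk$coords, pk$nv, pk$kb, pk$A0, pk$rigid, cpp_par(params))
}

#' Per-vertex forces of a snapshot
#'
#' The negative gradient of [total_energy()] with respect to all vertex
#' positions, with periodic minimum-image pair interactions. Fails if two
#' vertices of different cells are closer than `0.1 * sigma` (forces there
#' are numerically meaningless).
#'
#' @inheritParams total_energy
#' @return An `n_total x 2` matrix of forces (kT/um), rows in cell-major
#'   vertex order.
#' @export
total_forces <- function(snap, params) {
  pk <- pack_snapshot(snap)
  floor_r <- 0.1 * params$sigma
  dmin <- cpp_min_intercell_dist(pk$coords, pk$nv, params$domain[1],
                                 params$domain[2], floor_r * 1.001)
  if (dmin < floor_r) {
    stop(sprintf("overlapping vertices: inter-cell distance %.4g um below floor %.4g um",
                 dmin, floor_r))
  }
  cpp_system_forces(pk$coords, pk$nv, pk$kb, pk$A0, pk$rigid, cpp_par(params))
}

#' Advance a snapshot by Langevin steps
#'
#' Overdamped (Brownian) update: deformable cells move per vertex with
#' mobility `1/gamma` and thermal noise satisfying fluctuation-dissipation;
#' rigid cells translate and rotate as rigid bodies driven by the net force
#' and torque about their centroid, with matched translational and
#' rotational diffusion. An error is raised if any per-step displacement
#' exceeds `sigma / 2` (unstable time step).
#'
#' @inheritParams total_energy
#' @param n_steps Number of steps to take (default 1).
#' @param seed Integer seed for the thermal noise.
#' @return The advanced `rbc_snapshot`.
#' @export
langevin_step <- function(snap, params, n_steps = 1L, seed = params$seed) {
  pk <- pack_snapshot(snap)
  res <- cpp_run_langevin(pk$coords, pk$nv, pk$kb, pk$A0, pk$rigid,
                          cpp_par(params), n_steps = as.integer(n_steps),
                          save_every = 0L, kT = params$kT,
                          gamma = params$gamma, dt = params$dt,
                          seed = as.integer(seed),
                          cap_disp = thermal_cap(params))
  wrapped <- wrap_coords(res$final, params$domain)
  unpack_snapshot(wrapped, snap, time = snap$time + n_steps * params$dt)
}

#' Run an aggregation simulation
#'
#' Initializes a configuration at the target hematocrit and composition and
#' integrates the overdamped Langevin dynamics for `params$n_steps` steps,
#' saving snapshots at regular intervals. Fully reproducible given the
#' seed.
#'
#' @param params A [model_params()] object.
#' @param composition Named kind fractions (see
#'   [initialize_configuration()]).
#' @param seed Integer seed (defaults to `params$seed`); placement and
#'   thermal noise both derive from it.
#' @param n_save Number of saved snapshots along the trajectory.
#' @param init Optional pre-built initial `rbc_snapshot` (skips
#'   initialization).
#' @return An object of class `rbc_trajectory`: list with `snapshots`,
#'   `times`, `energies`, `params`, `composition`, `seed`.
#' @export
run_simulation <- function(params,
                           composition = c(healthy_discocyte = 1),
                           seed = params$seed, n_save = 8L, init = NULL) {
  validate_model_params(params)
  snap0 <- if (is.null(init)) {
    initialize_configuration(params, composition, seed = seed)
  } else init
  pk <- pack_snapshot(snap0)
  save_every <- max(1L, params$n_steps %/% n_save)
  res <- cpp_run_langevin(pk$coords, pk$nv, pk$kb, pk$A0, pk$rigid,
                          cpp_par(params), n_steps = params$n_steps,
                          save_every = save_every, kT = params$kT,
                          gamma = params$gamma, dt = params$dt,
                          seed = as.integer(seed) + 104729L,
                          cap_disp = thermal_cap(params))
  snaps <- c(list(snap0),
             lapply(seq_along(res$trajectory), function(i) {
               unpack_snapshot(res$trajectory[[i]], snap0,
                               time = res$steps[i] * params$dt)
             }))
  structure(list(snapshots = snaps,
                 times = c(0, res$steps * params$dt),
                 energies = res$energies,
                 max_disp = res$max_disp,
                 params = params, composition = composition, seed = seed),
            class = "rbc_trajectory")
}

#' @export
print.rbc_trajectory <- function(x, ...) {
  cat(sprintf("rbc_trajectory: %d snapshots, t in [0, %.4g], %d cells, seed %d\n",
              length(x$snapshots), max(x$times),
              length(x$snapshots[[1]]$cells), x$seed))
  invisible(x)
}

#' Cell contact graph of a snapshot
#'
#' Two cells are in contact when any inter-cell vertex pair is closer than
#' `r_contact` (default: the adhesion cutoff `r_cut`).
#'
#' @inheritParams total_energy
#' @param r_contact Contact distance, um.
#' @return List with `pairs` (two-column matrix of cell indices),
#'   `n_contacts` (per-cell contact counts) and `cluster` (cluster id per
#'   cell from the connected components of the contact graph).
#' @export
cell_contacts <- function(snap, params, r_contact = params$r_cut) {
  pk <- pack_snapshot(snap)
  prs <- cpp_cell_contact_pairs(pk$coords, pk$nv, params$domain[1],
                                params$domain[2], r_contact)
  n <- length(snap$cells)
  deg <- tabulate(c(prs[, 1], prs[, 2]), nbins = n)
  # union-find for clusters
  parent <- seq_len(n)
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  if (nrow(prs) > 0) {
    for (k in seq_len(nrow(prs))) {
      ra <- find(prs[k, 1]); rb <- find(prs[k, 2])
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  list(pairs = prs, n_contacts = deg,
       cluster = as.integer(factor(roots)))
}
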