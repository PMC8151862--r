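# User-facing energy functions for single cells and vertex pairs.

#' Spring (stretching) energy of a ring cell
#'
#' Sum over the ring bonds of the harmonic relative-extension energy
#' `(k_spring / 2) * ((l - l0) / l0)^2`.
#'
#' @param cell A `ring_cell`.
#' @param params A [model_params()] object.
#' @return Energy in kT (non-negative).
#' @export
spring_energy <- function(cell, params) {
  stopifnot(nrow(cell$vertices) >= 3)
  cpp_cell_energy(cell$vertices, params$k_spring, params$l0, 0, 0, 1)$spring
}

#' Bending energy of a ring cell
#'
#' Discrete bending energy `k_bend * sum_i (1 - cos(theta_i))` with
#' `theta_i` the turning angle between consecutive bonds. The bending
#' constant is the cell's own (`50` kT for healthy discocytes, `500` kT for
#' rigidified ones).
#'
#' @inheritParams spring_energy
#' @param k_bend Optional override of the cell's bending constant.
#' @return Energy in kT (non-negative).
#' @export
bending_energy <- function(cell, params, k_bend = NULL) {
  kb <- if (!is.null(k_bend)) k_bend else cell$k_bend
  if (is.null(kb) || is.na(kb)) {
    kb <- params$k_bend_healthy
  }
  cpp_cell_energy(cell$vertices, 0, params$l0, kb, 0, 1)$bending
}

#' Area-constraint energy of a ring cell
#'
#' `(k_area / 2) * ((A - A0) / A0)^2` with `A` the shoelace area of the
#' vertex polygon and `A0` the cell's reference area. Fails for a
#' self-intersecting polygon, whose enclosed area is ill-defined.
#'
#' @inheritParams spring_energy
#' @return Energy in kT; zero iff `A == A0`.
#' @export
area_energy <- function(cell, params) {
  if (!is_simple_polygon(cell$vertices)) {
    stop("polygon is self-intersecting: enclosed area is ill-defined")
  }
  cpp_cell_energy(cell$vertices, 0, params$l0, 0, params$k_area,
                  cell$A0)$area
}

#' Inter-vertex pair potential
#'
#' The interaction between vertices of different cells: an always-on purely
#' repulsive WCA core of strength `eps_rep` (cut at `2^(1/6) sigma`) plus an
#' adhesive tail scaled by `eps_attr`. The tail is the attractive remainder
#' of the truncated Lennard-Jones potential
#' `4 eps ((sigma/r)^12 - (sigma/r)^6)`, shifted to zero at `r_cut` and
#' normalized so that the potential minimum at `2^(1/6) sigma` has depth
#' exactly `-eps_attr`. The split keeps excluded volume intact when the
#' adhesion strength is zero.
#'
#' @param r Vector of distances (um), all `> 0`.
#' @param params A [model_params()] object.
#' @return Energies in kT.
#' @seealso [lj_potential()] for the plain truncated Lennard-Jones form.
#' @export
pair_potential <- function(r, params) {
  if (any(r <= 0)) stop("pair potential singular at r <= 0")
  cpp_pair_potential(r, params$sigma, params$r_cut, params$eps_attr,
                     params$eps_rep, params$sigma)
}

#' Plain truncated Lennard-Jones potential
#'
#' `4 eps ((sigma/r)^12 - (sigma/r)^6)` for distances below `r_cut`, zero beyond.
#'
#' @param r Distances (um).
#' @param eps Well depth (kT).
#' @param sigma Length scale (um).
#' @param r_cut Cutoff (um).
#' @return Energies in kT.
#' @export
lj_potential <- function(r, eps = 1, sigma = 0.3, r_cut = 0.72) {
  if (any(r <= 0)) stop("Lennard-Jones potential singular at r <= 0")
  s6 <- (sigma / r)^6
  ifelse(r < r_cut, 4 * eps * (s6^2 - s6), 0)
}
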