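#' Model parameters for the 2D ring-polymer RBC model
#'
#' Collects the mechanical, interaction and integration parameters of the
#' two-dimensional bead-spring red-blood-cell model. Each cell is a closed
#' ring of `n_vertices` vertices connected by stiff harmonic springs, with a
#' discrete bending energy at every joint and a quadratic penalty that holds
#' the enclosed area at its reference value. Cells interact through a
#' short-range potential made of a purely repulsive (WCA) excluded-volume
#' core and an adhesive tail whose depth `eps_attr` plays the role of the
#' aggregation interaction strength.
#'
#' Energies are measured in units of the thermal energy (`kT = 1`), lengths
#' in micrometres, and time in units of `gamma * um^2 / kT` (the friction
#' `gamma` is per vertex).
#'
#' @param n_vertices Number of vertices per cell ring (default 50).
#' @param circumference_L0 Ring circumference in um. The default 24.5 um
#'   gives a discocyte long axis of roughly 8 um.
#' @param reduced_area_s Reduced area `4*pi*A0/L0^2` of the discocyte in
#'   (0, 1]; 1 is the circle limit, 0.48 gives the biconcave-like shape.
#' @param k_spring Spring constant (kT) of the harmonic bonds, in the
#'   relative-extension form `(k/2) * ((l - l0)/l0)^2`. Large enough that
#'   membrane stretching is negligible.
#' @param k_bend_healthy,k_bend_rigidified Discrete bending constants (kT)
#'   for healthy (50) and rigidified (500) discocytes.
#' @param k_area Area-constraint constant (kT) in
#'   `(k/2) * ((A - A0)/A0)^2`.
#' @param kT Thermal energy (1 by definition of units).
#' @param gamma Friction coefficient per vertex.
#' @param dt Integration time step.
#' @param n_steps Default number of Langevin steps for [run_simulation()].
#' @param sigma Length scale of the inter-vertex pair potential, um.
#' @param r_cut Cutoff of the adhesive tail, um.
#' @param eps_attr Adhesion strength in kT (0 to 3).
#' @param eps_rep Strength of the always-on excluded-volume core, kT.
#' @param domain Periodic domain size `c(Lx, Ly)` in um.
#' @param hematocrit Target area fraction occupied by cells.
#' @param seed Integer seed controlling all randomness of a simulation.
#'
#' @return An object of class `model_params` (a named list with derived
#'   quantities `l0`, the bond rest length, and `A0_discocyte`, the
#'   discocyte reference area `reduced_area_s * L0^2 / (4*pi)`).
#' @examples
#' p <- model_params(domain = c(100, 100))
#' p$A0_discocyte
#' @export
model_params <- function(n_vertices = 50L,
                         circumference_L0 = 24.5,
                         reduced_area_s = 0.48,
                         k_spring = 1000,
                         k_bend_healthy = 50,
                         k_bend_rigidified = 500,
                         k_area = 100000,
                         kT = 1,
                         gamma = 1,
                         dt = 5e-5,
                         n_steps = 60000L,
                         sigma = 0.3,
                         r_cut = 0.72,
                         eps_attr = 1.5,
                         eps_rep = 1,
                         domain = c(300, 300),
                         hematocrit = 0.5,
                         seed = 1L) {
  p <- list(n_vertices = as.integer(n_vertices),
            circumference_L0 = circumference_L0,
            reduced_area_s = reduced_area_s,
            k_spring = k_spring,
            k_bend_healthy = k_bend_healthy,
            k_bend_rigidified = k_bend_rigidified,
            k_area = k_area,
            kT = kT, gamma = gamma, dt = dt,
            n_steps = as.integer(n_steps),
            sigma = sigma, r_cut = r_cut,
            eps_attr = eps_attr, eps_rep = eps_rep,
            domain = domain, hematocrit = hematocrit,
            seed = as.integer(seed))
  p$l0 <- circumference_L0 / n_vertices
  p$A0_discocyte <- reduced_area_s * circumference_L0^2 / (4 * pi)
  class(p) <- "model_params"
  validate_model_params(p)
  p
}

validate_model_params <- function(p) {
  stopifnot(
    "n_vertices must be >= 3" = p$n_vertices >= 3,
    "sigma must be < r_cut" = p$sigma < p$r_cut,
    "hematocrit must be in (0, 0.85]" =
      p$hematocrit > 0 && p$hematocrit <= 0.85,
    "eps_attr must be >= 0" = p$eps_attr >= 0,
    "eps_rep must be > 0" = p$eps_rep > 0,
    "dt must be > 0" = p$dt > 0,
    "reduced_area_s must be in (0, 1]" =
      p$reduced_area_s > 0 && p$reduced_area_s <= 1,
    "domain must be two positive lengths" =
      length(p$domain) == 2 && all(p$domain > 0),
    "kT must be >= 0" = p$kT >= 0,
    "gamma must be > 0" = p$gamma > 0
  )
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("2D ring-polymer RBC model parameters\n")
  cat(sprintf("  %d-vertex rings, L0 = %.3g um, reduced area %.3g (A0 = %.3g um^2)\n",
              x$n_vertices, x$circumference_L0, x$reduced_area_s,
              x$A0_discocyte))
  cat(sprintf("  k_spring %.3g, k_bend %.3g/%.3g, k_area %.3g (kT)\n",
              x$k_spring, x$k_bend_healthy, x$k_bend_rigidified, x$k_area))
  cat(sprintf("  pair: sigma %.3g um, r_cut %.3g um, eps_attr %.3g kT, eps_rep %.3g kT\n",
              x$sigma, x$r_cut, x$eps_attr, x$eps_rep))
  cat(sprintf("  domain %g x %g um, hematocrit %.2f, dt %.3g, %d steps, seed %d\n",
              x$domain[1], x$domain[2], x$hematocrit, x$dt, x$n_steps, x$seed))
  invisible(x)
}

# internal list of parameters passed to the C++ core
cpp_par <- function(params, sigma_rep = NULL, eps_attr = NULL) {
  list(l0 = params$l0,
       k_spring = params$k_spring,
       k_area = params$k_area,
       Lx = params$domain[1], Ly = params$domain[2],
       sigma = params$sigma, r_cut = params$r_cut,
       eps_attr = if (is.null(eps_attr)) params$eps_attr else eps_attr,
       eps_rep = params$eps_rep,
       sigma_rep = if (is.null(sigma_rep)) params$sigma else sigma_rep)
}

cell_kinds <- c("healthy_discocyte", "rigidified_discocyte", "acanthocyte")
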