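# Reference cell shapes: relaxed discocytes and rigid 6-lobed acanthocytes.

# Resample a closed dense curve (n x 2) to n_out points equally spaced in
# arc length.
resample_closed <- function(pts, n_out) {
  d <- sqrt(rowSums((pts - pts[c(2:nrow(pts), 1), , drop = FALSE])^2))
  s <- c(0, cumsum(d))
  total <- s[length(s)]
  target <- seq(0, total, length.out = n_out + 1)[-(n_out + 1)]
  closed <- rbind(pts, pts[1, ])
  cbind(stats::approx(s, closed[, 1], xout = target)$y,
        stats::approx(s, closed[, 2], xout = target)$y)
}

# Semi-axes ratio of an ellipse with a given reduced area 4*pi*A/L^2.
ellipse_axis_ratio <- function(s_target) {
  red_area <- function(k) {
    th <- seq(0, 2 * pi, length.out = 2001)
    x <- cos(th); y <- k * sin(th)
    L <- sum(sqrt(diff(x)^2 + diff(y)^2))
    4 * pi * (pi * k) / L^2
  }
  stats::uniroot(function(k) red_area(k) - s_target,
                 interval = c(1e-3, 1), tol = 1e-10)$root
}

ring_cell <- function(kind, vertices, A0, l0, k_bend, rigid) {
  structure(list(kind = kind, vertices = vertices, A0 = A0,
                 reference_bond_length = l0, k_bend = k_bend, rigid = rigid),
            class = "ring_cell")
}

#' @export
print.ring_cell <- function(x, ...) {
  cat(sprintf("ring_cell: %s, %d vertices, perimeter %.3f um, area %.3f um^2%s\n",
              x$kind, nrow(x$vertices), ring_perimeter(x$vertices),
              abs(cpp_polygon_area(x$vertices)), if (x$rigid) ", rigid" else ""))
  invisible(x)
}

ring_perimeter <- function(v) {
  sum(sqrt(rowSums((v - v[c(2:nrow(v), 1), , drop = FALSE])^2)))
}

#' Construct a relaxed discocyte ring cell
#'
#' Builds a closed ring with the target circumference and relaxes it to a
#' local minimum of the spring + bending + area energy, yielding the
#' elongated biconcave-like 2D discocyte shape at reduced area
#' `reduced_area_s` (a regular polygon in the circle limit
#' `reduced_area_s = 1`). The relaxation uses L-BFGS-B on the analytic
#' gradient, starting from an ellipse of matching reduced area.
#'
#' @param params A [model_params()] object.
#' @param kind `"healthy_discocyte"` (bending constant `k_bend_healthy`) or
#'   `"rigidified_discocyte"` (`k_bend_rigidified`). Both are deformable in
#'   the dynamics; rigidified discocytes are simply ten-fold stiffer.
#' @param grad_tol Convergence criterion: maximum gradient component
#'   (kT/um) allowed at the relaxed shape.
#' @return A `ring_cell` object.
#' @examples
#' cell <- make_discocyte(model_params())
#' ring_perimeter <- sum(sqrt(rowSums(
#'   (cell$vertices - cell$vertices[c(2:50, 1), ])^2)))
#' @export
make_discocyte <- function(params, kind = "healthy_discocyte",
                           grad_tol = 1e-3) {
  stopifnot(kind %in% c("healthy_discocyte", "rigidified_discocyte"))
  validate_model_params(params)
  nv <- params$n_vertices
  L0 <- params$circumference_L0
  A0 <- params$A0_discocyte
  kb <- if (kind == "healthy_discocyte") params$k_bend_healthy
        else params$k_bend_rigidified

  # ellipse start with the target reduced area, scaled to perimeter L0
  k <- if (params$reduced_area_s >= 0.999) 1 else
    ellipse_axis_ratio(params$reduced_area_s)
  th <- seq(0, 2 * pi, length.out = 4001)[-4001]
  dense <- cbind(cos(th), k * sin(th))
  dense <- dense * (L0 / ring_perimeter(dense))
  v0 <- resample_closed(dense, nv)

  fn <- function(z) {
    v <- matrix(z, ncol = 2)
    cpp_cell_energy(v, params$k_spring, params$l0, kb, params$k_area, A0)$total
  }
  gr <- function(z) {
    v <- matrix(z, ncol = 2)
    as.vector(cpp_cell_grad(v, params$k_spring, params$l0, kb,
                            params$k_area, A0))
  }
  opt <- stats::optim(as.vector(v0), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = 20000L, factr = 10))
  v <- matrix(opt$par, ncol = 2)
  gmax <- max(abs(gr(opt$par)))
  if (gmax > grad_tol) {
    stop(sprintf(paste0("discocyte relaxation did not converge: max |grad| ",
                        "= %.3g kT/um (tol %.3g), energy %.6g, optim code %d"),
                 gmax, grad_tol, opt$value, opt$convergence))
  }
  # centre at origin
  v <- sweep(v, 2, colMeans(v))
  if (cpp_polygon_area(v) < 0) v <- v[nrow(v):1, , drop = FALSE]
  ring_cell(kind, v, A0, params$l0, kb, rigid = FALSE)
}

#' Construct a rigid acanthocyte ring cell
#'
#' Builds the fully rigid acanthocyte as a flower-like shape with six
#' rounded corners from the polar curve `r(theta) = a (1 + b cos(6 theta))`,
#' sampled uniformly in arc length and rescaled so that the polygon
#' perimeter equals the discocyte circumference `circumference_L0` (the
#' enclosed area then differs from the discocyte area).
#'
#' @param params A [model_params()] object.
#' @param lobe_amplitude Relative lobe amplitude `b` in [0, 1); values
#'   `>= 1` would self-intersect (the radius would vanish) and are an error.
#' @return A rigid `ring_cell` of kind `"acanthocyte"`.
#' @export
make_acanthocyte <- function(params, lobe_amplitude = 0.3) {
  validate_model_params(params)
  if (lobe_amplitude < 0 || lobe_amplitude >= 1) {
    stop("lobe_amplitude must be in [0, 1): larger values self-intersect")
  }
  nv <- params$n_vertices
  L0 <- params$circumference_L0
  th <- seq(0, 2 * pi, length.out = 6001)[-6001]
  r <- 1 + lobe_amplitude * cos(6 * th)
  dense <- cbind(r * cos(th), r * sin(th))
  dense <- dense * (L0 / ring_perimeter(dense))
  v <- resample_closed(dense, nv)
  # exact perimeter after discretization
  v <- v * (L0 / ring_perimeter(v))
  v <- sweep(v, 2, colMeans(v))
  if (cpp_polygon_area(v) < 0) v <- v[nrow(v):1, , drop = FALSE]
  A <- cpp_polygon_area(v)
  ring_cell("acanthocyte", v, A, params$l0, NA_real_, rigid = TRUE)
}

# reference (template) cell for a kind
make_reference_cell <- function(params, kind) {
  if (kind == "acanthocyte") make_acanthocyte(params)
  else make_discocyte(params, kind)
}

#' Check that a ring polygon is simple (non-self-intersecting)
#'
#' Brute-force segment pair test; adjacent edges share an endpoint and are
#' skipped.
#' @param v An `n x 2` matrix of ring vertices.
#' @return `TRUE` if no two non-adjacent edges cross.
#' @export
is_simple_polygon <- function(v) {
  n <- nrow(v)
  a <- v
  b <- v[c(2:n, 1), , drop = FALSE]
  seg_int <- function(p1, p2, p3, p4) {
    d1 <- (p4[1] - p3[1]) * (p1[2] - p3[2]) - (p4[2] - p3[2]) * (p1[1] - p3[1])
    d2 <- (p4[1] - p3[1]) * (p2[2] - p3[2]) - (p4[2] - p3[2]) * (p2[1] - p3[1])
    d3 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
    d4 <- (p2[1] - p1[1]) * (p4[2] - p1[2]) - (p2[2] - p1[2]) * (p4[1] - p1[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      if (seg_int(a[i, ], b[i, ], a[j, ], b[j, ])) return(FALSE)
    }
  }
  TRUE
}
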