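# Microfluidic shape phase-diagram analysis: per-pressure shape fractions,
# saturating-exponential fits, croissant/slipper transition point, and the
# acanthocyte deformability fit.

shape_labels <- c("croissant", "slipper", "acanthocyte", "other")

#' Build a shape phase-diagram table from per-cell flow records
#'
#' Cells flowing at one distinct pressure drop form a group; for each group
#' the mean velocity and the per-shape counts and fractions are computed.
#'
#' @param records Data frame of per-cell observations with columns
#'   `pressure_mbar`, `velocity_mm_s` (> 0) and `shape` (one of
#'   `"croissant"`, `"slipper"`, `"acanthocyte"`, `"other"`); an optional
#'   `donor_id` column is carried along. Records with missing velocity are
#'   excluded with a warning.
#' @return A `phase_diagram_table` tibble, one row per pressure group,
#'   ordered by mean velocity, with columns `pressure_mbar`, `n`,
#'   `velocity_mm_s`, `n_<shape>` and `frac_<shape>`.
#' @export
build_phase_diagram <- function(records) {
  records <- as.data.frame(records)
  stopifnot(all(c("pressure_mbar", "velocity_mm_s", "shape") %in%
                  names(records)))
  bad <- setdiff(unique(records$shape), shape_labels)
  if (length(bad) > 0) {
    stop("unknown shape labels: ", paste(bad, collapse = ", "))
  }
  drop <- is.na(records$velocity_mm_s) | is.na(records$pressure_mbar)
  if (any(drop)) {
    warning(sprintf("excluding %d records with missing pressure/velocity",
                    sum(drop)))
    records <- records[!drop, , drop = FALSE]
  }
  if (length(unique(records$pressure_mbar)) < 2) {
    stop("need at least 2 distinct pressure groups")
  }
  if (any(records$velocity_mm_s <= 0)) stop("velocities must be positive")
  groups <- split(records, records$pressure_mbar)
  rows <- lapply(groups, function(g) {
    cnt <- vapply(shape_labels, function(s) sum(g$shape == s), integer(1))
    out <- tibble::tibble(pressure_mbar = g$pressure_mbar[1],
                          n = nrow(g),
                          velocity_mm_s = mean(g$velocity_mm_s))
    for (s in shape_labels) out[[paste0("n_", s)]] <- cnt[[s]]
    for (s in shape_labels) out[[paste0("frac_", s)]] <- cnt[[s]] / nrow(g)
    out
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$velocity_mm_s), , drop = FALSE]
  class(tab) <- c("phase_diagram_table", class(tab))
  tab
}

#' Fit a saturating exponential to shape fractions versus velocity
#'
#' Least-squares fit of `y(v) = y_inf + (y_0 - y_inf) * exp(-v / v_char)`,
#' the simplest family with an exponential approach to a finite plateau.
#' The sign of `y_0 - y_inf` is enforced by `direction`: `"growth"`
#' (fraction rises with velocity, e.g. croissants) constrains
#' `y_0 <= y_inf`, `"decay"` (e.g. slippers) constrains `y_0 >= y_inf`.
#' Internally the fit runs in a box-constrained parameterization that keeps
#' the whole fitted curve inside \[0, 1\], with multistart over the rate.
#'
#' @param velocities Strictly positive velocities (mm/s), length >= 4.
#' @param fractions Observed fractions in \[0, 1\].
#' @param direction `"growth"` or `"decay"`.
#' @param n Optional per-group cell counts. When given, the fit uses
#'   inverse-variance weights `n / (p (1 - p))` from the binomial sampling
#'   noise of the fractions (with `p` the observed fraction clamped away
#'   from 0 and 1), which makes the parameter covariance — and the
#'   confidence intervals built from it — match the actual noise level.
#' @return A `saturating_exp_fit`: list with `y_0`, `y_inf`, `v_char`
#'   (mm/s), `residual_norm`, `converged`, `degenerate` (TRUE for constant
#'   fractions, where `v_char` is unidentifiable), `direction`, `v_range`,
#'   and internal pieces used for delta-method intervals.
#' @export
fit_saturating_exponential <- function(velocities, fractions,
                                       direction = c("growth", "decay"),
                                       n = NULL) {
  direction <- match.arg(direction)
  v <- as.numeric(velocities); y <- as.numeric(fractions)
  stopifnot(length(v) == length(y), length(v) >= 4, all(v > 0),
            all(y >= -1e-9 & y <= 1 + 1e-9))
  if (stats::sd(y) < 1e-9) {
    return(structure(list(y_0 = mean(y), y_inf = mean(y), v_char = NA_real_,
                          residual_norm = 0, converged = FALSE,
                          degenerate = TRUE, direction = direction,
                          v_range = range(v)),
                     class = "saturating_exp_fit"))
  }
  # internal parameterization: p = y_inf in [0,1], q in [0,1] with
  # growth: y_0 = p*q ; decay: y_0 = p + (1-p)*q
  dat <- data.frame(v = v, y = y, w = binomial_weights(y, n))
  form <- if (direction == "growth") {
    y ~ p - p * (1 - q) * exp(-v / vc)
  } else {
    y ~ p + (1 - p) * q * exp(-v / vc)
  }
  vspan <- max(v) - min(v) + max(v) * 0.1
  head_y <- y[which.min(v)]; tail_y <- y[which.max(v)]
  p0 <- min(max(tail_y, 1e-3), 1 - 1e-6)
  q0 <- if (direction == "growth") {
    min(max(head_y / max(p0, 1e-6), 1e-3), 1)
  } else {
    min(max((head_y - p0) / max(1 - p0, 1e-6), 1e-3), 1)
  }
  best <- NULL
  for (vc0 in vspan * c(0.05, 0.15, 0.4, 1, 3)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = dat, weights = w,
                        start = list(p = p0, q = q0, vc = vc0),
                        lower = c(p = 0, q = 0, vc = vspan * 1e-4),
                        upper = c(p = 1, q = 1, vc = vspan * 1e4),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      ssr <- sum(stats::residuals(fit)^2)
      if (is.null(best) || ssr < best$ssr) best <- list(fit = fit, ssr = ssr)
    }
  }
  if (is.null(best)) {
    stop("saturating-exponential fit did not converge from any start")
  }
  cf <- stats::coef(best$fit)
  p <- cf[["p"]]; q <- cf[["q"]]; vc <- cf[["vc"]]
  y0 <- if (direction == "growth") p * q else p + (1 - p) * q
  vcv <- tryCatch(stats::vcov(best$fit), error = function(e) NULL)
  structure(list(y_0 = y0, y_inf = p, v_char = vc,
                 residual_norm = sqrt(best$ssr),
                 converged = TRUE, degenerate = FALSE,
                 direction = direction, v_range = range(v),
                 par = c(p = p, q = q, vc = vc), vcov = vcv,
                 df_residual = length(v) - 3, fit = best$fit),
            class = "saturating_exp_fit")
}

#' @export
print.saturating_exp_fit <- function(x, ...) {
  cat(sprintf("saturating_exp_fit (%s): y_0 = %.4g, y_inf = %.4g, v_char = %.4g mm/s%s\n",
              x$direction, x$y_0, x$y_inf, x$v_char,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' @export
predict.saturating_exp_fit <- function(object, v, ...) {
  if (object$degenerate) return(rep(object$y_inf, length(v)))
  object$y_inf + (object$y_0 - object$y_inf) * exp(-v / object$v_char)
}

# gradient of the fitted curve wrt the internal parameters (p, q, vc)
sat_exp_grad_par <- function(fit, v) {
  p <- fit$par[["p"]]; q <- fit$par[["q"]]; vc <- fit$par[["vc"]]
  E <- exp(-v / vc)
  if (fit$direction == "growth") {
    c(p = 1 - (1 - q) * E, q = p * E, vc = -p * (1 - q) * E * v / vc^2)
  } else {
    c(p = 1 - q * E, q = (1 - p) * E, vc = (1 - p) * q * E * v / vc^2)
  }
}

# dy/dv of the fitted curve
sat_exp_grad_v <- function(fit, v) {
  (fit$y_inf - fit$y_0) / fit$v_char * exp(-v / fit$v_char)
}

#' Croissant/slipper transition point
#'
#' The transition velocity is where the fitted croissant and slipper
#' fraction curves intersect (equivalently, where the two shape fractions
#' are equal). The root of the difference curve is bracketed on a grid over
#' the velocity range and polished with [stats::uniroot()]; with several
#' crossings the smallest is returned with a warning. A delta-method
#' standard error is attached when both fits carry a covariance (the two
#' fits are treated as independent).
#'
#' @param croissant_fit,slipper_fit Converged [fit_saturating_exponential()]
#'   results.
#' @param v_range Velocity interval searched; defaults to the union of the
#'   fitted ranges.
#' @return A `transition_result`: list with `v_t` (mm/s), `bracket`,
#'   `method`, `se` (possibly NA) and `n_roots`.
#' @export
transition_point <- function(croissant_fit, slipper_fit, v_range = NULL) {
  stopifnot(inherits(croissant_fit, "saturating_exp_fit"),
            inherits(slipper_fit, "saturating_exp_fit"))
  if (!croissant_fit$converged || !slipper_fit$converged) {
    stop("both fits must have converged")
  }
  if (is.null(v_range)) {
    v_range <- range(c(croissant_fit$v_range, slipper_fit$v_range))
  }
  g <- function(v) predict(croissant_fit, v) - predict(slipper_fit, v)
  grid <- seq(v_range[1], v_range[2], length.out = 512)
  gv <- g(grid)
  if (all(abs(gv) < 1e-12)) {
    # coinciding curves: every velocity is a "crossing"; refuse rather
    # than return an arbitrary one
    stop("no intersection in observed range (curves coincide)")
  }
  flips <- which(gv[-1] * gv[-length(gv)] < 0)
  exact <- which(gv == 0)
  if (length(flips) == 0 && length(exact) == 0) {
    stop("no intersection in observed range")
  }
  n_roots <- length(flips) + length(exact)
  if (n_roots > 1) {
    warning(sprintf("%d crossings in range; returning the smallest", n_roots))
  }
  if (length(exact) > 0 && (length(flips) == 0 || exact[1] <= flips[1])) {
    vt <- grid[exact[1]]
    bracket <- c(vt, vt)
  } else {
    bracket <- c(grid[flips[1]], grid[flips[1] + 1])
    vt <- stats::uniroot(g, bracket, tol = 1e-10)$root
  }
  se <- NA_real_
  if (!is.null(croissant_fit$vcov) && !is.null(slipper_fit$vcov)) {
    dgdv <- sat_exp_grad_v(croissant_fit, vt) - sat_exp_grad_v(slipper_fit, vt)
    gc <- sat_exp_grad_par(croissant_fit, vt)
    gs <- sat_exp_grad_par(slipper_fit, vt)
    var_vt <- (drop(t(gc) %*% croissant_fit$vcov %*% gc) +
               drop(t(gs) %*% slipper_fit$vcov %*% gs)) / dgdv^2
    se <- sqrt(max(var_vt, 0))
  }
  structure(list(v_t = vt, bracket = bracket, method = "fit_intersection",
                 se = se, n_roots = n_roots, v_range = v_range),
            class = "transition_result")
}

#' @export
print.transition_result <- function(x, ...) {
  cat(sprintf("transition point: v_t = %.4g mm/s (bracket [%.4g, %.4g]%s)\n",
              x$v_t, x$bracket[1], x$bracket[2],
              if (is.finite(x$se)) sprintf(", se %.3g", x$se) else ""))
  invisible(x)
}

#' Exponential fit of the acanthocyte fraction versus velocity
#'
#' Nonlinear least squares of `phi_Ac(v) = N0 * exp(d * v)` on the raw
#' fractions (no log transform, so zero counts are permitted). `N0` is the
#' acanthocyte fraction extrapolated to stasis (`v = 0`) and `d` (per mm/s)
#' is the deformability parameter; `d < 0` means the undeformed-acanthocyte
#' fraction decays with increasing flow velocity.
#'
#' @param velocities Velocities (mm/s), length >= 3.
#' @param fractions Acanthocyte fractions in \[0, 1\].
#' @param n Optional per-group cell counts enabling inverse-variance
#'   (binomial) weights, as in [fit_saturating_exponential()].
#' @return An `acanthocyte_fit`: list with `N0`, `d`, `vcov` (2 x 2, order
#'   N0, d), `se`, `residual_norm`, `converged`.
#' @export
fit_acanthocyte_decay <- function(velocities, fractions, n = NULL) {
  v <- as.numeric(velocities); phi <- as.numeric(fractions)
  stopifnot(length(v) == length(phi), length(v) >= 3,
            all(phi >= -1e-12 & phi <= 1 + 1e-12))
  if (all(phi == 0)) stop("all acanthocyte fractions are zero: nothing to fit")
  pos <- phi > 0
  d0 <- if (sum(pos) >= 2) {
    stats::coef(stats::lm(log(phi[pos]) ~ v[pos]))[[2]]
  } else -0.1
  N0_0 <- min(max(max(phi), 1e-6), 1)
  dat <- data.frame(v = v, phi = phi, w = binomial_weights(phi, n))
  fit <- minpack.lm::nlsLM(phi ~ N0 * exp(d * v), data = dat, weights = w,
                           start = list(N0 = N0_0, d = d0),
                           lower = c(N0 = 1e-10, d = -Inf),
                           upper = c(N0 = 1, d = Inf),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  vcv <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  structure(list(N0 = cf[["N0"]], d = cf[["d"]], vcov = vcv,
                 se = if (is.null(vcv)) c(NA_real_, NA_real_)
                      else sqrt(diag(vcv)),
                 residual_norm = sqrt(sum(stats::residuals(fit)^2)),
                 df_residual = length(v) - 2,
                 converged = TRUE, fit = fit),
            class = "acanthocyte_fit")
}

#' @export
print.acanthocyte_fit <- function(x, ...) {
  cat(sprintf("acanthocyte fit: N0 = %.4g, d = %.4g per mm/s (|d| = %.4g)\n",
              x$N0, x$d, abs(x$d)))
  invisible(x)
}

#' @export
predict.acanthocyte_fit <- function(object, v, ...) {
  object$N0 * exp(object$d * v)
}

# inverse-variance weights for binomially sampled fractions; uniform
# weights when counts are unknown
binomial_weights <- function(p, n) {
  if (is.null(n)) return(rep(1, length(p)))
  pc <- pmin(pmax(p, 1 / (2 * n)), 1 - 1 / (2 * n))
  n / (pc * (1 - pc))
}

#' Jackknife standard error of the transition point
#'
#' Leave-one-velocity-group-out jackknife over the rows of a phase-diagram
#' table: the croissant and slipper curves are refitted without each group
#' in turn and the transition point recomputed. Because both fractions are
#' measured on the same cells, they are negatively correlated within a
#' group; the delta-method error of [transition_point()] (which treats the
#' two fits as independent) understates the uncertainty, while the
#' jackknife resamples whole groups and captures that correlation.
#'
#' @param tab A `phase_diagram_table` (needs at least 5 velocity groups).
#' @param weighted Use binomial inverse-variance weights from the group
#'   sizes.
#' @return List with `se`, `v_t` (full-data estimate), `values`
#'   (leave-one-out estimates) and `df` (groups used minus 1).
#' @export
jackknife_transition_se <- function(tab, weighted = TRUE) {
  stopifnot(nrow(tab) >= 5)
  fit_vt <- function(rows) {
    nn <- if (weighted) tab$n[rows] else NULL
    cf <- fit_saturating_exponential(tab$velocity_mm_s[rows],
                                     tab$frac_croissant[rows], "growth",
                                     n = nn)
    sf <- fit_saturating_exponential(tab$velocity_mm_s[rows],
                                     tab$frac_slipper[rows], "decay",
                                     n = nn)
    transition_point(cf, sf,
                     v_range = range(tab$velocity_mm_s))$v_t
  }
  vt_full <- fit_vt(seq_len(nrow(tab)))
  vals <- vapply(seq_len(nrow(tab)), function(i) {
    tryCatch(fit_vt(setdiff(seq_len(nrow(tab)), i)),
             error = function(e) NA_real_)
  }, numeric(1))
  vals <- vals[is.finite(vals)]
  m <- length(vals)
  if (m < 3) stop("too few successful leave-one-out refits")
  se <- sqrt((m - 1) / m * sum((vals - mean(vals))^2))
  list(se = se, v_t = vt_full, values = vals, df = m - 1)
}

#' Compare transition points between two cohorts
#'
#' Shapiro-Wilk normality check per group followed by an unpaired
#' two-sided Student's t-test (pooled variance) on the transition
#' velocities.
#'
#' @param group_a,group_b Numeric vectors of transition velocities (mm/s),
#'   at least 3 each.
#' @return A `transition_comparison`: list with `shapiro` (tibble), `t`
#'   (`htest`), `p`, `label`.
#' @export
compare_transitions <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 3, length(group_b) >= 3)
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    stop("degenerate variance: all values identical in both groups")
  }
  shapiro <- tibble::tibble(
    group = c("a", "b"),
    W = c(unname(stats::shapiro.test(group_a)$statistic),
          unname(stats::shapiro.test(group_b)$statistic)),
    p = c(stats::shapiro.test(group_a)$p.value,
          stats::shapiro.test(group_b)$p.value))
  tt <- stats::t.test(group_a, group_b, var.equal = TRUE)
  structure(list(shapiro = shapiro, t = tt, p = tt$p.value,
                 label = significance_label(tt$p.value)),
            class = "transition_comparison")
}

#' @export
print.transition_comparison <- function(x, ...) {
  cat(sprintf("unpaired t-test: t = %.3f, df = %g, p = %.4g (%s)\n",
              unname(x$t$statistic), unname(x$t$parameter), x$p, x$label))
  invisible(x)
}

#' Full phase-diagram analysis of flow records
#'
#' Convenience wrapper: builds the phase-diagram table, fits the croissant
#' (growth) and slipper (decay) fraction curves on all points within the
#' exponential growth/decay (a leading head whose slope disagrees with the
#' expected direction is trimmed with a warning), locates the
#' croissant/slipper transition point, and, when acanthocytes are present,
#' fits the acanthocyte deformability decay.
#'
#' @param records Per-cell flow records (see [build_phase_diagram()]).
#' @param weighted Use binomial inverse-variance weights from the group
#'   sizes (default TRUE; see [fit_saturating_exponential()]).
#' @return List with `table`, `croissant_fit`, `slipper_fit`, `transition`,
#'   and `acanthocyte_fit` (NULL without acanthocytes).
#' @export
analyze_phase_diagram <- function(records, weighted = TRUE) {
  tab <- build_phase_diagram(records)
  nn <- if (weighted) tab$n else NULL
  # "all points within the exponential growth/decay": a leading head whose
  # 2-point slope disagrees with the expected direction is trimmed
  trim_head <- function(y, direction, label) {
    keep <- seq_along(y)
    while (length(keep) > 4) {
      slope_up <- y[keep[2]] > y[keep[1]]
      if (slope_up == (direction == "growth")) break
      keep <- keep[-1]
    }
    if (length(keep) < length(y)) {
      warning(sprintf("trimmed %d leading non-monotone %s point(s)",
                      length(y) - length(keep), label))
    }
    keep
  }
  kc <- trim_head(tab$frac_croissant, "growth", "croissant")
  ks <- trim_head(tab$frac_slipper, "decay", "slipper")
  cf <- fit_saturating_exponential(tab$velocity_mm_s[kc],
                                   tab$frac_croissant[kc],
                                   direction = "growth", n = nn[kc])
  sf <- fit_saturating_exponential(tab$velocity_mm_s[ks],
                                   tab$frac_slipper[ks],
                                   direction = "decay", n = nn[ks])
  tr <- transition_point(cf, sf)
  af <- if (sum(tab$n_acanthocyte) > 0) {
    fit_acanthocyte_decay(tab$velocity_mm_s, tab$frac_acanthocyte, n = nn)
  } else NULL
  list(table = tab, croissant_fit = cf, slipper_fit = sf,
       transition = tr, acanthocyte_fit = af)
}
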