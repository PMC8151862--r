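# Void ("hole") statistics of aggregated configurations: rasterization,
# periodic connected-component labeling, characteristic hole size, and
# rank-based comparisons across conditions.

#' Rasterize a snapshot to an occupancy grid
#'
#' A grid cell is occupied iff its centre lies inside any cell polygon or
#' within `sigma/2` of any vertex (membrane thickness). Polygons crossing
#' the periodic boundary are handled through their periodic images.
#'
#' @param snap An `rbc_snapshot`.
#' @param resolution Grid spacing in um; must be positive and at most
#'   `sigma` so the membrane is resolved.
#' @param sigma Membrane interaction length (um), used both as the maximum
#'   allowed resolution and for the `sigma/2` membrane dilation.
#' @return An `occupancy_grid`: list with `occupied` (integer matrix, rows
#'   = y), `resolution`, `domain`, `periodic`.
#' @export
rasterize <- function(snap, resolution = 0.3, sigma = 0.3) {
  if (resolution <= 0) stop("resolution must be positive")
  if (resolution > sigma) stop("resolution must not exceed sigma")
  pk <- pack_snapshot(snap)
  occ <- cpp_rasterize(pk$coords, pk$nv, snap$domain[1], snap$domain[2],
                       resolution, sigma / 2)
  structure(list(occupied = occ, resolution = resolution,
                 domain = snap$domain, periodic = isTRUE(snap$periodic)),
            class = "occupancy_grid")
}

#' @export
print.occupancy_grid <- function(x, ...) {
  cat(sprintf("occupancy_grid: %d x %d at %.3g um, occupied fraction %.3f\n",
              nrow(x$occupied), ncol(x$occupied), x$resolution,
              mean(x$occupied > 0)))
  invisible(x)
}

#' Label the holes (free-space components) of an occupancy grid
#'
#' Connected components of free grid cells under 4-connectivity; on a
#' periodic grid, components touching opposite boundaries are merged, so a
#' void straddling the boundary is counted once.
#'
#' With `seal_below > 0`, the occupied phase is first morphologically
#' closed so that gaps narrower than `seal_below` (in um) are sealed. This
#' treats cells whose membranes are within the adhesive interaction range
#' as being in contact, which turns the compartments between aggregated
#' cells into separate components; without it, the plasma phase of a
#' percolating aggregate network would form one connected void. Area
#' bookkeeping (holes + occupied = domain) then refers to the sealed grid.
#'
#' @param grid An `occupancy_grid`.
#' @param seal_below Seal free-space gaps narrower than this width (um)
#'   before labeling; 0 (default) labels the raw grid.
#' @return A `hole_set`: list with `areas` (um^2), `pixels` (component
#'   sizes), `labels` (label matrix, 0 = occupied), `connectivity` (4),
#'   `periodic_merged`, `seal_below`, `resolution`, `domain`.
#' @export
label_holes <- function(grid, seal_below = 0) {
  stopifnot(inherits(grid, "occupancy_grid"))
  occ <- grid$occupied
  if (seal_below > 0) {
    k <- max(1L, ceiling(seal_below / (2 * grid$resolution)))
    occ <- cpp_morph_close(occ, k, grid$periodic)
  }
  lab <- cpp_label_free(occ, grid$periodic)
  px <- tabulate(lab[lab > 0])
  structure(list(areas = px * grid$resolution^2, pixels = px,
                 labels = lab, connectivity = 4L,
                 periodic_merged = grid$periodic,
                 seal_below = seal_below,
                 resolution = grid$resolution, domain = grid$domain),
            class = "hole_set")
}

#' @export
print.hole_set <- function(x, ...) {
  cat(sprintf("hole_set: %d holes, total free area %.4g um^2 (4-connected%s)\n",
              length(x$areas), sum(x$areas),
              if (x$periodic_merged) ", periodic" else ""))
  invisible(x)
}

#' Characteristic hole size of a hole set
#'
#' Void-size distributions of gel-like aggregates have exponential tails,
#' so the characteristic size is the scale of a shifted exponential fitted
#' to the hole areas above a minimum-area cutoff (by default one discocyte
#' reference area, which removes intra-aggregate slivers and
#' discretization debris). Estimators for the same scale:
#'
#' * `"censored_mean_excess"` (default): `mean(area - cutoff)` over holes
#'   with `area >= cutoff`, excluding percolation-scale voids larger than
#'   `censor_fraction` of the domain. On small (desk-scale) periodic
#'   domains a single void can span a finite fraction of the whole domain;
#'   such an object violates the exponential law and would otherwise
#'   dominate the mean.
#' * `"mean_excess"`: the classical maximum-likelihood estimator
#'   `mean(area - cutoff)`, no censoring.
#' * `"median_excess"`: `median(area - cutoff) / log(2)`, a robust
#'   quantile estimator of the same exponential scale.
#' * `"mean"`: plain mean of all hole areas, no cutoff.
#'
#' @param holes A `hole_set`.
#' @param min_area_cutoff Minimum hole area (um^2) entering the estimate.
#' @param estimator Estimator label, see above.
#' @param censor_fraction Domain-area fraction above which a hole is
#'   treated as a percolating void and excluded
#'   (`"censored_mean_excess"` only).
#' @return A `hole_stats`: list with `characteristic_hole_size` (um^2),
#'   `n_holes` (holes entering the estimate), `estimator`,
#'   `min_area_cutoff`, `n_censored`, `degenerate` (TRUE when fewer than
#'   two holes enter or the estimate is 0).
#' @export
characteristic_hole_size <- function(holes, min_area_cutoff = 22.93,
                                     estimator = c("censored_mean_excess",
                                                   "mean_excess",
                                                   "median_excess",
                                                   "mean"),
                                     censor_fraction = 0.05) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(holes, "hole_set"))
  if (estimator == "mean") {
    a <- holes$areas
    if (length(a) == 0) stop("no holes")
    return(structure(list(characteristic_hole_size = mean(a),
                          n_holes = length(a), estimator = "mean",
                          min_area_cutoff = 0, n_censored = 0L,
                          degenerate = length(a) < 2),
                     class = "hole_stats"))
  }
  a <- holes$areas[holes$areas >= min_area_cutoff]
  if (length(a) == 0) {
    stop(sprintf("no holes above the minimum-area cutoff %.3g um^2",
                 min_area_cutoff))
  }
  n_cens <- 0L
  if (estimator == "censored_mean_excess") {
    domain_area <- prod(holes$domain)
    big <- a > censor_fraction * domain_area
    # never censor everything: with a single dominant void, fall back to
    # keeping it (flagged degenerate below if alone)
    if (any(big) && !all(big)) {
      n_cens <- sum(big)
      a <- a[!big]
    }
  }
  est <- switch(estimator,
                censored_mean_excess = mean(a - min_area_cutoff),
                mean_excess = mean(a - min_area_cutoff),
                median_excess = stats::median(a - min_area_cutoff) / log(2))
  structure(list(characteristic_hole_size = est, n_holes = length(a),
                 estimator = estimator,
                 min_area_cutoff = min_area_cutoff, n_censored = n_cens,
                 degenerate = length(a) < 2 || est == 0),
            class = "hole_stats")
}

#' @export
print.hole_stats <- function(x, ...) {
  cat(sprintf("hole_stats: characteristic size %.4g um^2 from %d holes (%s%s)\n",
              x$characteristic_hole_size, x$n_holes, x$estimator,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

significance_label <- function(p) {
  ifelse(p < 1e-4, "****",
         ifelse(p < 1e-3, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", "ns"))))
}

# Dunn-style rank comparison of each group against a reference group,
# using the pooled ranks of all groups and the tie-corrected variance of
# the rank means.
dunn_vs_reference <- function(values, reference) {
  groups <- names(values)
  x <- unlist(values, use.names = FALSE)
  g <- rep(groups, lengths(values))
  r <- rank(x)
  N <- length(x)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_corr
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  others <- setdiff(groups, reference)
  z <- (rbar[others] - rbar[reference]) /
    sqrt(v0 * (1 / n[others] + 1 / n[reference]))
  p <- 2 * stats::pnorm(-abs(z))
  tibble::tibble(condition = others, z = as.numeric(z),
                 p_raw = as.numeric(p))
}

#' Compare characteristic hole sizes across conditions
#'
#' For each condition the replicate characteristic hole sizes are first
#' checked for normality (Shapiro-Wilk); the omnibus comparison uses the
#' Kruskal-Wallis rank test, followed by Dunn-style rank comparisons of
#' every condition against the reference condition with Holm adjustment.
#' Significance labels: ns (p > 0.05), * (p < 0.05), ** (p < 0.01),
#' *** (p < 0.001), **** (p < 0.0001).
#'
#' @param values Named list of numeric vectors (replicate characteristic
#'   hole sizes per condition); at least 2 conditions with at least 3
#'   replicates each.
#' @param reference Name of the reference condition (default: first).
#' @return A `hole_comparison`: list with `shapiro` (tibble), `kruskal`
#'   (`htest`), `pairwise` (tibble with Holm-adjusted p values and labels)
#'   and `reference`.
#' @export
compare_hole_conditions <- function(values, reference = names(values)[1]) {
  if (length(values) < 2) stop("need at least 2 conditions")
  if (any(lengths(values) < 3)) stop("need at least 3 replicates per condition")
  if (is.null(names(values)) || any(names(values) == "")) {
    stop("conditions must be named")
  }
  stopifnot(reference %in% names(values))
  shapiro <- tibble::tibble(
    condition = names(values),
    W = vapply(values, function(v) unname(stats::shapiro.test(v)$statistic),
               numeric(1)),
    p = vapply(values, function(v) stats::shapiro.test(v)$p.value, numeric(1))
  )
  kw <- stats::kruskal.test(unlist(values, use.names = FALSE),
                            factor(rep(names(values), lengths(values))))
  pw <- dunn_vs_reference(values, reference)
  pw$p_adj <- stats::p.adjust(pw$p_raw, method = "holm")
  pw$label <- significance_label(pw$p_adj)
  structure(list(shapiro = shapiro, kruskal = kw, pairwise = pw,
                 reference = reference),
            class = "hole_comparison")
}

#' @export
print.hole_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.3f, df = %d, p = %.4g\n",
              unname(x$kruskal$statistic), unname(x$kruskal$parameter),
              x$kruskal$p.value))
  cat(sprintf("Pairwise (Dunn-style vs '%s', Holm):\n", x$reference))
  print(as.data.frame(x$pairwise))
  invisible(x)
}

#' Sweep simulation conditions and compare hole sizes
#'
#' Runs replicated aggregation simulations over a sweep of either the
#' adhesion strength `eps_attr` or the fraction of an abnormal cell kind
#' (rigid acanthocytes or rigidified discocytes, mixed with healthy
#' discocytes), computes the characteristic hole size of every final
#' configuration, and compares the conditions with
#' [compare_hole_conditions()].
#'
#' @param params A [model_params()] object (shared across conditions).
#' @param eps_values Numeric vector of adhesion strengths, or `NULL`.
#' @param fractions Numeric vector of abnormal-cell fractions in \[0, 1\], or
#'   `NULL`. Exactly one of `eps_values` / `fractions` must be given.
#' @param kind Abnormal kind for a fraction sweep: `"acanthocyte"` or
#'   `"rigidified_discocyte"`.
#' @param n_replicates Seeds per condition (default 5).
#' @param resolution Rasterization resolution, um.
#' @param min_area_cutoff Hole-size cutoff, um^2 (default: discocyte
#'   reference area).
#' @param n_tail Number of trailing saved snapshots averaged into the
#'   per-run characteristic size.
#' @param base_seed First seed; replicate r of condition c uses
#'   `base_seed + 1000 * (c - 1) + (r - 1)`.
#' @return A `hole_sweep`: list with `table` (tibble: condition, seed,
#'   n_holes, characteristic_hole_size) and `comparison`
#'   (a `hole_comparison`, reference = first condition).
#' @export
hole_size_sweep <- function(params, eps_values = NULL, fractions = NULL,
                            kind = c("acanthocyte", "rigidified_discocyte"),
                            n_replicates = 5L, resolution = 0.3,
                            min_area_cutoff = NULL, n_tail = 3L,
                            base_seed = params$seed) {
  kind <- match.arg(kind)
  if (is.null(eps_values) == is.null(fractions)) {
    stop("give exactly one of eps_values or fractions")
  }
  if (is.null(min_area_cutoff)) min_area_cutoff <- params$A0_discocyte
  conditions <- if (!is.null(eps_values)) {
    stats::setNames(eps_values, sprintf("eps_%.2g", eps_values))
  } else {
    stats::setNames(fractions, sprintf("%d%%", round(100 * fractions)))
  }
  rows <- list()
  for (ci in seq_along(conditions)) {
    for (r in seq_len(n_replicates)) {
      seed <- as.integer(base_seed + 1000L * (ci - 1L) + (r - 1L))
      p <- params
      if (!is.null(eps_values)) {
        p$eps_attr <- conditions[[ci]]
        comp <- c(healthy_discocyte = 1)
      } else {
        f <- conditions[[ci]]
        comp <- c(healthy_discocyte = 1 - f)
        comp[kind] <- f
        comp <- comp[comp > 0]
      }
      traj <- run_simulation(p, comp, seed = seed)
      seal <- p$r_cut - p$sigma
      n_snap <- length(traj$snapshots)
      size_at <- function(i) {
        characteristic_hole_size(
          label_holes(rasterize(traj$snapshots[[i]], resolution,
                                sigma = p$sigma), seal_below = seal),
          min_area_cutoff = min_area_cutoff)
      }
      # late-time statistic: average over the last n_tail snapshots (the
      # per-snapshot estimate fluctuates; the tail average measures the
      # same late-time state with less noise)
      tail_idx <- seq(max(2, n_snap - n_tail + 1), n_snap)
      tail_stats <- lapply(tail_idx, size_at)
      hole_size <- mean(vapply(tail_stats, `[[`, numeric(1),
                               "characteristic_hole_size"))
      # steady-state flag: characteristic size over the 3rd vs 4th
      # trajectory quarter must agree within 5%
      h3 <- size_at(max(1, round(0.75 * n_snap)))$characteristic_hole_size
      conv <- abs(h3 - hole_size) / max(hole_size, 1e-12) < 0.05
      rows[[length(rows) + 1]] <- tibble::tibble(
        condition = names(conditions)[ci], value = conditions[[ci]],
        seed = seed,
        n_holes = tail_stats[[length(tail_stats)]]$n_holes,
        characteristic_hole_size = hole_size,
        converged = conv)
    }
  }
  tab <- do.call(rbind, rows)
  values <- split(tab$characteristic_hole_size, tab$condition)
  values <- values[names(conditions)] # keep sweep order
  cmp <- if (length(values) >= 2) {
    compare_hole_conditions(values, reference = names(conditions)[1])
  } else NULL
  structure(list(table = tab, comparison = cmp, conditions = conditions,
                 kind = if (is.null(eps_values)) kind else NA_character_),
            class = "hole_sweep")
}

#' @export
print.hole_sweep <- function(x, ...) {
  med <- tapply(x$table$characteristic_hole_size, x$table$condition, median)
  cat("hole_sweep medians (um^2):\n")
  print(med[names(x$conditions)])
  print(x$comparison)
  invisible(x)
}
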