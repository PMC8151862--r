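# Synthetic data generators: microfluidic flow records with known shape
# fraction curves, tube image stacks with a known interface trajectory, and
# the treated-RBC cohort fraction model.

#' Specification of the synthetic flow-record generator
#'
#' Shape fractions follow the model curves of the phase-diagram analysis:
#' the croissant fraction grows and the slipper fraction decays as
#' saturating exponentials of the flow velocity, the (undeformed)
#' acanthocyte fraction decays as `N0 * exp(d * v)`, and a remainder class
#' `"other"` absorbs what is left so the four fractions always sum to 1.
#'
#' @param croissant,slipper Lists with `y_0`, `y_inf`, `v_char` (mm/s) of
#'   the saturating-exponential fraction curves.
#' @param acanthocyte List with `N0` and `d`; use `N0 = 0` for a healthy
#'   donor without acanthocytes.
#' @param velocity_grid Group mean velocities, mm/s.
#' @param n_per_group Cells recorded per pressure group.
#' @param velocity_jitter Relative sd of per-cell velocity around the group
#'   mean.
#' @param seed Integer seed.
#' @return A `flow_generator_spec` list.
#' @export
flow_generator_spec <- function(croissant = list(y_0 = 0.10, y_inf = 0.65,
                                                 v_char = 2.5),
                                slipper = list(y_0 = 0.75, y_inf = 0.20,
                                               v_char = 2.5),
                                acanthocyte = list(N0 = 0.12, d = -0.35),
                                velocity_grid = seq(0.5, 10, length.out = 8),
                                n_per_group = 200L,
                                velocity_jitter = 0.02,
                                seed = 1L) {
  spec <- list(croissant = croissant, slipper = slipper,
               acanthocyte = acanthocyte,
               velocity_grid = velocity_grid,
               n_per_group = as.integer(n_per_group),
               velocity_jitter = velocity_jitter,
               seed = as.integer(seed))
  class(spec) <- "flow_generator_spec"
  f <- flow_model_fractions(spec)
  if (any(f < -1e-12) || any(f > 1 + 1e-12) || any(f[, "other"] < -1e-12)) {
    stop("model fractions leave [0, 1] on the velocity grid")
  }
  spec
}

# model fractions at the grid velocities; matrix with one row per velocity
flow_model_fractions <- function(spec, v = spec$velocity_grid) {
  sat <- function(cv, v) {
    cv$y_inf + (cv$y_0 - cv$y_inf) * exp(-v / cv$v_char)
  }
  cro <- sat(spec$croissant, v)
  sli <- sat(spec$slipper, v)
  aca <- spec$acanthocyte$N0 * exp(spec$acanthocyte$d * v)
  oth <- 1 - cro - sli - aca
  cbind(croissant = cro, slipper = sli, acanthocyte = aca, other = oth)
}

#' Generate synthetic per-cell flow records
#'
#' For every velocity group, `n_per_group` shape labels are drawn
#' multinomially from the model fractions; per-cell velocities are
#' jittered around the group mean, and the pressure drop is mapped
#' linearly onto the 0-700 mbar range.
#'
#' @param spec A [flow_generator_spec()].
#' @return A tibble of flow records (`donor_id`, `pressure_mbar`,
#'   `velocity_mm_s`, `shape`), `n_per_group` rows per group.
#' @export
gen_flow_records <- function(spec) {
  stopifnot(inherits(spec, "flow_generator_spec"))
  set.seed(spec$seed)
  fr <- flow_model_fractions(spec)
  vmax <- max(spec$velocity_grid)
  rows <- lapply(seq_along(spec$velocity_grid), function(i) {
    v <- spec$velocity_grid[i]
    counts <- as.vector(stats::rmultinom(1, spec$n_per_group, fr[i, ]))
    shapes <- sample(rep(colnames(fr), counts))
    vel <- v * (1 + stats::rnorm(spec$n_per_group, 0, spec$velocity_jitter))
    vel <- pmax(vel, 1e-3)
    tibble::tibble(donor_id = "synthetic",
                   pressure_mbar = round(700 * v / vmax),
                   velocity_mm_s = vel,
                   shape = shapes)
  })
  do.call(rbind, rows)
}

#' Specification of the synthetic tube-stack generator
#'
#' Frames show bright plasma above a dark red-cell column; the interface
#' follows a logistic trajectory (height fallen versus time) with additive
#' Gaussian pixel noise. The logistic family mimics the sigmoidal
#' delay-collapse shape of measured sedimentation curves.
#'
#' @param plateau_mm Final height fallen, mm.
#' @param midpoint_min Time of fastest fall, min.
#' @param steepness_min Logistic time scale, min.
#' @param n_frames Number of frames, acquired 1 per minute starting at 0.
#' @param frame_rows,frame_cols Frame size in pixels.
#' @param mm_per_pixel Calibration along the tube axis.
#' @param start_row_px Interface row (pixels, sub-pixel allowed) in the
#'   first frame.
#' @param intensity_plasma,intensity_column Mean intensities of the two
#'   phases; their difference is the contrast.
#' @param noise_sd Additive Gaussian noise sd; must be below a third of the
#'   contrast for the stack to be usable.
#' @param seed Integer seed.
#' @return A `tube_generator_spec` list.
#' @export
tube_generator_spec <- function(plateau_mm = 60, midpoint_min = 150,
                                steepness_min = 40, n_frames = 40L,
                                frame_rows = 400L, frame_cols = 48L,
                                mm_per_pixel = 0.05, start_row_px = 40,
                                intensity_plasma = 0.85,
                                intensity_column = 0.15,
                                noise_sd = 0.035, seed = 1L) {
  contrast <- intensity_plasma - intensity_column
  if (contrast <= 3 * noise_sd) {
    stop("contrast must exceed 3 x noise sd for a testable stack")
  }
  structure(list(plateau_mm = plateau_mm, midpoint_min = midpoint_min,
                 steepness_min = steepness_min, n_frames = as.integer(n_frames),
                 frame_rows = as.integer(frame_rows),
                 frame_cols = as.integer(frame_cols),
                 mm_per_pixel = mm_per_pixel, start_row_px = start_row_px,
                 intensity_plasma = intensity_plasma,
                 intensity_column = intensity_column,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "tube_generator_spec")
}

# single synthetic frame: 3-pixel linear ramp centred at row_px (1-based,
# sub-pixel), bright above, dark below
synth_tube_frame <- function(row_px, spec, rng_noise = TRUE) {
  r <- seq_len(spec$frame_rows)
  contrast <- spec$intensity_plasma - spec$intensity_column
  ramp <- pmin(pmax((r - (row_px - 1.5)) / 3, 0), 1)
  col_profile <- spec$intensity_plasma - contrast * ramp
  frame <- matrix(col_profile, nrow = spec$frame_rows, ncol = spec$frame_cols)
  if (rng_noise && spec$noise_sd > 0) {
    frame <- frame + matrix(stats::rnorm(length(frame), 0, spec$noise_sd),
                            nrow = spec$frame_rows)
  }
  frame
}

#' Generate a synthetic tube stack with known interface trajectory
#'
#' @param spec A [tube_generator_spec()].
#' @return List with `stack` (a [tube_stack()]) and `truth` (tibble:
#'   `time_min`, `row_px`, `position_mm`, `height_mm` — the ground-truth
#'   interface trajectory).
#' @export
gen_tube_stack <- function(spec) {
  stopifnot(inherits(spec, "tube_generator_spec"))
  set.seed(spec$seed)
  t_min <- (seq_len(spec$n_frames) - 1)
  fall_mm <- spec$plateau_mm / (1 + exp(-(t_min - spec$midpoint_min) /
                                          spec$steepness_min))
  fall_mm <- fall_mm - fall_mm[1]
  row_px <- spec$start_row_px + fall_mm / spec$mm_per_pixel
  if (max(row_px) > spec$frame_rows - 3) {
    stop("trajectory leaves the frame: increase frame_rows or reduce plateau")
  }
  frames <- lapply(row_px, synth_tube_frame, spec = spec)
  st <- tube_stack(frames, t_min, spec$mm_per_pixel)
  truth <- tibble::tibble(time_min = t_min, row_px = row_px,
                          position_mm = (row_px - 1) * spec$mm_per_pixel,
                          height_mm = fall_mm)
  list(stack = st, truth = truth)
}

#' Fraction of circulating RBCs produced inside a treatment window
#'
#' Under uniform red-cell production, a fixed lifespan `L`, and a
#' maturation delay between production and appearance in the circulation,
#' the circulating population at time `t` consists of cells produced in
#' `[t - delay - L, t - delay]`. The fraction of cells produced during the
#' treatment window is the overlap of that production interval with the
#' window, divided by `L`, clamped to \[0, 1\]. The result is continuous and
#' piecewise linear in `t`.
#'
#' @param t Time(s) in days (same clock as the window).
#' @param window List or `treatment_window()` with `start`, `end` (days),
#'   `maturation_delay` (days, default 15) and `lifespan` (days, default
#'   117.5, the midpoint of the observed 115-120 day range).
#' @return Fraction(s) in \[0, 1\].
#' @export
rbc_cohort_fraction <- function(t, window) {
  w <- window
  stopifnot(w$end > w$start, w$maturation_delay >= 0, w$lifespan > 0)
  lo <- pmax(t - w$lifespan, w$start + w$maturation_delay)
  hi <- pmin(t, w$end + w$maturation_delay)
  overlap <- pmax(hi - lo, 0)
  pmin(pmax(overlap / w$lifespan, 0), 1)
}

#' Treatment window for the cohort-fraction model
#'
#' @param start,end Treatment start and end, days.
#' @param maturation_delay Days between production and appearance in the
#'   circulation (default 15).
#' @param lifespan Fixed RBC lifespan in days (default 117.5, midpoint of
#'   115-120).
#' @return A `treatment_window` list.
#' @export
treatment_window <- function(start, end, maturation_delay = 15,
                             lifespan = 117.5) {
  stopifnot(end > start, maturation_delay >= 0, lifespan > 0)
  structure(list(start = start, end = end,
                 maturation_delay = maturation_delay, lifespan = lifespan),
            class = "treatment_window")
}
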