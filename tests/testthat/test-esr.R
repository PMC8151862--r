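# Interface extraction, sedimentation curves, the 2-hour reading and
# percent change.

test_that("hard step interface is located to sub-pixel accuracy", {
  spec <- tube_generator_spec(noise_sd = 0, n_frames = 2,
                              frame_rows = 500L)
  fr <- erythrosim:::synth_tube_frame(412, spec, rng_noise = FALSE)
  pos <- extract_interface(fr, spec$mm_per_pixel)
  expect_equal(pos, (412 - 1) * 0.05, tolerance = 0.05)
  # fractional-row interface
  fr2 <- erythrosim:::synth_tube_frame(100.5, spec, rng_noise = FALSE)
  pos2 <- extract_interface(fr2, spec$mm_per_pixel)
  expect_equal(pos2, (100.5 - 1) * 0.05, tolerance = 0.02)
})

test_that("uniform frames raise a no-interface error", {
  expect_error(extract_interface(matrix(0.5, 200, 30), 0.05), "no interface")
  set.seed(1)
  noisy <- matrix(0.5 + rnorm(6000, 0, 0.02), 200, 30)
  expect_error(extract_interface(noisy, 0.05), "no interface")
})

test_that("extraction is invariant under affine brightness rescaling", {
  spec <- tube_generator_spec(seed = 8)
  set.seed(8)
  fr <- erythrosim:::synth_tube_frame(217.3, spec)
  p1 <- extract_interface(fr, spec$mm_per_pixel)
  p2 <- extract_interface(0.25 * fr + 0.4, spec$mm_per_pixel)
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("noisy ramp interfaces are recovered within 0.1 mm across seeds", {
  spec <- tube_generator_spec() # noise sd 5% of contrast
  errs <- vapply(1:50, function(s) {
    set.seed(s)
    true_row <- stats::runif(1, 50, 350)
    fr <- erythrosim:::synth_tube_frame(true_row, spec)
    pos <- extract_interface(fr, spec$mm_per_pixel)
    abs(pos - (true_row - 1) * spec$mm_per_pixel)
  }, numeric(1))
  expect_lte(max(errs), 0.1)
})

test_that("threshold-crossing alternative also finds the interface", {
  spec <- tube_generator_spec(noise_sd = 0)
  fr <- erythrosim:::synth_tube_frame(150.5, spec, rng_noise = FALSE)
  pos <- extract_interface(fr, spec$mm_per_pixel, method = "threshold")
  expect_equal(pos, (150.5 - 1) * 0.05, tolerance = 0.06)
})

test_that("sedimentation curve round-trips a synthetic logistic stack", {
  spec <- tube_generator_spec(n_frames = 40, plateau_mm = 15,
                              midpoint_min = 20, steepness_min = 8, seed = 5)
  gen <- gen_tube_stack(spec)
  curve <- sedimentation_curve(gen$stack)
  expect_equal(length(curve$times), spec$n_frames)
  rmse <- sqrt(mean((curve$heights - gen$truth$height_mm)^2))
  expect_lt(rmse, 0.1)
  # static stack: all heights zero
  spec0 <- tube_generator_spec(n_frames = 5, plateau_mm = 1e-9,
                               noise_sd = 0)
  gen0 <- gen_tube_stack(spec0)
  curve0 <- sedimentation_curve(gen0$stack)
  expect_equal(curve0$heights, rep(0, 5), tolerance = 1e-9)
})

test_that("monotone trajectories give monotone curves within tolerance", {
  spec <- tube_generator_spec(n_frames = 60, plateau_mm = 30,
                              midpoint_min = 25, steepness_min = 10,
                              frame_rows = 700L, seed = 12)
  gen <- gen_tube_stack(spec)
  curve <- sedimentation_curve(gen$stack)
  expect_true(all(diff(curve$heights) > -0.2))
})

test_that("2-hour reading interpolates linearly and flags it", {
  curve <- structure(list(times = c(0, 119, 121),
                          heights = c(0, 17.9, 18.1)),
                     class = "sedimentation_curve")
  rd <- esr_at_2h(curve)
  expect_equal(rd$height_at_2h, 18.0)
  expect_true(rd$interpolated)
  curve2 <- structure(list(times = c(0, 60, 120, 180),
                           heights = c(0, 9, 18, 20)),
                      class = "sedimentation_curve")
  rd2 <- esr_at_2h(curve2)
  expect_equal(rd2$height_at_2h, 18.0)
  expect_false(rd2$interpolated)
  expect_gte(rd2$height_at_2h, curve2$heights[curve2$times == 60])
  curve3 <- structure(list(times = c(0, 50, 100), heights = c(0, 5, 9)),
                      class = "sedimentation_curve")
  expect_error(esr_at_2h(curve3), "span")
})

test_that("percent change follows the treatment-over-baseline convention", {
  expect_equal(percent_change(10, 10), 0)
  expect_equal(percent_change(2.34 * 8, 8), 134)
  expect_lt(percent_change(5, 8), 0)
  expect_error(percent_change(5, 0), "baseline")
})
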