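test_that("thresholded area matches the closed form and the pixel-count oracle", {
  # full 512 x 512 field of view at 0.33 um/px
  expect_equal(thresholded_area(matrix(255L, 512, 512), 1), 512^2 * 0.33^2)
  expect_equal(thresholded_area(matrix(255L, 512, 512), 1), 28547.4816)
  expect_equal(thresholded_area(matrix(0L, 16, 16), 1), 0)
  expect_error(thresholded_area(matrix(0L, 4, 4), 256), "0, 255")
  expect_error(thresholded_area(matrix(0L, 4, 4), -1), "0, 255")

  set.seed(42)
  for (rep in 1:20) {
    plane <- matrix(sample(0:255, 256, replace = TRUE), 16, 16)
    thr <- sample(0:255, 1)
    expect_equal(thresholded_area(plane, thr),
                 pixel_area_oracle(plane, thr, 0.33))
  }
})

test_that("stack volume sums slabs of thresholded area", {
  st <- z_stack(array(255L, dim = c(512, 512, 10)), delta_z = 0.5)
  expect_equal(volume_ot(st, 1), 10 * 0.5 * 28547.4816)
  expect_equal(volume_ot(st, 1), 142737.408)
  # nothing survives above the stack maximum
  st2 <- binary_stack()
  expect_equal(volume_ot(st2, f_max(st2) + 1L), 0)
})

test_that("rendered pyramid volume approaches the analytic cone volume", {
  st <- pyramid_stack(base_px = 60, apex_um = 20)
  b_um <- 60 * 0.33
  analytic <- b_um^2 * 20 / 3
  v <- volume_ot(st, 1)
  # discretization allowance: one z-slab over the base plus one pixel shell
  slab <- 0.5 * b_um^2
  shell <- 4 * b_um * 0.33 * 20
  expect_lt(abs(v - analytic), slab + shell)
})

test_that("stack height is the fencepost span of the planes", {
  expect_equal(stack_height(87, 0.5), 43)
  expect_equal(stack_height(1, 0.5), 0)
  expect_equal(stack_height(11, 0.5), 5)
  expect_error(stack_height(0), ">= 1")
})

test_that("threshold curves are flat for a two-level stack and drop above the object level", {
  st <- binary_stack(object = 200L, bg = 0L)
  curves <- threshold_curves(st)
  expect_equal(nrow(curves), 201L)
  on_object <- curves$threshold %in% 1:200
  expect_true(all(curves$volume[on_object] == curves$volume[curves$threshold == 1]))
  expect_true(all(curves$height[on_object] == curves$height[curves$threshold == 1]))
})

test_that("both curves are non-increasing and match per-threshold recomputation", {
  set.seed(7)
  for (rep in 1:10) {
    planes <- array(sample(0:80, 16 * 16 * 5, replace = TRUE), dim = c(16, 16, 5))
    st <- z_stack(planes)
    curves <- threshold_curves(st)
    expect_true(all(diff(curves$volume) <= 0))
    expect_true(all(diff(curves$height) <= 0))
  }
  # noisy pyramid: curves equal brute-force recomputation threshold by threshold
  st <- pyramid_stack(side = 40, base_px = 24, apex_um = 6,
                      background_mean = 8, background_sd = 5, signal_sd = 5,
                      seed = 99)
  curves <- threshold_curves(st)
  for (thr in seq(0, f_max(st), by = 17)) {
    expect_equal(curves$volume[curves$threshold == thr], volume_ot(st, thr))
    surviving <- which(apply(st$intensity, 3, max) >= thr)
    h_expect <- if (length(surviving)) (max(surviving) - 1) * st$delta_z else 0
    expect_equal(curves$height[curves$threshold == thr], h_expect)
  }
  # every pixel survives at threshold 0
  expect_equal(curves$volume[curves$threshold == 0],
               n_planes(st) * st$delta_z * 40^2 * 0.33^2)
})

test_that("the selected threshold sits at the height-curve plateau", {
  st <- binary_stack(object = 200L, bg = 0L)
  expect_identical(select_optimal_threshold(threshold_curves(st)), 200L)
  dark <- z_stack(array(0L, dim = c(8, 8, 3)))
  expect_error(select_optimal_threshold(threshold_curves(dark)), "degenerate|identically zero")
})

test_that("auto-thresholding recovers a noisy pyramid volume within 15%", {
  st <- pyramid_stack(base_px = 60, apex_um = 20, side = 80,
                      background_mean = 8, background_sd = 5, signal_sd = 5,
                      seed = 31)
  truth <- attr(st, "truth")$volume_rendered
  fit <- ot_volumetry(st)
  expect_lt(abs(fit$volume - truth) / truth, 0.15)
  # propagated threshold uncertainty is in the expected order of magnitude
  expect_gt(fit$relative_uncertainty, 0.0)
  expect_lt(fit$relative_uncertainty, 0.5)
})

test_that("volume uncertainty propagates the slope times the uniform-threshold term", {
  curves <- tibble::tibble(threshold = 0:100, volume = 1000 - 5 * (0:100),
                           height = rep(10, 101))
  u <- volume_uncertainty(curves, 50, delta_thr = 3)
  expect_equal(u * curves$volume[curves$threshold == 50], 5 * sqrt(3))
  flat <- tibble::tibble(threshold = 0:10, volume = rep(100, 11), height = rep(1, 11))
  expect_equal(volume_uncertainty(flat, 5), 0)
  # one-sided fallback at the boundary
  expect_equal(volume_uncertainty(curves, 0) * 1000, 5 * sqrt(3))
  expect_error(volume_uncertainty(curves, 500), "outside")
})

test_that("sensitivity analysis reports percent change relative to the reference threshold", {
  st <- binary_stack(object = 200L, bg = 0L)
  sens <- sensitivity_analysis(st, 100, halfwidth = 10)
  expect_equal(nrow(sens), 21L)
  expect_equal(sens$delta_v_pct[sens$offset == 0], 0)
  # all offsets inside the two-level plateau leave the volume unchanged
  expect_true(all(sens$delta_v_pct == 0))
  # per-offset values match direct recomputation on a noisy stack
  noisy <- pyramid_stack(side = 40, base_px = 24, apex_um = 6,
                         background_mean = 8, background_sd = 5, signal_sd = 5,
                         seed = 5)
  thr <- select_optimal_threshold(threshold_curves(noisy))
  sens <- sensitivity_analysis(noisy, thr, halfwidth = 5)
  v0 <- volume_ot(noisy, thr)
  for (row in seq_len(nrow(sens))) {
    expect_equal(sens$delta_v_pct[row],
                 100 * (volume_ot(noisy, sens$threshold[row]) - v0) / v0)
  }
  expect_true(all(diff(sens$delta_v_pct) <= 0))
  expect_error(sensitivity_analysis(st, 5, halfwidth = 10), ">= 0")
})

test_that("ot_volumetry ties the pieces together with broom-style accessors", {
  st <- binary_stack(object = 200L, bg = 0L, n = 6, object_planes = 3)
  fit <- ot_volumetry(st)
  expect_s3_class(fit, "ot_volume")
  expect_identical(fit$threshold, 200L)
  # exact on a noiseless two-level stack: 12^2 px * 3 planes
  expect_equal(fit$volume, 12^2 * 0.33^2 * 3 * 0.5)
  expect_equal(fit$h_zstack, (6 - 1) * 0.5)
  g <- glance(fit)
  expect_equal(g$volume, fit$volume)
  expect_named(tidy(fit), c("threshold", "volume", "height"))
  expect_s3_class(autoplot(fit), "ggplot")
  # manual threshold override
  expect_identical(ot_volumetry(st, thr = 150)$threshold, 150L)
})

test_that("non-8-bit input is rescaled onto 0..255 with a warning", {
  arr <- array(seq(0, 4095, length.out = 64), dim = c(4, 4, 4))
  expect_warning(st <- z_stack(arr), "rescal")
  expect_identical(max(st$intensity), 255L)
  expect_identical(min(st$intensity), 0L)
})
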