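test_that("generators are seed-deterministic", {
  f1 <- make_thrombus_field(3, seed = 5, dim = c(128, 128), base_range = c(20, 40))
  f2 <- make_thrombus_field(3, seed = 5, dim = c(128, 128), base_range = c(20, 40))
  expect_identical(f1$height, f2$height)
  expect_identical(f1$components, f2$components)
  s1 <- render_zstack(f1, seed = 6)
  s2 <- render_zstack(f2, seed = 6)
  expect_identical(s1$intensity, s2$intensity)
  t1 <- make_trace(3, seed = 7)
  t2 <- make_trace(3, seed = 7)
  expect_identical(t1$zmag_ohm, t2$zmag_ohm)
})

test_that("thrombus fields carry exact analytic component volumes", {
  flat <- make_thrombus_field(0, dim = c(64, 64))
  expect_equal(flat$volume, 0)
  expect_true(all(flat$height == 0))
  # one pyramid: V = B^2 H / 3
  set.seed(1)
  pyr <- make_thrombus_field(1, base_range = c(60, 60), height_range = c(20, 20),
                             shape = "pyramid", seed = 1, dim = c(128, 128))
  expect_equal(pyr$volume, (60 * 0.33)^2 * 20 / 3)
  # analytic totals agree with the numeric grid integral to 0.5%
  for (shp in c("pyramid", "frustum", "dome")) {
    fld <- make_thrombus_field(2, base_range = c(60, 120), shape = shp,
                               seed = 11, dim = c(256, 256))
    grid_integral <- sum(fld$height) * fld$pixel_pitch^2
    expect_lt(abs(grid_integral - fld$volume) / fld$volume, 0.005)
  }
  expect_error(
    make_thrombus_field(30, base_range = c(40, 60), dim = c(64, 64),
                        max_tries = 20),
    "packing"
  )
  expect_error(make_thrombus_field(1, height_range = c(50, 200)), "channel height")
})

test_that("noiseless renders are exactly recoverable at any threshold in the object band", {
  fld <- make_thrombus_field(2, base_range = c(20, 40), height_range = c(5, 12),
                             seed = 3, dim = c(96, 96))
  st <- render_zstack(fld, background_mean = 0, background_sd = 0, signal_sd = 0)
  truth <- attr(st, "truth")
  expect_equal(truth$volume_rendered,
               0.5 * 0.33^2 * sum(ceiling(fld$height / 0.5)))
  for (thr in c(1, 100, 200)) {
    expect_equal(volume_ot(st, thr), truth$volume_rendered)
  }
  # voxelization bias is one-sided and bounded by one z-slab over the footprint
  slab_bound <- 0.5 * 0.33^2 * sum(fld$height > 0)
  expect_gte(truth$volume_rendered, fld$volume)
  expect_lte(truth$volume_rendered - fld$volume, slab_bound)
})

test_that("rendered background matches the specified noise model", {
  st <- render_zstack(matrix(0, 64, 64), background_mean = 8, background_sd = 5,
                      seed = 13, pad_planes = 3)
  bg <- as.vector(st$intensity)
  # clipped-at-zero gaussian: check the mean and sd loosely
  expect_lt(abs(mean(bg) - 8), 1)
  expect_lt(abs(sd(bg) - 5), 1)
  expect_true(all(bg >= 0 & bg <= 255))
})

test_that("projection images invert the intensity-height model", {
  flat <- render_projection_image(matrix(0, 16, 16), 0.1)
  expect_true(all(flat == 0L))
  one <- render_projection_image(matrix(25.5, 4, 4), 0.1)
  expect_true(all(one == 255L))
  expect_warning(render_projection_image(matrix(40, 4, 4), 0.1), "clip")
  fld <- make_thrombus_field(2, base_range = c(30, 60), height_range = c(5, 20),
                             seed = 9, dim = c(128, 128))
  img <- render_projection_image(fld, 0.1)
  # per-pixel rounding bound: half a level times the scale factor
  bound <- 0.5 * 0.1 * 0.33^2 * length(img)
  expect_lt(abs(volume_im(img, 0.1) - fld$volume), bound)
})

test_that("archetype traces hit their band and crossing anchors", {
  for (g in 1:4) {
    tr <- make_trace(g, noise_sd = 0, seed = g)
    dz <- delta_z(tr)
    cls <- classify_trace(dz)
    expect_identical(cls$group, g, info = paste("group", g))
    expect_true(cls$consistent, info = paste("group", g))
    if (g > 1) {
      anchors <- c(NA, 213.83, 159.32, 72.37)
      expect_equal(cls$crossing_time_10pct, anchors[g], tolerance = 0.02)
    }
  }
  # noiseless traces rise monotonically and contain no events
  tr <- make_trace(2, noise_sd = 0, seed = 1)
  dz <- delta_z(tr)
  expect_true(all(diff(dz$delta_z_pct) >= 0))
  expect_equal(nrow(detect_detachment(dz)), 0L)
  expect_equal(dz$delta_z_pct[1], 0)
  expect_error(make_trace(2, final_dz = 50), "band")
})

test_that("a small noiseless cohort is exactly recoverable and perfectly correlated", {
  g <- fast_grid()
  red <- function(ex) {
    fit <- ot_volumetry(ex$stack)
    inv <- invert_scale_factor(ex$image, ex$z_measured, grid = g)
    tibble::tibble(v_ot = fit$volume, v_im = inv$v_im,
                   rendered = ex$truth$volume_rendered,
                   analytic = ex$truth$volume_analytic)
  }
  co <- make_paired_cohort(3, seed = 17, stack_noise_sd = 0,
                           impedance_noise_sd = 0, background_mean = 0,
                           dim = c(160, 160), n_thrombi_range = c(1, 4),
                           base_range = c(30, 70), carpet_range = c(1, 1),
                           height_range = c(8, 20), grid = g, reduce = red)
  df <- dplyr::bind_rows(co)
  # optical route: exact against the rendered voxel volume
  expect_equal(df$v_ot, df$rendered, tolerance = 1e-12)
  # impedance route: k recovered to the bisection tolerance
  expect_lt(max(abs(df$v_im - df$analytic) / df$analytic), 0.05)
  # unity correlation up to the (per-experiment) voxelization/rounding bias
  expect_gt(cor(df$v_ot, df$v_im), 0.995)
})
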