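test_that("projection volume is the clamped per-pixel height sum", {
  expect_equal(volume_im(matrix(100L, 8, 8), 0), 0)
  img <- matrix(0L, 3, 3); img[2, 2] <- 255L
  expect_equal(volume_im(img, 0.1), 0.33^2 * 25.5)
  expect_equal(volume_im(img, 0.1), 2.77695)
  # clamped at the channel roof
  expect_equal(volume_im(img, 1, channel_height = 100), 0.33^2 * 100)
  set.seed(12)
  img <- matrix(sample(0:255, 100, replace = TRUE), 10, 10)
  acc <- 0
  for (i in 1:10) for (j in 1:10) acc <- acc + min(0.2 * img[i, j], 100)
  expect_equal(volume_im(img, 0.2), 0.33^2 * acc)
})

test_that("a baseline measurement inverts to zero thrombus", {
  g <- fast_grid()
  img <- matrix(60L, 48, 48)
  z0 <- baseline_impedance(grid = g)
  fit <- invert_scale_factor(img, z0, grid = g)
  expect_equal(fit$scale_factor, 0)
  expect_equal(fit$v_im, 0)
})

test_that("out-of-range measurements raise typed conditions", {
  g <- fast_grid()
  img <- matrix(60L, 48, 48)
  z0 <- baseline_impedance(grid = g)
  expect_error(invert_scale_factor(img, 0.8 * z0, grid = g),
               class = "thrombovol_no_solution")
  z_top <- forward_impedance(build_field(img, 100 / 60, grid = g))
  expect_error(invert_scale_factor(img, 1.5 * z_top, grid = g),
               class = "thrombovol_saturation")
  expect_error(invert_scale_factor(matrix(0L, 8, 8), z0, grid = g), "zero")
})

test_that("the forward/inverse round trip recovers the scale factor", {
  g <- fast_grid()
  set.seed(21)
  field <- make_thrombus_field(2, base_range = c(30, 60), dim = c(128, 128),
                               height_range = c(8, 20), seed = 21)
  img <- render_projection_image(field$height + 1, 0.1)
  z <- forward_impedance(build_field(img, 0.1, grid = g))
  fit <- invert_scale_factor(img, z, grid = g)
  expect_lt(abs(fit$scale_factor - 0.1) / 0.1, 1e-3)
  expect_lte(fit$residual, 1e-3)
  expect_equal(fit$v_im, volume_im(img, fit$scale_factor), tolerance = 1e-9)
  g2 <- glance(fit)
  expect_true(all(c("scale_factor", "v_im", "residual") %in% names(g2)))
})

test_that("v_im grows with the measured impedance for a fixed image", {
  g <- fast_grid()
  set.seed(22)
  field <- make_thrombus_field(2, base_range = c(30, 60), dim = c(128, 128),
                               height_range = c(8, 20), seed = 22)
  img <- render_projection_image(field$height + 1, 0.1)
  z0 <- baseline_impedance(grid = g)
  z1 <- forward_impedance(build_field(img, 0.08, grid = g))
  z2 <- forward_impedance(build_field(img, 0.15, grid = g))
  v <- vapply(c(z0 * 1.0005, z1, z2), function(z) {
    invert_scale_factor(img, z, grid = g)$v_im
  }, 0)
  expect_true(all(diff(v) > 0))
})

test_that("saturated projection pixels trigger a linearity warning", {
  g <- fast_grid()
  img <- matrix(60L, 32, 32); img[1:4, 1:4] <- 255L
  z <- forward_impedance(build_field(img, 0.05, grid = g))
  expect_warning(fit <- invert_scale_factor(img, z, grid = g), "saturat")
  expect_equal(fit$saturation_fraction, 16 / (32 * 32))
})

test_that("height-field meshes are watertight and enclose the projection volume", {
  flat <- reconstruct_3d(matrix(0L, 16, 16), 0.1)
  expect_equal(mesh_volume(flat), 0)
  # square plateau: an exact box
  img <- matrix(0L, 16, 16); img[5:12, 5:12] <- 200L
  mesh <- reconstruct_3d(img, 0.1, block = 1)
  expect_equal(mesh_volume(mesh), 64 * 0.33^2 * 20, tolerance = 1e-12)
  # random image: mesh volume equals volume_im within 1% at any decimation
  set.seed(8)
  img <- matrix(sample(0:255, 48 * 48, replace = TRUE), 48, 48)
  for (block in c(1, 4)) {
    mesh <- reconstruct_3d(img, 0.1, block = block)
    expect_lt(abs(mesh_volume(mesh) - volume_im(img, 0.1)) / volume_im(img, 0.1), 0.01)
  }
})

test_that("meshes export to OBJ and binary STL", {
  img <- matrix(0L, 8, 8); img[3:6, 3:6] <- 100L
  mesh <- reconstruct_3d(img, 0.1, block = 2)
  obj <- tempfile(fileext = ".obj")
  write_mesh_obj(mesh, obj)
  lines <- readLines(obj)
  expect_equal(sum(grepl("^v ", lines)), nrow(mesh$vertices))
  expect_equal(sum(grepl("^f ", lines)), nrow(mesh$faces))
  stl <- tempfile(fileext = ".stl")
  write_mesh_stl(mesh, stl)
  expect_equal(file.size(stl), 84 + 50 * nrow(mesh$faces))
  con <- file(stl, "rb")
  seek(con, 80)
  expect_identical(readBin(con, "integer", 1, size = 4, endian = "little"),
                   nrow(mesh$faces))
  close(con)
})

test_that("volume comparison flags compatibility and reproduces the textbook correlation", {
  same <- data.frame(v_ot = c(1e4, 2e4, 3e4), v_im = c(1e4, 2e4, 3e4))
  cmp <- compare_volumes(same)
  expect_equal(attr(cmp, "pearson_r"), 1)
  expect_true(all(cmp$compatible))
  anti <- data.frame(v_ot = c(1, 2, 3), v_im = c(3, 2, 1))
  expect_equal(attr(compare_volumes(anti), "pearson_r"), -1)
  set.seed(14)
  pairs <- data.frame(v_ot = runif(22, 1e4, 2e5))
  pairs$v_im <- pairs$v_ot * (1 + rnorm(22, 0, 0.08))
  cmp <- compare_volumes(pairs)
  expect_equal(attr(cmp, "pearson_r"), pearson_oracle(pairs$v_ot, pairs$v_im),
               tolerance = 1e-12)
  g <- glance(cmp)
  expect_equal(g$n, 22L)
  expect_error(compare_volumes(data.frame(v_ot = 1:2, v_im = 1:2)), "3 pairs")
  expect_warning(cmp0 <- compare_volumes(data.frame(v_ot = rep(1, 4), v_im = 1:4)),
                 "undefined")
  expect_true(is.na(attr(cmp0, "pearson_r")))
  # compatibility tolerance: coverage factor 2 over 15%/10% uncertainties
  one <- suppressWarnings(
    compare_volumes(data.frame(v_ot = c(100, 100, 100), v_im = c(100, 130, 150)))
  )
  expect_equal(one$tolerance, rep(2 * sqrt((0.15 * 100)^2 + (0.10 * one$v_im)^2), 1),
               tolerance = 1e-12)
  expect_s3_class(autoplot(one), "ggplot")
})
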