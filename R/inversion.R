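#' Thrombus volume from a projection image and height scale factor
#'
#' Under the intensity-proportional height model, the volume is the sum of
#' per-pixel heights (clamped at the channel roof) times the pixel area:
#' `V_IM = f^2 * sum min(k * I(x, y), h)`.
#'
#' @param image integer matrix of 8-bit intensities.
#' @param k height scale factor, micrometres per intensity unit (>= 0).
#' @param pixel_pitch pixel size `f`, micrometres per pixel.
#' @param channel_height channel height `h`, micrometres (clamp level).
#' @return volume in cubic micrometres.
#' @export
volume_im <- function(image, k, pixel_pitch = 0.33, channel_height = 100) {
  if (!is.finite(k) || k < 0) abort("scale factor `k` must be >= 0")
  image <- as_plane(image)
  pixel_pitch^2 * sum(pmin(k * image, channel_height))
}

#' Invert a measured impedance into a height scale factor
#'
#' The fusion step: given the 2-D projection image and the impedance
#' magnitude measured at the same instant, find the scale factor `k` at
#' which the simulated impedance of the reconstructed solid matches the
#' measurement. Because a larger `k` means more insulating volume between
#' the electrodes, the forward impedance is strictly increasing in `k`, and
#' plain bisection on `k` in `[0, k_max]` (with
#' `k_max = h / max(1, max(image))`, the factor at which the brightest pixel
#' reaches the roof) is guaranteed to converge. Iteration stops when the
#' relative impedance mismatch drops below `tol`.
#'
#' A measurement below the thrombus-free baseline (beyond `baseline_tol`)
#' has no physical solution under this model and signals a condition of
#' class `thrombovol_no_solution` (possible detachment or artifact); a
#' measurement above the impedance at `k_max` signals
#' `thrombovol_saturation` (occlusive thrombus beyond the model range).
#'
#' @param image integer matrix of 8-bit intensities (the projection image).
#' @param z_measured measured impedance magnitude, ohms.
#' @param geom a [channel_geometry()].
#' @param layout an [electrode_layout()].
#' @param model a [conductivity_model()].
#' @param grid a [solver_grid()].
#' @param pixel_pitch pixel size, micrometres per pixel.
#' @param tol relative impedance mismatch at convergence.
#' @param k_tol relative bracket width at which bisection stops refining
#'   `k`; with a shallow `|Z|(k)` slope the impedance mismatch alone can be
#'   met by a wide range of `k`, so both criteria must hold.
#' @param max_iter maximum bisection iterations.
#' @param baseline_tol tolerated relative dip below the baseline before the
#'   no-solution condition is raised.
#' @return an object of class `fuseit_fit` with fields `scale_factor`,
#'   `v_im`, `relative_uncertainty` (0.10 by construction of the method),
#'   `iterations`, `residual`, `baseline`, `z_measured`,
#'   `saturation_fraction` (fraction of pixels at 255, where the
#'   intensity-height linearity breaks) and `warnings`.
#' @export
invert_scale_factor <- function(image, z_measured,
                                geom = channel_geometry(),
                                layout = electrode_layout(),
                                model = conductivity_model(),
                                grid = solver_grid(geom, layout),
                                pixel_pitch = 0.33,
                                tol = 1e-3, k_tol = 1e-4, max_iter = 60,
                                baseline_tol = 0.02) {
  image <- as_plane(image)
  if (!is.finite(z_measured) || z_measured <= 0) abort("`z_measured` must be > 0")
  if (max(image) == 0) abort("projection image is identically zero")
  warnings <- character(0)
  sat_frac <- mean(image == 255L)
  if (sat_frac > 0) {
    msg <- sprintf(
      "%.2f%% of pixels are saturated at 255; intensity-height linearity is broken there",
      100 * sat_frac
    )
    warn(msg)
    warnings <- c(warnings, msg)
  }
  fwd <- function(k) {
    forward_impedance(build_field(image, k, geom, layout, model, grid, pixel_pitch))
  }
  z0 <- baseline_impedance(geom, layout, model, grid)
  if (z_measured < z0 * (1 - baseline_tol)) {
    abort(
      sprintf(
        "measured impedance (%.4g ohm) is below the thrombus-free baseline (%.4g ohm): no physical solution (possible detachment or artifact)",
        z_measured, z0
      ),
      class = "thrombovol_no_solution"
    )
  }
  mk_fit <- function(k, v, iterations, residual) {
    structure(
      list(
        scale_factor = k, v_im = v, relative_uncertainty = 0.10,
        iterations = iterations, residual = residual,
        baseline = z0, z_measured = z_measured,
        saturation_fraction = sat_frac, warnings = warnings
      ),
      class = "fuseit_fit"
    )
  }
  if (z_measured <= z0 * (1 + tol)) {
    return(mk_fit(0, 0, 0L, abs(z0 - z_measured) / z_measured))
  }
  k_max <- geom$height / max(1, max(image))
  z_hi <- fwd(k_max)
  if (z_measured > z_hi) {
    abort(
      sprintf(
        "measured impedance (%.4g ohm) exceeds the model range (%.4g ohm at k_max): occlusive thrombus beyond the height-field model",
        z_measured, z_hi
      ),
      class = "thrombovol_saturation"
    )
  }
  lo <- 0
  hi <- k_max
  k <- k_max / 2
  residual <- Inf
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    k <- (lo + hi) / 2
    zk <- fwd(k)
    residual <- abs(zk - z_measured) / z_measured
    if (zk < z_measured) lo <- k else hi <- k
    if (residual <= tol && (hi - lo) <= k_tol * max(k, k_max * 1e-3)) break
  }
  if (residual > tol) {
    msg <- sprintf("bisection stopped at max_iter = %d with residual %.3g", max_iter, residual)
    warn(msg)
    warnings <- c(warnings, msg)
  }
  v <- volume_im(image, k, pixel_pitch, geom$height)
  mk_fit(k, v, iter, residual)
}

#' @export
print.fuseit_fit <- function(x, ...) {
  cat(sprintf(
    "<fuseit_fit> k* = %.5g um/level, V_IM = %.1f um^3 (u = %.0f%%), residual %.2g after %d iterations\n",
    x$scale_factor, x$v_im, 100 * x$relative_uncertainty, x$residual, x$iterations
  ))
  invisible(x)
}

#' @rdname invert_scale_factor
#' @param x,object a `fuseit_fit`.
#' @param ... unused.
#' @method tidy fuseit_fit
#' @export
tidy.fuseit_fit <- function(x, ...) {
  tibble(
    term = c("scale_factor", "v_im", "baseline", "z_measured", "residual"),
    estimate = c(x$scale_factor, x$v_im, x$baseline, x$z_measured, x$residual)
  )
}

#' @rdname invert_scale_factor
#' @method glance fuseit_fit
#' @export
glance.fuseit_fit <- function(x, ...) {
  tibble(
    scale_factor = x$scale_factor,
    v_im = x$v_im,
    relative_uncertainty = x$relative_uncertainty,
    iterations = x$iterations,
    residual = x$residual,
    baseline = x$baseline,
    z_measured = x$z_measured,
    saturation_fraction = x$saturation_fraction
  )
}

#' Watertight 3-D reconstruction of the thrombus surface
#'
#' Builds a stepped height-field surface over the image extent from the
#' per-pixel heights `min(k * I, h)`. Pixels are merged into `block x block`
#' tiles carrying the mean height, each tile contributes a flat top face,
#' vertical walls close the steps between neighboring tiles and around the
#' rim, and a single bottom face closes the solid. Because each tile's top
#' face carries the mean of its pixel heights, the enclosed mesh volume
#' equals [volume_im()] up to floating-point error.
#'
#' @param image integer matrix of 8-bit intensities.
#' @param k height scale factor, micrometres per intensity unit.
#' @param pixel_pitch pixel size, micrometres per pixel.
#' @param channel_height clamp height, micrometres.
#' @param block tile size in pixels (mesh decimation factor).
#' @return an object of class `height_mesh`: list with `vertices` (n x 3
#'   matrix, micrometres), `faces` (m x 3 integer matrix, counter-clockwise
#'   from outside) and `extent`.
#' @seealso [mesh_volume()], [write_mesh_obj()], [write_mesh_stl()]
#' @export
reconstruct_3d <- function(image, k, pixel_pitch = 0.33, channel_height = 100,
                           block = 4) {
  if (!is.finite(k) || k < 0) abort("scale factor `k` must be >= 0")
  image <- as_plane(image)
  h_px <- pmin(k * image, channel_height)
  f <- pixel_pitch
  nr <- nrow(h_px)
  nc <- ncol(h_px)
  rg <- ceiling(seq_len(nr) / block)
  cg <- ceiling(seq_len(nc) / block)
  sums <- rowsum(t(rowsum(h_px, rg)), cg)            # |cg| x |rg|
  cnt <- outer(tabulate(cg), tabulate(rg))
  H <- sums / cnt                                     # tile means, x = cols, y = rows
  nxt <- nrow(H)
  nyt <- ncol(H)
  xe <- c(seq(0, nc - 1, by = block), nc) * f         # tile edges
  ye <- c(seq(0, nr - 1, by = block), nr) * f
  verts <- list()
  faces <- list()
  nv <- 0L
  add_quad <- function(p1, p2, p3, p4) {
    # two triangles, vertices given counter-clockwise seen from outside
    verts[[length(verts) + 1L]] <<- rbind(p1, p2, p3, p4)
    faces[[length(faces) + 1L]] <<- rbind(
      nv + c(1L, 2L, 3L),
      nv + c(1L, 3L, 4L)
    )
    nv <<- nv + 4L
  }
  for (i in seq_len(nxt)) {
    for (j in seq_len(nyt)) {
      z <- H[i, j]
      x0 <- xe[i]; x1 <- xe[i + 1]; y0 <- ye[j]; y1 <- ye[j + 1]
      # top face, outward normal +z
      add_quad(c(x0, y0, z), c(x1, y0, z), c(x1, y1, z), c(x0, y1, z))
      # wall toward -x neighbor (or rim)
      zn <- if (i > 1) H[i - 1, j] else 0
      if (z > zn) add_quad(c(x0, y0, zn), c(x0, y0, z), c(x0, y1, z), c(x0, y1, zn))
      zn <- if (i < nxt) H[i + 1, j] else 0
      if (z > zn) add_quad(c(x1, y1, zn), c(x1, y1, z), c(x1, y0, z), c(x1, y0, zn))
      zn <- if (j > 1) H[i, j - 1] else 0
      if (z > zn) add_quad(c(x1, y0, zn), c(x1, y0, z), c(x0, y0, z), c(x0, y0, zn))
      zn <- if (j < nyt) H[i, j + 1] else 0
      if (z > zn) add_quad(c(x0, y1, zn), c(x0, y1, z), c(x1, y1, z), c(x1, y1, zn))
    }
  }
  # bottom face, outward normal -z
  add_quad(c(0, ye[nyt + 1], 0), c(xe[nxt + 1], ye[nyt + 1], 0),
           c(xe[nxt + 1], 0, 0), c(0, 0, 0))
  structure(
    list(
      vertices = do.call(rbind, verts),
      faces = do.call(rbind, faces),
      extent = c(x = nc * f, y = nr * f),
      pixel_pitch = pixel_pitch,
      k = k
    ),
    class = "height_mesh"
  )
}

#' Enclosed volume of a watertight triangle mesh
#'
#' Divergence-theorem integrator: the signed volume is the sum of signed
#' tetrahedron volumes `det(v1, v2, v3) / 6` over all faces, positive for a
#' consistently outward-oriented closed surface.
#'
#' @param mesh a `height_mesh` (or any list with `vertices` and `faces`).
#' @return enclosed volume, cubic micrometres.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  cross <- cbind(
    b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
    b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
    b[, 1] * c_[, 2] - b[, 2] * c_[, 1]
  )
  sum(rowSums(a * cross)) / 6
}

#' @export
print.height_mesh <- function(x, ...) {
  cat(sprintf(
    "<height_mesh> %d vertices, %d triangles over %.1f x %.1f um, enclosed volume %.1f um^3\n",
    nrow(x$vertices), nrow(x$faces), x$extent[1], x$extent[2], mesh_volume(x)
  ))
  invisible(x)
}

#' Write a mesh to Wavefront OBJ (text) or binary STL
#'
#' @param mesh a `height_mesh`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_mesh_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# thrombovol height-field reconstruction (units: micrometres)", con)
  writeLines(sprintf("v %.6g %.6g %.6g",
                     mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d",
                     mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]), con)
  invisible(path)
}

#' @rdname write_mesh_obj
#' @export
write_mesh_stl <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(formatC("thrombovol height-field mesh (um)", width = 80, flag = "-"))
  writeBin(header[1:80], con)
  nf <- nrow(mesh$faces)
  writeBin(as.integer(nf), con, size = 4, endian = "little")
  v <- mesh$vertices
  for (t in seq_len(nf)) {
    a <- v[mesh$faces[t, 1], ]
    b <- v[mesh$faces[t, 2], ]
    cc <- v[mesh$faces[t, 3], ]
    e1 <- b - a
    e2 <- cc - a
    n <- c(
      e1[2] * e2[3] - e1[3] * e2[2],
      e1[3] * e2[1] - e1[1] * e2[3],
      e1[1] * e2[2] - e1[2] * e2[1]
    )
    nn <- sqrt(sum(n^2))
    if (nn > 0) n <- n / nn
    writeBin(as.numeric(c(n, a, b, cc)), con, size = 4, endian = "little")
    writeBin(as.integer(0), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Compare optical and impedance volume estimates
#'
#' Pairs one optical-thresholding volume with one impedance-inverted volume
#' per experiment, flags each pair as metrologically compatible when
#' `|V_OT - V_IM| <= 2 * sqrt((0.15 V_OT)^2 + (0.10 V_IM)^2)` (coverage
#' factor 2 over the two methods' standard uncertainties, 15% optical and
#' 10% impedance), and computes the Pearson correlation across pairs.
#'
#' @param pairs a data frame with columns `v_ot` and `v_im` (um^3).
#' @return a tibble of class `volume_comparison` with the input columns plus
#'   `tolerance` and `compatible`; the correlation is available through
#'   [glance()] (columns `n`, `pearson_r`, `frac_compatible`).
#' @examples
#' cmp <- compare_volumes(data.frame(v_ot = c(1, 2, 3) * 1e4, v_im = c(1.1, 1.9, 3.2) * 1e4))
#' glance(cmp)
#' @export
compare_volumes <- function(pairs) {
  stopifnot(is.data.frame(pairs))
  if (!all(c("v_ot", "v_im") %in% names(pairs))) {
    abort("`pairs` must have columns `v_ot` and `v_im`")
  }
  if (nrow(pairs) < 3) abort("at least 3 pairs are required for a correlation")
  tol <- 2 * sqrt((0.15 * pairs$v_ot)^2 + (0.10 * pairs$v_im)^2)
  out <- tibble(
    v_ot = pairs$v_ot,
    v_im = pairs$v_im,
    tolerance = tol,
    compatible = abs(pairs$v_ot - pairs$v_im) <= tol
  )
  r <- if (sd(out$v_ot) == 0 || sd(out$v_im) == 0) {
    warn("zero variance in one volume list: Pearson correlation is undefined")
    NA_real_
  } else {
    cor(out$v_ot, out$v_im)
  }
  out <- new_tibble(out, nrow = nrow(out), class = "volume_comparison")
  attr(out, "pearson_r") <- r
  out
}

#' @rdname compare_volumes
#' @param x,object a `volume_comparison`.
#' @param ... unused.
#' @method glance volume_comparison
#' @export
glance.volume_comparison <- function(x, ...) {
  tibble(
    n = nrow(x),
    pearson_r = attr(x, "pearson_r"),
    frac_compatible = mean(x$compatible),
    all_compatible = all(x$compatible)
  )
}

#' @rdname compare_volumes
#' @method autoplot volume_comparison
#' @export
autoplot.volume_comparison <- function(object, ...) {
  r <- attr(object, "pearson_r")
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$v_ot, y = .data$v_im)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "red") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE, colour = "black") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$compatible)) +
    ggplot2::labs(
      x = expression(V[OT] ~ (mu * m^3)),
      y = expression(V[IM] ~ (mu * m^3)),
      title = sprintf("Optical vs impedance volumes (r = %.3f)", r),
      colour = "compatible"
    ) +
    ggplot2::theme_minimal()
}
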