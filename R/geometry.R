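#' Microchannel geometry
#'
#' Rectangular flow channel of the perfusion chamber. Defaults reproduce the
#' device: 500 um wide, 100 um high, perfused at 75 ul/min, which yields the
#' arteriolar wall shear rate of 1500 1/s (see [shear_rate()]).
#'
#' @param width channel width `w`, micrometres.
#' @param height channel height `h`, micrometres.
#' @param flow_rate volumetric flow rate `Q`, microlitres per minute.
#' @param length modeled channel length, micrometres (defaults to three
#'   window-widths of the electrode layout, i.e. the investigation window
#'   extended by one window-width up- and downstream).
#' @return an object of class `channel_geometry`.
#' @export
channel_geometry <- function(width = 500, height = 100, flow_rate = 75, length = 840) {
  vals <- c(width = width, height = height, flow_rate = flow_rate, length = length)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all channel geometry values must be positive and finite")
  }
  structure(as.list(vals), class = "channel_geometry")
}

#' Wall shear rate of plane channel flow
#'
#' For a wide rectangular channel, `gamma = 6 Q / (w h^2)`. At the default
#' geometry and 75 ul/min this is 1500 1/s, the physiological shear of
#' arterioles, where platelet adhesion is shear-driven.
#'
#' @param geom a [channel_geometry()].
#' @return wall shear rate in 1/s.
#' @examples
#' shear_rate(channel_geometry()) # 1500
#' @export
shear_rate <- function(geom = channel_geometry()) {
  stopifnot(inherits(geom, "channel_geometry"))
  q_si <- geom$flow_rate * 1e-9 / 60       # ul/min -> m^3/s
  w_si <- geom$width * 1e-6
  h_si <- geom$height * 1e-6
  6 * q_si / (w_si * h_si^2)
}

#' Coplanar u-shaped electrode layout
#'
#' Two nested u-shaped gold tracks on the bottom wall delimit a square
#' investigation window. The outer U (track width 30 um) opens toward +y;
#' the inner U (track width 20 um) is nested inside it and opens toward -y.
#' Only the track widths and the window size are fixed by the device; the arm
#' positions are parametric with symmetric defaults that concentrate the
#' tracks and inter-track gaps inside the central region imaged by a
#' 512 x 512 px field of view at 0.33 um/px (169 x 169 um), so that the
#' measurement is most sensitive exactly where aggregate heights can be read
#' off the image.
#'
#' All coordinates are local window coordinates in micrometres, with the
#' window spanning `[0, window]` in x and y.
#'
#' @param window side of the square investigation window, micrometres.
#' @param outer_track outer electrode track width, micrometres.
#' @param inner_track inner electrode track width, micrometres.
#' @param margin distance from the window edge to the outer track, um.
#' @param inner_x0,inner_x1 x-extent of the inner U (outer edges of its two
#'   arms), um.
#' @param inner_y0 y at which the inner arms start, um.
#' @return an object of class `electrode_layout`.
#' @export
electrode_layout <- function(window = 280, outer_track = 30, inner_track = 20,
                             margin = 60, inner_x0 = 110, inner_x1 = 170,
                             inner_y0 = 110) {
  lay <- list(
    window = window, outer_track = outer_track, inner_track = inner_track,
    margin = margin, inner_x0 = inner_x0, inner_x1 = inner_x1, inner_y0 = inner_y0
  )
  if (any(!vapply(lay, function(v) is.finite(v) && v > 0, TRUE))) {
    abort("all electrode layout values must be positive and finite")
  }
  if (inner_x0 + inner_track >= inner_x1 - inner_track) {
    abort("inner electrode arms overlap; widen `inner_x1 - inner_x0`")
  }
  if (inner_x0 <= margin + outer_track || inner_x1 >= window - margin - outer_track) {
    abort("inner electrode must be nested strictly inside the outer U")
  }
  if (inner_y0 <= margin + outer_track) {
    abort("inner arms must start above the outer base track")
  }
  structure(lay, class = "electrode_layout")
}

#' Electrode footprint masks on a grid of cell centers
#'
#' Rasterizes the two u-shaped footprints onto the bottom-wall cells of a
#' solver grid. A cell belongs to an electrode if its center lies inside the
#' footprint polygon. The two masks are disjoint by construction.
#'
#' @param layout an [electrode_layout()].
#' @param xc,yc cell-center coordinates (window coordinates, um).
#' @return list with logical `nx x ny` matrices `outer` and `inner`.
#' @export
electrode_masks <- function(layout, xc, yc) {
  stopifnot(inherits(layout, "electrode_layout"))
  W <- layout$window
  m <- layout$margin
  wo <- layout$outer_track
  wi <- layout$inner_track
  in_strip <- function(v, a, b) v >= a & v <= b
  X <- matrix(xc, nrow = length(xc), ncol = length(yc))
  Y <- matrix(yc, nrow = length(xc), ncol = length(yc), byrow = TRUE)
  inside <- in_strip(X, m, W - m) & in_strip(Y, m, W - m)
  outer <- inside & (
    in_strip(X, m, m + wo) |                  # left arm
    in_strip(X, W - m - wo, W - m) |          # right arm
    in_strip(Y, m, m + wo)                    # base
  )
  x0 <- layout$inner_x0
  x1 <- layout$inner_x1
  y0 <- layout$inner_y0
  inner <- (
    (in_strip(X, x0, x0 + wi) & in_strip(Y, y0, W - m)) |    # left arm
    (in_strip(X, x1 - wi, x1) & in_strip(Y, y0, W - m)) |    # right arm
    (in_strip(X, x0, x1) & in_strip(Y, W - m - wi, W - m))   # top base
  )
  if (any(outer & inner)) abort("electrode footprints overlap; adjust the layout")
  list(outer = outer, inner = inner)
}

#' Electrical model of the perfused medium
#'
#' Two-phase conductivity model at the working frequency. At 150 kHz platelet
#' membranes behave as insulators, so the aggregate is modeled as a purely
#' resistive low-conductivity phase inside conductive blood; the default
#' thrombus conductivity is one eighth of blood (an effective-medium value,
#' see [thrombus_conductivity()]).
#'
#' @param sigma_blood blood conductivity, S/m.
#' @param sigma_thrombus thrombus conductivity, S/m; must satisfy
#'   `0 < sigma_thrombus < sigma_blood`.
#' @param working_frequency measurement frequency, Hz.
#' @param drive_voltage drive amplitude, volts.
#' @return an object of class `conductivity_model`.
#' @export
conductivity_model <- function(sigma_blood = 0.59,
                               sigma_thrombus = sigma_blood / 8,
                               working_frequency = 150e3,
                               drive_voltage = 0.1) {
  if (!is.finite(sigma_blood) || sigma_blood <= 0) abort("`sigma_blood` must be > 0")
  if (!is.finite(sigma_thrombus) || sigma_thrombus <= 0 || sigma_thrombus >= sigma_blood) {
    abort("`sigma_thrombus` must satisfy 0 < sigma_thrombus < sigma_blood")
  }
  if (working_frequency <= 0 || drive_voltage <= 0) {
    abort("frequency and drive voltage must be positive")
  }
  structure(
    list(
      sigma_blood = sigma_blood, sigma_thrombus = sigma_thrombus,
      working_frequency = working_frequency, drive_voltage = drive_voltage
    ),
    class = "conductivity_model"
  )
}

#' Voxel grid for the conduction solver
#'
#' Builds the finite-volume mesh of the modeled channel section. Laterally
#' the grid covers the investigation window plus one window-width up- and
#' downstream (flow direction x); transversely it covers the window.
#' Vertically a graded mesh resolves the electrode wall: fine layers near
#' z = 0 where the current crowds and the thrombus sits, coarsening toward
#' the channel roof.
#'
#' @param geom a [channel_geometry()].
#' @param layout an [electrode_layout()].
#' @param voxel_xy lateral cell size, micrometres.
#' @param z_edges vertical cell-interface positions, micrometres, from 0 to
#'   the channel height. The default is a 14-layer graded mesh.
#' @param extension up/downstream extension in window-widths (default 1).
#' @return an object of class `solver_grid` with cell edges, centers and
#'   sizes in each direction (micrometres; x spans `[-e*W, (1+e)*W]` in
#'   window coordinates).
#' @export
solver_grid <- function(geom = channel_geometry(), layout = electrode_layout(),
                        voxel_xy = 10, z_edges = NULL, extension = 1) {
  W <- layout$window
  h <- geom$height
  if (is.null(z_edges)) {
    z_edges <- c(0, 2, 4, 6, 8, 10, 13, 16, 20, 25, 31, 40, 55, 75, 100) * (h / 100)
  }
  z_edges <- sort(unique(z_edges))
  if (abs(z_edges[1]) > 1e-9 || abs(z_edges[length(z_edges)] - h) > 1e-9) {
    abort("`z_edges` must run from 0 to the channel height")
  }
  nwin <- round(W / voxel_xy)
  if (abs(nwin * voxel_xy - W) > 1e-6) {
    abort("`voxel_xy` must divide the window size evenly")
  }
  # up/downstream extensions carry no electrodes and little current, so their
  # cells grow geometrically away from the window
  ext_len <- extension * W
  ext_sizes <- numeric(0)
  if (ext_len > 0) {
    s <- voxel_xy * 1.5
    while (sum(ext_sizes) + s < ext_len) {
      ext_sizes <- c(ext_sizes, s)
      s <- s * 1.5
    }
    ext_sizes <- c(ext_sizes, ext_len - sum(ext_sizes))
  }
  win_edges <- seq(0, W, by = voxel_xy)
  x_edges <- c(-rev(cumsum(ext_sizes)), win_edges, W + cumsum(ext_sizes))
  y_edges <- win_edges
  grid <- list(
    x_edges = x_edges, y_edges = y_edges, z_edges = z_edges,
    xc = (head(x_edges, -1) + tail(x_edges, -1)) / 2,
    yc = (head(y_edges, -1) + tail(y_edges, -1)) / 2,
    zc = (head(z_edges, -1) + tail(z_edges, -1)) / 2,
    dx = diff(x_edges), dy = diff(y_edges), dz = diff(z_edges),
    window = W, height = h
  )
  grid$nx <- length(grid$xc)
  grid$ny <- length(grid$yc)
  grid$nz <- length(grid$zc)
  structure(grid, class = "solver_grid")
}

#' @export
print.solver_grid <- function(x, ...) {
  cat(sprintf(
    "<solver_grid> %d x %d x %d cells (%d unknowns), window %g um, height %g um\n",
    x$nx, x$ny, x$nz, x$nx * x$ny * x$nz, x$window, x$height
  ))
  invisible(x)
}
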