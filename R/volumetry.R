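#' Area above an intensity threshold
#'
#' Counts the pixels of one confocal plane whose intensity is at least `thr`
#' and converts the count to physical area, `A = count * f^2`.
#'
#' @param plane integer matrix of 8-bit intensities (one z-plane).
#' @param thr intensity threshold, integer in `[0, 255]`; a pixel survives if
#'   `intensity >= thr`.
#' @param pixel_pitch lateral pixel size `f`, micrometres per pixel.
#' @return thresholded area in square micrometres.
#' @examples
#' thresholded_area(matrix(255L, 512, 512), thr = 1) # full 512x512 field of view
#' @export
thresholded_area <- function(plane, thr, pixel_pitch = 0.33) {
  check_threshold(thr)
  plane <- as_plane(plane)
  sum(plane >= thr) * pixel_pitch^2
}

check_threshold <- function(thr) {
  if (length(thr) != 1L || !is.finite(thr) || thr < 0 || thr > 255 || thr != round(thr)) {
    abort("`thr` must be a single integer in [0, 255]")
  }
  invisible(as.integer(thr))
}

#' Optical-thresholding volume of a z-stack
#'
#' Sums the thresholded areas of all planes and multiplies by the axial step:
#' `V_OT = dz * sum_i A_i(thr)`. Each plane contributes one slab of thickness
#' `delta_z`.
#'
#' @param stack a [z_stack()].
#' @param thr intensity threshold in `[0, 255]`.
#' @return volume in cubic micrometres.
#' @export
volume_ot <- function(stack, thr) {
  stopifnot(inherits(stack, "z_stack"))
  check_threshold(thr)
  if (prod(dim(stack$intensity)) == 0L) abort("empty z-stack")
  stack$delta_z * sum(stack$intensity >= thr) * stack$pixel_pitch^2
}

#' Height spanned by a z-stack
#'
#' `N` planes spaced `delta_z` apart span `(N - 1) * delta_z` micrometres
#' (fencepost: the first plane sits at height zero).
#'
#' @param n_planes number of planes `N` (>= 1).
#' @param delta_z axial step, micrometres.
#' @return height in micrometres.
#' @examples
#' stack_height(87, 0.5) # 43 um
#' @export
stack_height <- function(n_planes, delta_z = 0.5) {
  if (length(n_planes) != 1L || !is.finite(n_planes) || n_planes < 1) {
    abort("`n_planes` must be a single value >= 1")
  }
  (n_planes - 1) * delta_z
}

#' Volume and maximum-height curves over all thresholds
#'
#' For every threshold from 0 to the stack maximum `F_max`, computes the
#' optical-thresholding volume and the maximum thrombus height. The height at
#' threshold `t` is `i_max * delta_z` where `i_max` is the 0-based index of
#' the topmost plane containing at least one surviving pixel (0 when no pixel
#' survives). Both curves are non-increasing in the threshold; the volume
#' curve blows up toward low thresholds while the height curve saturates,
#' which is what the automatic threshold selection exploits.
#'
#' Internally each plane is reduced to its 256-level histogram so the full
#' curve costs one pass over the stack rather than one per threshold.
#'
#' @param stack a [z_stack()].
#' @return a tibble of class `threshold_curves` with columns `threshold`,
#'   `volume` (um^3) and `height` (um), and attributes `delta_z`,
#'   `pixel_pitch`, `n_planes`.
#' @seealso [select_optimal_threshold()], [volume_uncertainty()]
#' @export
threshold_curves <- function(stack) {
  stopifnot(inherits(stack, "z_stack"))
  fx <- max(stack$intensity)
  np <- n_planes(stack)
  thr <- 0:fx
  # per-plane histogram of the 256 intensity levels
  counts <- vapply(
    seq_len(np),
    function(i) tabulate(stack$intensity[, , i] + 1L, nbins = 256L),
    numeric(256L)
  )
  # survival[t + 1, i] = number of pixels in plane i with intensity >= t
  survival <- apply(counts[256:1, , drop = FALSE], 2L, cumsum)[256:1, , drop = FALSE]
  vol <- stack$delta_z * stack$pixel_pitch^2 * rowSums(survival)[thr + 1L]
  plane_max <- vapply(seq_len(np), function(i) max(stack$intensity[, , i]), 0L)
  height <- vapply(thr, function(t) {
    surviving <- which(plane_max >= t)
    if (length(surviving) == 0L) 0 else (max(surviving) - 1) * stack$delta_z
  }, 0)
  out <- new_tibble(
    list(threshold = thr, volume = vol, height = height),
    nrow = length(thr),
    class = "threshold_curves"
  )
  attr(out, "delta_z") <- stack$delta_z
  attr(out, "pixel_pitch") <- stack$pixel_pitch
  attr(out, "n_planes") <- np
  out
}

#' Automatic threshold selection at the height-curve plateau
#'
#' Picks the threshold at the saturation point of the height curve, which
#' coincides with the elbow of the volume curve: lowering the threshold past
#' this point no longer reveals taller structure, it only inflates the volume
#' with background noise. Operationally: the largest threshold at which the
#' height curve attains its maximum over thresholds >= 1 (threshold 0 is
#' excluded because every pixel survives there), ties broken toward the
#' larger threshold.
#'
#' @param curves a [threshold_curves()] tibble.
#' @return the selected threshold (integer).
#' @export
select_optimal_threshold <- function(curves) {
  stopifnot(inherits(curves, "threshold_curves") || is.data.frame(curves))
  keep <- curves$threshold >= 1L
  if (!any(keep)) abort("threshold range is degenerate (F_max = 0)")
  h <- curves$height[keep]
  t <- curves$threshold[keep]
  if (all(h == 0)) abort("height curve is identically zero: stack has no content above threshold 0")
  plateau <- max(h)
  max(t[h == plateau])
}

#' Relative uncertainty of the optical-thresholding volume
#'
#' Propagates the threshold-identification uncertainty through the volume
#' curve: `u(V) = |dV/dThr| * u(Thr)` with `u(Thr) = delta_thr / sqrt(3)`,
#' the standard uncertainty of a uniform distribution of half-width
#' `delta_thr` (the worst-case step size of the stepwise curves).
#' The slope is a central finite difference on the integer
#' threshold grid, falling back to a one-sided difference at the curve ends.
#'
#' @param curves a [threshold_curves()] tibble.
#' @param thr threshold at which to evaluate, within the curve range.
#' @param delta_thr worst-case threshold identification error, threshold
#'   units (default 3).
#' @return relative uncertainty, as a fraction of `V(thr)`.
#' @export
volume_uncertainty <- function(curves, thr, delta_thr = 3) {
  stopifnot(is.data.frame(curves))
  i <- match(thr, curves$threshold)
  if (is.na(i)) abort("`thr` outside the threshold curve range")
  v <- curves$volume
  n <- length(v)
  dv <- if (i == 1L) {
    v[2L] - v[1L]
  } else if (i == n) {
    v[n] - v[n - 1L]
  } else {
    (v[i + 1L] - v[i - 1L]) / 2
  }
  if (v[i] <= 0) abort("volume at `thr` is zero; relative uncertainty undefined")
  abs(dv) * (delta_thr / sqrt(3)) / v[i]
}

#' Sensitivity of the volume to the threshold choice
#'
#' Recomputes the volume at thresholds `thr + i` for offsets
#' `i = -halfwidth .. +halfwidth` and expresses each as a percentage change
#' relative to the volume at `thr`:
#' `dV(thr + i) = 100 * (V(thr + i) - V(thr)) / V(thr)`.
#'
#' @param stack a [z_stack()].
#' @param thr reference threshold (usually the automatically selected one).
#' @param halfwidth maximum offset explored on each side (default 10).
#' @return a tibble with columns `offset`, `threshold`, `volume`,
#'   `delta_v_pct`; `delta_v_pct` is exactly 0 at offset 0.
#' @export
sensitivity_analysis <- function(stack, thr, halfwidth = 10) {
  stopifnot(inherits(stack, "z_stack"))
  check_threshold(thr)
  if (thr - halfwidth < 0) abort("`thr - halfwidth` must be >= 0")
  v0 <- volume_ot(stack, thr)
  if (v0 <= 0) abort("volume at the reference threshold is zero")
  offsets <- seq(-halfwidth, halfwidth)
  thrs <- thr + offsets
  vols <- vapply(thrs, function(t) {
    if (t > 255) 0 else volume_ot(stack, t)
  }, 0)
  tibble(
    offset = offsets,
    threshold = thrs,
    volume = vols,
    delta_v_pct = 100 * (vols - v0) / v0
  )
}

#' End-to-end optical volumetry of a z-stack
#'
#' Runs the full optical route: threshold curves, automatic (or overridden)
#' threshold selection, volume, propagated relative uncertainty and the stack
#' height `(N - 1) * delta_z`.
#'
#' @param stack a [z_stack()].
#' @param thr optional manual threshold overriding the automatic selection.
#' @param delta_thr threshold identification error passed to
#'   [volume_uncertainty()].
#' @return an object of class `ot_volume` with fields `volume`,
#'   `relative_uncertainty`, `threshold`, `h_zstack`, `curves`, `n_planes`,
#'   `delta_z`, `pixel_pitch`, `method = "OT"`. [tidy()] returns the
#'   threshold curves, [glance()] a one-row summary, [autoplot()] the
#'   curve/elbow figure.
#' @examples
#' st <- z_stack(array(c(rep(200L, 64), rep(0L, 64 * 3)), dim = c(8, 8, 4)))
#' fit <- ot_volumetry(st)
#' glance(fit)
#' @export
ot_volumetry <- function(stack, thr = NULL, delta_thr = 3) {
  curves <- threshold_curves(stack)
  threshold <- if (is.null(thr)) select_optimal_threshold(curves) else check_threshold(thr)
  v <- volume_ot(stack, threshold)
  u <- volume_uncertainty(curves, threshold, delta_thr = delta_thr)
  structure(
    list(
      volume = v,
      relative_uncertainty = u,
      threshold = threshold,
      h_zstack = stack_height(n_planes(stack), stack$delta_z),
      curves = curves,
      n_planes = n_planes(stack),
      delta_z = stack$delta_z,
      pixel_pitch = stack$pixel_pitch,
      method = "OT"
    ),
    class = "ot_volume"
  )
}

#' @export
print.ot_volume <- function(x, ...) {
  cat(sprintf(
    "<ot_volume> V_OT = %.1f um^3 (u = %.1f%%) at threshold %d; H_zstack = %g um (%d planes)\n",
    x$volume, 100 * x$relative_uncertainty, x$threshold, x$h_zstack, x$n_planes
  ))
  invisible(x)
}

#' @rdname ot_volumetry
#' @param x an `ot_volume` object.
#' @param ... unused.
#' @method tidy ot_volume
#' @export
tidy.ot_volume <- function(x, ...) {
  as_tibble(x$curves)
}

#' @rdname ot_volumetry
#' @method glance ot_volume
#' @export
glance.ot_volume <- function(x, ...) {
  tibble(
    volume = x$volume,
    relative_uncertainty = x$relative_uncertainty,
    threshold = x$threshold,
    h_zstack = x$h_zstack,
    n_planes = x$n_planes,
    method = x$method
  )
}

#' @rdname ot_volumetry
#' @param object an `ot_volume` object.
#' @method autoplot ot_volume
#' @export
autoplot.ot_volume <- function(object, ...) {
  curves <- as_tibble(object$curves)
  hmax <- max(curves$height)
  vmax <- max(curves$volume)
  scale <- if (hmax > 0) vmax / hmax else 1
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$threshold)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$volume, colour = "V_OT")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$height * scale, colour = "H_max")) +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = "dashed") +
    ggplot2::scale_y_continuous(
      name = expression(V[OT] ~ (mu * m^3)),
      sec.axis = ggplot2::sec_axis(~ . / scale, name = expression(H[max] ~ (mu * m)))
    ) +
    ggplot2::labs(
      x = "intensity threshold",
      colour = NULL,
      title = sprintf("Automatic threshold selection (Thr = %d)", object$threshold)
    ) +
    ggplot2::theme_minimal()
}
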