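#' Confocal z-stack container
#'
#' A z-stack is an ordered sequence of 8-bit grayscale planes acquired along
#' the optical axis, bottom (focal/adhesion) plane first. Planes are stored as
#' a single `rows x cols x n` integer array together with the lateral pixel
#' pitch `f` (micrometres per pixel) and the axial step `delta_z` (micrometres
#' between consecutive planes).
#'
#' Intensities outside `[0, 255]` are linearly rescaled so that the stack
#' maximum maps to 255 (with a warning): the volumetry operates on 8-bit
#' levels, and higher-bit-depth acquisitions are only defined up to this
#' rescaling.
#'
#' @param planes a `rows x cols x n` numeric array, a single matrix (one
#'   plane), or a list of equally-shaped matrices ordered bottom-to-top.
#' @param pixel_pitch lateral pixel size, micrometres per pixel.
#' @param delta_z axial spacing between consecutive planes, micrometres.
#' @return an object of class `z_stack`: a list with elements `intensity`
#'   (integer array), `pixel_pitch` and `delta_z`.
#' @examples
#' st <- z_stack(array(200L, dim = c(8, 8, 4)))
#' n_planes(st)
#' f_max(st)
#' @export
z_stack <- function(planes, pixel_pitch = 0.33, delta_z = 0.5) {
  if (is.list(planes) && !is.array(planes)) {
    shapes <- vapply(planes, function(p) paste(dim(as.matrix(p)), collapse = "x"), "")
    if (length(unique(shapes)) > 1L) {
      abort("all planes in a z-stack must share the same shape")
    }
    planes <- array(unlist(planes, use.names = FALSE),
                    dim = c(dim(as.matrix(planes[[1]])), length(planes)))
  }
  if (is.matrix(planes)) planes <- array(planes, dim = c(dim(planes), 1L))
  if (!is.array(planes) || length(dim(planes)) != 3L) {
    abort("`planes` must be a matrix, a 3-d array, or a list of matrices")
  }
  if (any(dim(planes) < 1L)) abort("z-stack dimensions must all be >= 1")
  if (!is.finite(pixel_pitch) || pixel_pitch <= 0) abort("`pixel_pitch` must be > 0")
  if (!is.finite(delta_z) || delta_z <= 0) abort("`delta_z` must be > 0")
  planes <- coerce_8bit(planes)
  structure(
    list(intensity = planes, pixel_pitch = pixel_pitch, delta_z = delta_z),
    class = "z_stack"
  )
}

# Rescale arbitrary intensity data onto integer 8-bit levels. Values already
# in {0, ..., 255} pass through untouched.
coerce_8bit <- function(x) {
  if (anyNA(x)) abort("intensities must not contain missing values")
  mx <- max(x)
  mn <- min(x)
  if (mn < 0 || mx > 255) {
    warn(sprintf(
      "intensities outside [0, 255] (range %.6g..%.6g): rescaling so the maximum maps to 255",
      mn, mx
    ))
    if (mx > mn) x <- (x - mn) / (mx - mn) * 255 else x <- x * 0
  }
  storage.mode(x) <- "integer"
  x
}

#' @rdname z_stack
#' @param x a `z_stack`.
#' @export
n_planes <- function(x) {
  stopifnot(inherits(x, "z_stack"))
  dim(x$intensity)[3L]
}

#' @rdname z_stack
#' @export
f_max <- function(x) {
  stopifnot(inherits(x, "z_stack"))
  max(x$intensity)
}

#' @export
print.z_stack <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf(
    "<z_stack> %d planes of %d x %d px  (f = %g um/px, dz = %g um, F_max = %d)\n",
    d[3L], d[1L], d[2L], x$pixel_pitch, x$delta_z, max(x$intensity)
  ))
  invisible(x)
}

#' @export
dim.z_stack <- function(x) dim(x$intensity)

# Validate a single image plane; returns an integer matrix on 8-bit levels.
as_plane <- function(plane) {
  plane <- as.matrix(plane)
  if (any(dim(plane) < 1L)) abort("a plane must have at least one pixel")
  coerce_8bit(plane)
}
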