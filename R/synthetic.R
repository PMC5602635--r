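#' Synthetic thrombus height field with analytic ground truth
#'
#' Scatters non-overlapping solid shapes over the imaging field and returns
#' both the sampled height map and the exact analytic volume of each
#' component. Shapes mimic the morphology of platelet aggregates formed
#' under flow:
#' \describe{
#'   \item{pyramid}{square base, apex height `H`; `V = B^2 H / 3`.}
#'   \item{frustum}{square tent with a flat top of side `c B` (c = 0.5);
#'     `V = B^2 H (1 + c + c^2) / 3`.}
#'   \item{dome}{spherical-cap-like bump over the inscribed circle;
#'     `V = 2 pi a^2 H / 3` with `a = B / 2`.}
#' }
#'
#' @param n_thrombi number of components (0 gives a flat field).
#' @param base_range base side range, pixels.
#' @param height_range apex height range, micrometres (must stay below the
#'   channel height).
#' @param shape shape family, one or more of `"pyramid"`, `"frustum"`,
#'   `"dome"` (sampled per component).
#' @param seed RNG seed; `NULL` uses the current RNG stream.
#' @param dim image grid `c(rows, cols)`, pixels.
#' @param pixel_pitch pixel size, micrometres per pixel.
#' @param channel_height channel height bound, micrometres.
#' @param max_tries placement retries per component size; a component that
#'   does not fit is halved (at most twice, to a floor of 8 px) before the
#'   packing is declared infeasible.
#' @return an object of class `thrombus_field`: `height` matrix (um),
#'   `volume` (sum of analytic component volumes, um^3), `components`
#'   tibble, `pixel_pitch`, `seed`.
#' @export
make_thrombus_field <- function(n_thrombi = 3, base_range = c(40, 120),
                                height_range = c(8, 30),
                                shape = c("pyramid", "frustum", "dome"),
                                seed = NULL, dim = c(512, 512),
                                pixel_pitch = 0.33, channel_height = 100,
                                max_tries = 200) {
  shape <- match.arg(shape, several.ok = TRUE)
  if (max(height_range) > channel_height) {
    abort("`height_range` must stay below the channel height")
  }
  if (!is.null(seed)) set.seed(seed)
  h <- matrix(0, dim[1], dim[2])
  comps <- list()
  boxes <- matrix(numeric(0), ncol = 4)  # r0, r1, c0, c1 (with margin)
  margin <- 4
  # draw all component parameters up front, then place largest-first; on a
  # crowded field a component that cannot be placed is halved (at most
  # twice) before the packing is declared infeasible -- late-arriving
  # aggregates in a crowded field are small
  draw <- tibble(
    b = pmin(round(runif(n_thrombi, base_range[1], base_range[2])), min(dim) - 2),
    hgt = runif(n_thrombi, height_range[1], height_range[2]),
    shp = sample(shape, n_thrombi, replace = TRUE)
  )
  draw <- draw[order(-draw$b), , drop = FALSE]
  for (ith in seq_len(n_thrombi)) {
    placed <- FALSE
    b <- draw$b[ith]
    hgt <- draw$hgt[ith]
    shp <- draw$shp[ith]
    for (try in seq_len(3 * max_tries)) {
      if (try %% max_tries == 0) b <- max(8, round(b / 2))
      r0 <- round(runif(1, 1, dim[1] - b))
      c0 <- round(runif(1, 1, dim[2] - b))
      box <- c(r0 - margin, r0 + b + margin, c0 - margin, c0 + b + margin)
      overlaps <- nrow(boxes) > 0 && any(
        boxes[, 1] <= box[2] & boxes[, 2] >= box[1] &
        boxes[, 3] <= box[4] & boxes[, 4] >= box[3]
      )
      if (overlaps) next
      rows <- r0:(r0 + b - 1)
      cols <- c0:(c0 + b - 1)
      # distances from the component center in units of the half-base
      u <- (seq_along(rows) - (b + 1) / 2) / (b / 2)
      v <- (seq_along(cols) - (b + 1) / 2) / (b / 2)
      B <- b * pixel_pitch
      if (shp == "pyramid") {
        cheb <- pmin(outer(abs(u), abs(v), pmax), 1)
        bump <- hgt * (1 - cheb)
        vol <- B^2 * hgt / 3
      } else if (shp == "frustum") {
        cc <- 0.5
        cheb <- pmin(outer(abs(u), abs(v), pmax), 1)
        bump <- hgt * pmin(1, (1 - cheb) / (1 - cc))
        vol <- B^2 * hgt * (1 + cc + cc^2) / 3
      } else {
        r2 <- outer(u^2, v^2, `+`)
        bump <- hgt * sqrt(pmax(0, 1 - r2))
        vol <- 2 * pi * (B / 2)^2 * hgt / 3
      }
      h[rows, cols] <- h[rows, cols] + bump
      boxes <- rbind(boxes, box)
      comps[[length(comps) + 1L]] <- tibble(
        shape = shp, base_px = b, height_um = hgt,
        row = r0, col = c0, volume = vol
      )
      placed <- TRUE
      break
    }
    if (!placed) {
      abort(sprintf("could not place component %d after %d tries: packing infeasible",
                    ith, max_tries))
    }
  }
  components <- if (length(comps)) dplyr::bind_rows(comps) else
    tibble(shape = character(0), base_px = integer(0), height_um = numeric(0),
           row = integer(0), col = integer(0), volume = numeric(0))
  structure(
    list(
      height = h,
      volume = sum(components$volume),
      components = components,
      pixel_pitch = pixel_pitch,
      seed = seed
    ),
    class = "thrombus_field"
  )
}

#' @export
print.thrombus_field <- function(x, ...) {
  cat(sprintf(
    "<thrombus_field> %d x %d px, %d components, analytic volume %.1f um^3\n",
    nrow(x$height), ncol(x$height), nrow(x$components), x$volume
  ))
  invisible(x)
}

#' Render a confocal z-stack from a height field
#'
#' Emulates the confocal acquisition of a fluorescently labeled aggregate:
#' plane `i` (0-based, bottom first) shows object signal wherever the local
#' height exceeds `i * delta_z`, and background elsewhere. Object pixels get
#' `object_intensity` plus Gaussian signal noise; background pixels get
#' Gaussian background noise; everything is rounded and clipped to 8 bits.
#' No optical blur is simulated: the downstream thresholding operates on
#' intensity levels only.
#'
#' The `truth` attribute records the analytic volume (when a
#' `thrombus_field` is supplied) and the rendered voxel volume
#' `dz * f^2 * sum ceil(h / dz)`, which is what a noiseless stack yields at
#' any threshold between background and object intensity.
#'
#' @param field a `thrombus_field`, or a bare height matrix (um).
#' @param delta_z axial step, micrometres.
#' @param object_intensity mean object level (must exceed the background
#'   mean, at most 255).
#' @param background_mean,background_sd background noise parameters.
#' @param signal_sd object signal noise sd.
#' @param seed RNG seed; `NULL` uses the current stream.
#' @param pixel_pitch pixel size (taken from `field` when available).
#' @param pad_planes empty planes appended above the tallest structure, as
#'   an acquisition would include the first plane past the tips.
#' @return a [z_stack()] with attribute `truth` (list: `volume_analytic`,
#'   `volume_rendered`, `height_map`, `seed`).
#' @export
render_zstack <- function(field, delta_z = 0.5, object_intensity = 200,
                          background_mean = 8, background_sd = 5,
                          signal_sd = 5, seed = NULL, pixel_pitch = 0.33,
                          pad_planes = 2) {
  if (inherits(field, "thrombus_field")) {
    hmap <- field$height
    pixel_pitch <- field$pixel_pitch
    v_analytic <- field$volume
  } else {
    hmap <- as.matrix(field)
    v_analytic <- NA_real_
  }
  if (object_intensity <= background_mean || object_intensity > 255) {
    abort("`object_intensity` must lie in (background_mean, 255]")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- max(1, ceiling(max(hmap) / delta_z)) + pad_planes
  planes <- array(0L, dim = c(nrow(hmap), ncol(hmap), n))
  npix <- length(hmap)
  for (i in seq_len(n)) {
    obj <- hmap > (i - 1) * delta_z
    plane <- rnorm(npix, background_mean, background_sd)
    if (any(obj)) plane[obj] <- object_intensity + rnorm(sum(obj), 0, signal_sd)
    planes[, , i] <- pmax(0L, pmin(255L, as.integer(round(plane))))
  }
  st <- z_stack(planes, pixel_pitch = pixel_pitch, delta_z = delta_z)
  attr(st, "truth") <- list(
    volume_analytic = v_analytic,
    volume_rendered = delta_z * pixel_pitch^2 * sum(ceiling(hmap / delta_z)),
    height_map = hmap,
    seed = seed
  )
  st
}

#' Render the 2-D projection image implied by a height field
#'
#' Inverse of the intensity-proportional height model: `I = round(h / k)`,
#' clipped to 255 with a saturation warning (heights above `255 k` are no
#' longer resolvable from the image).
#'
#' @param field a `thrombus_field` or a height matrix (um).
#' @param k_true generative scale factor, micrometres per intensity unit
#'   (> 0).
#' @return integer intensity matrix with attribute `truth` (list:
#'   `k_true`, `volume_analytic`, `clipped_fraction`).
#' @export
render_projection_image <- function(field, k_true) {
  if (!is.finite(k_true) || k_true <= 0) abort("`k_true` must be > 0")
  if (inherits(field, "thrombus_field")) {
    hmap <- field$height
    v_analytic <- field$volume
  } else {
    hmap <- as.matrix(field)
    v_analytic <- NA_real_
  }
  raw <- round(hmap / k_true)
  clipped <- mean(raw > 255)
  if (clipped > 0) {
    warn(sprintf("%.2f%% of pixels exceed intensity 255 and are clipped (saturation)",
                 100 * clipped))
  }
  img <- matrix(as.integer(pmin(raw, 255)), nrow(hmap), ncol(hmap))
  attr(img, "truth") <- list(
    k_true = k_true, volume_analytic = v_analytic, clipped_fraction = clipped
  )
  img
}

# printed per-group anchors: mean final rise (%) and mean 10%-crossing (s)
group_archetypes <- function() {
  tibble(
    group = 1:4,
    final_dz = c(7.55, 16.55, 31.15, 65.46),
    crossing_time = c(NA, 213.83, 159.32, 72.37)
  )
}

#' Synthesize an impedance trace of a given behavior group
#'
#' Generates a saturating logistic rise of the relative impedance hitting a
#' prescribed final value at the end of perfusion and a prescribed
#' 10%-crossing time, adds Gaussian noise, optionally injects detachment
#' drops, and converts to an impedance magnitude series over a baseline.
#' Defaults reproduce each group's mean final rise and crossing time
#' (group 1: 7.55%, never crossing; group 2: 16.55% at 213.83 s; group 3:
#' 31.15% at 159.32 s; group 4: 65.46% at 72.37 s).
#'
#' @param group behavior group 1-4.
#' @param final_dz final relative rise at `duration`, percent; must lie in
#'   the group's band.
#' @param crossing_time 10%-crossing time, seconds (ignored for group 1).
#' @param noise_sd Gaussian noise sd, percentage points.
#' @param events optional detachment drops: a data frame with columns `t1`,
#'   `t2`, `drop` (seconds, seconds, percentage points).
#' @param seed RNG seed; `NULL` uses the current stream.
#' @param baseline_ohm baseline impedance magnitude.
#' @param duration trace length, seconds.
#' @param rate sampling rate, Hz.
#' @param steepness logistic rate parameter, 1/s.
#' @return a tibble (`time_s`, `zmag_ohm`) with attributes `frequency`
#'   (150 kHz) and `truth` (group, final_dz, crossing_time, seed, events).
#' @export
make_trace <- function(group, final_dz = NULL, crossing_time = NULL,
                       noise_sd = 0.5, events = NULL, seed = NULL,
                       baseline_ohm = 1000, duration = 300, rate = 1,
                       steepness = 0.04) {
  stopifnot(group %in% 1:4)
  arch <- group_archetypes()
  final_dz <- final_dz %||% arch$final_dz[group]
  crossing_time <- crossing_time %||% arch$crossing_time[group]
  bands <- group_bands()
  if (!(final_dz >= bands$lower[group] && final_dz < bands$upper[group])) {
    abort(sprintf("`final_dz` = %g lies outside the band of group %d", final_dz, group))
  }
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, duration, by = 1 / rate)
  logistic <- function(tt, t0) 1 / (1 + exp(-steepness * (tt - t0)))
  if (group == 1L) {
    t0 <- duration / 2
  } else {
    if (is.na(crossing_time) || crossing_time <= 0 || crossing_time >= duration) {
      abort("groups 2-4 need a `crossing_time` inside (0, duration)")
    }
    target <- 10 / final_dz
    # shift the sigmoid until the normalized curve crosses 10% at the anchor
    shape_at <- function(t0) {
      g0 <- logistic(0, t0)
      (logistic(crossing_time, t0) - g0) / (logistic(duration, t0) - g0) - target
    }
    t0 <- uniroot(shape_at, interval = c(-2 * duration, 2 * duration), tol = 1e-8)$root
  }
  g0 <- logistic(0, t0)
  dz_clean <- final_dz * (logistic(t, t0) - g0) / (logistic(duration, t0) - g0)
  if (!is.null(events)) {
    stopifnot(all(c("t1", "t2", "drop") %in% names(events)))
    for (e in seq_len(nrow(events))) {
      ramp <- pmin(1, pmax(0, (t - events$t1[e]) / (events$t2[e] - events$t1[e])))
      dz_clean <- dz_clean - events$drop[e] * ramp
    }
  }
  noise <- c(0, rnorm(length(t) - 1, 0, noise_sd))  # baseline sample stays exact
  dz_pct <- dz_clean + noise
  out <- tibble(time_s = t, zmag_ohm = baseline_ohm * (1 + dz_pct / 100))
  attr(out, "frequency") <- 150e3
  attr(out, "truth") <- list(
    group = as.integer(group), final_dz = final_dz, crossing_time = crossing_time,
    noise_sd = noise_sd, events = events, seed = seed, baseline_ohm = baseline_ohm
  )
  out
}

#' Paired synthetic cohort for the optical/impedance comparison
#'
#' Generates `n` independent experiments, each consisting of a thrombus
#' field, a noisy confocal z-stack of it, the projection image at the
#' generative scale factor, and a measured impedance obtained by running the
#' forward conduction model at the true scale factor and perturbing it with
#' multiplicative noise. This is the ground-truth harness for validating the
#' whole pipeline: the optical route sees only the noisy stack, the
#' impedance route only the image and the noisy measurement.
#'
#' @param n number of experiments (>= 3 for downstream correlation).
#' @param seed RNG seed driving the whole cohort.
#' @param k_true generative height scale factor, um per intensity level.
#' @param carpet_range thickness range of the uniform platelet adhesion
#'   layer laid under the aggregates, micrometres (sampled per experiment).
#'   Regular adhesion covers the surface with roughly a platelet monolayer
#'   before towering aggregates form; electrically this laterally continuous
#'   layer is what couples the measured impedance tightly to the height
#'   scale, and without it the inversion is poorly conditioned.
#' @param stack_noise_sd Gaussian intensity noise on the stacks (both
#'   background and signal sd, 8-bit levels).
#' @param background_mean mean background level of the rendered stacks; use
#'   0 together with zero noise for the exactly-recoverable noiseless limit.
#' @param impedance_noise_sd multiplicative noise sd on the measured
#'   impedance (fraction).
#' @param dim stack/image grid `c(rows, cols)`, pixels.
#' @param n_thrombi_range components per experiment (sampled uniformly).
#'   The defaults, together with `base_range`, give aggregate coverage whose
#'   forward impedance rise spans roughly 10-40% over the baseline, the band
#'   the device reports for regular-to-strong aggregation.
#' @param base_range,height_range component geometry ranges (px, um).
#' @param geom,layout,model,grid forward-model context.
#' @param reduce optional function applied to each experiment's list
#'   (`stack`, `image`, `z_measured`, `truth`); when supplied only its value
#'   is kept, which avoids holding `n` full stacks in memory.
#' @return a list of `n` experiments (or reduced values) with attribute
#'   `seed`.
#' @export
make_paired_cohort <- function(n, seed = 1, k_true = 0.12,
                               carpet_range = c(0.8, 1.5),
                               stack_noise_sd = 5, impedance_noise_sd = 0.02,
                               background_mean = 8, dim = c(512, 512),
                               n_thrombi_range = c(2, 6),
                               base_range = c(80, 200), height_range = c(8, 28),
                               geom = channel_geometry(),
                               layout = electrode_layout(),
                               model = conductivity_model(),
                               grid = solver_grid(geom, layout),
                               reduce = NULL) {
  if (n < 1) abort("`n` must be >= 1")
  set.seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    field <- make_thrombus_field(
      n_thrombi = sample(seq(n_thrombi_range[1], n_thrombi_range[2]), 1),
      base_range = base_range, height_range = height_range,
      dim = dim, channel_height = geom$height
    )
    carpet <- runif(1, carpet_range[1], carpet_range[2])
    hmap <- field$height + carpet
    carpet_volume <- carpet * prod(dim(field$height)) * field$pixel_pitch^2
    stack <- render_zstack(hmap, background_mean = background_mean,
                           background_sd = stack_noise_sd,
                           signal_sd = stack_noise_sd,
                           pixel_pitch = field$pixel_pitch)
    image <- render_projection_image(hmap, k_true)
    z_true <- forward_impedance(
      build_field(image, k_true, geom, layout, model, grid,
                  pixel_pitch = field$pixel_pitch)
    )
    z_measured <- z_true * (1 + rnorm(1, 0, impedance_noise_sd))
    experiment <- list(
      stack = stack,
      image = image,
      z_measured = z_measured,
      truth = list(
        volume_analytic = field$volume + carpet_volume,
        volume_rendered = attr(stack, "truth")$volume_rendered,
        carpet_um = carpet,
        k_true = k_true,
        z_true = z_true,
        components = field$components
      )
    )
    out[[i]] <- if (is.null(reduce)) experiment else reduce(experiment)
  }
  attr(out, "seed") <- seed
  out
}
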