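# shared fixture builders (all generated in code; nothing on disk)

# two-level stack: a centered square object at `object` intensity over `bg`,
# spanning the bottom `object_planes` of `n` planes
binary_stack <- function(n = 6, side = 32, object_px = 12, object = 200L,
                         bg = 0L, object_planes = 3, delta_z = 0.5, f = 0.33) {
  planes <- array(bg, dim = c(side, side, n))
  sel <- seq_len(object_px) + (side - object_px) %/% 2
  for (i in seq_len(object_planes)) planes[sel, sel, i] <- object
  z_stack(planes, pixel_pitch = f, delta_z = delta_z)
}

# noiseless rendered square pyramid (chebyshev cone) on a dark background
pyramid_stack <- function(base_px = 60, apex_um = 20, side = 80,
                          delta_z = 0.5, f = 0.33,
                          background_mean = 0, background_sd = 0,
                          signal_sd = 0, seed = NULL) {
  h <- matrix(0, side, side)
  sel <- seq_len(base_px) + (side - base_px) %/% 2
  u <- (seq_len(base_px) - (base_px + 1) / 2) / (base_px / 2)
  h[sel, sel] <- apex_um * (1 - pmin(outer(abs(u), abs(u), pmax), 1))
  render_zstack(h, delta_z = delta_z, object_intensity = 200,
                background_mean = background_mean,
                background_sd = background_sd, signal_sd = signal_sd,
                seed = seed, pixel_pitch = f)
}

# coarse solver grid for fast conduction tests
fast_grid <- function() {
  solver_grid(voxel_xy = 20, z_edges = c(0, 2, 5, 10, 20, 40, 70, 100),
              extension = 0.5)
}

random_delta_z <- function(n = 120, seed = 1) {
  set.seed(seed)
  steps <- rnorm(n - 1, 0.1, 2)
  tibble::tibble(
    time_s = seq(0, n - 1),
    zmag_ohm = 1000 * (1 + cumsum(c(0, steps)) / 100)
  )
}
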