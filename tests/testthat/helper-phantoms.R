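# Phantom fixtures used across the suite. All stacks are generated in code;
# nothing is read from disk.

AP <- axial_pitch_um(voxel_geometry())  # physical um per axial row

# Homogeneous enamel slab: no attenuation, no specular surface boost, dark
# background. With thickness_um an exact multiple of the axial pitch the
# enamel occupies a known integer number of rows per column.
slab_phantom <- function(rows = 110, cols = 200, frames = 10,
                         thickness_um = 100 * AP, speckle_shape = 0,
                         seed = 1, surface_top_row = 5) {
  phantom_spec(rows = rows, cols = cols, frames = frames,
               layers = list(layer_spec("enamel", 0, thickness_um, 200, 0)),
               surface_top_row = surface_top_row,
               speckle_shape = speckle_shape, surface_reflection = 0,
               noise_floor = 0, seed = seed)
}

# Layered tooth phantom with an optional full-width demineralization lesion
# (reflectivity scaled over the whole visible depth, enamel locally eroded).
tooth_phantom <- function(scale = 1, erosion_um = 0, seed = 1,
                          rows = 200, cols = 40, frames = 2) {
  lesions <- if (scale < 1 || erosion_um > 0) {
    list(lesion_spec(center_lateral_px = (cols + 1) / 2, width_px = cols,
                     depth_extent_um = 1000, reflectivity_scale = scale,
                     enamel_erosion_um = erosion_um))
  } else {
    list()
  }
  phantom_spec(rows = rows, cols = cols, frames = frames, lesions = lesions,
               seed = seed)
}

# Brute-force double-loop oracles, independent of the implementation paths.
brute_count <- function(frame, row_lo, row_hi, col_lo, col_hi, lo, hi) {
  n <- 0L
  for (r in row_lo:row_hi) for (c in col_lo:col_hi) {
    if (frame[r, c] >= lo && frame[r, c] <= hi) n <- n + 1L
  }
  n
}

brute_depth_sum <- function(frame, surface_row, max_depth_um, ap) {
  s <- 0
  for (r in seq_len(nrow(frame))) {
    d <- (r - surface_row) * ap
    if (d >= 0 && d < max_depth_um) s <- s + sum(frame[r, ])
  }
  s
}
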