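test_that("a noise-free single-layer phantom equals its piecewise-constant model", {
  spec <- phantom_spec(rows = 60, cols = 30, frames = 1,
                       layers = list(layer_spec("enamel", 0, 20 * AP, 200, 0)),
                       surface_top_row = 10, speckle_shape = 0,
                       surface_reflection = 0, noise_floor = 3)
  f <- generate_bscan(spec, 1)
  for (c in c(1, 15, 30)) {
    expect_equal(f[10:29, c], rep(200, 20))        # enamel band
    expect_equal(f[1:9, c], rep(3, 9))             # air above
    expect_equal(f[30:60, c], rep(3, 31))          # below the slab
  }
})

test_that("noise-free attenuation follows the closed-form exponential decay", {
  a <- 0.01
  spec <- phantom_spec(rows = 80, cols = 5, frames = 1,
                       layers = list(layer_spec("enamel", 0, 400, 200, a)),
                       surface_top_row = 8, speckle_shape = 0,
                       surface_reflection = 0, noise_floor = 0)
  f <- generate_bscan(spec, 1)
  d <- (seq_len(80) - 8) * AP
  expected <- ifelse(d >= 0 & d < 400, floor(200 * exp(-a * d) + 0.5), 0)
  for (c in 1:5) expect_equal(f[, c], expected)
})

test_that("phantom generation is deterministic and order-independent", {
  spec <- tooth_phantom(seed = 7)
  expect_identical(generate_bscan(spec, 1), generate_bscan(spec, 1))
  # frame 2 rendered alone equals frame 2 rendered within the full stack
  alone <- generate_bscan(spec, 2)
  stacked <- generate_volume(spec)$volume
  expect_identical(get_frame(stacked, 2), alone)
  # and a different seed changes the speckle
  spec2 <- tooth_phantom(seed = 8)
  expect_false(identical(generate_bscan(spec2, 1), generate_bscan(spec, 1)))
})

test_that("slab ground truth counts voxels and volume analytically", {
  spec <- slab_phantom()  # enamel = exactly 100 rows x 200 cols x 10 frames
  gen <- generate_volume(spec)
  expect_equal(gen$truth$enamel_rows_per_column, rep(100L, 200))
  expect_equal(gen$truth$enamel_voxels_per_frame, rep(20000L, 10))
  expect_equal(gen$truth$enamel_voxels_total, 2e5)  # 100 x 200 x 10
  expect_equal(gen$truth$enamel_volume_mm3, 2e5 * 12 * 12 * 7 * 1e-9)  # 0.2016
})

test_that("surface tilt shifts per-column surface rows by the specified amount", {
  spec <- tooth_phantom()
  spec$surface_tilt_px_per_col <- 0.5
  gen <- generate_volume(spec)
  cols <- seq_len(40)
  expect_equal(gen$truth$surface_row, as.integer(20 + floor(0.5 * (cols - 1) + 0.5)))
  expect_equal(gen$truth$enamel_top_row, gen$truth$surface_row)
})

test_that("lesion erosion recedes the enamel top in lesion columns only", {
  spec <- phantom_spec(rows = 200, cols = 40, frames = 1,
                       lesions = list(lesion_spec(30, 11, 500, 0.7,
                                                  enamel_erosion_um = 5 * AP)))
  gen <- generate_volume(spec)
  lesion_cols <- 25:35
  expect_equal(gen$truth$enamel_top_row[lesion_cols], rep(25L, 11))
  expect_equal(gen$truth$enamel_top_row[1:24], rep(20L, 24))
})

test_that("layers deeper than the image are rejected", {
  expect_error(
    phantom_spec(rows = 40, cols = 10, frames = 1),
    "rows")
})

test_that("ground truth serializes to a JSON sidecar", {
  gen <- generate_volume(slab_phantom(frames = 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_truth(gen$truth, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$enamel_voxels_total, gen$truth$enamel_voxels_total)
  expect_equal(back$enamel_top_row, gen$truth$enamel_top_row)
})
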