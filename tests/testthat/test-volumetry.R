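test_that("pixel_area is the product of the lateral pitches", {
  expect_equal(pixel_area(voxel_geometry()), 144)
  expect_equal(pixel_area(voxel_geometry(1, 1, 1, 1)), 1)
  expect_equal(pixel_area(voxel_geometry(10, 7, 5, 1.5)), 70)
})

test_that("count_threshold_pixels matches its examples and the brute-force oracle", {
  expect_equal(count_threshold_pixels(matrix(0, 50, 50)), 0)
  win <- image_window(1, 20, 1, 30)
  expect_equal(count_threshold_pixels(matrix(100, 40, 40), win), 600)
  set.seed(23)
  for (k in 1:10) {
    f <- matrix(sample(0:255, 30 * 25, replace = TRUE), 30)
    w <- image_window(3, 28, 2, 24)
    th <- threshold_range(40, 200)
    expect_identical(count_threshold_pixels(f, w, th),
                     brute_count(f, 3, 28, 2, 24, 40, 200))
  }
})

test_that("threshold bounds are inclusive on both sides", {
  f <- matrix(c(44, 45, 255, 100), 2)
  expect_equal(count_threshold_pixels(f), 3)   # 45, 100, 255 qualify; 44 not
})

test_that("residual_volume applies the literal voxel-volume formula", {
  # nothing above threshold -> zero volume
  v0 <- oct_volume(array(10, dim = c(20, 20, 3)))
  expect_equal(residual_volume(v0)$volume_mm3, 0)

  # slab phantom with exactly 200000 supra-threshold voxels (100 rows x
  # 200 cols x 10 frames) -> 200000 x 1008 um^3 = 0.2016 mm^3
  gen <- generate_volume(slab_phantom())
  res <- residual_volume(gen$volume)
  expect_equal(res$total_count, gen$truth$enamel_voxels_total)
  expect_equal(res$volume_mm3, 0.2016)
  expect_equal(res$volume_mm3, gen$truth$enamel_volume_mm3)
})

test_that("residual_volume equals brute-force voxel enumeration on random stacks", {
  set.seed(29)
  for (k in 1:20) {
    v <- oct_volume(array(sample(0:255, 20 * 20 * 5, replace = TRUE),
                          dim = c(20, 20, 5)))
    w <- image_window(2, 18, 3, 19)
    th <- threshold_range(45, 255)
    res <- residual_volume(v, w, th)
    brute <- sum(vapply(1:5, function(i)
      brute_count(get_frame(v, i), 2, 18, 3, 19, 45, 255), integer(1)))
    expect_identical(res$total_count, as.numeric(brute))
    expect_equal(res$volume_mm3, brute * 1008e-9)
  }
})

test_that("volume is monotone in threshold and window", {
  set.seed(37)
  v <- oct_volume(array(sample(0:255, 30 * 30 * 4, replace = TRUE),
                        dim = c(30, 30, 4)))
  v_lo45 <- residual_volume(v, threshold = threshold_range(45, 255))$volume_mm3
  v_lo90 <- residual_volume(v, threshold = threshold_range(90, 255))$volume_mm3
  expect_lte(v_lo90, v_lo45)
  small <- residual_volume(v, image_window(5, 20, 5, 20))$volume_mm3
  large <- residual_volume(v, image_window(2, 28, 2, 28))$volume_mm3
  expect_gte(large, small)
})

test_that("volume is additive over sub-stacks", {
  set.seed(41)
  v <- oct_volume(array(sample(0:255, 15 * 15 * 6, replace = TRUE),
                        dim = c(15, 15, 6)))
  full <- residual_volume(v)$volume_mm3
  head <- residual_volume(oct_volume(v$data[, , 1:3]))$volume_mm3
  tail <- residual_volume(oct_volume(v$data[, , 4:6]))$volume_mm3
  expect_equal(head + tail, full)
})

test_that("phantom volume is recovered exactly noise-free and within 5% with speckle", {
  clean <- generate_volume(slab_phantom(frames = 3))
  expect_equal(residual_volume(clean$volume)$volume_mm3,
               clean$truth$enamel_volume_mm3)
  rel_err <- vapply(1:20, function(s) {
    gen <- generate_volume(slab_phantom(frames = 3, speckle_shape = 8, seed = s))
    res <- residual_volume(gen$volume)
    abs(res$volume_mm3 - gen$truth$enamel_volume_mm3) / gen$truth$enamel_volume_mm3
  }, numeric(1))
  expect_lt(max(rel_err), 0.05)
})

test_that("degenerate volumetry inputs are rejected", {
  expect_error(threshold_range(-1, 100), "0 <= lo")
  expect_error(threshold_range(100, 45), "0 <= lo")
  expect_error(image_window(5, 4, 1, 10), "non-empty")
  v <- oct_volume(array(0, dim = c(10, 10, 2)))
  expect_error(residual_volume(v, image_window(1, 11, 1, 10)), "exceeds")
})
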