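test_that("detect_peak_index finds the global maximum, ties to the shallowest row", {
  expect_equal(detect_peak_index(c(0, 3, 9, 2)), 3L)
  expect_equal(as.integer(detect_peak_index(c(5, 9, 9, 1))), 2L)
  zero <- detect_peak_index(rep(0, 6))
  expect_equal(as.integer(zero), 1L)
  expect_true(attr(zero, "degenerate"))
})

test_that("detect_peak_index agrees with a brute-force scan on 1000 random columns", {
  set.seed(3)
  for (i in 1:1000) {
    col <- sample(0:255, 40, replace = TRUE)
    best <- 1L
    for (r in 2:40) if (col[r] > col[best]) best <- r   # strict > keeps first tie
    expect_identical(as.integer(detect_peak_index(col)), best)
  }
})

spike_column <- function(n, peak_row, peak = 9, base = 1) {
  x <- rep(base, n); x[peak_row] <- peak; x
}

test_that("flatten_window aligns every peak on the lower-median reference", {
  w <- ascan_window(cbind(spike_column(60, 38), spike_column(60, 40),
                          spike_column(60, 44)), 1, 3)
  fl <- flatten_window(w)
  expect_equal(fl$shifts, c(2L, 0L, -4L))
  expect_equal(fl$ref_index, 40L)
  for (j in 1:3) expect_equal(which.max(fl$data[, j]), 40L)
  # vacated samples are zero-filled
  expect_equal(fl$data[1:2, 1], c(0, 0))
})

test_that("flattening an already-flat window is the identity, and flatten is idempotent", {
  flat <- ascan_window(sapply(1:5, function(j) spike_column(30, 12, 9 + j)), 1, 5)
  out <- flatten_window(flat)
  expect_equal(out$data, flat$data)
  expect_equal(out$shifts, rep(0L, 5))

  set.seed(21)
  w <- ascan_window(matrix(sample(0:255, 50 * 15, replace = TRUE), 50), 1, 15)
  once <- flatten_window(w)
  expect_identical(flatten_window(once)$data, once$data)
})

test_that("averaged_profile reproduces hand-computed means after flattening", {
  # W identical columns: profile is the column over its maximum
  col <- c(1, 4, 8, 2)
  w <- ascan_window(cbind(col, col, col), 1, 3)
  p <- averaged_profile(w)
  expect_equal(p$values, col / 8)
  expect_equal(p$peak_index, 3L)

  # two columns peaking at rows 3 and 2: the first shifts up by one
  # (lower median of {3, 2} is 2), giving means (1, 5, 2) -> /5
  w2 <- ascan_window(cbind(c(0, 2, 4), c(0, 6, 4)), 1, 2)
  p2 <- averaged_profile(w2)
  expect_equal(p2$values, c(1, 5, 2) / 5)
  expect_equal(p2$depth_um, (0:2) * AP)
})

test_that("every non-degenerate profile is normalized to maximum 1", {
  for (seed in 1:10) {
    f <- generate_bscan(tooth_phantom(seed = seed), 1)
    p <- averaged_profile(ascan_window(f, 5, 15))
    expect_equal(max(p$values), 1)
  }
  expect_warning(p0 <- averaged_profile(ascan_window(matrix(0, 20, 15), 1, 15)),
                 "all-zero")
  expect_true(all(p0$values == 0))
})

test_that("axially shifting all columns leaves the profile unchanged except k edge samples", {
  set.seed(31)
  k <- 3L
  n <- 60L
  m <- matrix(sample(0:255, n * 15, replace = TRUE), n)
  m[55:60, ] <- 0                       # quiet tail so the shift cannot clip the peak
  shifted <- apply(m, 2, function(col) c(numeric(k), col[1:(n - k)]))
  p0 <- averaged_profile(ascan_window(m, 1, 15))
  p1 <- averaged_profile(ascan_window(shifted, 1, 15))
  expect_equal(p1$values[(k + 1):n], p0$values[1:(n - k)])
})

test_that("profile surface peak tracks the phantom surface over 50 seeds", {
  errs <- vapply(1:50, function(s) {
    spec <- tooth_phantom(seed = s, cols = 20, frames = 1)
    p <- averaged_profile(ascan_window(generate_bscan(spec, 1), 3, 15))
    p$peak_index - 20L                  # ground-truth surface row
  }, integer(1))
  expect_lte(stats::median(abs(errs)), 1)
  expect_lte(max(abs(errs)), 4)
})

test_that("noise-free phantom thickness is recovered within one axial pixel", {
  spec <- phantom_spec(rows = 200, cols = 40, frames = 1, speckle_shape = 0)
  p <- averaged_profile(ascan_window(generate_bscan(spec, 1), 5, 15))
  t <- estimate_enamel_thickness(p)
  expect_lte(abs(t$thickness_um - 250), AP)
  expect_equal(t$surface_index, 20L)
})

test_that("a profile without a secondary peak yields NA thickness and a diagnostic", {
  spec <- slab_phantom(rows = 200, cols = 40, frames = 1, thickness_um = 250)
  p <- averaged_profile(ascan_window(generate_bscan(spec, 1), 5, 15))
  t <- estimate_enamel_thickness(p)
  expect_true(is.na(t$thickness_um))
  expect_match(t$diagnostic, "junction")
})

test_that("a profile below the detectability floor is flagged", {
  dim_profile <- averaged_profile(ascan_window(matrix(3, 30, 15), 1, 15))
  t <- estimate_enamel_thickness(dim_profile)
  expect_true(is.na(t$thickness_um))
  expect_match(t$diagnostic, "floor")
})

test_that("percent_reduction reproduces the published worked examples", {
  expect_equal(percent_reduction(100.20, 255.45), 60.8)
  expect_equal(percent_reduction(255.45, 255.45), 0)
  expect_equal(percent_reduction(180.36, 255.45), 29.4)
  expect_equal(percent_reduction(140.28, 255.45), 45.1)
  expect_equal(percent_reduction(150.30, 255.45), 41.2)  # published as 41.1 (truncation)
  expect_error(percent_reduction(100, 0), "> 0")
})
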