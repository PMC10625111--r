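test_that("a pure tilted plane flattens to zero exactly", {
  hm <- sim_height_map(64, 64, step_height = 0,
                       patch_mask = matrix(FALSE, 64, 64),
                       tilt_per_row = 2e-9 / 64, tilt_per_col = 1e-9 / 64)
  flat <- flatten_height_map(hm)
  expect_lt(max(abs(flat$heights)), 1e-21)   # < 1e-12 nm
})

test_that("flattening preserves a patch on a tilted background", {
  truth_mask <- matrix(FALSE, 64, 64)
  truth_mask[, 20:45] <- TRUE                 # 40% of every line
  hm <- sim_height_map(64, 64, step_height = 6.2e-9,
                       patch_mask = truth_mask,
                       tilt_per_row = 2e-9 / 64, tilt_per_col = 2e-9 / 64)
  flat <- flatten_height_map(hm)
  expect_lt(max(abs(flat$heights[!truth_mask])), 0.05e-9)
  expect_lt(max(abs(flat$heights[truth_mask] - 6.2e-9)), 0.05e-9)
})

test_that("a line almost fully covered by patch starves the fit with a warning", {
  # 13 of 16 pixels sit 50 nm above the 3 substrate pixels: the first
  # rejection pass removes the whole patch and leaves < 4 pixels
  h <- matrix(0, 16, 16)
  h[5, c(2:7, 9:15)] <- 50e-9
  expect_warning(flatten_height_map(height_map(h)), "starved")
})

test_that("flattening an already-flat map is idempotent", {
  hm <- sim_height_map(64, 64, step_height = 6.2e-9, patch_coverage = 0.4,
                       tilt_per_row = 2e-9 / 64, roughness_sd = 0.1e-9,
                       seed = 9)
  f1 <- flatten_height_map(hm)
  f2 <- flatten_height_map(f1)
  rms <- sqrt(mean((f2$heights - f1$heights)^2))
  expect_lt(rms, 1e-12)   # < 1e-3 nm
})

test_that("moving-average smoothing has the stated kernel arithmetic", {
  const <- height_map(matrix(3e-9, 32, 32))
  expect_equal(smooth_height_map(const)$heights, const$heights,
               tolerance = 1e-15)
  imp <- matrix(0, 40, 40)
  imp[20, 20] <- 1e-9
  sm <- smooth_height_map(height_map(imp))
  # interior pixels covered by the impulse window hold h/100
  expect_equal(sm$heights[18, 18], 1e-11, tolerance = 1e-10)
  expect_equal(sm$heights[24, 24], 1e-11, tolerance = 1e-10)
  expect_equal(sm$heights[20, 30], 0)
  set.seed(31)
  noise <- height_map(matrix(rnorm(200 * 200, sd = 1e-9), 200, 200))
  smn <- smooth_height_map(noise)
  inner <- smn$heights[20:180, 20:180]
  expect_lt(abs(sd(inner) / 1e-10 - 1), 0.2)   # SD ~ s/10
  expect_error(smooth_height_map(height_map(matrix(0, 16, 16)),
                                 window = 20), "window")
})

test_that("two-level noiseless map yields the exact step height", {
  mask <- matrix(FALSE, 32, 32)
  mask[10:20, 10:20] <- TRUE
  hm <- sim_height_map(32, 32, step_height = 6.2e-9, patch_mask = mask)
  res <- patch_thickness(hm)
  expect_equal(res$thickness, 6.2e-9, tolerance = 1e-15)
  expect_equal(res$substrate_peak, 0, tolerance = 1e-15)
  expect_equal(res$n_pixels_patch, sum(mask))
})

test_that("thickness is invariant to a constant height offset", {
  hm <- sim_height_map(64, 64, step_height = 6.2e-9, patch_coverage = 0.4,
                       roughness_sd = 0.1e-9, seed = 17)
  r1 <- patch_thickness(hm)
  hm2 <- height_map(hm$heights + 5e-9, pixel_size = hm$pixel_size)
  r2 <- patch_thickness(hm2)
  expect_equal(r2$thickness, r1$thickness, tolerance = 1e-12)
  expect_equal(r2$substrate_peak - r1$substrate_peak, 5e-9,
               tolerance = 1e-11)
})

test_that("degenerate histograms are reported, not guessed", {
  flat <- height_map(matrix(rnorm(32 * 32, sd = 0.05e-9), 32, 32))
  expect_error(patch_thickness(flat), "peaks")
  # three levels with two comparable upper peaks -> ambiguous
  h <- matrix(0, 32, 32)
  h[1:10, ] <- 4e-9
  h[11:20, ] <- 8e-9
  expect_error(patch_thickness(height_map(h)), "ambiguous")
  expect_error(patch_thickness(height_map(matrix(0:1, 32, 32) * 6e-9),
                               crop = c(1, 40, 1, 4)), "crop")
})

test_that("full pipeline recovers the patch height on tilted noisy maps", {
  hm <- sim_height_map(256, 256, step_height = 6.2e-9,
                       patch_coverage = 0.4,
                       tilt_per_row = 2e-9 / 256, tilt_per_col = 1e-9 / 256,
                       roughness_sd = 0.1e-9, seed = 4)
  res <- patch_thickness(smooth_height_map(flatten_height_map(hm)))
  expect_lt(abs(res$thickness - 6.2e-9), 0.1e-9)
})
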