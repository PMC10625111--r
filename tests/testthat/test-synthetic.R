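test_that("all generators are bit-reproducible under a fixed seed", {
  kappa <- 20 * kT296
  a <- sim_flicker_contours(kappa, 1e-8, 15e-6, n_frames = 5, seed = 11)
  b <- sim_flicker_contours(kappa, 1e-8, 15e-6, n_frames = 5, seed = 11)
  expect_identical(a$radii, b$radii)
  c1 <- sim_aspect_trace(0.5, noise_sd = 0.01, seed = 4)
  c2 <- sim_aspect_trace(0.5, noise_sd = 0.01, seed = 4)
  expect_identical(c1$aspect, c2$aspect)
  s1 <- sim_frequency_sweep(0.43e-2, 42.7e-4, 82.1e-4, 5e-6,
                            ar_noise_sd = 0.02, seed = 9)
  s2 <- sim_frequency_sweep(0.43e-2, 42.7e-4, 82.1e-4, 5e-6,
                            ar_noise_sd = 0.02, seed = 9)
  expect_identical(s1$aspect, s2$aspect)
  h1 <- sim_height_map(32, 32, roughness_sd = 0.1e-9, seed = 2)
  h2 <- sim_height_map(32, 32, roughness_sd = 0.1e-9, seed = 2)
  expect_identical(h1$heights, h2$heights)
  p1 <- sim_tension_area(noise_frac = 0.03, seed = 6)
  p2 <- sim_tension_area(noise_frac = 0.03, seed = 6)
  expect_identical(p1$tension, p2$tension)
  # and the RNG stream is independent of the global state
  expect_identical(sim_height_map(32, 32, roughness_sd = 1e-10,
                                  seed = 2)$heights, h1$heights)
})

test_that("flicker generator matches the Helfrich spectrum it advertises", {
  kappa <- 20 * kT296
  R <- 15e-6
  sigma <- 10 * kappa / R^2             # reduced tension 10
  ct <- sim_flicker_contours(kappa, sigma, R, n_frames = 3000, seed = 42)
  expect_lt(abs(mean(ct$radii) - R) / R, 0.01)
  sp <- compute_spectrum(ct)
  V5 <- helfrich_mode_variance(5L, kappa, 10, l_max = 508)
  expect_lt(abs(sp$msa[sp$modes == 5] - V5) / V5, 0.05)
  # every reported mode within 3 standard errors of the model
  Vm <- helfrich_mode_variance(sp$modes, kappa, 10, l_max = 508)
  expect_lt(max(abs(sp$msa - Vm) / sp$msa_se), 3.5)
})

test_that("flicker generator degenerates to circles at very high tension", {
  ct <- sim_flicker_contours(20 * kT296, 1, 15e-6, n_frames = 50, seed = 1)
  expect_lt(max(abs(ct$radii - 15e-6)) / 15e-6, 1e-3)
})

test_that("flicker generator rejects invalid truths", {
  expect_error(sim_flicker_contours(-1e-19, 1e-8, 15e-6), "kappa")
  expect_error(sim_flicker_contours(1e-19, 1e-8, 15e-6, n_points = 100),
               "power of two")
  expect_error(sim_flicker_contours(1e-19, 1e-8, -15e-6), "radius")
})

test_that("noiseless aspect trace is the exact exponential", {
  tau <- 0.525
  tr <- sim_aspect_trace(tau, baseline = 1.1, amplitude = 0.2,
                         frame_rate = 100, duration = 5)
  expect_equal(tr$aspect, 1.3 - 0.2 * exp(-tr$time / tau), tolerance = 1e-12)
  fit <- fit_relaxation(tr, "UV")
  expect_lt(abs(fit$tau - tau) / tau, 1e-6)
})

test_that("trace generator handles schedules, flat traces and bad epochs", {
  tr <- sim_aspect_trace(0.3, amplitude = 0,
                         epochs = data.frame(start = 0, label = "UV"))
  expect_equal(var(tr$aspect), 0)
  sched <- data.frame(start = c(0, 2, 4), label = c("dark", "UV", "blue"))
  tr2 <- sim_aspect_trace(0.3, duration = 6, epochs = sched)
  ep <- segment_epochs(tr2)
  expect_equal(ep$label, sched$label)
  expect_equal(ep$start, sched$start)
  expect_error(sim_aspect_trace(0.3, epochs = data.frame(
    start = c(2, 1), label = c("UV", "blue"))), "ordered")
  expect_error(sim_aspect_trace(0.3, epochs = data.frame(
    start = 0, label = "green")), "labels")
  expect_error(sim_aspect_trace(-1), "tau")
})

test_that("sweep generator crosses 1 exactly at the model frequency", {
  li <- 42.70e-4
  sw <- sim_frequency_sweep(0.43e-2, li, li / 0.52, 6e-6)
  fc_model <- critical_frequency_model(6e-6, 0.43e-2, li, 0.52)
  expect_lt(abs(detect_critical_frequency(sw) - fc_model) / fc_model, 0.005)
  expect_equal(attr(sw, "truth")$fc, fc_model)
  expect_error(sim_frequency_sweep(0.43e-2, li, li, 6e-6), "ratio")
  expect_error(sim_frequency_sweep(0.43e-2, li, li / 0.5, 6e-6,
                                   frequencies = c(2, 1)), "increasing")
})

test_that("height-map generator builds tilt + step + roughness as stated", {
  hm <- sim_height_map(32, 32, step_height = 6.2e-9,
                       tilt_per_row = 1e-11, tilt_per_col = 2e-11)
  truth <- attr(hm, "truth")
  r <- 10; co <- 20
  expect_equal(hm$heights[r, co],
               (r - 1) * 1e-11 + (co - 1) * 2e-11 +
                 6.2e-9 * truth$mask[r, co])
  expect_error(sim_height_map(32, 32, patch_coverage = 0.9), "80%")
  expect_error(sim_height_map(8, 8), "16 x 16")
  expect_error(sim_height_map(32, 32, step_height = -1e-9), "step_height")
})

test_that("no-patch map makes the thickness pipeline report no patch", {
  hm <- sim_height_map(64, 64, step_height = 0, roughness_sd = 0.05e-9,
                       patch_mask = matrix(FALSE, 64, 64), seed = 3)
  sm <- smooth_height_map(flatten_height_map(hm))
  expect_error(patch_thickness(sm), "peaks")
})
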