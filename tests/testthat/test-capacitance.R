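test_that("critical frequency closed form and scaling laws", {
  # frozen from high-precision evaluation of the closed form
  expect_equal(critical_frequency_model(10e-6, 0.43e-2, 42.70e-4, 0.52),
               12158.706, tolerance = 1e-6)
  f1 <- critical_frequency_model(5e-6, 0.5e-2, 4e-3, 0.5)
  f2 <- critical_frequency_model(10e-6, 0.5e-2, 4e-3, 0.5)
  expect_equal(f1 / f2, 2, tolerance = 1e-12)
  # divergence as the conductivity ratio approaches 1
  ratios <- c(0.9, 0.99, 0.999, 0.9999)
  fcs <- critical_frequency_model(5e-6, 0.5e-2, 4e-3, ratios)
  expect_true(all(diff(fcs) > 0))
  expect_gt(fcs[4L] / fcs[1L], 10)
  expect_error(critical_frequency_model(5e-6, 0.5e-2, 4e-3, 1.2), "ratio")
})

test_that("crossing detection interpolates in log frequency", {
  sw <- data.frame(frequency = c(4000, 8000, 10000, 20000),
                   aspect = c(1.3, 1.05, 0.95, 0.7))
  class(sw) <- c("frequency_sweep", "data.frame")
  expect_equal(detect_critical_frequency(sw), sqrt(8000 * 10000),
               tolerance = 1e-9)
  allpro <- data.frame(frequency = c(1e3, 1e4, 1e5),
                       aspect = c(1.4, 1.3, 1.2))
  expect_error(detect_critical_frequency(allpro), "no transition")
  wob <- data.frame(frequency = 10^seq(3, 4.4, length.out = 8),
                    aspect = c(1.2, 1.1, 0.9, 0.85, 1.1, 1.15, 0.8, 0.7))
  class(wob) <- c("frequency_sweep", "data.frame")
  expect_warning(fc <- detect_critical_frequency(wob), "multiple crossings")
  expect_lt(fc, 10^3.6)   # the lowest-frequency crossing is reported
})

test_that("capacitance slope fit inverts the forward model exactly", {
  li <- 42.70e-4
  ratio <- 0.52
  cm <- 0.43e-2
  radii <- seq(3e-6, 10e-6, length.out = 10)
  pts <- data.frame(radius = radii,
                    fc = critical_frequency_model(radii, cm, li, ratio))
  fit <- fit_specific_capacitance(pts, li, ratio)
  expect_equal(fit$cm, cm, tolerance = 1e-10)
  expect_error(fit_specific_capacitance(pts[1:2, ], li, ratio),
               "insufficient")
  bad <- data.frame(radius = radii, fc = rev(pts$fc))
  expect_error(fit_specific_capacitance(bad, li, ratio), "slope")
})

test_that("Debye lengths reproduce the experimental solution values", {
  expect_equal(debye_length(0.3) * 1e9, 17.5, tolerance = 0.02)
  expect_equal(debye_length(0.6) * 1e9, 12.4, tolerance = 0.02)
  expect_equal(debye_length(0.4) / debye_length(1.6), 2, tolerance = 1e-12)
  expect_error(debye_length(-1), "concentration")
})

test_that("double-layer capacitances match the printed estimates", {
  expect_equal(double_layer_capacitance(17.5e-9) * 1e2, 4.05,
               tolerance = 0.01)
  expect_equal(double_layer_capacitance(12.4e-9) * 1e2, 5.715,
               tolerance = 0.01)
  expect_equal(double_layer_capacitance(2e-9) /
                 double_layer_capacitance(4e-9), 2, tolerance = 1e-12)
})

test_that("series-capacitor inversion and its precondition", {
  expect_equal(bare_bilayer_capacitance(0.43e-2, 4.05e-2, 5.72e-2) * 1e2,
               0.52525, tolerance = 1e-4)
  # infinite double layers: bare capacitance equals the measured one
  expect_equal(bare_bilayer_capacitance(0.43e-2, 1e6, 1e6), 0.43e-2,
               tolerance = 1e-6)
  expect_error(bare_bilayer_capacitance(5e-2, 4.05e-2, 5.72e-2),
               "double layers dominate")
})

test_that("dielectric constants of the full chain match the study values", {
  trans <- capacitance_set(0.52e-2, 4.05e-2, 5.72e-2, 6.2e-9)
  expect_equal(trans$eps_membrane, 4.62, tolerance = 0.05)
  popc <- capacitance_set(0.43e-2, 4.05e-2, 5.72e-2, 4.7e-9)
  expect_equal(popc$eps_membrane, 2.86, tolerance = 0.05)
  # identity case
  eps0 <- physical_constants()$eps0
  expect_equal(dielectric_constant(eps0 / 5e-9, 5e-9), 1, tolerance = 1e-12)
  # series identity holds after construction
  expect_equal(1 / trans$cm,
               1 / trans$cb + 1 / trans$cd_in + 1 / trans$cd_out,
               tolerance = 1e-12)
})

test_that("laboratory unit conversions are the expected factors", {
  # 1 uF/cm^2 = 1e-2 F/m^2 ; 1 uS/cm = 1e-4 S/m
  expect_equal(0.43e-6 / 1e-4, 0.43e-2)
  expect_equal(42.70e-6 / 1e-2, 42.70e-4)
  # and the worked chain uses them consistently
  expect_equal(critical_frequency_model(10e-6, 0.43 * 1e-2, 42.70 * 1e-4,
                                        0.52),
               critical_frequency_model(10e-6, 0.43e-2, 42.70e-4, 0.52))
})

test_that("round trip: forward model -> sweeps -> detection -> fitted Cm", {
  li <- 42.70e-4
  ratio <- 0.52
  cm <- 0.52e-2
  radii <- seq(3e-6, 10e-6, length.out = 10)
  pts <- do.call(rbind, lapply(radii, function(R) {
    sw <- sim_frequency_sweep(cm, li, li / ratio, R)
    data.frame(radius = R, fc = detect_critical_frequency(sw))
  }))
  fit <- fit_specific_capacitance(pts, li, ratio)
  expect_lt(abs(fit$cm - cm) / cm, 0.005)
})
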