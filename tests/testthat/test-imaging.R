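test_that("a rendered circle is radially symmetric about the centre", {
  ctr <- vesicle_contour(rep(10e-6, 128))
  img <- render_vesicle_image(ctr, pixel_size = 0.25e-6,
                              shape = c(128, 128), center = c(64.5, 64.5))
  px <- img$pixels
  # 90 degree rotation about the centre maps the image onto itself
  rot <- t(px[, rev(seq_len(128))])
  expect_equal(px, rot, tolerance = 1e-9)
})

test_that("render -> detect round trip on an ellipse is subpixel accurate", {
  ps <- 0.25e-6
  ctr <- vesicle_contour(ellipse_radii(10e-6, 8e-6))
  img <- render_vesicle_image(ctr, pixel_size = ps, shape = c(128, 128))
  det <- detect_contour(img, 256)
  rms_px <- sqrt(mean((det$radii - ctr$radii)^2)) / ps
  expect_lt(rms_px, 0.2)
  ar <- max(det$radii) / min(det$radii)
  expect_lt(abs(ar - 10 / 8) / (10 / 8), 0.005)
})

test_that("a rotated ellipse keeps its aspect ratio", {
  phi <- 2 * pi * (0:255) / 256
  a <- 10e-6; b <- 8e-6; rot <- pi / 5
  radii <- a * b / sqrt((b * cos(phi - rot))^2 + (a * sin(phi - rot))^2)
  img <- render_vesicle_image(vesicle_contour(radii), pixel_size = 0.25e-6,
                              shape = c(128, 128))
  det <- detect_contour(img, 256)
  ar <- max(det$radii) / min(det$radii)
  expect_lt(abs(ar - a / b) / (a / b), 0.005)
})

test_that("noisy circle detection recovers the mean radius", {
  ctr <- vesicle_contour(rep(15e-6, 128))
  img <- render_vesicle_image(ctr, pixel_size = 0.3e-6, shape = c(128, 128),
                              contrast = 0.8, noise_sd = 0.016, seed = 2)
  det <- detect_contour(img, 256)
  expect_lt(abs(mean(det$radii) - 15e-6) / 0.3e-6, 0.1)
})

test_that("detection is invariant to intensity scaling and fails on flat images", {
  ctr <- vesicle_contour(rep(12e-6, 128))
  img <- render_vesicle_image(ctr, pixel_size = 0.3e-6, shape = c(128, 128))
  d1 <- detect_contour(img, 128)
  img2 <- img
  img2$pixels <- img$pixels * 7.3 + 0.1
  d2 <- detect_contour(img2, 128)
  expect_equal(d1$radii, d2$radii, tolerance = 1e-12)
  flat <- img
  flat$pixels <- matrix(0.5, 128, 128)
  expect_error(detect_contour(flat), "no edge found")
  zero <- render_vesicle_image(ctr, pixel_size = 0.3e-6,
                               shape = c(128, 128), contrast = 0)
  expect_error(detect_contour(zero), "no edge found")
})

test_that("rotating the image rotates the detected contour", {
  ctr <- vesicle_contour(ellipse_radii(10e-6, 7e-6, 128))
  img <- render_vesicle_image(ctr, pixel_size = 0.25e-6,
                              shape = c(129, 129), center = c(65, 65))
  n <- 128L
  d0 <- detect_contour(img, n)
  rot <- img
  # counterclockwise quarter turn of the pixel grid
  rot$pixels <- t(img$pixels[, rev(seq_len(129))])
  d90 <- detect_contour(rot, n)
  shift <- n / 4L
  expect_equal(d90$radii[(seq_len(n) - 1L + shift) %% n + 1L], d0$radii,
               tolerance = 0.02)
})

test_that("two rings are ambiguous without a centre hint", {
  ps <- 0.4e-6
  # concentric rings: every ray sees two comparable minima
  inner <- render_vesicle_image(vesicle_contour(rep(5e-6, 128)),
                                pixel_size = ps, shape = c(128, 128))
  outer <- render_vesicle_image(vesicle_contour(rep(14e-6, 128)),
                                pixel_size = ps, shape = c(128, 128))
  conc <- inner
  conc$pixels <- pmin(inner$pixels, outer$pixels)
  expect_error(detect_contour(conc, 128), "ambiguous")
  # two separated vesicles: a hint picks the intended one
  c1 <- vesicle_contour(rep(8e-6, 128))
  i1 <- render_vesicle_image(c1, pixel_size = ps, shape = c(96, 192),
                             center = c(48, 48))
  i2 <- render_vesicle_image(c1, pixel_size = ps, shape = c(96, 192),
                             center = c(48, 144))
  both <- i1
  both$pixels <- pmin(i1$pixels, i2$pixels)
  expect_error(detect_contour(both, 128), "ambiguous|open contour|no edge")
  hinted <- detect_contour(both, 128, center_hint = c(48, 48))
  expect_lt(abs(mean(hinted$radii) - 8e-6) / ps, 0.5)
})

test_that("rendering rejects contours that leave the frame", {
  big <- vesicle_contour(rep(30e-6, 64))
  expect_error(render_vesicle_image(big, pixel_size = 0.25e-6,
                                    shape = c(128, 128)), "frame")
})

test_that("TIFF round trip preserves the image within quantization", {
  ctr <- vesicle_contour(rep(10e-6, 64))
  img <- render_vesicle_image(ctr, pixel_size = 0.3e-6, shape = c(96, 96))
  path <- tempfile(fileext = ".tif")
  write_image_tiff(img, path)
  back <- read_image_tiff(path, pixel_size = 0.3e-6)
  expect_equal(dim(back$pixels), c(96, 96))
  expect_lt(max(abs(back$pixels - img$pixels)), 1 / 65535 + 1e-6)
  det <- detect_contour(back)
  expect_lt(abs(mean(det$radii) - 10e-6) / 0.3e-6, 0.1)
})
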