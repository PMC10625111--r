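#' Simulate equatorial contours of a fluctuating quasi-spherical vesicle
#'
#' Forward model of the flicker analysis: for every frame the complex
#' Fourier mode amplitudes \eqn{u_q} (modes `2 .. n_points/2 - 1`) are drawn
#' as independent zero-mean complex Gaussians whose variances equal the
#' Helfrich spectrum of [helfrich_mode_variance()] at the requested rigidity
#' and tension; the contour radii are then \eqn{r(\phi_j) = R(1 + u(\phi_j))}
#' plus optional radial pixel noise. Mode amplitudes are independent between
#' frames: the estimator uses only per-mode variances, so temporal
#' correlations are deliberately not modelled.
#'
#' @param kappa Bending rigidity (J).
#' @param sigma Membrane tension (N/m).
#' @param radius Mean vesicle radius (m).
#' @param temperature Temperature (K), default 296 (room temperature, 23 C).
#' @param n_frames Number of frames; experimental sequences use 3000.
#' @param n_points Contour samples per frame; must be a power of two
#'   (>= 64) so spectra come from radix-2 transforms.
#' @param pixel_noise Radial detection noise SD (m), added after synthesis.
#' @param seed Integer seed; the global RNG state is restored afterwards.
#' @return A `vesicle_contours` object: list with `radii`
#'   (`n_frames x n_points` matrix, m), `angles` (rad), `radius`,
#'   `temperature` and the generating `truth`.
#' @export
#' @examples
#' ct <- sim_flicker_contours(kappa = 20 * 1.380649e-23 * 296, sigma = 1e-8,
#'                            radius = 15e-6, n_frames = 200, seed = 1)
#' sp <- compute_spectrum(ct)
sim_flicker_contours <- function(kappa, sigma, radius, temperature = 296,
                                 n_frames = 3000, n_points = 256,
                                 pixel_noise = 0, seed = NULL) {
  if (kappa <= 0) stop2("kappa must be > 0")
  if (radius <= 0) stop2("radius must be > 0")
  if (n_frames < 1) stop2("n_frames must be >= 1")
  if (n_points < 64 || !is_power_of_two(n_points))
    stop2("n_points must be a power of two >= 64")
  sigma_bar <- sigma * radius^2 / kappa
  q <- 2:(n_points %/% 2L - 1L)
  V <- helfrich_mode_variance(q, kappa, sigma_bar, temperature)
  with_seed(seed, {
    nq <- length(q)
    re <- matrix(rnorm(n_frames * nq, sd = rep(sqrt(V / 2), each = n_frames)),
                 n_frames, nq)
    im <- matrix(rnorm(n_frames * nq, sd = rep(sqrt(V / 2), each = n_frames)),
                 n_frames, nq)
    spec <- matrix(0 + 0i, n_points, n_frames)
    spec[q + 1L, ] <- t(re + 1i * im)
    spec[n_points - q + 1L, ] <- t(re - 1i * im)
    u <- Re(mvfft(spec, inverse = TRUE))        # n_points x n_frames
    radii <- radius * (1 + t(u))
    if (pixel_noise > 0)
      radii <- radii + matrix(rnorm(length(radii), sd = pixel_noise),
                              nrow = n_frames)
    structure(list(
      radii = radii,
      angles = 2 * pi * (seq_len(n_points) - 1L) / n_points,
      radius = radius, temperature = temperature,
      truth = list(kappa = kappa, sigma = sigma, sigma_bar = sigma_bar,
                   pixel_noise = pixel_noise, seed = seed)
    ), class = "vesicle_contours")
  })
}

#' @export
print.vesicle_contours <- function(x, ...) {
  cat(sprintf("Vesicle contour stack: %d frames x %d points, R = %.1f um\n",
              nrow(x$radii), ncol(x$radii), x$radius * 1e6))
  invisible(x)
}

#' Simulate an aspect-ratio trace under an illumination schedule
#'
#' Generates the aspect ratio a/b of an electrodeformed vesicle responding to
#' stepwise illumination. During a `"dark"` epoch the mean trace sits at
#' `baseline`; a `"UV"` epoch relaxes exponentially from the epoch-start
#' value towards `baseline + amplitude` (photo-induced area increase pulls
#' the prolate further out); a `"blue"` epoch relaxes back towards
#' `baseline`. All relaxations share the time constant `tau`. Gaussian noise
#' of SD `noise_sd` is added per frame.
#'
#' @param tau Relaxation time constant (s).
#' @param baseline Dark-state aspect ratio.
#' @param amplitude Aspect-ratio change at full photoconversion.
#' @param frame_rate Frames per second.
#' @param duration Total trace duration (s).
#' @param noise_sd Per-frame Gaussian noise SD (dimensionless).
#' @param epochs Data frame with columns `start` (s) and `label`
#'   (`"dark"`, `"UV"`, `"blue"`), ordered and non-overlapping; each epoch
#'   runs until the next start (the last until `duration`).
#' @param seed Integer seed.
#' @return An `aspect_trace` object: data frame with columns `time`,
#'   `aspect`, `illumination`, `field_on` plus a `truth` attribute.
#' @export
sim_aspect_trace <- function(tau, baseline = 1.1, amplitude = 0.2,
                             frame_rate = 100, duration = 5,
                             noise_sd = 0,
                             epochs = data.frame(start = 0, label = "UV"),
                             seed = NULL) {
  if (tau <= 0) stop2("tau must be > 0")
  if (frame_rate <= 0) stop2("frame_rate must be > 0")
  if (!all(epochs$label %in% c("dark", "UV", "blue")))
    stop2("illumination labels must be in {dark, UV, blue}")
  if (is.unsorted(epochs$start, strictly = TRUE))
    stop2("epochs must be ordered in time and non-overlapping")
  t <- seq(0, duration, by = 1 / frame_rate)
  t <- t[t < duration | seq_along(t) == 1L]
  ends <- c(epochs$start[-1L], Inf)
  labels <- rep("dark", length(t))
  mean_tr <- rep(baseline, length(t))
  level <- baseline    # value at the start of the current epoch
  for (k in seq_len(nrow(epochs))) {
    in_ep <- t >= epochs$start[k] & t < ends[k]
    if (!any(in_ep)) next
    lab <- epochs$label[k]
    labels[in_ep] <- lab
    target <- switch(lab, dark = level, UV = baseline + amplitude,
                     blue = baseline)
    mean_tr[in_ep] <- target + (level - target) *
      exp(-(t[in_ep] - epochs$start[k]) / tau)
    level <- target + (level - target) * exp(-(ends[k] - epochs$start[k]) / tau)
    if (!is.finite(level)) level <- target
  }
  aspect <- with_seed(seed, mean_tr +
                        if (noise_sd > 0) rnorm(length(t), sd = noise_sd) else 0)
  out <- data.frame(time = t, aspect = aspect, illumination = labels,
                    field_on = TRUE)
  attr(out, "truth") <- list(tau = tau, baseline = baseline,
                             amplitude = amplitude, noise_sd = noise_sd,
                             seed = seed)
  class(out) <- c("aspect_trace", "data.frame")
  out
}

#' Simulate a frequency sweep of an electrodeformed vesicle
#'
#' Aspect ratio versus AC field frequency for a vesicle with conductivity
#' ratio \eqn{\Lambda < 1}: prolate (a/b > 1) at low frequency, decreasing
#' smoothly through the sphere (a/b = 1) exactly at the critical frequency of
#' [critical_frequency_model()], oblate beyond. The shape of the transition
#' is a tanh profile in log-frequency with amplitude `transition_amp` and
#' width `transition_width` decades; only the crossing location carries
#' physical information and is what the analysis extracts.
#'
#' @param cm Specific membrane capacitance (F/m^2).
#' @param lambda_in,lambda_out Inner/outer solution conductivities (S/m);
#'   `lambda_in/lambda_out` must be < 1.
#' @param radius Vesicle radius (m).
#' @param frequencies Strictly increasing field frequencies (Hz); default 25
#'   log-spaced points over the experimental window 500 Hz - 1 MHz.
#' @param ar_noise_sd Gaussian noise SD added to each aspect ratio.
#' @param transition_amp,transition_width Shape parameters of the sweep.
#' @param seed Integer seed.
#' @return A `frequency_sweep` object: data frame `frequency`, `aspect`
#'   with attributes `radius`, `lambda_in`, `lambda_out` and `truth`
#'   (including the generating critical frequency `fc`).
#' @export
sim_frequency_sweep <- function(cm, lambda_in, lambda_out, radius,
                                frequencies = 10^seq(log10(500), 6,
                                                     length.out = 25),
                                ar_noise_sd = 0, transition_amp = 0.35,
                                transition_width = 0.4, seed = NULL) {
  if (lambda_in <= 0 || lambda_out <= 0) stop2("conductivities must be > 0")
  ratio <- lambda_in / lambda_out
  if (ratio >= 1)
    stop2("conductivity ratio >= 1: no prolate-oblate transition")
  if (is.unsorted(frequencies, strictly = TRUE))
    stop2("frequencies must be strictly increasing")
  fc <- critical_frequency_model(radius, cm, lambda_in, ratio)
  mean_ar <- 1 + transition_amp *
    tanh(log10(fc / frequencies) / transition_width)
  aspect <- with_seed(seed, mean_ar +
                        if (ar_noise_sd > 0)
                          rnorm(length(frequencies), sd = ar_noise_sd) else 0)
  out <- data.frame(frequency = frequencies, aspect = aspect)
  attr(out, "radius") <- radius
  attr(out, "lambda_in") <- lambda_in
  attr(out, "lambda_out") <- lambda_out
  attr(out, "truth") <- list(cm = cm, fc = fc, ar_noise_sd = ar_noise_sd,
                             seed = seed)
  class(out) <- c("frequency_sweep", "data.frame")
  out
}

#' Simulate a tilted, noisy AFM height map with a bilayer patch
#'
#' Height model: `row * tilt_per_row + col * tilt_per_col + step_height *
#' mask + N(0, roughness_sd)`, emulating a supported-bilayer patch on a glass
#' substrate scanned with residual sample tilt.
#'
#' @param nrow,ncol Map dimensions in pixels (>= 16 each).
#' @param step_height Patch height above the substrate (m), >= 0.
#' @param patch_mask Logical matrix marking patch pixels; by default a
#'   centred rectangle covering `patch_coverage` of the map. Must leave the
#'   substrate identifiable (< 80% coverage).
#' @param patch_coverage Fraction of pixels covered by the default patch.
#' @param tilt_per_row,tilt_per_col Background tilt (m per pixel).
#' @param roughness_sd Gaussian roughness SD (m).
#' @param pixel_size Lateral pixel size (m).
#' @param seed Integer seed.
#' @return A `height_map` object (see [height_map()]) with a `truth`
#'   attribute recording the generator parameters and mask.
#' @export
sim_height_map <- function(nrow = 256, ncol = 256, step_height = 6.2e-9,
                           patch_mask = NULL, patch_coverage = 0.4,
                           tilt_per_row = 0, tilt_per_col = 0,
                           roughness_sd = 0, pixel_size = 40e-9,
                           seed = NULL) {
  if (nrow < 16 || ncol < 16) stop2("height map must be at least 16 x 16")
  if (step_height < 0) stop2("step_height must be >= 0")
  if (is.null(patch_mask)) {
    side <- sqrt(patch_coverage)
    r0 <- floor(nrow * (1 - side) / 2) + 1L
    r1 <- min(nrow, r0 + ceiling(nrow * side) - 1L)
    c0 <- floor(ncol * (1 - side) / 2) + 1L
    c1 <- min(ncol, c0 + ceiling(ncol * side) - 1L)
    patch_mask <- matrix(FALSE, nrow, ncol)
    patch_mask[r0:r1, c0:c1] <- TRUE
  }
  stopifnot(is.logical(patch_mask), all(dim(patch_mask) == c(nrow, ncol)))
  if (mean(patch_mask) >= 0.8)
    stop2("patch must cover < 80% of pixels so the substrate stays visible")
  h <- outer(seq_len(nrow) - 1L, seq_len(ncol) - 1L,
             function(r, co) r * tilt_per_row + co * tilt_per_col) +
    step_height * patch_mask
  h <- with_seed(seed, h +
                   if (roughness_sd > 0)
                     matrix(rnorm(length(h), sd = roughness_sd), nrow) else 0)
  hm <- height_map(h, pixel_size = pixel_size)
  attr(hm, "truth") <- list(step_height = step_height, mask = patch_mask,
                            tilt_per_row = tilt_per_row,
                            tilt_per_col = tilt_per_col,
                            roughness_sd = roughness_sd, seed = seed)
  hm
}

#' Simulate tension versus area-per-lipid points
#'
#' Points on the linear stretching law \eqn{\Sigma = K_A (A - A_0)/A_0} with
#' optional multiplicative Gaussian noise on the tension, emulating bilayer
#' simulations run at a small set of lateral pressures.
#'
#' @param k_a Stretching (area-compressibility) modulus (N/m).
#' @param a0 Zero-tension area per lipid (m^2).
#' @param strains Relative area strains \eqn{(A - A_0)/A_0} to sample.
#' @param noise_frac Multiplicative tension noise SD (fraction).
#' @param seed Integer seed.
#' @return Data frame with columns `area` (m^2) and `tension` (N/m).
#' @export
sim_tension_area <- function(k_a = 0.2218, a0 = 0.62e-18,
                             strains = seq(0.01, 0.08, length.out = 5),
                             noise_frac = 0, seed = NULL) {
  stopifnot(k_a > 0, a0 > 0, all(strains > -1))
  tension <- k_a * strains
  tension <- with_seed(seed, tension *
                         (1 + if (noise_frac > 0)
                           rnorm(length(strains), sd = noise_frac) else 0))
  data.frame(area = a0 * (1 + strains), tension = tension)
}
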