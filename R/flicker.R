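#' Helfrich mode variance of a quasi-spherical vesicle contour
#'
#' Model variance of the equatorial Fourier modes of the relative radial
#' displacement \eqn{u(\phi) = (r(\phi) - R)/R} of a quasi-spherical vesicle
#' fluctuating under bending rigidity \eqn{\kappa} and reduced tension
#' \eqn{\bar\sigma = \sigma R^2/\kappa}.
#'
#' The shape is expanded in orthonormal spherical harmonics with amplitude
#' variances \eqn{\langle|u_{lm}|^2\rangle = k_BT / [\kappa (l-1)(l+2)
#' (l(l+1)+\bar\sigma)]}. Projecting onto the equator and taking the
#' one-sided complex Fourier coefficient \eqn{u_q = (1/2\pi)\int u(\phi)
#' e^{-iq\phi} d\phi} gives
#' \deqn{\langle|u_q|^2\rangle = \frac{k_BT}{\kappa} \sum_{l\ge q}
#'   \frac{N_{lq}}{(l-1)(l+2)(l(l+1)+\bar\sigma)}}
#' with equatorial projection weight \eqn{N_{lq} = |Y_{lq}(\pi/2,0)|^2 =
#' \frac{2l+1}{4\pi}\frac{(l-q)!}{(l+q)!}\,[P_l^q(0)]^2}, nonzero only for
#' even \eqn{l+q}. The sum is truncated at `l_max`; the default
#' `4 * max(q)` keeps the truncation error below 1% for every mode
#' (doubling `l_max` changes no variance by more than that, see the
#' package tests).
#'
#' @param q Integer vector of Fourier mode numbers, all `>= 2`.
#' @param kappa Bending rigidity (J).
#' @param sigma_bar Dimensionless reduced tension \eqn{\sigma R^2/\kappa},
#'   `>= 0`.
#' @param temperature Temperature (K).
#' @param l_max Spherical-harmonic truncation order.
#' @return Numeric vector of dimensionless mode variances
#'   \eqn{\langle|u_q|^2\rangle}, one per element of `q`.
#' @seealso [fit_helfrich()], [sim_flicker_contours()]
#' @export
#' @examples
#' helfrich_mode_variance(2:10, kappa = 20 * 1.380649e-23 * 296,
#'                        sigma_bar = 5)
helfrich_mode_variance <- function(q, kappa, sigma_bar, temperature = 296,
                                   l_max = 4L * max(q)) {
  stopifnot(all(q >= 2), all(q == round(q)), kappa > 0, sigma_bar >= -6,
            temperature > 0, l_max >= max(q))
  kT <- .const$kB * temperature
  vapply(as.integer(q), function(qi) {
    l <- seq.int(max(qi, 2L), l_max)
    l <- l[(l + qi) %% 2L == 0L]
    if (!length(l)) return(0)
    A <- (l + qi) / 2
    B <- (l - qi) / 2
    # N_lq in logs: (2l+1)/(4pi) * (2B)!(2A)! / (2^(2A+2B) (A!)^2 (B!)^2)
    logN <- log((2 * l + 1) / (4 * pi)) +
      lgamma(2 * B + 1) + lgamma(2 * A + 1) -
      (2 * A + 2 * B) * log(2) - 2 * lgamma(A + 1) - 2 * lgamma(B + 1)
    sum(exp(logN) / ((l - 1) * (l + 2) * (l * (l + 1) + sigma_bar))) *
      kT / kappa
  }, numeric(1))
}

#' Time-averaged fluctuation mode spectrum of a contour sequence
#'
#' For every frame the relative radial displacement
#' \eqn{u(\phi) = (r(\phi) - R_f)/R_f} (with \eqn{R_f} the frame mean radius)
#' is Fourier transformed with the one-sided normalization
#' \eqn{u_q = \frac{1}{n}\sum_j u(\phi_j) e^{-iq\phi_j}}, and the mean square
#' amplitude \eqn{\langle|u_q|^2\rangle} is averaged across frames.
#'
#' @param contours A `vesicle_contours` object (see
#'   [sim_flicker_contours()]) or a list of `vesicle_contour` objects with
#'   identical angular sampling.
#' @param q_max Largest mode to report; defaults to `n_points / 4`.
#' @return A `mode_spectrum` object: list with `modes`, `msa` (mean-square
#'   amplitude per mode), `msa_se` (standard error across frames),
#'   `n_frames`, `n_points`, `mean_radius` (m).
#' @export
compute_spectrum <- function(contours, q_max = NULL) {
  radii <- contour_radii_matrix(contours)   # n_frames x n_points
  n_frames <- nrow(radii)
  n_points <- ncol(radii)
  if (n_frames < 100)
    stop2("compute_spectrum() needs at least 100 frames, got ", n_frames)
  if (is.null(q_max)) q_max <- n_points %/% 4L
  if (q_max > n_points %/% 2L - 1L)
    stop2("q_max exceeds the Nyquist limit of the contour sampling")
  r_mean <- rowMeans(radii)
  u <- radii / r_mean - 1
  # columns of mvfft are per-frame transforms
  coefs <- mvfft(t(u)) / n_points          # n_points x n_frames, complex
  q <- 2:q_max
  p <- Mod(coefs[q + 1L, , drop = FALSE])^2
  structure(list(
    modes = q,
    msa = rowMeans(p),
    msa_se = apply(p, 1L, sd) / sqrt(n_frames),
    n_frames = n_frames,
    n_points = n_points,
    mean_radius = mean(r_mean)
  ), class = "mode_spectrum")
}

# Accept a vesicle_contours stack or a list of single-frame contours.
contour_radii_matrix <- function(contours) {
  if (inherits(contours, "vesicle_contours")) return(contours$radii)
  if (inherits(contours, "vesicle_contour"))
    return(matrix(contours$radii, nrow = 1L))
  if (is.list(contours)) {
    np <- unique(vapply(contours, function(ct) length(ct$radii), integer(1)))
    if (length(np) != 1L)
      stop2("all contours must have the same number of points")
    return(do.call(rbind, lapply(contours, function(ct) ct$radii)))
  }
  if (is.matrix(contours)) return(contours)
  stop2("unsupported contour container")
}

#' @export
print.mode_spectrum <- function(x, ...) {
  cat("Fluctuation mode spectrum\n")
  cat(sprintf("  frames: %d, contour points: %d, mean radius: %.2f um\n",
              x$n_frames, x$n_points, x$mean_radius * 1e6))
  cat(sprintf("  modes %d..%d; msa(q=%d) = %.3g\n",
              min(x$modes), max(x$modes), min(x$modes), x$msa[1L]))
  invisible(x)
}

#' Fit the Helfrich spectrum to a measured mode spectrum
#'
#' Weighted least squares of the measured mean-square mode amplitudes against
#' the quasi-spherical model of [helfrich_mode_variance()], with weights
#' \eqn{1/\mathrm{SE}^2}. The model is linear in \eqn{k_BT/\kappa} at fixed
#' reduced tension, so the fit profiles \eqn{\kappa} analytically and
#' optimizes a single parameter, \eqn{\log\bar\sigma}.
#'
#' @param spectrum A `mode_spectrum` from [compute_spectrum()].
#' @param temperature Temperature (K).
#' @param q_min,q_max Fit range in mode number. The default `q_min = 3`
#'   discards the lowest modes, which are dominated by tension; `q_max`
#'   defaults to `n_points / 8`.
#' @param l_max Spherical-harmonic truncation, default `4 * q_max`.
#' @return A `flicker_fit` object: `kappa` (J), `kappa_kBT`, `sigma` (N/m),
#'   `sigma_bar`, standard errors, fit range, `sigma_pinned` flag (reduced
#'   tension at the search bound, a QC failure) and the input metadata.
#' @seealso [qc_filter()]
#' @export
fit_helfrich <- function(spectrum, temperature = 296, q_min = 3,
                         q_max = NULL, l_max = NULL) {
  stopifnot(inherits(spectrum, "mode_spectrum"))
  if (is.null(q_max)) q_max <- min(max(spectrum$modes), spectrum$n_points %/% 8L)
  if (q_max > max(spectrum$modes))
    stop2("q_max exceeds the largest mode in the spectrum")
  if (q_min < 2 || q_max <= q_min) stop2("need 2 <= q_min < q_max")
  if (is.null(l_max)) l_max <- 4L * q_max
  keep <- spectrum$modes >= q_min & spectrum$modes <= q_max
  q <- spectrum$modes[keep]
  y <- spectrum$msa[keep]
  se <- spectrum$msa_se[keep]
  w <- if (all(se > 0)) 1 / se^2 else rep(1, length(y))
  kT <- .const$kB * temperature

  # model: y = a * S(q, sigma_bar) with a = kBT/kappa; profile a analytically
  shape <- function(sb)
    helfrich_mode_variance(q, kappa = kT, sigma_bar = sb,
                           temperature = temperature, l_max = l_max)
  a_hat <- function(S) sum(w * y * S) / sum(w * S^2)
  rss <- function(log_sb) {
    S <- shape(exp(log_sb))
    a <- a_hat(S)
    sum(w * (y - a * S)^2)
  }
  bounds <- log(c(1e-6, 1e8))
  opt <- optimize(rss, interval = bounds, tol = 1e-10)
  sigma_bar <- exp(opt$minimum)
  sigma_pinned <- opt$minimum < bounds[1] + 1e-3 ||
    opt$minimum > bounds[2] - 1e-3
  S <- shape(sigma_bar)
  a <- a_hat(S)
  if (!is.finite(a) || a <= 0)
    stop2("Helfrich fit did not converge to a positive rigidity")
  kappa <- kT / a
  R <- spectrum$mean_radius
  sigma <- sigma_bar * kappa / R^2

  # covariance of (a, sigma_bar) from the weighted Jacobian
  dS <- (shape(sigma_bar * (1 + 1e-6)) - S) / (sigma_bar * 1e-6)
  J <- cbind(S, a * dS)
  JtWJ <- crossprod(J * sqrt(w))
  cov2 <- tryCatch(solve(JtWJ), error = function(e) matrix(NA_real_, 2, 2))
  a_se <- sqrt(cov2[1, 1])
  sb_se <- sqrt(cov2[2, 2])
  kappa_se <- kT / a^2 * a_se
  # sigma = sb * kT / (a R^2): delta method
  g <- c(-sigma / a, kT / (a * R^2))
  sigma_se <- sqrt(drop(t(g) %*% cov2 %*% g))

  structure(list(
    kappa = kappa, kappa_kBT = kappa / kT, kappa_se = kappa_se,
    sigma = sigma, sigma_se = sigma_se, sigma_bar = sigma_bar,
    sigma_bar_se = sb_se, temperature = temperature,
    q_min = q_min, q_max = q_max, l_max = l_max,
    sigma_pinned = sigma_pinned, mean_radius = R,
    n_frames = spectrum$n_frames, rss = opt$objective
  ), class = "flicker_fit")
}

#' @export
print.flicker_fit <- function(x, ...) {
  cat("Helfrich spectrum fit\n")
  cat(sprintf("  kappa = %.3g J (%.1f kBT) +/- %.2g J\n",
              x$kappa, x$kappa_kBT, x$kappa_se))
  cat(sprintf("  sigma = %.3g N/m (reduced tension %.3g)\n",
              x$sigma, x$sigma_bar))
  cat(sprintf("  fit range q = %d..%d, l_max = %d, %d frames, R = %.1f um\n",
              x$q_min, x$q_max, x$l_max, x$n_frames, x$mean_radius * 1e6))
  if (x$sigma_pinned) cat("  WARNING: reduced tension pinned at bound (QC fail)\n")
  invisible(x)
}

#' Quality-control filter for flicker analyses
#'
#' Accepts only defect-free, quasi-spherical vesicles in the radius range
#' 10-25 um whose fitted tension lies in the low-tension window
#' \eqn{10^{-9}}-\eqn{10^{-7}} N/m, the regime in which the quasi-spherical
#' spectrum model is reliable.
#'
#' @param fit A `flicker_fit` object.
#' @param defect Logical; `TRUE` marks optically visible defects.
#' @param radius_range,sigma_range Acceptance windows (m and N/m).
#' @return List with `accept` (logical) and `reason` (`"ok"` or the first
#'   violated rule: `"radius"`, `"tension"`, `"defect"`, `"fit"`).
#' @export
qc_filter <- function(fit, defect = FALSE,
                      radius_range = c(10e-6, 25e-6),
                      sigma_range = c(1e-9, 1e-7)) {
  stopifnot(inherits(fit, "flicker_fit"))
  R <- fit$mean_radius
  if (isTRUE(defect))
    return(list(accept = FALSE, reason = "defect"))
  if (R < radius_range[1] || R > radius_range[2])
    return(list(accept = FALSE, reason = "radius"))
  if (fit$sigma < sigma_range[1] || fit$sigma > sigma_range[2])
    return(list(accept = FALSE, reason = "tension"))
  if (isTRUE(fit$sigma_pinned))
    return(list(accept = FALSE, reason = "fit"))
  list(accept = TRUE, reason = "ok")
}
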