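#' Stretching modulus from tension versus area-per-lipid points
#'
#' Fits the linear stretching law \eqn{\Sigma(A) = K_A (A - A_0)/A_0} to
#' tension/area pairs. The fit is performed in the equivalent linear-in-A
#' parameterization \eqn{\Sigma = (K_A/A_0)\,A - K_A} (identical optimum,
#' better conditioning than the nonlinear form), so \eqn{K_A} is minus the
#' intercept and \eqn{A_0 = -c/m} follows from intercept and slope.
#'
#' @param points Data frame with columns `area` (m^2 per lipid) and
#'   `tension` (N/m); >= 3 points with nonzero tension variation.
#' @return List with `k_a` (N/m), `k_a_se`, `a0` (m^2), `negative_k`
#'   (flag), `fit` (the underlying `lm`).
#' @export
#' @examples
#' pts <- sim_tension_area(k_a = 0.2218, a0 = 0.62e-18)
#' fit_stretching_modulus(pts)$k_a   # 0.2218
fit_stretching_modulus <- function(points) {
  stopifnot(all(c("area", "tension") %in% names(points)))
  if (nrow(points) < 3) stop2("need at least 3 tension-area points")
  if (any(points$area <= 0)) stop2("areas must be > 0")
  if (max(points$tension) - min(points$tension) == 0)
    stop2("no tension variation: stretching modulus unidentifiable")
  if (max(points$area) - min(points$area) == 0)
    stop2("degenerate area spacing")
  fit <- lm(tension ~ area, data = points)
  cf <- coef(fit)
  k_a <- -cf[[1L]]
  a0 <- -cf[[1L]] / cf[[2L]]
  # intercept SE computed directly (silent on noiseless closure data)
  x <- points$area
  s2 <- sum(residuals(fit)^2) / (nrow(points) - 2L)
  k_a_se <- sqrt(s2 * (1 / nrow(points) + mean(x)^2 /
                         sum((x - mean(x))^2)))
  if (k_a <= 0)
    warning("fitted stretching modulus is not positive", call. = FALSE)
  list(k_a = k_a, k_a_se = k_a_se, a0 = a0, negative_k = k_a <= 0,
       fit = fit)
}

#' Interleaflet coupling constant
#'
#' From the polymer-brush style relation \eqn{\kappa/K = \beta d^2} the
#' dimensionless coupling constant is \eqn{1/\beta = K d^2 / \kappa}.
#' Reference values: 12 for rigidly bound leaflets, 24 for the
#' polymer-brush prediction, 48 for freely sliding leaflets.
#'
#' @param kappa Bending rigidity (J).
#' @param k Stretching modulus (N/m).
#' @param d Bilayer thickness (m).
#' @return The coupling constant \eqn{1/\beta} (dimensionless).
#' @export
#' @examples
#' coupling_constant(8.28e-20, 0.2218, 3.65e-9)   # ~35.7
coupling_constant <- function(kappa, k, d) {
  if (any(kappa <= 0) || any(k <= 0) || any(d <= 0))
    stop2("kappa, k and d must be > 0")
  k * d^2 / kappa
}

#' Elasticity set with a consistency-checked coupling constant
#'
#' Bundles bending rigidity, stretching modulus, thickness and the coupling
#' constant, enforcing \eqn{1/\beta = K d^2/\kappa} to within 1e-12.
#'
#' @param kappa Bending rigidity (J).
#' @param k Stretching modulus (N/m).
#' @param d Bilayer thickness (m).
#' @param a0 Optional zero-tension area per lipid (m^2).
#' @return An `elasticity_set` list: `kappa`, `k`, `d`, `inv_beta`, `a0`.
#' @export
elasticity_set <- function(kappa, k, d, a0 = NA_real_) {
  inv_beta <- coupling_constant(kappa, k, d)
  stopifnot(abs(inv_beta - k * d^2 / kappa) <= 1e-12 * inv_beta)
  structure(list(kappa = kappa, k = k, d = d, inv_beta = inv_beta, a0 = a0),
            class = "elasticity_set")
}

#' @export
print.elasticity_set <- function(x, ...) {
  cat("Membrane elasticity set\n")
  cat(sprintf("  kappa = %.3g J, K = %.1f mN/m, d = %.2f nm\n",
              x$kappa, x$k * 1e3, x$d * 1e9))
  cat(sprintf("  interleaflet coupling 1/beta = %.1f\n", x$inv_beta))
  invisible(x)
}

#' Thickness change of a volume-conserving stretched membrane
#'
#' An elastic sheet conserving its volume (area times thickness) thins when
#' it expands: a relative area increase \eqn{\alpha = \Delta A/A} gives
#' \eqn{\Delta d/d_0 = \alpha/(1+\alpha)} and
#' \eqn{d_{new} = d_0/(1+\alpha)}.
#'
#' @param area_increase_fraction Relative area change \eqn{\Delta A/A},
#'   > -1.
#' @param d0 Initial thickness (m).
#' @return List with `dd_frac` (relative thickness decrease), `d_new` (m),
#'   `dd` (absolute decrease, m).
#' @export
#' @examples
#' thickness_from_area_conservation(0.20, 6.2e-9)$dd_frac   # ~0.167
thickness_from_area_conservation <- function(area_increase_fraction, d0) {
  if (any(area_increase_fraction <= -1))
    stop2("area change fraction must be > -1")
  if (any(d0 <= 0)) stop2("d0 must be > 0")
  a <- area_increase_fraction
  d_new <- d0 / (1 + a)
  list(dd_frac = a / (1 + a), d_new = d_new, dd = d0 - d_new)
}

#' Relative area change of a sphere from radii
#'
#' For vesicles assumed spherical (e.g. LUVs sized by dynamic light
#' scattering) the area is \eqn{4\pi R^2}, so the percent area change is
#' \eqn{100 (R_{after}^2 - R_{before}^2)/R_{before}^2}.
#'
#' @param r_before,r_after Radii (m), > 0.
#' @return Percent change (signed).
#' @export
#' @examples
#' sphere_area_change(100e-9, 105e-9)   # 10.25
sphere_area_change <- function(r_before, r_after) {
  if (any(r_before <= 0) || any(r_after <= 0)) stop2("radii must be > 0")
  100 * (r_after^2 - r_before^2) / r_before^2
}

#' Monolayer area expansion between photoswitch states
#'
#' Percent expansion of the area per lipid upon trans-to-cis isomerization
#' at fixed surface pressure, with the positive-expansion sign convention:
#' \eqn{100 (A_{cis} - A_{trans})/A_{trans}}. Reverse switching (a smaller
#' cis area) therefore comes out negative.
#'
#' @param area_trans Area per lipid in the trans state (any consistent
#'   unit), > 0.
#' @param area_cis Area per lipid in the cis state, > 0.
#' @return Percent change (signed).
#' @export
#' @examples
#' monolayer_expansion(60, 75)   # 25
monolayer_expansion <- function(area_trans, area_cis) {
  if (any(area_trans <= 0) || any(area_cis <= 0))
    stop2("areas must be > 0")
  100 * (area_cis - area_trans) / area_trans
}
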