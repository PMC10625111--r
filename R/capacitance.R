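#' Critical frequency of the prolate-oblate transition
#'
#' For a vesicle with conductivity ratio \eqn{\Lambda =
#' \lambda_{in}/\lambda_{out} < 1} the aspect ratio decreases with AC field
#' frequency and crosses a/b = 1 at
#' \deqn{f_c = \frac{\lambda_{in}}{2\pi R C_m}
#'   \left[(1-\Lambda)(3+\Lambda)\right]^{-1/2}.}
#' The exponent of the radical is kept as a single named constant
#' (`.fc_radical_exponent`) because typeset versions of this relation are
#' easy to misread; this form reproduces the downstream capacitance and
#' dielectric-constant numbers of the measurements it is used for.
#'
#' @param radius Vesicle radius (m).
#' @param cm Specific membrane capacitance (F/m^2).
#' @param lambda_in Inner solution conductivity (S/m).
#' @param ratio Conductivity ratio \eqn{\Lambda}, in (0, 1).
#' @return Critical frequency (Hz); strictly decreasing in `radius` and
#'   `cm`, diverging as \eqn{\Lambda \to 1}.
#' @export
#' @examples
#' critical_frequency_model(10e-6, 0.43e-2, 42.70e-4, 0.52)  # ~1.22e4 Hz
critical_frequency_model <- function(radius, cm, lambda_in, ratio) {
  if (any(ratio <= 0) || any(ratio >= 1))
    stop2("conductivity ratio must lie in (0, 1): no transition otherwise")
  if (any(radius <= 0) || any(cm <= 0) || any(lambda_in <= 0))
    stop2("radius, cm and lambda_in must be > 0")
  lambda_in / (2 * pi * radius * cm) *
    ((1 - ratio) * (3 + ratio))^.fc_radical_exponent
}

.fc_radical_exponent <- -0.5

#' Detect the critical frequency in a measured sweep
#'
#' Locates the aspect-ratio crossing of a/b = 1 by linear interpolation in
#' log10 frequency, after a 3-point running-median prefilter. Sweeps are
#' log-spaced, so interpolating in log frequency between the two points
#' bracketing the crossing returns the geometric-mean style estimate. If
#' several crossings survive the prefilter the lowest-frequency one is
#' returned with a warning.
#'
#' @param sweep A `frequency_sweep` (data frame with `frequency`, `aspect`).
#' @return Critical frequency (Hz).
#' @export
detect_critical_frequency <- function(sweep) {
  f <- sweep$frequency
  a <- sweep$aspect
  if (length(f) < 3) stop2("sweep too short")
  a_s <- if (length(a) >= 3) runmed(a, 3, endrule = "keep") else a
  d <- a_s - 1
  hit0 <- which(d == 0)
  sgn <- sign(d)
  cross <- which(sgn[-length(sgn)] * sgn[-1L] < 0)
  n_cross <- length(cross) + length(hit0)
  if (n_cross == 0)
    stop2("no transition in sweep: aspect ratio never crosses 1")
  if (n_cross > 1)
    warning("noisy sweep: multiple crossings; using the lowest frequency",
            call. = FALSE)
  if (length(hit0) && (!length(cross) || hit0[1L] <= cross[1L]))
    return(f[hit0[1L]])
  i <- cross[1L]
  lf <- log10(f[i]) + (0 - d[i]) / (d[i + 1L] - d[i]) *
    (log10(f[i + 1L]) - log10(f[i]))
  10^lf
}

#' Specific membrane capacitance from critical frequencies of many vesicles
#'
#' The critical frequency is linear in inverse radius,
#' \eqn{f_c = s / R} with slope \eqn{s = \lambda_{in} /
#' (2\pi C_m \sqrt{(1-\Lambda)(3+\Lambda)})}. A least-squares line (with
#' free intercept) of \eqn{f_c} against \eqn{1/R} over >= 3 vesicles gives
#' the slope, hence \eqn{C_m = \lambda_{in}/(2\pi s
#' \sqrt{(1-\Lambda)(3+\Lambda)})}; the standard error is propagated from
#' the slope standard error.
#'
#' @param points Data frame with columns `radius` (m) and `fc` (Hz).
#' @param lambda_in Inner conductivity (S/m), shared by all vesicles.
#' @param ratio Conductivity ratio \eqn{\Lambda}, shared.
#' @return List with `cm` (F/m^2), `cm_se`, `slope`, `slope_se`,
#'   `n_vesicles`.
#' @export
fit_specific_capacitance <- function(points, lambda_in, ratio) {
  stopifnot(all(c("radius", "fc") %in% names(points)))
  if (nrow(points) < 3) stop2("insufficient vesicles: need >= 3")
  if (ratio <= 0 || ratio >= 1) stop2("conductivity ratio must be in (0, 1)")
  inv_r <- 1 / points$radius
  fit <- lm(points$fc ~ inv_r)
  s <- coef(fit)[["inv_r"]]
  # slope SE computed directly (avoids the perfect-fit summary warning on
  # noiseless closure tests)
  dof <- nrow(points) - 2L
  s_se <- sqrt(sum(residuals(fit)^2) / dof / sum((inv_r - mean(inv_r))^2))
  if (s <= 0) stop2("negative slope: sweep data inconsistent with the model")
  k <- sqrt((1 - ratio) * (3 + ratio))
  cm <- lambda_in / (2 * pi * s * k)
  list(cm = cm, cm_se = cm * s_se / s, slope = s, slope_se = s_se,
       n_vesicles = nrow(points))
}

#' Debye screening length of a 1:1 electrolyte
#'
#' \deqn{\lambda_D = \sqrt{\frac{\varepsilon_{r,W}\,\varepsilon_0\, k_B T}
#'   {2 N_A e^2 c}}}
#' for a symmetric monovalent salt of concentration `c_salt`.
#'
#' @param c_salt Salt concentration (mol/m^3; 1 mM = 1 mol/m^3), > 0.
#' @param temperature Temperature (K).
#' @param eps_water Relative dielectric constant of the solution.
#' @return Debye length (m); halves when the concentration quadruples.
#' @export
#' @examples
#' debye_length(0.3) * 1e9   # ~17.5 nm for 0.3 mM NaCl
debye_length <- function(c_salt, temperature = 296, eps_water = 80) {
  if (any(c_salt <= 0)) stop2("salt concentration must be > 0")
  sqrt(eps_water * .const$eps0 * .const$kB * temperature /
         (2 * .const$NA_avogadro * .const$e^2 * c_salt))
}

#' Diffuse double-layer capacitance
#'
#' \eqn{C_D = \varepsilon_{r,W}\varepsilon_0 / \lambda_D}: the space-charge
#' region adjacent to the membrane acts as a plate capacitor of thickness
#' one Debye length filled with water.
#'
#' @param lambda_d Debye length (m), > 0.
#' @param eps_water Relative dielectric constant of the solution.
#' @return Capacitance per unit area (F/m^2).
#' @export
#' @examples
#' double_layer_capacitance(17.5e-9) * 1e2   # ~4.05 uF/cm^2
double_layer_capacitance <- function(lambda_d, eps_water = 80) {
  if (any(lambda_d <= 0)) stop2("Debye length must be > 0")
  eps_water * .const$eps0 / lambda_d
}

#' Bare bilayer capacitance from the measured membrane capacitance
#'
#' The measured specific membrane capacitance is the series combination
#' \eqn{C_m = (1/C_B + 1/C_{D,in} + 1/C_{D,out})^{-1}}; inverting gives
#' \eqn{C_B = (1/C_m - 1/C_{D,in} - 1/C_{D,out})^{-1}}, valid only when the
#' membrane, not the double layers, dominates the series impedance.
#'
#' @param cm Measured specific membrane capacitance (F/m^2).
#' @param cd_in,cd_out Double-layer capacitances (F/m^2).
#' @return Bare bilayer capacitance (F/m^2).
#' @export
bare_bilayer_capacitance <- function(cm, cd_in, cd_out) {
  if (any(cm <= 0) || any(cd_in <= 0) || any(cd_out <= 0))
    stop2("capacitances must be > 0")
  inv <- 1 / cm - 1 / cd_in - 1 / cd_out
  if (any(inv <= 0))
    stop2("double layers dominate; bare bilayer capacitance undefined")
  1 / inv
}

#' Relative dielectric constant of the bilayer
#'
#' From the plate-capacitor relation \eqn{C_B = \varepsilon_{r,B}
#' \varepsilon_0 / d}: \eqn{\varepsilon_{r,B} = C_B d / \varepsilon_0}.
#'
#' @param cb Bare bilayer capacitance (F/m^2).
#' @param d Bilayer thickness (m).
#' @return Dimensionless relative dielectric constant.
#' @export
dielectric_constant <- function(cb, d) {
  if (any(cb <= 0) || any(d <= 0)) stop2("cb and d must be > 0")
  cb * d / .const$eps0
}

#' Assemble the full capacitance chain for one membrane composition
#'
#' Chains [bare_bilayer_capacitance()] and [dielectric_constant()] and
#' checks the series identity \eqn{1/C_m = 1/C_B + 1/C_{D,in} + 1/C_{D,out}}
#' to within 1e-12 relative.
#'
#' @param cm Measured specific membrane capacitance (F/m^2).
#' @param cd_in,cd_out Double-layer capacitances (F/m^2).
#' @param thickness Bilayer thickness d (m).
#' @param eps_water Relative dielectric constant of water.
#' @return A `capacitance_set`: `cm`, `cb`, `cd_in`, `cd_out`,
#'   `eps_membrane`, `thickness`, `eps_water`.
#' @export
#' @examples
#' cs <- capacitance_set(cm = 0.52e-2, cd_in = 4.05e-2, cd_out = 5.72e-2,
#'                       thickness = 6.2e-9)
#' cs$eps_membrane   # ~4.66
capacitance_set <- function(cm, cd_in, cd_out, thickness, eps_water = 80) {
  cb <- bare_bilayer_capacitance(cm, cd_in, cd_out)
  stopifnot(abs(1 / cm - (1 / cb + 1 / cd_in + 1 / cd_out)) <= 1e-12 / cm)
  structure(list(
    cm = cm, cb = cb, cd_in = cd_in, cd_out = cd_out,
    eps_membrane = dielectric_constant(cb, thickness),
    thickness = thickness, eps_water = eps_water
  ), class = "capacitance_set")
}

#' @export
print.capacitance_set <- function(x, ...) {
  cat("Membrane capacitance chain\n")
  cat(sprintf("  Cm = %.3f uF/cm^2, CB = %.3f uF/cm^2 (CD,in = %.2f, CD,out = %.2f)\n",
              x$cm * 1e2, x$cb * 1e2, x$cd_in * 1e2, x$cd_out * 1e2))
  cat(sprintf("  thickness d = %.2f nm  =>  eps_r,B = %.3f\n",
              x$thickness * 1e9, x$eps_membrane))
  invisible(x)
}
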