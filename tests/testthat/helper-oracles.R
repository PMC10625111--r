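# Independent oracles used across the suite.

# Direct-summation DFT of the relative displacement of one frame:
# u_q = (1/n) sum_j u(phi_j) exp(-i q phi_j)
dft_direct <- function(u, q) {
  n <- length(u)
  phi <- 2 * pi * (seq_len(n) - 1) / n
  vapply(q, function(qq)
    abs(sum(u * exp(-1i * qq * phi)) / n)^2, numeric(1))
}

# Spheroid area by numerical surface-of-revolution quadrature: rotate the
# ellipse x = a cos(t), y = b sin(t) about the x axis (the field axis, with
# semi-axis a). The parametric form keeps the integrand smooth at the poles,
# so the quadrature is accurate at any aspect ratio. Works for prolate
# (a > b) and oblate (a < b) alike.
spheroid_area_quadrature <- function(a, b) {
  integrand <- function(t)
    2 * pi * b * sin(t) * sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2)
  # split at the equator so the adaptive rule resolves both caps
  stats::integrate(integrand, 0, pi / 2, rel.tol = 1e-13,
                   subdivisions = 2000L)$value +
    stats::integrate(integrand, pi / 2, pi, rel.tol = 1e-13,
                     subdivisions = 2000L)$value
}
prolate_area_quadrature <- spheroid_area_quadrature
oblate_area_quadrature <- spheroid_area_quadrature

# room-temperature thermal energy used throughout the tests
kT296 <- 1.380649e-23 * 296

# elliptical contour radii r(phi) on the default uniform grid
ellipse_radii <- function(a, b, n = 256) {
  phi <- 2 * pi * (seq_len(n) - 1) / n
  a * b / sqrt((b * cos(phi))^2 + (a * sin(phi))^2)
}
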