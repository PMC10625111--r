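#' Surface area of an electrodeformed prolate vesicle
#'
#' Area of a prolate spheroid with semi-axis `a` along the field and `b`
#' perpendicular to it:
#' \deqn{A = 2\pi b \left(b + a\,\frac{\arcsin\varepsilon}{\varepsilon}\right),
#'   \qquad \varepsilon^2 = 1 - (b/a)^2.}
#' For \eqn{\varepsilon < 10^{-4}} the series
#' \eqn{\arcsin\varepsilon/\varepsilon = 1 + \varepsilon^2/6 +
#' 3\varepsilon^4/40} is used, giving the sphere limit \eqn{4\pi R^2}
#' continuously. Oblate inputs (`b > a`) are rejected by default because the
#' area-measurement protocol guarantees prolate deformation (higher interior
#' conductivity); `allow_oblate = TRUE` switches to the standard oblate
#' spheroid formula for frequency-sweep data.
#'
#' @param a Semi-axis along the field (m).
#' @param b Semi-axis perpendicular to the field (m).
#' @param allow_oblate Use the oblate formula when `b > a` instead of
#'   raising an error.
#' @return Surface area (m^2); vectorized over `a` and `b`.
#' @export
#' @examples
#' ellipsoid_area(10e-6, 5e-6) * 1e12   # ~537 um^2
ellipsoid_area <- function(a, b, allow_oblate = FALSE) {
  stopifnot(length(a) == length(b) || length(a) == 1L || length(b) == 1L)
  if (any(a <= 0) || any(b <= 0)) stop2("semi-axes must be > 0")
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  out <- numeric(n)
  obl <- b > a
  if (any(obl) && !allow_oblate)
    stop2("oblate shape (b > a): prolate area formula inapplicable; ",
          "set allow_oblate = TRUE for the oblate spheroid formula")
  pro <- !obl
  if (any(pro)) {
    eps2 <- 1 - (b[pro] / a[pro])^2
    eps <- sqrt(pmax(eps2, 0))
    f <- ifelse(eps < 1e-4,
                1 + eps2 / 6 + 3 * eps2^2 / 40,
                asin(eps) / eps)
    out[pro] <- 2 * pi * b[pro] * (b[pro] + a[pro] * f)
  }
  if (any(obl)) {
    # oblate: equatorial radius b > polar radius a
    e2 <- 1 - (a[obl] / b[obl])^2
    e <- sqrt(pmax(e2, 0))
    f <- ifelse(e < 1e-4,
                1 - e2 / 3 - e2^2 / 15,   # (1-e^2)/e * atanh(e) series
                (1 - e2) / e * atanh(e))
    out[obl] <- 2 * pi * b[obl]^2 * (1 + f)
  }
  out
}

#' Photo-induced relative area change
#'
#' Percentage change \eqn{100 (A_l - A_i)/A_i} between the vesicle area
#' under the AC field alone (`area_initial`) and under illumination
#' (`area_light`). The sign is preserved: shrinkage is negative.
#'
#' @param area_initial Area before illumination (m^2), > 0.
#' @param area_light Area under illumination (m^2).
#' @return Percent change (vectorized).
#' @export
relative_area_change <- function(area_initial, area_light) {
  if (any(area_initial <= 0)) stop2("initial area must be > 0")
  100 * (area_light - area_initial) / area_initial
}

#' Segment an aspect-ratio trace into illumination epochs
#'
#' Maximal runs of constant illumination label, in time order.
#'
#' @param trace An `aspect_trace` data frame with columns `time` and
#'   `illumination`.
#' @return Data frame with columns `label`, `start`, `end` (s), `i_start`,
#'   `i_end` (frame indices); zero rows for an empty trace.
#' @export
segment_epochs <- function(trace) {
  if (nrow(trace) == 0L)
    return(data.frame(label = character(), start = numeric(),
                      end = numeric(), i_start = integer(),
                      i_end = integer()))
  r <- rle(as.character(trace$illumination))
  i_end <- cumsum(r$lengths)
  i_start <- c(1L, head(i_end, -1L) + 1L)
  data.frame(label = r$values, start = trace$time[i_start],
             end = trace$time[i_end], i_start = i_start, i_end = i_end)
}

#' Fit an exponential relaxation to one illumination epoch
#'
#' Nonlinear least squares of
#' \eqn{a/b(t) = \mathrm{baseline} + B\, e^{-(t - t_0)/\tau}} over the
#' selected epoch, with \eqn{t_0} fixed to the epoch start (stepwise
#' illumination; fitting \eqn{t_0} would correlate strongly with \eqn{\tau}).
#' `B` is signed, so both the rise under UV and the decay under blue light
#' are covered; the reported `amplitude` is `|B|`.
#'
#' @param trace An `aspect_trace` data frame.
#' @param epoch Illumination label of the epoch to fit (`"UV"` or
#'   `"blue"`), or a row index into [segment_epochs()] output.
#' @param which For a label occurring several times, which occurrence.
#' @return A `kinetics_fit`: `tau` (s), `tau_se`, `amplitude`, `baseline`,
#'   `rmse`, `window`, `flat` (amplitude indistinguishable from zero; `tau`
#'   is `NA` in that case) and `converged`.
#' @export
fit_relaxation <- function(trace, epoch = "UV", which = 1L) {
  eps <- segment_epochs(trace)
  if (is.character(epoch)) {
    hits <- which(eps$label == epoch)
    if (length(hits) < which)
      stop2("epoch '", epoch, "' (occurrence ", which, ") not present")
    row <- hits[which]
  } else row <- as.integer(epoch)
  idx <- seq.int(eps$i_start[row], eps$i_end[row])
  if (length(idx) < 20)
    stop2("epoch has fewer than 20 frames")
  t <- trace$time[idx] - eps$start[row]
  y <- trace$aspect[idx]
  window <- c(eps$start[row], eps$end[row])

  if (sd(y) < 1e-12)
    return(structure(list(tau = NA_real_, tau_se = NA_real_, amplitude = 0,
                          amplitude_signed = 0, baseline = mean(y), rmse = 0,
                          window = window, flat = TRUE, converged = TRUE),
                     class = "kinetics_fit"))

  base0 <- mean(tail(y, max(5L, length(y) %/% 5L)))
  b0 <- y[1L] - base0
  if (abs(b0) < 1e-12) b0 <- 1e-3
  tau0 <- max(diff(range(t)) / 5, 1e-6)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ base + b * exp(-t / tau),
                      start = list(base = base0, b = b0, tau = tau0),
                      lower = c(-Inf, -Inf, 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) stop2("relaxation fit did not converge")
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e)
    rep(NA_real_, 3L))
  names(se) <- names(cf)
  resid_sd <- sqrt(mean(residuals(fit)^2))
  flat <- abs(cf[["b"]]) < 2 * max(se[["b"]], 0, na.rm = TRUE) ||
    abs(cf[["b"]]) < 1e-10
  structure(list(
    tau = if (flat) NA_real_ else cf[["tau"]],
    tau_se = se[["tau"]],
    amplitude = abs(cf[["b"]]), amplitude_signed = cf[["b"]],
    baseline = cf[["base"]], rmse = resid_sd,
    window = window, flat = flat, converged = TRUE
  ), class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat("Exponential relaxation fit\n")
  if (x$flat) {
    cat("  flat trace: amplitude indistinguishable from zero, tau undefined\n")
  } else {
    cat(sprintf("  tau = %.4g s +/- %.2g, amplitude = %.3g, baseline = %.4g\n",
                x$tau, x$tau_se, x$amplitude, x$baseline))
  }
  cat(sprintf("  window %.2f..%.2f s, rmse = %.3g\n",
              x$window[1], x$window[2], x$rmse))
  invisible(x)
}

#' One-way analysis of variance
#'
#' Classical one-way ANOVA F statistic and p-value with (k-1, N-k) degrees
#' of freedom, as used to test whether photo-induced area changes differ
#' between switching directions. Wraps [stats::oneway.test()] with equal
#' variances; the degenerate case of identical groups (zero between- and
#' within-group variance) is reported as F = 0, p = 1.
#'
#' @param groups List of numeric vectors, each of length >= 2.
#' @return List with `f`, `p`, `df1`, `df2`.
#' @export
#' @examples
#' anova_oneway(list(c(1, 2, 3), c(11, 12, 13)))
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop2("need at least two groups")
  if (any(lengths(groups) < 2L)) stop2("each group needs at least 2 values")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  means <- vapply(groups, mean, numeric(1))
  wvar <- vapply(groups, var, numeric(1))
  if (all(wvar == 0)) {
    if (max(means) - min(means) == 0)
      return(list(f = 0, p = 1, df1 = length(groups) - 1L,
                  df2 = length(y) - length(groups)))
    return(list(f = Inf, p = 0, df1 = length(groups) - 1L,
                df2 = length(y) - length(groups)))
  }
  tst <- oneway.test(y ~ g, var.equal = TRUE)
  list(f = unname(tst$statistic), p = unname(tst$p.value),
       df1 = unname(tst$parameter[1L]), df2 = unname(tst$parameter[2L]))
}

#' Construct an aspect-ratio trace
#'
#' @param time Strictly increasing times (s).
#' @param aspect Aspect ratios a/b, > 0.
#' @param illumination Per-frame labels in `{dark, UV, blue}`.
#' @param field_on Logical, per frame.
#' @return An `aspect_trace` data frame.
#' @export
aspect_trace <- function(time, aspect, illumination = "dark",
                         field_on = TRUE) {
  if (is.unsorted(time, strictly = TRUE))
    stop2("times must be strictly increasing")
  if (any(aspect <= 0)) stop2("aspect ratios must be > 0")
  illumination <- rep_len(as.character(illumination), length(time))
  if (!all(illumination %in% c("dark", "UV", "blue")))
    stop2("illumination labels must be in {dark, UV, blue}")
  out <- data.frame(time = time, aspect = aspect,
                    illumination = illumination,
                    field_on = rep_len(field_on, length(time)))
  class(out) <- c("aspect_trace", "data.frame")
  out
}
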