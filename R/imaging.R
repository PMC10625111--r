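#' Construct a single-frame vesicle contour
#'
#' Radii versus polar angle on a uniform angular grid. Angles are measured
#' counterclockwise from the +x (column) axis; the pixel grid is row-major
#' with origin at top-left, so image row increases downwards.
#'
#' @param radii Radii (m), > 0, one per angle.
#' @param angles Uniform strictly increasing grid in `[0, 2*pi)`; default
#'   `2*pi*(0:(n-1))/n`.
#' @param center Optional contour centre in pixel coordinates
#'   `c(row, col)`.
#' @param frame_time Acquisition time of the frame (s).
#' @return A `vesicle_contour` object.
#' @export
vesicle_contour <- function(radii, angles = NULL, center = c(NA_real_, NA_real_),
                            frame_time = NA_real_) {
  n <- length(radii)
  if (is.null(angles)) angles <- 2 * pi * (seq_len(n) - 1L) / n
  if (length(angles) != n) stop2("angles and radii lengths differ")
  if (any(radii <= 0)) stop2("radii must be > 0")
  d <- diff(angles)
  if (any(d <= 0) || max(d) - min(d) > 1e-9)
    stop2("angles must be a uniform strictly increasing grid")
  structure(list(radii = radii, angles = angles, center = center,
                 frame_time = frame_time), class = "vesicle_contour")
}

#' @export
print.vesicle_contour <- function(x, ...) {
  cat(sprintf("Vesicle contour: %d points, mean radius %.2f um\n",
              length(x$radii), mean(x$radii) * 1e6))
  invisible(x)
}

#' Render a synthetic phase-contrast style vesicle image
#'
#' Draws the vesicle as a dark ring on a light background: intensity
#' \eqn{I = \mathrm{bg} - \mathrm{contrast} \cdot
#' \exp[-(\rho - r(\theta))^2/(2 w^2)]} where \eqn{\rho, \theta} are polar
#' pixel coordinates about the image centre and \eqn{r(\theta)} the contour
#' radius, plus optional Gaussian noise.
#'
#' @param contour A `vesicle_contour` (radii in m).
#' @param pixel_size Metres per pixel.
#' @param shape Image dimensions `c(rows, cols)` (each >= 64).
#' @param ring_width Gaussian ring half-width w (m).
#' @param contrast Ring depth in intensity units.
#' @param noise_sd Gaussian noise SD in intensity units.
#' @param background Background intensity.
#' @param center Ring centre in pixels `c(row, col)`; default image centre.
#' @param seed Integer seed for the noise.
#' @return A `vesicle_image`: list with `pixels` (matrix), `pixel_size`,
#'   `center_hint`.
#' @export
render_vesicle_image <- function(contour, pixel_size, shape = c(128L, 128L),
                                 ring_width = 0.5e-6, contrast = 0.8,
                                 noise_sd = 0, background = 1,
                                 center = NULL, seed = NULL) {
  stopifnot(inherits(contour, "vesicle_contour"))
  if (any(shape < 64)) stop2("image must be at least 64 x 64 pixels")
  if (is.null(center)) center <- (shape + 1) / 2
  rmax_px <- (max(contour$radii) + 3 * ring_width) / pixel_size
  if (center[1] - rmax_px < 1 || center[1] + rmax_px > shape[1] ||
      center[2] - rmax_px < 1 || center[2] + rmax_px > shape[2])
    stop2("contour (plus ring width) exceeds the frame bounds")
  rows <- seq_len(shape[1]); cols <- seq_len(shape[2])
  dy <- -(rows - center[1])          # y up, angles counterclockwise from +x
  dx <- cols - center[2]
  X <- matrix(dx, shape[1], shape[2], byrow = TRUE)
  Y <- matrix(dy, shape[1], shape[2])
  rho <- sqrt(X^2 + Y^2) * pixel_size
  theta <- atan2(Y, X) %% (2 * pi)
  r_theta <- interp_periodic(contour$angles, contour$radii, theta)
  img <- background - contrast * exp(-(rho - r_theta)^2 / (2 * ring_width^2))
  img <- with_seed(seed, img +
                     if (noise_sd > 0)
                       matrix(rnorm(length(img), sd = noise_sd), shape[1])
                     else 0)
  structure(list(pixels = img, pixel_size = pixel_size,
                 center_hint = center), class = "vesicle_image")
}

#' @export
print.vesicle_image <- function(x, ...) {
  cat(sprintf("Vesicle image: %d x %d pixels, %.2f um/px\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size * 1e6))
  invisible(x)
}

# periodic linear interpolation of r(theta) on [0, 2pi)
interp_periodic <- function(angles, values, at) {
  n <- length(angles)
  xs <- c(angles, angles[1L] + 2 * pi)
  ys <- c(values, values[1L])
  approx(xs, ys, xout = at %% (2 * pi), rule = 2)$y
}

#' Detect a vesicle contour in a grayscale image at subpixel precision
#'
#' Casts `n_points` rays from an estimated centre and localizes the dark
#' ring on each as the minimum of the lightly smoothed radial intensity
#' profile, refined to subpixel precision by parabolic interpolation of the
#' extremum. The centre starts at the intensity centroid of the inverted
#' image (or `center_hint`) and is refined iteratively with the contour
#' centroid until it shifts by less than 0.1 pixel. Detection is invariant
#' to multiplying the image by a positive constant.
#'
#' The edge is defined as the radial intensity minimum (dark ring on a
#' light background, the phase-contrast appearance), not the maximum
#' gradient; switching the definition would be a one-line change in the
#' profile score.
#'
#' @param image A `vesicle_image`, or a plain matrix plus `pixel_size`.
#' @param n_points Number of rays (contour points).
#' @param center_hint Optional starting centre `c(row, col)` in pixels.
#' @param pixel_size Metres per pixel (taken from the image object when
#'   present).
#' @param threshold Minimum ring depth as a fraction of the image intensity
#'   range for a ray to count as detected.
#' @param step Radial sampling step (pixels).
#' @param max_iter Maximum centre-refinement iterations.
#' @return A `vesicle_contour` with radii in metres and the refined
#'   `center`.
#' @export
detect_contour <- function(image, n_points = 256L, center_hint = NULL,
                           pixel_size = NULL, threshold = 0.1, step = 0.25,
                           max_iter = 25L) {
  if (inherits(image, "vesicle_image")) {
    px <- image$pixels
    if (is.null(pixel_size)) pixel_size <- image$pixel_size
  } else {
    px <- as.matrix(image)
    if (is.null(pixel_size)) stop2("pixel_size required for a bare matrix")
  }
  rng <- max(px) - min(px)
  if (rng <= 0) stop2("no edge found: image has no contrast")
  inv <- max(px) - px
  if (is.null(center_hint)) {
    w <- inv / sum(inv)
    center <- c(sum(row(px) * w), sum(col(px) * w))
  } else center <- center_hint
  angles <- 2 * pi * (seq_len(n_points) - 1L) / n_points
  ca <- cos(angles); sa <- sin(angles)

  for (it in seq_len(max_iter)) {
    rmax <- min(center[1] - 1, nrow(px) - center[1],
                center[2] - 1, ncol(px) - center[2]) - 1
    if (rmax < 3) stop2("no edge found: centre too close to the border")
    rr <- seq(1, rmax, by = step)
    # sample all rays at once: rows decrease with +y
    R <- matrix(rep(rr, each = n_points), n_points)
    Pr <- center[1] - R * rep(sa, length(rr))
    Pc <- center[2] + R * rep(ca, length(rr))
    prof <- matrix(bilinear(px, Pr, Pc), n_points)
    # light smoothing along the ray
    prof_s <- t(apply(prof, 1L, smooth3))
    radii_px <- rep(NA_real_, n_points)
    ncand <- integer(n_points)
    for (k in seq_len(n_points)) {
      p <- prof_s[k, ]
      i <- which.min(p)
      depth <- stats::median(p) - p[i]
      if (!is.finite(depth) || depth < threshold * rng) next
      # count rival local minima nearly as deep (two-ring ambiguity)
      loc <- which(diff(sign(diff(p))) > 0) + 1L
      deep <- loc[stats::median(p) - p[loc] >= 0.8 * depth]
      ncand[k] <- length(unique(c(deep, i)))
      if (i > 1L && i < length(p)) {
        den <- p[i - 1L] - 2 * p[i] + p[i + 1L]
        off <- if (den > 0) 0.5 * (p[i - 1L] - p[i + 1L]) / den else 0
      } else off <- 0
      radii_px[k] <- rr[1L] + (i - 1L + off) * step
    }
    ok <- is.finite(radii_px)
    if (!any(ok)) stop2("no edge found: no ray has sufficient contrast")
    if (mean(!ok) > 0.05)
      stop2("open contour: more than 5% of rays failed")
    if (mean(ncand[ok] > 1L) > 0.5) {
      if (is.null(center_hint))
        stop2("ambiguous contour: multiple rings detected; supply center_hint")
      # nearest-to-hint rule: keep, per ambiguous ray, the candidate radius
      # closest to the median radius of the unambiguous rays
      ref <- stats::median(radii_px[ok & ncand == 1L])
      if (is.finite(ref)) {
        for (k in which(ok & ncand > 1L)) {
          p <- prof_s[k, ]
          loc <- which(diff(sign(diff(p))) > 0) + 1L
          depth <- stats::median(p) - min(p)
          deep <- loc[stats::median(p) - p[loc] >= 0.8 * depth]
          if (length(deep))
            radii_px[k] <- rr[1L] + (deep[which.min(abs(rr[deep] -
                                                          ref))] - 1L) * step
        }
      }
    }
    radii_px[!ok] <- stats::median(radii_px[ok])
    new_center <- c(center[1] - mean(radii_px * sa),
                    center[2] + mean(radii_px * ca))
    shift <- sqrt(sum((new_center - center)^2))
    center <- new_center
    if (shift < 0.1) break
  }
  vesicle_contour(radii = radii_px * pixel_size, angles = angles,
                  center = center)
}

smooth3 <- function(v) {
  n <- length(v)
  out <- (c(v[1L], v[-n]) + v + c(v[-1L], v[n])) / 3
  out
}

# vectorized bilinear interpolation with edge clamping
bilinear <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  r <- pmin(pmax(as.vector(r), 1), nr)
  c <- pmin(pmax(as.vector(c), 1), nc)
  r0 <- pmin(floor(r), nr - 1); c0 <- pmin(floor(c), nc - 1)
  fr <- r - r0; fc <- c - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    m[cbind(r0 + 1, c0 + 1)] * fr * fc
}

#' Read and write grayscale TIFF vesicle images
#'
#' Thin wrappers over the tiff package. Intensities are stored in `[0, 1]`
#' (images are rescaled on write when needed); `pixel_size` is carried in R,
#' not in the file.
#'
#' @param path File path.
#' @param pixel_size Metres per pixel to attach to the returned image.
#' @return `read_image_tiff()` returns a `vesicle_image`;
#'   `write_image_tiff()` returns `path` invisibly.
#' @export
read_image_tiff <- function(path, pixel_size) {
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  structure(list(pixels = px, pixel_size = pixel_size, center_hint = NULL),
            class = "vesicle_image")
}

#' @rdname read_image_tiff
#' @param image A `vesicle_image` or numeric matrix.
#' @param bits_per_sample 8 or 16.
#' @export
write_image_tiff <- function(image, path, bits_per_sample = 16L) {
  px <- if (inherits(image, "vesicle_image")) image$pixels else as.matrix(image)
  rng <- range(px)
  if (rng[1] < 0 || rng[2] > 1)
    px <- (px - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
  tiff::writeTIFF(px, path, bits.per.sample = bits_per_sample)
  invisible(path)
}
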