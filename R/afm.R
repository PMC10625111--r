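#' Construct an AFM height map
#'
#' @param heights Numeric matrix of heights (m), at least 16 x 16, finite.
#' @param pixel_size Lateral pixel size (m).
#' @param metadata Optional free-form list.
#' @return A `height_map` object.
#' @export
height_map <- function(heights, pixel_size = 40e-9, metadata = list()) {
  heights <- as.matrix(heights)
  if (nrow(heights) < 16 || ncol(heights) < 16)
    stop2("height map must be at least 16 x 16 pixels")
  if (!all(is.finite(heights))) stop2("heights must be finite")
  structure(list(heights = heights, pixel_size = pixel_size,
                 metadata = metadata), class = "height_map")
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf("AFM height map: %d x %d pixels (%.0f nm/px), range %.2f..%.2f nm\n",
              nrow(x$heights), ncol(x$heights), x$pixel_size * 1e9,
              min(x$heights) * 1e9, max(x$heights) * 1e9))
  invisible(x)
}

#' Line-wise background flattening with iterative upward rejection
#'
#' Removes the scanner/sample background from each fast-scan line (row) by
#' fitting and subtracting a first-order polynomial, excluding
#' bilayer-patch pixels through an iterative one-sided rejection: (i) linear
#' fit to all pixels of the line, (ii) refit after rejecting pixels more
#' than 1 nm above the first fit, (iii) refit after rejecting pixels more
#' than 0.5 nm above the second fit, then subtract the final line fit.
#' Rejection is one-sided because bilayer patches protrude upward from the
#' substrate. If fewer than 4 pixels survive a rejection step the previous
#' fit is kept for that line, with a warning. Finally the substrate mode of
#' the whole map (histogram mode at 0.05 nm binning) is shifted to zero.
#'
#' @param map A `height_map`.
#' @param reject Rejection thresholds of the two refit passes (m).
#' @param min_pixels Minimum surviving pixels per line fit.
#' @return The flattened `height_map`.
#' @export
flatten_height_map <- function(map, reject = c(1e-9, 0.5e-9),
                               min_pixels = 4L) {
  stopifnot(inherits(map, "height_map"))
  h <- map$heights
  x <- seq_len(ncol(h))
  X <- cbind(1, x)
  starved <- 0L
  for (r in seq_len(nrow(h))) {
    y <- h[r, ]
    fit <- stats::lm.fit(X, y)$coefficients
    for (thr in reject) {
      resid <- y - (fit[1L] + fit[2L] * x)
      keep <- resid <= thr
      if (sum(keep) < min_pixels) {
        starved <- starved + 1L
        break
      }
      fit <- stats::lm.fit(X[keep, , drop = FALSE], y[keep])$coefficients
    }
    h[r, ] <- y - (fit[1L] + fit[2L] * x)
  }
  if (starved > 0L)
    warning(starved, " line(s) starved the rejection fit; previous-pass fit kept",
            call. = FALSE)
  # centre the substrate mode at zero
  h <- h - histogram_mode(h, bin_width = 0.05e-9)
  height_map(h, pixel_size = map$pixel_size, metadata = map$metadata)
}

# location of the most populated 0.05 nm histogram bin, parabolic refined
histogram_mode <- function(h, bin_width = 0.05e-9) {
  # breaks aligned so the lowest value sits at a bin centre: a two-level
  # map then yields exact peak positions
  brk <- seq(min(h) - bin_width / 2, max(h) + bin_width, by = bin_width)
  ct <- tabulate(findInterval(h, brk), nbins = length(brk) - 1L)
  centers <- brk[-length(brk)] + bin_width / 2
  refine_peak(centers, ct, which.max(ct))
}

# parabolic interpolation of a histogram peak position
refine_peak <- function(centers, counts, i) {
  if (i <= 1L || i >= length(counts)) return(centers[i])
  y0 <- counts[i - 1L]; y1 <- counts[i]; y2 <- counts[i + 1L]
  den <- y0 - 2 * y1 + y2
  if (den == 0) return(centers[i])
  centers[i] + 0.5 * (y0 - y2) / den * (centers[2L] - centers[1L])
}

#' Moving-average smoothing of a height map
#'
#' Uniform `window x window` moving average (default 10 x 10); pixels near
#' the edges use the shrunken window that fits inside the map, so a constant
#' map is unchanged everywhere.
#'
#' @param map A `height_map` of at least `window x window` pixels.
#' @param window Window size in pixels.
#' @return The smoothed `height_map`.
#' @export
smooth_height_map <- function(map, window = 10L) {
  stopifnot(inherits(map, "height_map"))
  h <- map$heights
  if (nrow(h) < window || ncol(h) < window)
    stop2("map smaller than the smoothing window")
  lo <- (window - 1L) %/% 2L          # window rows i-lo .. i+hi
  hi <- window - 1L - lo
  sums <- box_sums(h, lo, hi)
  ones <- box_sums(matrix(1, nrow(h), ncol(h)), lo, hi)
  height_map(sums / ones, pixel_size = map$pixel_size,
             metadata = map$metadata)
}

# clamped box sums via integral image
box_sums <- function(m, lo, hi) {
  nr <- nrow(m); nc <- ncol(m)
  I <- matrix(0, nr + 1L, nc + 1L)
  I[-1L, -1L] <- apply(apply(m, 2L, cumsum), 1L, cumsum) |> t()
  r0 <- pmax(seq_len(nr) - lo, 1L); r1 <- pmin(seq_len(nr) + hi, nr)
  c0 <- pmax(seq_len(nc) - lo, 1L); c1 <- pmin(seq_len(nc) + hi, nc)
  I[r1 + 1L, c1 + 1L] - I[r0, c1 + 1L] - I[r1 + 1L, c0] + I[r0, c0]
}

#' Bilayer thickness from the height histogram of a patch-containing crop
#'
#' Builds a histogram (default 0.05 nm bins) of all pixel heights inside the
#' crop and identifies the two most prominent local maxima separated by at
#' least `min_separation`: the lower peak is the substrate, the upper one
#' the bilayer patch, and their distance is the patch thickness. Peak
#' positions are refined by parabolic interpolation around the histogram
#' mode (a Gaussian fit of the peak neighbourhood is available with
#' `gaussian = TRUE`). A third peak whose prominence is within 20% of the
#' second is reported as ambiguous.
#'
#' @param map A (flattened, smoothed) `height_map`.
#' @param crop Optional crop `c(row0, row1, col0, col1)` (inclusive pixel
#'   indices); default is the whole map.
#' @param bin_width Histogram bin width (m).
#' @param min_separation Minimum substrate-patch peak distance (m).
#' @param gaussian Refine peak positions by a local Gaussian fit instead of
#'   parabolic interpolation.
#' @return A `thickness_result`: `substrate_peak`, `patch_peak`,
#'   `thickness` (m), `histogram` (data frame `center`, `count`),
#'   `n_pixels_patch`, `prominences`.
#' @export
patch_thickness <- function(map, crop = NULL, bin_width = 0.05e-9,
                            min_separation = 1e-9, gaussian = FALSE) {
  stopifnot(inherits(map, "height_map"))
  h <- map$heights
  if (!is.null(crop)) {
    stopifnot(length(crop) == 4L, crop[1] >= 1, crop[2] <= nrow(h),
              crop[3] >= 1, crop[4] <= ncol(h), crop[1] <= crop[2],
              crop[3] <= crop[4])
    h <- h[crop[1]:crop[2], crop[3]:crop[4], drop = FALSE]
  }
  v <- as.vector(h)
  brk <- seq(min(v) - bin_width / 2, max(v) + bin_width, by = bin_width)
  ct <- tabulate(findInterval(v, brk), nbins = length(brk) - 1L)
  centers <- brk[-length(brk)] + bin_width / 2

  pk <- find_peaks(ct)
  if (nrow(pk) < 2L)
    stop2("< 2 peaks found: no patch detected in crop")
  pk <- pk[order(-pk$prominence), ]
  first <- pk[1L, ]
  far <- pk[abs(centers[pk$i] - centers[first$i]) >= min_separation, ]
  if (nrow(far) == 0L)
    stop2("< 2 peaks found: no second peak at least ",
          format(min_separation * 1e9), " nm away")
  second <- far[1L, ]
  # ambiguity: a third distinct peak nearly as prominent as the second
  others <- pk[!(pk$i %in% c(first$i, second$i)) &
                 abs(centers[pk$i] - centers[first$i]) >= min_separation &
                 abs(centers[pk$i] - centers[second$i]) >= min_separation, ]
  if (nrow(others) > 0L && others$prominence[1L] >= 0.8 * second$prominence)
    stop2("ambiguous peaks: a third histogram peak rivals the patch peak")

  locate <- function(i) {
    if (!gaussian) return(refine_peak(centers, ct, i))
    idx <- max(1L, i - 3L):min(length(ct), i + 3L)
    w <- ct[idx]
    if (sum(w > 0) < 3) return(centers[i])
    fit <- tryCatch(lm(log(pmax(w, 0.5)) ~ poly(centers[idx], 2, raw = TRUE)),
                    error = function(e) NULL)
    if (is.null(fit)) return(centers[i])
    cf <- coef(fit)
    if (!is.finite(cf[3L]) || cf[3L] >= 0) return(centers[i])
    -cf[2L] / (2 * cf[3L])
  }
  pos <- c(locate(first$i), locate(second$i))
  substrate <- min(pos); patch <- max(pos)
  mid <- (substrate + patch) / 2
  structure(list(
    substrate_peak = substrate, patch_peak = patch,
    thickness = patch - substrate,
    histogram = data.frame(center = centers, count = ct),
    n_pixels_patch = sum(v > mid),
    prominences = c(first$prominence, second$prominence)
  ), class = "thickness_result")
}

# local maxima of a count vector with topographic prominence
find_peaks <- function(ct) {
  n <- length(ct)
  is_max <- which(vapply(seq_len(n), function(i) {
    if (ct[i] == 0) return(FALSE)
    left <- if (i > 1L) ct[i - 1L] else -Inf
    right <- if (i < n) ct[i + 1L] else -Inf
    ct[i] > left && ct[i] >= right
  }, logical(1)))
  prom <- vapply(is_max, function(i) {
    # topographic prominence: drop to the key saddle towards higher terrain;
    # a side without higher terrain imposes no constraint, and the global
    # maximum drops all the way to the histogram floor
    saddle <- function(idx) {
      v <- ct[i]
      for (j in idx) {
        if (ct[j] > ct[i]) return(v)
        v <- min(v, ct[j])
      }
      NA_real_
    }
    s_left <- if (i > 1L) saddle(seq.int(i - 1L, 1L)) else NA_real_
    s_right <- if (i < n) saddle(seq.int(i + 1L, n)) else NA_real_
    if (is.na(s_left) && is.na(s_right)) return(ct[i] - min(ct))
    ct[i] - max(s_left, s_right, na.rm = TRUE)
  }, numeric(1))
  data.frame(i = is_max, height = ct[is_max], prominence = prom)
}

#' @export
print.thickness_result <- function(x, ...) {
  cat("Bilayer patch thickness\n")
  cat(sprintf("  substrate peak %.3f nm, patch peak %.3f nm => d = %.3f nm\n",
              x$substrate_peak * 1e9, x$patch_peak * 1e9, x$thickness * 1e9))
  cat(sprintf("  %d patch pixels; peak prominences %d / %d counts\n",
              x$n_pixels_patch, x$prominences[1L], x$prominences[2L]))
  invisible(x)
}
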