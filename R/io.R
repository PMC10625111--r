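#' Contour CSV input and output
#'
#' Contours travel as CSV with columns `frame`, `angle_rad`, `radius_um`
#' (radii in micrometres on disk, metres in memory).
#'
#' @param contours A `vesicle_contours` stack or list of `vesicle_contour`.
#' @param path File path.
#' @return `read_contours_csv()` returns a `vesicle_contours` object;
#'   `write_contours_csv()` returns `path` invisibly.
#' @export
write_contours_csv <- function(contours, path) {
  radii <- contour_radii_matrix(contours)
  n <- ncol(radii)
  angles <- if (inherits(contours, "vesicle_contours")) contours$angles
            else 2 * pi * (seq_len(n) - 1L) / n
  df <- data.frame(
    frame = rep(seq_len(nrow(radii)), each = n),
    angle_rad = rep(angles, nrow(radii)),
    radius_um = as.vector(t(radii)) * 1e6
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contours_csv
#' @export
read_contours_csv <- function(path) {
  df <- read.csv(path)
  need <- c("frame", "angle_rad", "radius_um")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop2("contour CSV is missing column(s): ", paste(miss, collapse = ", "))
  frames <- sort(unique(df$frame))
  df <- df[order(df$frame, df$angle_rad), ]
  n <- sum(df$frame == frames[1L])
  if (nrow(df) != n * length(frames))
    stop2("contour CSV frames have inconsistent point counts")
  radii <- matrix(df$radius_um * 1e-6, nrow = length(frames), ncol = n,
                  byrow = TRUE)
  structure(list(radii = radii, angles = df$angle_rad[seq_len(n)],
                 radius = mean(radii), temperature = NA_real_,
                 truth = NULL), class = "vesicle_contours")
}

#' Aspect-ratio trace CSV input and output
#'
#' Columns: `time_s`, then either `aspect` or the semi-axis pair
#' `a_um`, `b_um` (micrometres), plus `illumination` and `field_on`.
#'
#' @param trace An `aspect_trace` data frame.
#' @param path File path.
#' @return `read_trace_csv()` returns an `aspect_trace`;
#'   `write_trace_csv()` returns `path` invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  df <- data.frame(time_s = trace$time, aspect = trace$aspect,
                   illumination = trace$illumination,
                   field_on = trace$field_on)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- read.csv(path)
  if (!"time_s" %in% names(df))
    stop2("trace CSV is missing column: time_s")
  if (!"aspect" %in% names(df)) {
    if (all(c("a_um", "b_um") %in% names(df))) {
      df$aspect <- df$a_um / df$b_um
    } else stop2("trace CSV needs either 'aspect' or 'a_um' and 'b_um'")
  }
  if (is.null(df$illumination)) df$illumination <- "dark"
  if (is.null(df$field_on)) df$field_on <- TRUE
  aspect_trace(df$time_s, df$aspect, df$illumination, df$field_on)
}

#' Frequency-sweep CSV input and output
#'
#' Columns `frequency_hz`, `aspect_ratio`; per-vesicle metadata (radius and
#' conductivities) travels in a JSON sidecar or as function arguments.
#'
#' @param sweep A `frequency_sweep` data frame.
#' @param path File path.
#' @param radius,lambda_in,lambda_out Vesicle metadata attached on read
#'   (SI units).
#' @return `read_sweep_csv()` returns a `frequency_sweep`;
#'   `write_sweep_csv()` returns `path` invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  write.csv(data.frame(frequency_hz = sweep$frequency,
                       aspect_ratio = sweep$aspect),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sweep_csv
#' @export
read_sweep_csv <- function(path, radius = NA_real_, lambda_in = NA_real_,
                           lambda_out = NA_real_) {
  df <- read.csv(path)
  need <- c("frequency_hz", "aspect_ratio")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop2("sweep CSV is missing column(s): ", paste(miss, collapse = ", "))
  out <- data.frame(frequency = df$frequency_hz, aspect = df$aspect_ratio)
  attr(out, "radius") <- radius
  attr(out, "lambda_in") <- lambda_in
  attr(out, "lambda_out") <- lambda_out
  class(out) <- c("frequency_sweep", "data.frame")
  out
}

#' Height-map CSV input and output (Gwyddion-export style)
#'
#' Plain numeric matrix; the column separator (comma or semicolon) is
#' sniffed, lines starting with `#` are skipped. Heights are in nanometres
#' on disk by default (`units = "nm"`) and metres in memory.
#'
#' @param path File path.
#' @param units `"nm"` or `"m"`, the unit used in the file.
#' @param pixel_size Lateral pixel size (m) to attach.
#' @return `read_height_map_csv()` returns a `height_map`;
#'   `write_height_map_csv()` returns `path` invisibly.
#' @export
read_height_map_csv <- function(path, units = c("nm", "m"),
                                pixel_size = 40e-9) {
  units <- match.arg(units)
  lines <- readLines(path)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (!length(lines)) stop2("height-map CSV is empty")
  sep <- if (lengths(regmatches(lines[1L], gregexpr(";", lines[1L]))) >
             lengths(regmatches(lines[1L], gregexpr(",", lines[1L]))))
    ";" else ","
  rows <- strsplit(lines, sep, fixed = TRUE)
  ncols <- unique(lengths(rows))
  if (length(ncols) != 1L)
    stop2("height-map CSV rows have differing column counts (first bad line: ",
          which(lengths(rows) != lengths(rows)[1L])[1L], ")")
  m <- matrix(as.numeric(unlist(rows)), nrow = length(rows), byrow = TRUE)
  if (anyNA(m)) stop2("height-map CSV contains non-numeric entries")
  if (units == "nm") m <- m * 1e-9
  height_map(m, pixel_size = pixel_size)
}

#' @rdname read_height_map_csv
#' @param map A `height_map`.
#' @export
write_height_map_csv <- function(map, path, units = c("nm", "m")) {
  units <- match.arg(units)
  m <- map$heights
  if (units == "nm") m <- m * 1e9
  utils::write.table(m, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Tension-area CSV input
#'
#' Columns `area_nm2` (area per lipid, nm^2) and `tension_mN_per_m`;
#' converted to SI (m^2, N/m) on read.
#'
#' @param path File path.
#' @return Data frame with columns `area` and `tension` (SI).
#' @export
read_tension_area_csv <- function(path) {
  df <- read.csv(path)
  need <- c("area_nm2", "tension_mN_per_m")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop2("tension-area CSV is missing column(s): ",
          paste(miss, collapse = ", "))
  data.frame(area = df$area_nm2 * 1e-18, tension = df$tension_mN_per_m * 1e-3)
}

#' @rdname read_tension_area_csv
#' @param points Data frame with SI columns `area`, `tension`.
#' @export
write_tension_area_csv <- function(points, path) {
  write.csv(data.frame(area_nm2 = points$area * 1e18,
                       tension_mN_per_m = points$tension * 1e3),
            path, row.names = FALSE)
  invisible(path)
}
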