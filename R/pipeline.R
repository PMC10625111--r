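#' Pipeline configuration
#'
#' Flat key-value configuration shared by all pipeline commands. Defaults
#' mirror the experimental constants of the measurement protocols: room
#' temperature 296 K, water dielectric constant 80, crossover modes from 3,
#' AFM rejection thresholds 1 nm / 0.5 nm and a 10 x 10 smoothing window.
#'
#' @param temperature Temperature (K).
#' @param eps_water Relative dielectric constant of the aqueous phase.
#' @param q_min Smallest flicker mode used in the rigidity fit.
#' @param afm_reject AFM line-flattening rejection thresholds (m).
#' @param afm_window AFM smoothing window (pixels).
#' @param afm_bin AFM histogram bin width (m).
#' @param keep_rejected Keep results that fail quality control instead of
#'   flagging the run as failed.
#' @param ... Further per-command overrides stored verbatim.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(temperature = 296, eps_water = 80, q_min = 3,
                            afm_reject = c(1e-9, 0.5e-9), afm_window = 10L,
                            afm_bin = 0.05e-9, keep_rejected = FALSE, ...) {
  structure(list(temperature = temperature, eps_water = eps_water,
                 q_min = q_min, afm_reject = afm_reject,
                 afm_window = afm_window, afm_bin = afm_bin,
                 keep_rejected = keep_rejected, ...),
            class = "pipeline_config")
}

#' Run an analysis command end to end from files
#'
#' Orchestrates simulate -> analyze -> report chains over the CSV dialects
#' of the `read_*`/`write_*` helpers. Each report is a JSON file embedding
#' the configuration and package version used; reruns with the same inputs
#' and config are byte-identical (no timestamps). Unit-carrying key names
#' are used for every numeric result.
#'
#' Commands:
#' \describe{
#'   \item{`flicker`}{`input` = contour CSV; reports bending rigidity,
#'     tension and QC status.}
#'   \item{`kinetics`}{`input` = trace CSV; reports an exponential time
#'     constant per UV/blue epoch.}
#'   \item{`capacitance`}{`input` = CSV with columns `vesicle`,
#'     `frequency_hz`, `aspect_ratio`, `radius_um`; `lambda_in`, `ratio`
#'     and optionally `thickness_nm` come via `...`; reports the fitted
#'     specific capacitance and, when a thickness is given, the full
#'     dielectric chain.}
#'   \item{`afm`}{`input` = height-map CSV (nm); optional `crop =
#'     c(row0, row1, col0, col1)`; reports the bilayer thickness.}
#'   \item{`mechanics`}{`input` = tension-area CSV; reports the stretching
#'     modulus.}
#' }
#'
#' @param command One of `"flicker"`, `"kinetics"`, `"capacitance"`,
#'   `"afm"`, `"mechanics"`.
#' @param input Path to the input CSV.
#' @param out_dir Output directory; created if missing. The report is
#'   written to `<out_dir>/<command>/report.json`.
#' @param config A [pipeline_config()].
#' @param ... Command-specific parameters (see Details).
#' @return The report list, invisibly; `status` is `"ok"` or `"qc_reject"`.
#' @export
run_pipeline <- function(command = c("flicker", "kinetics", "capacitance",
                                     "afm", "mechanics"),
                         input, out_dir = "out",
                         config = pipeline_config(), ...) {
  command <- match.arg(command)
  if (!file.exists(input)) stop2("input file not found: ", input)
  extra <- list(...)
  report <- switch(command,
    flicker = {
      contours <- read_contours_csv(input)
      sp <- compute_spectrum(contours)
      fit <- fit_helfrich(sp, temperature = config$temperature,
                          q_min = config$q_min)
      qc <- qc_filter(fit, defect = isTRUE(extra$defect))
      list(kappa_J = fit$kappa, kappa_kBT = fit$kappa_kBT,
           kappa_se_J = fit$kappa_se, sigma_N_per_m = fit$sigma,
           sigma_se_N_per_m = fit$sigma_se,
           mean_radius_um = fit$mean_radius * 1e6,
           q_range = c(fit$q_min, fit$q_max), n_frames = fit$n_frames,
           qc_accept = qc$accept, qc_reason = qc$reason,
           status = if (qc$accept || config$keep_rejected) "ok"
                    else "qc_reject")
    },
    kinetics = {
      trace <- read_trace_csv(input)
      eps <- segment_epochs(trace)
      lit <- eps[eps$label %in% c("UV", "blue") &
                   (eps$i_end - eps$i_start + 1L) >= 20L, ]
      fits <- lapply(seq_len(nrow(lit)), function(i)
        fit_relaxation(trace, epoch = which(eps$label == lit$label[i] &
                                              eps$start == lit$start[i])))
      list(epochs = lapply(seq_len(nrow(lit)), function(i) list(
        label = lit$label[i], t_start_s = lit$start[i],
        tau_s = fits[[i]]$tau, tau_se_s = fits[[i]]$tau_se,
        amplitude = fits[[i]]$amplitude, flat = fits[[i]]$flat)),
        status = "ok")
    },
    capacitance = {
      df <- read.csv(input)
      need <- c("vesicle", "frequency_hz", "aspect_ratio", "radius_um")
      miss <- setdiff(need, names(df))
      if (length(miss))
        stop2("capacitance CSV is missing column(s): ",
              paste(miss, collapse = ", "))
      if (is.null(extra$lambda_in) || is.null(extra$ratio))
        stop2("capacitance command needs lambda_in (S/m) and ratio")
      pts <- do.call(rbind, lapply(split(df, df$vesicle), function(d) {
        sw <- data.frame(frequency = d$frequency_hz,
                         aspect = d$aspect_ratio)
        class(sw) <- c("frequency_sweep", "data.frame")
        data.frame(radius = d$radius_um[1L] * 1e-6,
                   fc = detect_critical_frequency(sw))
      }))
      fit <- fit_specific_capacitance(pts, extra$lambda_in, extra$ratio)
      rep <- list(cm_uF_per_cm2 = fit$cm * 1e2,
                  cm_se_uF_per_cm2 = fit$cm_se * 1e2,
                  n_vesicles = fit$n_vesicles, status = "ok")
      if (!is.null(extra$thickness_nm)) {
        cd_in <- extra$cd_in %||%
          double_layer_capacitance(debye_length(0.3, config$temperature,
                                                config$eps_water),
                                   config$eps_water)
        cd_out <- extra$cd_out %||%
          double_layer_capacitance(debye_length(0.6, config$temperature,
                                                config$eps_water),
                                   config$eps_water)
        cs <- capacitance_set(fit$cm, cd_in, cd_out,
                              extra$thickness_nm * 1e-9, config$eps_water)
        rep$cb_uF_per_cm2 <- cs$cb * 1e2
        rep$eps_membrane <- cs$eps_membrane
      }
      rep
    },
    afm = {
      hm <- read_height_map_csv(input)
      flat <- flatten_height_map(hm, reject = config$afm_reject)
      sm <- smooth_height_map(flat, window = config$afm_window)
      res <- patch_thickness(sm, crop = extra$crop,
                             bin_width = config$afm_bin)
      list(thickness_nm = res$thickness * 1e9,
           substrate_peak_nm = res$substrate_peak * 1e9,
           patch_peak_nm = res$patch_peak * 1e9,
           n_pixels_patch = res$n_pixels_patch, status = "ok")
    },
    mechanics = {
      pts <- read_tension_area_csv(input)
      fit <- fit_stretching_modulus(pts)
      list(k_a_mN_per_m = fit$k_a * 1e3, k_a_se_mN_per_m = fit$k_a_se * 1e3,
           a0_nm2 = fit$a0 * 1e18, status = "ok")
    })

  report$command <- command
  report$input <- basename(input)
  report$config <- unclass(config)
  report$package_version <- as.character(utils::packageVersion("photomem"))
  dir <- file.path(out_dir, command)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
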