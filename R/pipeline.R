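#' Demonstration pipeline configuration
#'
#' A fully synthetic run: one sinusoidal departure rendered to video, a
#' checkerboard calibration with mild corner noise, tracking with the default
#' tracker, rectification, jump flagging, Kalman smoothing, path-shape
#' metrics, body-to-burrow angles under the illustrative eye compass, and a
#' PERMANOVA over a simulated three-excursion descriptor table.
#'
#' @param outdir output directory for artifacts.
#' @param seed global seed; every stage derives its own sub-seed from it.
#' @return a nested configuration list accepted by [run_pipeline()].
#' @export
demo_config <- function(outdir = tempfile("spiderwalk_demo_"), seed = 1) {
  list(
    seed = seed,
    outdir = outdir,
    simulate = list(
      wavelength = 50, amplitude = 20, axial_speed = 10, duration = 15,
      axis_heading = 20, start = c(30, 0), path_noise_sd = 0,
      px_per_cm = 2.5, margin_px = 60,
      scene = list()                      # scene_spec() overrides
    ),
    tracker = list(),                     # tracker_config() overrides
    calibration = list(corner_noise_sd = 0.2),
    cleaning = list(),                    # cleaning_config() overrides
    kalman = list(),                      # kalman_config() overrides
    geometry = list(stillness_speed = 0.5, full_period = TRUE),
    eyes = list(model = "default"),
    stats = list(
      n_perm = 9951,
      simulate_descriptors = list(
        ## three excursion groups; consecutive departures straighten
        ## (longer wavelengths), amplitudes stay comparable
        groups = list(
          list(excursion = 1, n = 8, wavelength = 45, amplitude = 20),
          list(excursion = 2, n = 6, wavelength = 80, amplitude = 18),
          list(excursion = 3, n = 4, wavelength = 130, amplitude = 19)
        ),
        rel_sd = 0.15
      )
    )
  )
}

pipeline_fail <- function(stage, fmt, ...) {
  stop(sprintf("[stage %s] %s", stage, sprintf(fmt, ...)), call. = FALSE)
}

#' Run the full measurement pipeline
#'
#' Executes track -> calibrate/rectify -> clean -> smooth -> geometry ->
#' eye fields -> stats on the configured inputs, writing every intermediate
#' as CSV/JSON into `config$outdir`. Deterministic given the configured
#' seeds. Configuration may be a nested list (see [demo_config()]) or the
#' path of a YAML file with the same structure. Referenced files are
#' validated before any computation starts.
#'
#' @param config nested list or YAML file path.
#' @return a `run_report` list: per-stage parameter echo, sample counts,
#'   warnings, artifact paths; also written to `outdir/report.json`.
#' @export
run_pipeline <- function(config = demo_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  t_start <- proc.time()[["elapsed"]]
  seed <- config$seed %||% 1
  outdir <- config$outdir %||% tempfile("spiderwalk_run_")

  ## ---- validation before any computation ----
  eye_model_path <- config$eyes$model %||% "default"
  if (!identical(eye_model_path, "default") && !file.exists(eye_model_path)) {
    pipeline_fail("validate", "eye model file not found: %s", eye_model_path)
  }
  for (f in c(config$video, config$calibration$corners, config$stats$table)) {
    if (!is.null(f) && !file.exists(f)) {
      pipeline_fail("validate", "input file not found: %s", f)
    }
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  report <- list(seed = seed, outdir = outdir, stages = list(),
                 warnings = character(0), artifacts = character(0))
  add_artifact <- function(p) report$artifacts <<- c(report$artifacts, p)

  ## ---- simulate ----
  truth <- NULL; calib_true <- NULL; stack <- NULL; init_px <- NULL
  burrow_px <- config$calibration$burrow_px
  if (!is.null(config$simulate)) {
    sc <- config$simulate
    truth <- gen_sinusoidal_path(
      wavelength = sc$wavelength %||% 50, amplitude = sc$amplitude %||% 20,
      axial_speed = sc$axial_speed %||% 10, duration = sc$duration %||% 15,
      frame_rate = sc$frame_rate %||% 25,
      axis_heading = sc$axis_heading %||% 0,
      start = sc$start %||% c(30, 0), noise_sd = sc$path_noise_sd %||% 0,
      seed = seed)
    geomfit <- calibration_for_path(truth, px_per_cm = sc$px_per_cm %||% 2.5,
                                    margin_px = sc$margin_px %||% 60)
    calib_true <- geomfit$calib
    spec <- do.call(scene_spec, modifyList(
      list(frame_size = geomfit$frame_size, seed = seed + 1L),
      sc$scene %||% list()))
    stack <- render_video(truth, calib_true, spec)
    init_px <- ground_to_pixels(truth[1, c("x_cm", "y_cm")], calib_true)[1, ]
    burrow_px <- ground_to_pixels(matrix(attr(truth, "params")$burrow, 1, 2),
                                  calib_true)[1, ]
    write_track(truth, file.path(outdir, "truth.csv"))
    add_artifact(file.path(outdir, "truth.csv"))
    report$stages$simulate <- list(
      params = attr(truth, "params")[c("wavelength", "amplitude",
                                       "axial_speed", "duration",
                                       "frame_rate", "axis_heading")],
      scene = unclass(spec)[c("frame_size", "background_level",
                              "blob_contrast", "blob_radius", "noise_sd",
                              "vignette_strength")],
      n_frames = length(stack$timestamps))
  } else {
    if (is.null(config$video)) {
      pipeline_fail("track", "no video input and no simulate section")
    }
    stack <- read_frames(config$video)
    init_px <- config$tracker$init_position
    if (is.null(init_px)) pipeline_fail("track", "tracker$init_position required")
    if (is.null(burrow_px)) {
      pipeline_fail("rectify", "calibration$burrow_px required")
    }
  }

  ## ---- track ----
  tcfg <- do.call(tracker_config, config$tracker[setdiff(names(config$tracker),
                                                         "init_position")] %||%
                    list())
  ptrack <- track_video(stack, init_px, tcfg)
  write_track(ptrack, file.path(outdir, "track_px.csv"))
  add_artifact(file.path(outdir, "track_px.csv"))
  trep <- attr(ptrack, "report")
  report$stages$track <- list(config = trep$config, n_frames = trep$n_frames,
                              n_detected = trep$n_detected,
                              n_gaps = length(attr(ptrack, "gaps")))
  if (!is.null(truth)) {
    tp <- ground_to_pixels(as.matrix(truth[, c("x_cm", "y_cm")]), calib_true)
    ok <- !is.na(ptrack$x_px)
    report$stages$track$rmse_px <- sqrt(mean(
      (ptrack$x_px[ok] - tp[ok, 1])^2 + (ptrack$y_px[ok] - tp[ok, 2])^2))
  }

  ## ---- calibrate ----
  if (!is.null(config$calibration$corners)) {
    corners <- read.csv(config$calibration$corners)
  } else {
    board <- render_checkerboard(
      squares_per_side = config$calibration$squares_per_side %||% 9,
      square_size = config$calibration$square_size %||% (100 / 9),
      homography = calib_true$H,
      corner_noise_sd = config$calibration$corner_noise_sd %||% 0.2,
      seed = seed + 2L)
    corners <- board$correspondences
  }
  calib <- estimate_homography(corners,
                               refine_distortion =
                                 isTRUE(config$calibration$refine_distortion))
  write_calibration(calib, file.path(outdir, "calib.json"))
  add_artifact(file.path(outdir, "calib.json"))
  report$stages$calibrate <- list(n_corners = nrow(corners),
                                  rms_error_px = calib$rms_error,
                                  k1 = calib$k1)

  ## ---- rectify ----
  gtrack <- pixels_to_ground(ptrack, calib, burrow_px,
                             direction_label = "departure",
                             excursion_number = 1L)
  write_track(gtrack, file.path(outdir, "track_ground.csv"))
  add_artifact(file.path(outdir, "track_ground.csv"))
  report$stages$rectify <- list(burrow_px = as.numeric(burrow_px),
                                n_samples = nrow(gtrack))

  ## ---- clean ----
  ccfg <- do.call(cleaning_config, config$cleaning %||% list())
  flags <- flag_jumps(gtrack, ccfg)
  clean <- gtrack
  if (length(flags)) clean[flags, c("x_cm", "y_cm")] <- NA
  report$stages$clean <- list(config = unclass(ccfg), n_flagged = length(flags),
                              flagged = as.integer(flags))

  ## ---- smooth ----
  kcfg <- do.call(kalman_config, config$kalman %||% list())
  smooth <- kalman_smooth(clean, kcfg)
  write_track(smooth, file.path(outdir, "track_smooth.csv"))
  add_artifact(file.path(outdir, "track_smooth.csv"))
  report$stages$smooth <- list(model = attr(smooth, "model"),
                               n_imputed = sum(smooth$imputed))

  ## ---- geometry ----
  gcfg <- config$geometry %||% list()
  metrics <- extract_sinusoid_metrics(smooth,
                                      full_period = gcfg$full_period %||% TRUE)
  summ <- excursion_summary(smooth,
                            stillness_speed = gcfg$stillness_speed %||% 0.5,
                            direction_label = "departure",
                            excursion_number = 1L)
  dep <- departure_rate(smooth)
  ray <- fit_rayleigh(track_speeds(smooth))
  jsonlite::write_json(list(
    sinusoidal = metrics$sinusoidal,
    mean_wavelength_cm = metrics$mean_wavelength,
    mean_amplitude_cm = metrics$mean_amplitude,
    wavelengths_cm = metrics$wavelengths, amplitudes_cm = metrics$amplitudes,
    axis_heading_deg = metrics$axis$heading_deg,
    departure_rate_cm_s = dep$slope_cm_s,
    rayleigh = list(sigma = ray$sigma, mean = ray$mean,
                    variance = ray$variance, n = ray$n)
  ), file.path(outdir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  add_artifact(file.path(outdir, "metrics.json"))
  write_summary_table(summ, file.path(outdir, "summary.csv"))
  add_artifact(file.path(outdir, "summary.csv"))
  report$stages$geometry <- list(
    config = gcfg, sinusoidal = metrics$sinusoidal,
    mean_wavelength_cm = metrics$mean_wavelength,
    mean_amplitude_cm = metrics$mean_amplitude,
    departure_rate_cm_s = dep$slope_cm_s,
    rayleigh_mean_cm_s = ray$mean)

  ## ---- eye fields ----
  model <- if (identical(eye_model_path, "default")) {
    default_eye_model()
  } else {
    read_eye_model(eye_model_path)
  }
  aseries <- eyes_along_track(alpha_series(smooth), model)
  write_csv_stable(aseries, file.path(outdir, "alpha.csv"))
  add_artifact(file.path(outdir, "alpha.csv"))
  asum <- circular_summary(aseries$abs_alpha_deg, seed = seed + 3L)
  report$stages$eye_fields <- list(
    model = if (identical(eye_model_path, "default")) "default (illustrative)"
            else eye_model_path,
    n_steps = nrow(aseries), mean_abs_alpha_deg = asum$mean_deg,
    ci_deg = asum$ci)

  ## ---- stats ----
  if (!is.null(config$stats)) {
    st <- config$stats
    if (!is.null(st$table)) {
      dtab <- read.csv(st$table)
    } else if (!is.null(st$simulate_descriptors)) {
      sd_cfg <- st$simulate_descriptors
      dtab <- do.call(rbind, lapply(sd_cfg$groups, function(gr) {
        mult <- with_seed_opt(seed + 10L + gr$excursion,
                              matrix(rnorm(2 * gr$n, 1, sd_cfg$rel_sd %||% 0.15),
                                     ncol = 2))
        data.frame(excursion_number = gr$excursion,
                   mean_wavelength_cm = gr$wavelength * abs(mult[, 1]),
                   mean_amplitude_cm = gr$amplitude * abs(mult[, 2]))
      }))
      dtab$departure_id <- seq_len(nrow(dtab))
      write_csv_stable(dtab, file.path(outdir, "descriptors.csv"))
      add_artifact(file.path(outdir, "descriptors.csv"))
    } else {
      dtab <- NULL
    }
    if (!is.null(dtab)) {
      pr <- permanova_descriptors(dtab, n_perm = st$n_perm %||% 9951,
                                  seed = seed + 20L)
      jsonlite::write_json(list(
        pseudo_F = pr$pseudo_F, p_value = pr$p_value,
        n_permutations_used = pr$n_permutations_used, exact = pr$exact,
        ss_between = pr$ss_between, ss_within = pr$ss_within
      ), file.path(outdir, "permanova.json"), auto_unbox = TRUE, digits = NA)
      add_artifact(file.path(outdir, "permanova.json"))
      report$stages$stats <- list(n_perm = st$n_perm %||% 9951,
                                  n_rows = nrow(dtab),
                                  pseudo_F = pr$pseudo_F, p_value = pr$p_value)
    }
  }

  report$elapsed_s <- proc.time()[["elapsed"]] - t_start
  class(report) <- "run_report"
  jsonlite::write_json(unclass(report), file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("spiderwalk pipeline run\n")
  cat(sprintf("  output: %s\n  stages: %s\n", x$outdir,
              paste(names(x$stages), collapse = " -> ")))
  if (!is.null(x$stages$track$rmse_px)) {
    cat(sprintf("  tracker RMSE vs truth: %.3f px\n", x$stages$track$rmse_px))
  }
  if (!is.null(x$stages$geometry)) {
    cat(sprintf("  mean wavelength %.2f cm, mean amplitude %.2f cm\n",
                x$stages$geometry$mean_wavelength_cm,
                x$stages$geometry$mean_amplitude_cm))
  }
  if (!is.null(x$stages$stats)) {
    cat(sprintf("  PERMANOVA pseudo-F = %.3f, p = %.4g\n",
                x$stages$stats$pseudo_F, x$stages$stats$p_value))
  }
  invisible(x)
}
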