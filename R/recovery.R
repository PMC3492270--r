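#' End-to-end recovery of path-shape parameters from synthetic video
#'
#' The full validation loop for the measurement pipeline: generate a
#' ground-truth sinusoidal departure, render it to a noisy vignetted frame
#' stack, track the blob, calibrate from a synthetic checkerboard imaged
#' under the same homography (with realistic corner noise), rectify to
#' burrow-centred ground coordinates, Kalman-smooth, and extract the
#' wavelength/amplitude descriptors — then compare against the generative
#' truth.
#'
#' @param wavelength,amplitude generative sinusoid parameters (cm).
#' @param axial_speed speed along the departure axis (cm/s).
#' @param n_cycles number of full oscillation cycles to simulate.
#' @param seed integer seed driving every stochastic stage of the run.
#' @param axis_heading departure axis heading (degrees).
#' @param px_per_cm rendering scale.
#' @param corner_noise_sd checkerboard corner noise (px).
#' @param scene named list of [scene_spec()] overrides.
#' @return list with `wavelength_hat`, `amplitude_hat`, `rel_err_wavelength`,
#'   `rel_err_amplitude`, `rmse_px` (tracker error against projected truth),
#'   `coverage` (fraction of frames with a detection) and `n_frames`.
#' @export
simulate_and_recover <- function(wavelength, amplitude, axial_speed = 10,
                                 n_cycles = 3, seed = 1, axis_heading = 15,
                                 px_per_cm = 2.5, corner_noise_sd = 0.2,
                                 scene = list()) {
  duration <- (n_cycles + 0.2) * wavelength / axial_speed
  truth <- gen_sinusoidal_path(wavelength, amplitude, axial_speed, duration,
                               axis_heading = axis_heading, start = c(30, 0),
                               noise_sd = 0, seed = seed)
  geom <- calibration_for_path(truth, px_per_cm = px_per_cm)
  spec <- do.call(scene_spec, modifyList(
    list(frame_size = geom$frame_size, seed = seed), scene))
  stack <- render_provider(truth, geom$calib, spec)  # lazy: frames on demand
  truth_px <- ground_to_pixels(as.matrix(truth[, c("x_cm", "y_cm")]),
                               geom$calib)
  ptrack <- track_video(stack, truth_px[1, ])
  ok <- !is.na(ptrack$x_px)
  rmse_px <- sqrt(mean((ptrack$x_px[ok] - truth_px[ok, 1])^2 +
                         (ptrack$y_px[ok] - truth_px[ok, 2])^2))

  board <- render_checkerboard(9, 100 / 9, geom$calib$H,
                               corner_noise_sd = corner_noise_sd,
                               seed = seed + 1L)
  calib <- estimate_homography(board$correspondences)
  burrow_px <- ground_to_pixels(matrix(c(0, 0), 1, 2), geom$calib)[1, ]
  gtrack <- pixels_to_ground(ptrack, calib, burrow_px)
  smooth <- kalman_smooth(gtrack)
  m <- extract_sinusoid_metrics(smooth)
  list(
    wavelength = wavelength, amplitude = amplitude, seed = seed,
    n_frames = nrow(ptrack), coverage = mean(ok), rmse_px = rmse_px,
    sinusoidal = m$sinusoidal,
    wavelength_hat = m$mean_wavelength, amplitude_hat = m$mean_amplitude,
    rel_err_wavelength = abs(m$mean_wavelength / wavelength - 1),
    rel_err_amplitude = abs(m$mean_amplitude / amplitude - 1)
  )
}
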