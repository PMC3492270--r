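#' Generate a ground-truth sinusoidal departure path
#'
#' Simulates a spider leaving its burrow along a straight departure axis while
#' oscillating laterally, the path shape reported for naive burrow departures:
#' p(t) = start + s*t*u + A*sin(2*pi*s*t/lambda)*n + noise, where u is the unit
#' vector of the departure axis, n its left normal, s the axial speed, lambda
#' the wavelength and A the amplitude of the sinusoid.
#'
#' @param wavelength wavelength lambda of the sinusoid along the axis (cm), > 0.
#' @param amplitude peak lateral deviation A from the axis (cm), >= 0.
#' @param axial_speed speed of progression along the axis (cm/s).
#' @param duration total duration of the path (s), > 0.
#' @param frame_rate sampling rate (Hz), > 0. Default 25, a 25-frame batch = 1 s.
#' @param axis_heading heading of the departure axis (degrees, 0 = +x east,
#'   counter-clockwise positive).
#' @param start starting position `c(x, y)` in cm (burrow-centred frame).
#' @param noise_sd iid Gaussian positional noise per coordinate (cm).
#' @param seed integer seed; all randomness is local to the call.
#' @param burrow burrow position `c(x, y)` in cm (metadata; origin by default).
#' @return A `path_truth` object: data.frame with columns `t_s`, `x_cm`, `y_cm`
#'   and the generative parameters stored as attributes (`params`).
#' @examples
#' p <- gen_sinusoidal_path(50, 20, 10, duration = 15, noise_sd = 0)
#' head(p)
#' @export
gen_sinusoidal_path <- function(wavelength, amplitude, axial_speed, duration,
                                frame_rate = 25, axis_heading = 0,
                                start = c(0, 0), noise_sd = 0, seed = NULL,
                                burrow = c(0, 0)) {
  if (wavelength <= 0) stopf("wavelength must be > 0 (got %g)", wavelength)
  if (amplitude < 0) stopf("amplitude must be >= 0 (got %g)", amplitude)
  if (duration <= 0) stopf("duration must be > 0 (got %g)", duration)
  if (frame_rate <= 0) stopf("frame_rate must be > 0 (got %g)", frame_rate)
  t <- seq(0, duration, by = 1 / frame_rate)
  h <- deg2rad(axis_heading)
  u <- c(cos(h), sin(h))
  nrm <- c(-sin(h), cos(h))                      # left normal of the axis
  s_along <- axial_speed * t
  d_lat <- amplitude * sin(2 * pi * s_along / wavelength)
  x <- start[1] + s_along * u[1] + d_lat * nrm[1]
  y <- start[2] + s_along * u[2] + d_lat * nrm[2]
  if (noise_sd > 0) {
    eps <- with_seed_opt(seed, matrix(rnorm(2 * length(t), 0, noise_sd), ncol = 2))
    x <- x + eps[, 1]
    y <- y + eps[, 2]
  }
  out <- data.frame(t_s = t, x_cm = x, y_cm = y)
  attr(out, "params") <- list(
    wavelength = wavelength, amplitude = amplitude, axial_speed = axial_speed,
    duration = duration, frame_rate = frame_rate, axis_heading = axis_heading,
    start = start, noise_sd = noise_sd, seed = seed, burrow = burrow
  )
  class(out) <- c("path_truth", "ground_track", "data.frame")
  out
}

#' Analytic arc length of a noiseless sinusoidal path
#'
#' Numerically integrates sqrt(|p'(t)|^2) for the closed-form path generated by
#' [gen_sinusoidal_path()] with `noise_sd = 0`; used as an independent oracle
#' for path-length summaries.
#'
#' @param truth a `path_truth` object (its stored parameters are used).
#' @param n_quad number of integration subintervals.
#' @return arc length in cm over the path's duration.
#' @export
sinusoid_arc_length <- function(truth, n_quad = 20000L) {
  p <- attr(truth, "params")
  s <- p$axial_speed
  w <- 2 * pi * s / p$wavelength
  speed_fun <- function(t) sqrt(s^2 + (p$amplitude * w * cos(w * t))^2)
  ## Simpson's rule
  tt <- seq(0, p$duration, length.out = 2L * n_quad + 1L)
  f <- speed_fun(tt)
  h <- tt[2] - tt[1]
  h / 3 * (f[1] + f[length(f)] +
             4 * sum(f[seq(2, length(f) - 1, by = 2)]) +
             2 * sum(f[seq(3, length(f) - 2, by = 2)]))
}

#' Draw frame-wise walking speeds from a Rayleigh distribution
#'
#' Frame-to-frame walking speeds are modelled as Rayleigh(sigma): the norm of a
#' 2-D isotropic Gaussian step. The sample mean converges to sigma*sqrt(pi/2).
#'
#' @param sigma Rayleigh scale parameter (cm/s), > 0.
#' @param n number of draws, >= 1.
#' @param seed integer seed.
#' @return numeric vector of `n` non-negative speeds (cm/s).
#' @export
gen_speed_samples <- function(sigma, n, seed = NULL) {
  if (sigma <= 0) stopf("sigma must be > 0 (got %g)", sigma)
  if (n < 1) stopf("n must be >= 1 (got %g)", n)
  with_seed_opt(seed, sigma * sqrt(-2 * log(runif(n))))
}
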