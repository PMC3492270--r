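test_that("collinear points give the exact axis direction", {
  tr <- data.frame(t_s = 0:10 / 25, x_cm = 0:10, y_cm = 0:10)
  ax <- fit_axis(tr)
  expect_equal(ax$direction, c(sqrt(2) / 2, sqrt(2) / 2), tolerance = 1e-9)
  expect_equal(ax$heading_deg, 45)
  same <- data.frame(t_s = 0:3 / 25, x_cm = rep(1, 4), y_cm = rep(2, 4))
  expect_error(fit_axis(same), "coincident")
})

test_that("a three-cycle sinusoid's axis is recovered to well under half a degree", {
  p <- gen_sinusoidal_path(50, 20, 10, duration = 15, noise_sd = 0)
  expect_lt(abs(fit_axis(p)$heading_deg), 0.5)
})

test_that("rotating the input rotates the fitted axis equivariantly", {
  p <- gen_sinusoidal_path(50, 20, 10, duration = 15, noise_sd = 0)
  for (theta in c(30, 120, 250)) {
    rot <- transform_track(p, theta)
    expect_equal(norm_angle_deg(fit_axis(rot)$heading_deg - theta), 0,
                 tolerance = 1e-6)
  }
})

test_that("noiseless sinusoid metrics recover the generative parameters", {
  p <- gen_sinusoidal_path(50, 20, 10, duration = 15, frame_rate = 25,
                           noise_sd = 0)
  m <- extract_sinusoid_metrics(p)
  expect_true(m$sinusoidal)
  expect_lt(abs(m$mean_wavelength / 50 - 1), 0.01)
  expect_lt(abs(m$mean_amplitude / 20 - 1), 0.01)
})

test_that("recovered means stay within 2% over a wavelength/amplitude grid", {
  for (lam in c(20, 50, 100)) {
    for (amp in c(5, 20, 40)) {
      p <- gen_sinusoidal_path(lam, amp, 10, duration = 3.2 * lam / 10,
                               noise_sd = 0)
      m <- extract_sinusoid_metrics(p)
      expect_lt(abs(m$mean_wavelength / lam - 1), 0.02)
      expect_lt(abs(m$mean_amplitude / amp - 1), 0.02)
    }
  }
})

test_that("a straight path is reported as not sinusoidal", {
  p <- gen_sinusoidal_path(50, 0, 10, duration = 10, noise_sd = 0)
  m <- extract_sinusoid_metrics(p)
  expect_false(m$sinusoidal)
  expect_length(m$wavelengths, 0)
  expect_true(is.na(m$mean_wavelength))
})

test_that("median wavelength recovery under positional noise is within 5%", {
  lams <- vapply(1:20, function(s) {
    p <- gen_sinusoidal_path(50, 20, 10, duration = 15, noise_sd = 1, seed = s)
    extract_sinusoid_metrics(p)$mean_wavelength
  }, numeric(1))
  expect_lt(abs(median(lams) / 50 - 1), 0.05)
})

test_that("shape metrics are invariant under rigid motions", {
  p <- gen_sinusoidal_path(50, 20, 10, duration = 15, noise_sd = 1, seed = 2)
  m0 <- extract_sinusoid_metrics(p)
  mt <- extract_sinusoid_metrics(transform_track(p, 73, c(40, -17)))
  expect_equal(mt$wavelengths, m0$wavelengths, tolerance = 1e-9)
  expect_equal(mt$amplitudes, m0$amplitudes, tolerance = 1e-9)
  s0 <- excursion_summary(p)
  st <- excursion_summary(transform_track(p, 73, c(40, -17)))
  expect_equal(st$path_length_cm, s0$path_length_cm, tolerance = 1e-9)
  expect_equal(st$duration_s, s0$duration_s)
})

test_that("excursion summary arithmetic: square circuit and pause", {
  ## square of side 25 cm traversed in 10 s
  corners <- rbind(c(0, 0), c(25, 0), c(25, 25), c(0, 25), c(0, 0))
  seg <- 100L
  path <- do.call(rbind, lapply(1:4, function(i) {
    f <- seq(0, 1, length.out = seg + 1)[-(seg + 1)]
    cbind(corners[i, 1] + f * (corners[i + 1, 1] - corners[i, 1]),
          corners[i, 2] + f * (corners[i + 1, 2] - corners[i, 2]))
  }))
  path <- rbind(path, c(0, 0))
  t <- seq(0, 10, length.out = nrow(path))
  tr <- data.frame(t_s = t, x_cm = path[, 1], y_cm = path[, 2])
  s <- excursion_summary(tr)
  expect_equal(s$path_length_cm, 100, tolerance = 1e-9)
  expect_equal(s$duration_s, 10)
  expect_equal(s$mean_speed_cm_s, 10, tolerance = 1e-9)

  ## + 5 s stationary hold: mean speed drops, moving speed unchanged
  hold_t <- seq(10 + 0.025, 15, by = 0.025)
  tr2 <- rbind(tr, data.frame(t_s = hold_t, x_cm = 0, y_cm = 0))
  s2 <- excursion_summary(tr2)
  expect_equal(s2$mean_speed_cm_s, 100 / 15, tolerance = 1e-9)
  expect_equal(s2$mean_speed_moving_cm_s, 10, tolerance = 1e-3)
  ## identity: mean_speed * duration = path_length
  expect_equal(s2$mean_speed_cm_s * s2$duration_s, s2$path_length_cm,
               tolerance = 1e-9)
})

test_that("summary path length matches the analytic arc length", {
  p <- gen_sinusoidal_path(50, 20, 10, duration = 15, frame_rate = 100,
                           noise_sd = 0)
  s <- excursion_summary(p, stillness_speed = 0)
  expect_lt(abs(s$path_length_cm / sinusoid_arc_length(p) - 1), 0.005)
})

test_that("departure rate recovers radial and sinusoidal rates", {
  t <- seq(0, 20, by = 0.04)
  rad <- data.frame(t_s = t, x_cm = 5 + 8 * t * cos(0.3),
                    y_cm = 2 + 8 * t * sin(0.3))
  dr <- departure_rate(rad, burrow = c(5, 2))
  expect_equal(dr$slope_cm_s, 8, tolerance = 0.01)

  still <- data.frame(t_s = t, x_cm = rep(10, length(t)),
                      y_cm = rep(-4, length(t)))
  expect_equal(departure_rate(still)$slope_cm_s, 0, tolerance = 1e-9)

  p <- gen_sinusoidal_path(50, 20, 10, duration = 17, start = c(30, 0),
                           noise_sd = 0)
  keep <- p[sqrt(p$x_cm^2 + p$y_cm^2) <= 200, ]
  dp <- departure_rate(keep, burrow = c(0, 0))
  expect_lt(abs(dp$slope_cm_s / 10 - 1), 0.10)
  expect_error(departure_rate(rad[c(1, 1, 1), ]), "time")
})

test_that("Rayleigh MLE and moment identities hold", {
  ## the reported mean/variance pairing: mean 9.6 implies variance 25.2
  rf <- rayleigh_from_mean(9.6)
  expect_equal(round(rf$variance, 1), 25.2)
  ## closed-form moments at sigma = 1
  r1 <- fit_rayleigh(gen_speed_samples(1, 1e5, seed = 3))
  expect_equal(r1$mean / (sqrt(pi / 2) * r1$sigma), 1)
  expect_equal(r1$variance, (4 - pi) * r1$sigma^2 / 2)
  an <- rayleigh_from_mean(1.2533)
  expect_equal(an$sigma, 1, tolerance = 1e-4)
  expect_equal(an$variance, 0.4292, tolerance = 1e-3)
  ## seeded MLE recovery
  rhat <- fit_rayleigh(gen_speed_samples(7.66, 1e5, seed = 4))
  expect_lt(abs(rhat$sigma / 7.66 - 1), 0.01)
  expect_error(fit_rayleigh(c(-1, 2)), ">= 0")
})

test_that("Rayleigh MLE agrees with an independent distribution fitter", {
  v <- gen_speed_samples(7.66, 5000, seed = 5)
  ours <- fit_rayleigh(v)
  ## Rayleigh(sigma) == Weibull(shape 2, scale sigma*sqrt(2))
  wb <- fitdistrplus::fitdist(v, "weibull", fix.arg = list(shape = 2),
                              start = list(scale = 10))
  expect_equal(ours$sigma, unname(wb$estimate["scale"]) / sqrt(2),
               tolerance = 1e-3)
})
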