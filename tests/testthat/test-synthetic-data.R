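test_that("noiseless sinusoidal path follows its closed form", {
  p <- gen_sinusoidal_path(50, 20, 10, duration = 15, frame_rate = 25,
                           axis_heading = 30, start = c(5, -3), noise_sd = 0)
  t <- p$t_s
  h <- 30 * pi / 180
  u <- c(cos(h), sin(h)); nv <- c(-sin(h), cos(h))
  x_exp <- 5 + 10 * t * u[1] + 20 * sin(2 * pi * 10 * t / 50) * nv[1]
  y_exp <- -3 + 10 * t * u[2] + 20 * sin(2 * pi * 10 * t / 50) * nv[2]
  expect_lt(max(abs(p$x_cm - x_exp)), 1e-9)
  expect_lt(max(abs(p$y_cm - y_exp)), 1e-9)
})

test_that("lateral deviation attains the amplitude twice per period", {
  ## frame rate chosen so the quarter-period instants land on samples
  p <- gen_sinusoidal_path(50, 20, 10, duration = 5, frame_rate = 20,
                           noise_sd = 0)
  d <- p$y_cm            # axis along x: deviation is y
  expect_equal(max(d), 20)
  expect_equal(min(d), -20)
  expect_equal(sum(abs(abs(d) - 20) < 1e-12), 2)  # one peak, one trough per 5 s
})

test_that("zero amplitude gives collinear points along the heading", {
  p <- gen_sinusoidal_path(50, 0, 10, duration = 10, axis_heading = 45,
                           noise_sd = 0)
  dx <- diff(p$x_cm); dy <- diff(p$y_cm)
  expect_lt(max(abs(dy - dx)), 1e-9)   # 45 degrees: dy == dx
})

test_that("path generation is bit-identical under a fixed seed", {
  a <- gen_sinusoidal_path(50, 20, 10, 10, noise_sd = 1, seed = 42)
  b <- gen_sinusoidal_path(50, 20, 10, 10, noise_sd = 1, seed = 42)
  expect_identical(a$x_cm, b$x_cm)
  expect_identical(a$y_cm, b$y_cm)
  c <- gen_sinusoidal_path(50, 20, 10, 10, noise_sd = 1, seed = 43)
  expect_false(identical(a$x_cm, c$x_cm))
})

test_that("invalid path parameters are rejected", {
  expect_error(gen_sinusoidal_path(-1, 20, 10, 10), "wavelength")
  expect_error(gen_sinusoidal_path(50, 20, 10, 0), "duration")
  expect_error(gen_sinusoidal_path(50, 20, 10, 10, frame_rate = 0),
               "frame_rate")
})

test_that("checkerboard geometry matches the 1 m, 9-squares board", {
  cal <- demo_calibration(2, c(100, 100))
  b <- render_checkerboard(9, 11.11, cal$H)
  expect_equal(nrow(b$corner_cm), 64)             # 8 x 8 interior corners
  xs <- sort(unique(b$corner_cm[, 1]))
  expect_equal(length(xs), 8)
  expect_equal(unique(round(diff(xs), 9)), 11.11) # grid spacing = square size
  expect_equal(9 * b$square_size, 99.99)          # full board ~ 1 m
})

test_that("checkerboard corners map exactly under identity and scaling", {
  H_id <- diag(3)
  b <- render_checkerboard(9, 11.11, H_id, corner_noise_sd = 0)
  expect_equal(b$corner_px, b$corner_cm, ignore_attr = TRUE)
  H_s <- diag(c(2, 2, 1))
  b2 <- render_checkerboard(9, 11.11, H_s, corner_noise_sd = 0)
  expect_equal(b2$corner_px, 2 * b2$corner_cm, ignore_attr = TRUE)
  expect_error(render_checkerboard(9, 11.11, matrix(0, 3, 3)), "singular")
})

test_that("Rayleigh speed samples satisfy the moment identity", {
  v <- gen_speed_samples(1, 1e6, seed = 7)
  expect_lt(abs(mean(v) / 1.2533 - 1), 0.01)
  v2 <- gen_speed_samples(7.66, 1e6, seed = 8)
  expect_lt(abs(mean(v2) / 9.6 - 1), 0.01)   # 9.6 / sqrt(pi/2) = 7.659
  expect_length(gen_speed_samples(1, 1, seed = 1), 1)
  expect_gt(gen_speed_samples(1, 1, seed = 1), 0)
  expect_error(gen_speed_samples(0, 10), "sigma")
})

test_that("invisible blob is statistically indistinguishable from background", {
  p <- gen_sinusoidal_path(50, 10, 10, duration = 1, noise_sd = 0)
  cf <- calibration_for_path(p, px_per_cm = 2, margin_px = 20)
  sp0 <- scene_spec(frame_size = cf$frame_size, blob_contrast = 0, seed = 5)
  spb <- scene_spec(frame_size = cf$frame_size, blob_contrast = 50, seed = 5)
  s0 <- render_video(p, cf$calib, sp0)
  sb <- render_video(p, cf$calib, spb)
  ## background-only reference: vignetted background with no noise
  d <- dim(s0$frames)
  bgmap <- spiderwalk:::vignette_map(d[2], d[1], sp0$vignette_strength) *
    sp0$background_level
  idx <- withr::with_seed(1, sample(length(s0$frames), 1000))
  bg_rep <- rep(as.vector(bgmap), d[3])
  expect_lt(abs(mean(s0$frames[idx] - bg_rep[idx])), sp0$noise_sd / 10)
  expect_gt(max(abs(sb$frames - s0$frames)), 10)  # nonzero contrast shows up
})

test_that("clean render produces exactly one connected off-background patch", {
  p <- gen_sinusoidal_path(50, 10, 10, duration = 1, noise_sd = 0)
  cf <- calibration_for_path(p, px_per_cm = 2, margin_px = 20)
  sp <- scene_spec(frame_size = cf$frame_size, noise_sd = 0,
                   vignette_strength = 0)
  st <- render_video(p, cf$calib, sp)
  for (k in c(1, 13, 26)) {
    fr <- st$frames[, , k]
    diffpx <- abs(fr - sp$background_level) > 1e-9
    expect_gt(sum(diffpx), 0)
    ## single blob: differing pixels form one bounding box fully filled rows
    cc <- spiderwalk::select_spider_component(
      array(rep(diffpx, 2), c(dim(diffpx), 2)),
      tracker_config(min_volume = 1))
    expect_true(cc$found)
    expect_equal(cc$n_components, 1)
  }
})

test_that("frame-wise argmax of |frame - temporal mean| tracks the blob", {
  p <- gen_sinusoidal_path(50, 20, 10, duration = 24 / 25, frame_rate = 25)
  cf <- calibration_for_path(p, px_per_cm = 2.5, margin_px = 20)
  sp <- scene_spec(frame_size = cf$frame_size, seed = 3)
  st <- render_video(p, cf$calib, sp)
  truth_px <- ground_to_pixels(as.matrix(p[, c("x_cm", "y_cm")]), cf$calib)
  mu <- rowMeans(st$frames, dims = 2)
  hits <- 0
  for (k in seq_len(25)) {
    dif <- abs(st$frames[, , k] - mu)
    w <- which(dif == max(dif), arr.ind = TRUE)[1, ]
    if (sqrt((w[2] - truth_px[k, 1])^2 + (w[1] - truth_px[k, 2])^2) <=
          sp$blob_radius) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 24)
})

test_that("rendering fails loudly when the path leaves the frame", {
  p <- gen_sinusoidal_path(50, 20, 10, duration = 10, noise_sd = 0)
  cal <- demo_calibration(2.5, c(50, 50))
  expect_error(render_video(p, cal, scene_spec(frame_size = c(100, 100))),
               "outside")
})

test_that("rendering is bit-identical under a fixed scene seed", {
  p <- gen_sinusoidal_path(50, 10, 10, duration = 1, noise_sd = 0)
  cf <- calibration_for_path(p, px_per_cm = 2, margin_px = 20)
  sp <- scene_spec(frame_size = cf$frame_size, seed = 11)
  expect_identical(render_video(p, cf$calib, sp)$frames,
                   render_video(p, cf$calib, sp)$frames)
})
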