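test_that("difference mask matches the brute-force per-voxel oracle", {
  ## small noisy batch with a moving synthetic blob
  p <- gen_sinusoidal_path(30, 8, 10, duration = 24 / 25)
  cf <- calibration_for_path(p, px_per_cm = 1.5, margin_px = 10)
  st <- render_video(p, cf$calib, scene_spec(frame_size = cf$frame_size,
                                             blob_contrast = 50, noise_sd = 2,
                                             seed = 2))
  mask <- temporal_diff_mask(st$frames, 8)
  expect_identical(mask, brute_force_mask(st$frames, 8))
})

test_that("threshold boundary behaves exactly at 8 intensity units", {
  batch <- array(100, c(5, 5, 4))
  batch[3, 3, 2] <- 100 + 10 * 4 / 3   # deviation from mean = 10
  m <- temporal_diff_mask(batch, 8)
  expect_true(m[3, 3, 2])
  expect_equal(sum(m), 1)              # the other 3 frames deviate only 10/3
  batch2 <- array(100, c(5, 5, 4))
  batch2[3, 3, 2] <- 100 + 7 * 4 / 3   # deviation = 7 < 8
  expect_false(any(temporal_diff_mask(batch2, 8)))
})

test_that("identical frames yield an all-false mask and short batches error", {
  batch <- array(37, c(6, 6, 5))
  expect_false(any(temporal_diff_mask(batch, 8)))
  expect_error(temporal_diff_mask(array(0, c(6, 6, 1)), 8), "n >= 2")
})

test_that("raising the threshold never adds a true voxel", {
  p <- gen_sinusoidal_path(30, 8, 10, duration = 24 / 25)
  cf <- calibration_for_path(p, px_per_cm = 1.5, margin_px = 10)
  st <- render_video(p, cf$calib, scene_spec(frame_size = cf$frame_size,
                                             seed = 9))
  prev <- temporal_diff_mask(st$frames, 4)
  for (tau in c(8, 16, 32)) {
    cur <- temporal_diff_mask(st$frames, tau)
    expect_false(any(cur & !prev))
    prev <- cur
  }
})

test_that("component selection filters by volume and falls back to no detection", {
  mask <- array(FALSE, c(30, 30, 10))
  mask[5:14, 5:14, 1:5] <- TRUE        # volume 500
  mask[25, 25, 8:9] <- TRUE            # volume 2
  sel <- select_spider_component(mask, tracker_config(min_volume = 100))
  expect_true(sel$found)
  expect_equal(sel$volume, 500)
  expect_equal(sel$n_components, 2)
  ## enumerate-and-filter oracle: surviving component centroid per frame
  expect_equal(sel$centroids$x, rep(9.5, 5))
  expect_equal(sel$centroids$y, rep(9.5, 5))
  expect_equal(sel$centroids$k, 1:5)

  flicker <- array(FALSE, c(10, 10, 5))
  flicker[4, 4, 3] <- TRUE
  none <- select_spider_component(flicker, tracker_config(min_volume = 50))
  expect_false(none$found)

  single <- array(FALSE, c(10, 10, 5))
  single[2:6, 2:6, 1:4] <- TRUE
  s1 <- select_spider_component(single, tracker_config(min_volume = 10))
  expect_true(s1$found)
  expect_equal(s1$n_components, 1)
})

test_that("elongated components are rejected by the shape criterion", {
  mask <- array(FALSE, c(40, 40, 6))
  mask[20, 3:38, 1:6] <- TRUE          # 1-px-wide line: eccentricity ~ 1
  sel <- select_spider_component(mask, tracker_config(min_volume = 10,
                                                      max_eccentricity = 0.95))
  expect_false(sel$found)
  sel2 <- select_spider_component(mask, tracker_config(min_volume = 10,
                                                       max_eccentricity = 1))
  expect_true(sel2$found)
})

test_that("tracker defaults echo the published processing settings", {
  cfg <- tracker_config()
  expect_equal(cfg$batch_size, 25L)
  expect_equal(cfg$crop_size, 300L)
  expect_equal(cfg$threshold, 8)
  p <- gen_sinusoidal_path(50, 10, 10, duration = 2)
  cf <- calibration_for_path(p, px_per_cm = 2, margin_px = 20)
  st <- render_video(p, cf$calib, scene_spec(frame_size = cf$frame_size))
  tr <- track_video(st, ground_to_pixels(p[1, c("x_cm", "y_cm")],
                                         cf$calib)[1, ])
  rep <- attr(tr, "report")
  expect_equal(rep$config$batch_size, 25L)
  expect_equal(rep$config$crop_size, 300L)
  expect_equal(rep$config$threshold, 8)
})

test_that("a quasi-static blob is recovered to within the blob scale", {
  ## temporal-mean subtraction is blind to a perfectly static target (it IS
  ## the temporal mean); a slow drift stands in for a near-stationary
  ## animal. Coverage is partial and the residual ghost of the batch mean
  ## biases centroids by a pixel or two at these speeds — recovered
  ## positions stay well within the blob radius of the truth.
  p <- gen_sinusoidal_path(1000, 0, 1.6, duration = 2, frame_rate = 25)
  cf <- calibration_for_path(p, px_per_cm = 2.5, margin_px = 25)
  st <- render_video(p, cf$calib, scene_spec(frame_size = cf$frame_size,
                                             noise_sd = 1, seed = 4))
  truth_px <- ground_to_pixels(as.matrix(p[, c("x_cm", "y_cm")]), cf$calib)
  tr <- track_video(st, truth_px[1, ])
  ok <- !is.na(tr$x_px)
  expect_gt(mean(ok), 0.3)
  err <- sqrt((tr$x_px[ok] - truth_px[ok, 1])^2 +
                (tr$y_px[ok] - truth_px[ok, 2])^2)
  expect_lt(max(err), 2)
})

test_that("rendered sinusoidal departure is recovered with small error", {
  p <- gen_sinusoidal_path(50, 20, 10, duration = 15)
  cf <- calibration_for_path(p)
  st <- render_video(p, cf$calib, scene_spec(frame_size = cf$frame_size,
                                             seed = 6))
  truth_px <- ground_to_pixels(as.matrix(p[, c("x_cm", "y_cm")]), cf$calib)
  tr <- track_video(st, truth_px[1, ])
  ok <- !is.na(tr$x_px)
  rmse <- sqrt(mean((tr$x_px[ok] - truth_px[ok, 1])^2 +
                      (tr$y_px[ok] - truth_px[ok, 2])^2))
  expect_lte(rmse, 2)
  gaps <- attr(tr, "gaps")
  if (length(gaps)) {
    expect_lte(max(vapply(gaps, function(g) g[2] - g[1] + 1, numeric(1))), 25)
  }
})

test_that("cropping to a window does not change the recovered centroids", {
  p <- gen_sinusoidal_path(40, 10, 10, duration = 4)
  cf <- calibration_for_path(p, px_per_cm = 2.5, margin_px = 80)
  st <- render_video(p, cf$calib, scene_spec(frame_size = cf$frame_size,
                                             seed = 13))
  init <- ground_to_pixels(p[1, c("x_cm", "y_cm")], cf$calib)[1, ]
  full <- track_video(st, init, tracker_config(crop_size = 10000L))
  crop <- track_video(st, init, tracker_config(crop_size = 150L))
  ok <- !is.na(full$x_px) & !is.na(crop$x_px)
  expect_gt(mean(ok), 0.9)
  expect_lt(max(abs(full$x_px[ok] - crop$x_px[ok])), 1e-6)
  expect_lt(max(abs(full$y_px[ok] - crop$y_px[ok])), 1e-6)
})

test_that("tracking rejects an out-of-frame initial position", {
  p <- gen_sinusoidal_path(40, 10, 10, duration = 1)
  cf <- calibration_for_path(p, px_per_cm = 2, margin_px = 20)
  st <- render_video(p, cf$calib, scene_spec(frame_size = cf$frame_size))
  expect_error(track_video(st, c(-5, 10)), "outside")
})
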