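#' Scene specification for synthetic infrared recordings
#'
#' Bundles the rendering parameters of the synthetic night scene: a dim,
#' vignetted sand background with a single compact bright (or dark) blob for
#' the spider, plus additive sensor noise. Defaults emulate an infrared-lit
#' 8-bit recording: a mid-grey background that darkens towards the periphery,
#' a spider-body-sized blob a moderate contrast step above it, and mild
#' Gaussian pixel noise.
#'
#' @param frame_size `c(width, height)` in px.
#' @param frame_rate Hz (used for frame timestamps).
#' @param background_level background intensity (0-255).
#' @param blob_contrast intensity delta of the blob peak relative to the
#'   background; may be negative for a dark animal.
#' @param blob_radius blob radius in px (radially linear falloff disc).
#' @param noise_sd additive Gaussian pixel noise sd (intensity units).
#' @param vignette_strength 0-1; relative darkening at the frame corners.
#' @param seed integer seed for the pixel noise.
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(frame_size = c(480, 480), frame_rate = 25,
                       background_level = 120, blob_contrast = 50,
                       blob_radius = 5, noise_sd = 2,
                       vignette_strength = 0.3, seed = 1) {
  lo <- background_level + min(0, blob_contrast)
  hi <- background_level + max(0, blob_contrast)
  if (lo < 0 || hi > 255) {
    stopf("background_level +/- blob_contrast must stay within 0..255")
  }
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  structure(list(frame_size = as.integer(frame_size), frame_rate = frame_rate,
                 background_level = background_level,
                 blob_contrast = blob_contrast, blob_radius = blob_radius,
                 noise_sd = noise_sd, vignette_strength = vignette_strength,
                 seed = seed),
            class = "scene_spec")
}

#' Frame stack container
#'
#' @param frames numeric array `[height, width, n]` with intensities 0-255.
#' @param timestamps numeric vector of frame times (s), strictly increasing.
#' @return a `frame_stack` object.
#' @export
frame_stack <- function(frames, timestamps) {
  if (length(dim(frames)) != 3) stopf("frames must be a [h, w, n] array")
  if (dim(frames)[3] != length(timestamps)) {
    stopf("timestamps length must match frame count")
  }
  if (any(diff(timestamps) <= 0)) stopf("timestamps must be strictly increasing")
  structure(list(frames = frames, timestamps = as.numeric(timestamps),
                 frame_size = c(dim(frames)[2], dim(frames)[1])),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf("Frame stack: %d frames of %dx%d px, %.3f-%.3f s\n",
              length(x$timestamps), x$frame_size[1], x$frame_size[2],
              min(x$timestamps), max(x$timestamps)))
  invisible(x)
}

## multiplicative cos^4-like radial vignette, 1 at centre, 1-strength at corners
vignette_map <- function(w, h, strength) {
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  rmax <- sqrt((w - cx)^2 + (h - cy)^2)
  X <- matrix(rep(seq_len(w), each = h), nrow = h)
  Y <- matrix(rep(seq_len(h), times = w), nrow = h)
  r <- sqrt((X - cx)^2 + (Y - cy)^2) / rmax
  falloff <- cos(pmin(r, 1) * pi / 2)^4
  (1 - strength) + strength * falloff
}

#' Lazy renderer for a synthetic scene
#'
#' Returns a `frame_provider`: an object that renders any single frame of the
#' scene on demand, so long recordings can be tracked without materialising
#' the whole stack in memory. Frame `k` is deterministic given the scene seed
#' (per-frame noise streams are seeded `seed + k`).
#'
#' @param truth a `path_truth` / `ground_track` (columns `t_s`, `x_cm`,
#'   `y_cm`).
#' @param calib a [planar_calibration()] (ground cm -> image px).
#' @param spec a [scene_spec()].
#' @return a `frame_provider` list: `n`, `timestamps`, `frame_size` and
#'   `frame(k)` returning the `[h, w]` intensity matrix of frame `k`.
#' @export
render_provider <- function(truth, calib, spec = scene_spec()) {
  w <- spec$frame_size[1]; h <- spec$frame_size[2]
  pxy <- ground_to_pixels(as.matrix(truth[, c("x_cm", "y_cm")]), calib)
  out_of_frame <- which(pxy[, 1] < 1 | pxy[, 1] > w | pxy[, 2] < 1 | pxy[, 2] > h)
  if (length(out_of_frame)) {
    stopf("truth positions project outside the %dx%d frame at indices: %s",
          w, h, paste(head(out_of_frame, 10), collapse = ", "))
  }
  vig <- vignette_map(w, h, spec$vignette_strength)
  bg <- spec$background_level
  r <- spec$blob_radius
  render_one <- function(k) {
    img <- matrix(bg, h, w)
    x0 <- pxy[k, 1]; y0 <- pxy[k, 2]
    ## blob only touches a small window around its centre
    xs <- max(1L, floor(x0 - r - 1)):min(w, ceiling(x0 + r + 1))
    ys <- max(1L, floor(y0 - r - 1)):min(h, ceiling(y0 + r + 1))
    d <- sqrt(outer((ys - y0)^2, (xs - x0)^2, `+`))
    img[ys, xs] <- img[ys, xs] + spec$blob_contrast * pmax(0, 1 - d / r)
    img <- img * vig
    if (spec$noise_sd > 0) {
      img <- img + with_seed_opt(
        (spec$seed %||% 0) + k,
        matrix(rnorm(h * w, 0, spec$noise_sd), h, w))
    }
    pmin(pmax(img, 0), 255)
  }
  structure(list(n = nrow(pxy), timestamps = truth$t_s,
                 frame_size = c(w, h), frame = render_one),
            class = "frame_provider")
}

#' Render a ground-truth path to a synthetic video
#'
#' Projects each truth position through the calibration and renders one frame
#' per sample: a radially shaded disc of the configured contrast on the
#' vignetted background, plus additive Gaussian noise, clipped to 0-255. For
#' long scenes consider [render_provider()], which renders frames lazily.
#'
#' @inheritParams render_provider
#' @return a [frame_stack()] with one frame per truth sample.
#' @export
render_video <- function(truth, calib, spec = scene_spec()) {
  p <- render_provider(truth, calib, spec)
  h <- p$frame_size[2]; w <- p$frame_size[1]
  frames <- array(0, c(h, w, p$n))
  for (k in seq_len(p$n)) frames[, , k] <- p$frame(k)
  frame_stack(frames, p$timestamps)
}

#' Synthetic checkerboard calibration target
#'
#' Builds the interior-corner grid of a `squares_per_side` x `squares_per_side`
#' checkerboard (board centred on the ground origin), maps it through a known
#' homography and optionally perturbs the pixel corners with Gaussian noise —
#' the synthetic analogue of imaging a 1 m board of 9x9 squares (11.11 cm
#' each) laid over the burrow.
#'
#' @param squares_per_side squares along one side (9 -> 8x8 = 64 interior
#'   corners).
#' @param square_size square edge length (cm).
#' @param homography 3x3 ground-cm -> px matrix (must be invertible).
#' @param corner_noise_sd Gaussian noise sd added to each pixel coordinate.
#' @param seed integer seed for the corner noise.
#' @return a `checkerboard_truth` list: `corner_cm`, `corner_px` (n x 2),
#'   `correspondences` (data.frame `x_px,y_px,x_cm,y_cm`), `homography_true`,
#'   `squares_per_side`, `square_size`.
#' @export
render_checkerboard <- function(squares_per_side = 9, square_size = 11.11,
                                homography, corner_noise_sd = 0, seed = NULL) {
  H <- as.matrix(homography)
  if (abs(det(H)) < 1e-12) stopf("homography is singular")
  H <- H / H[3, 3]
  m <- squares_per_side
  if (m < 2) stopf("squares_per_side must be >= 2")
  ## interior grid lines at i*square_size from the board edge, board centred at 0
  pos <- (seq_len(m - 1) - m / 2) * square_size
  corner_cm <- as.matrix(expand.grid(x_cm = pos, y_cm = pos))
  corner_px <- apply_homography(H, corner_cm)
  if (corner_noise_sd > 0) {
    corner_px <- corner_px + with_seed_opt(
      seed, matrix(rnorm(length(corner_px), 0, corner_noise_sd),
                   ncol = 2))
  }
  structure(list(
    squares_per_side = m, square_size = square_size,
    homography_true = H, corner_cm = corner_cm, corner_px = corner_px,
    correspondences = data.frame(x_px = corner_px[, 1], y_px = corner_px[, 2],
                                 x_cm = corner_cm[, 1], y_cm = corner_cm[, 2])
  ), class = "checkerboard_truth")
}

#' Convenience calibration for rendering synthetic scenes
#'
#' A ground-cm to image-px map with uniform scale, the y handedness flip
#' (ground y north/up vs image y down) and a given pixel origin for the
#' ground origin.
#'
#' @param px_per_cm uniform scale (default 2.5 px/cm, an HD sensor over a
#'   roughly 4 m field of view).
#' @param origin_px pixel position of the ground origin `c(x, y)`.
#' @return a [planar_calibration()].
#' @export
demo_calibration <- function(px_per_cm = 2.5, origin_px = c(240, 240)) {
  H <- rbind(c(px_per_cm, 0, origin_px[1]),
             c(0, -px_per_cm, origin_px[2]),
             c(0, 0, 1))
  planar_calibration(H, center = origin_px)
}

#' Fit a rendering calibration and frame size around a truth path
#'
#' Chooses a frame just large enough (plus margin) to contain every projected
#' truth position at the requested scale, so arbitrary departure geometries
#' can be rendered without clipping.
#'
#' @param truth a `path_truth` / `ground_track`.
#' @param px_per_cm uniform scale.
#' @param margin_px border margin in px.
#' @return list with elements `calib` ([planar_calibration()]) and
#'   `frame_size` (`c(w, h)`).
#' @export
calibration_for_path <- function(truth, px_per_cm = 2.5, margin_px = 40) {
  xr <- range(truth$x_cm); yr <- range(truth$y_cm)
  w <- ceiling(diff(xr) * px_per_cm) + 2 * margin_px
  h <- ceiling(diff(yr) * px_per_cm) + 2 * margin_px
  ## ground (xr[1], yr[2]) — top-left of the scene — maps to (margin, margin)
  origin <- c(margin_px - xr[1] * px_per_cm, margin_px + yr[2] * px_per_cm)
  list(calib = demo_calibration(px_per_cm, origin), frame_size = c(w, h))
}
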