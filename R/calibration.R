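#' Planar ground-plane calibration
#'
#' A calibration maps burrow-area ground coordinates (cm; x east, y north) to
#' image pixels (x right, y down from the top-left origin) through a 3x3
#' homography `H` (scale fixed at `H[3,3] = 1`), optionally preceded by a
#' one-parameter radial lens distortion about the image centre. The y-axis
#' handedness flip between the two frames lives inside `H`.
#'
#' @param H 3x3 invertible matrix, ground cm -> image px.
#' @param k1 radial distortion coefficient (default 0, i.e. pure homography).
#'   Distortion acts on ideal pixel coordinates: `p_d = c + (1 + k1*r^2)*(p - c)`
#'   with `r` the distance to `center` in units of 1000 px.
#' @param center image centre `c(x, y)` in px used by the distortion model.
#' @param rms_error root-mean-square reprojection error (px) of the fit that
#'   produced this calibration; `NA` for exact constructions.
#' @return a `planar_calibration` object.
#' @export
planar_calibration <- function(H, k1 = 0, center = c(0, 0), rms_error = NA_real_) {
  H <- as.matrix(H)
  if (!all(dim(H) == c(3, 3))) stopf("H must be 3x3")
  if (abs(det(H)) < 1e-12) stopf("H is singular")
  if (abs(H[3, 3]) > 1e-12) H <- H / H[3, 3]
  structure(list(H = H, k1 = k1, center = as.numeric(center),
                 rms_error = rms_error),
            class = "planar_calibration")
}

#' @export
print.planar_calibration <- function(x, ...) {
  cat("Planar calibration (ground cm -> image px)\n")
  cat("H =\n")
  print(signif(x$H, 6))
  cat(sprintf("k1 = %g, rms reprojection error = %s px\n",
              x$k1, format(x$rms_error)))
  invisible(x)
}

## homogeneous application of a 3x3 matrix to n x 2 points
apply_homography <- function(H, xy) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  ph <- cbind(xy, 1) %*% t(H)
  w <- ph[, 3]
  if (any(abs(w) < 1e-12, na.rm = TRUE)) {
    bad <- which(abs(w) < 1e-12)
    stopf("point(s) %s map to the plane at infinity (w ~ 0)",
          paste(bad, collapse = ", "))
  }
  ph[, 1:2, drop = FALSE] / w
}

distort_px <- function(xy, k1, center) {
  if (k1 == 0) return(xy)
  d <- sweep(xy, 2, center)
  r2 <- rowSums(d^2) / 1e6            # r in units of 1000 px
  sweep(d * (1 + k1 * r2), 2, center, `+`)
}

undistort_px <- function(xy, k1, center) {
  if (k1 == 0) return(xy)
  d <- sweep(xy, 2, center)
  u <- d
  for (i in 1:20) {                    # fixed-point inversion of the radial model
    r2 <- rowSums(u^2) / 1e6
    u <- d / (1 + k1 * r2)
  }
  sweep(u, 2, center, `+`)
}

#' Project ground coordinates into the image
#'
#' Forward map of a calibration: ground cm -> (distorted) pixel coordinates.
#'
#' @param xy_cm n x 2 matrix or data.frame of ground coordinates (cm).
#' @param calib a [planar_calibration()].
#' @return n x 2 matrix of pixel coordinates.
#' @export
ground_to_pixels <- function(xy_cm, calib) {
  distort_px(apply_homography(calib$H, xy_cm), calib$k1, calib$center)
}

#' Estimate the ground-to-image homography from corner correspondences
#'
#' Normalized direct linear transform (similarity normalization of both point
#' sets, SVD solution), followed by iterative refinement of the geometric
#' reprojection error, optionally co-estimating a single radial distortion
#' coefficient about the image centre. This replaces toolbox camera
#' calibration for the flat-ground, single-view setting: the scene is a plane,
#' so a homography fully describes the overhead rectification.
#'
#' @param correspondences data.frame with columns `x_px`, `y_px`, `x_cm`,
#'   `y_cm` (>= 4 non-collinear points).
#' @param refine_distortion if `TRUE`, co-estimate `k1`.
#' @return a [planar_calibration()] with `rms_error` set to the RMS point
#'   reprojection distance in px.
#' @export
estimate_homography <- function(correspondences, refine_distortion = FALSE) {
  cc <- correspondences
  need <- c("x_px", "y_px", "x_cm", "y_cm")
  if (!all(need %in% names(cc))) {
    stopf("correspondences must have columns %s", paste(need, collapse = ", "))
  }
  px <- as.matrix(cc[, c("x_px", "y_px")])
  cm <- as.matrix(cc[, c("x_cm", "y_cm")])
  n <- nrow(px)
  if (n < 4) stopf("need >= 4 correspondences, got %d", n)
  if (min(svd(scale(cm, scale = FALSE))$d) < 1e-9 * max(1, max(abs(cm)))) {
    stopf("degenerate configuration: ground points are collinear")
  }

  normalise <- function(p) {
    ctr <- colMeans(p)
    d <- sweep(p, 2, ctr)
    s <- sqrt(2) / mean(sqrt(rowSums(d^2)))
    T <- rbind(c(s, 0, -s * ctr[1]), c(0, s, -s * ctr[2]), c(0, 0, 1))
    list(T = T, p = cbind(d * s))
  }
  np <- normalise(px); nc <- normalise(cm)
  X <- nc$p[, 1]; Y <- nc$p[, 2]; x <- np$p[, 1]; y <- np$p[, 2]
  A <- matrix(0, 2 * n, 9)
  A[seq(1, 2 * n, 2), ] <- cbind(-X, -Y, -1, 0, 0, 0, x * X, x * Y, x)
  A[seq(2, 2 * n, 2), ] <- cbind(0, 0, 0, -X, -Y, -1, y * X, y * Y, y)
  h <- svd(A)$v[, 9]
  Hn <- matrix(h, 3, 3, byrow = TRUE)
  H <- solve(np$T) %*% Hn %*% nc$T
  H <- H / H[3, 3]

  center <- colMeans(px)
  reproj_rms <- function(H, k1) {
    pr <- distort_px(apply_homography(H, cm), k1, center)
    sqrt(mean(rowSums((pr - px)^2)))
  }
  obj <- function(par) {
    H2 <- matrix(c(par[1:8], 1), 3, 3, byrow = TRUE)
    k1 <- if (length(par) == 9) par[9] else 0
    pr <- distort_px(apply_homography(H2, cm), k1, center)
    sum((pr - px)^2)
  }
  par0 <- as.numeric(t(H))[1:8]
  if (refine_distortion) par0 <- c(par0, 0)
  opt <- stats::optim(par0, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14,
                                     parscale = pmax(abs(par0), 1e-2)))
  H <- matrix(c(opt$par[1:8], 1), 3, 3, byrow = TRUE)
  k1 <- if (refine_distortion) opt$par[9] else 0
  planar_calibration(H, k1 = k1, center = center,
                     rms_error = reproj_rms(H, k1))
}

#' Rectify a pixel track into burrow-centred ground coordinates
#'
#' Each detected position is undistorted (if `k1 != 0`), mapped through the
#' inverse homography to the ground plane, and translated so the burrow sits
#' at the origin. Timestamps and gap rows (NA positions) are preserved.
#'
#' @param track a `pixel_track` (or data.frame with `t_s`, `x_px`, `y_px`).
#' @param calib a [planar_calibration()].
#' @param burrow_px burrow position `c(x, y)` in image pixels.
#' @param direction_label optional `"departure"` or `"return"` label.
#' @param excursion_number optional ordinal of the excursion.
#' @return a `ground_track` data.frame with columns `t_s`, `x_cm`, `y_cm`
#'   (burrow at the origin); extra columns of the input are carried through.
#' @export
pixels_to_ground <- function(track, calib, burrow_px,
                             direction_label = NULL, excursion_number = NULL) {
  Hinv <- solve(calib$H)
  px <- as.matrix(track[, c("x_px", "y_px")])
  ok <- complete.cases(px)
  g <- matrix(NA_real_, nrow(px), 2)
  if (any(ok)) {
    u <- undistort_px(px[ok, , drop = FALSE], calib$k1, calib$center)
    g[ok, ] <- apply_homography(Hinv, u)
  }
  b <- apply_homography(Hinv, matrix(
    undistort_px(matrix(burrow_px, 1, 2), calib$k1, calib$center), 1, 2))
  out <- data.frame(t_s = track$t_s, x_cm = g[, 1] - b[1], y_cm = g[, 2] - b[2])
  extra <- setdiff(names(track), c("t_s", "x_px", "y_px", names(out)))
  for (cn in extra) out[[cn]] <- track[[cn]]
  attr(out, "burrow") <- c(0, 0)
  attr(out, "direction_label") <- direction_label
  attr(out, "excursion_number") <- excursion_number
  class(out) <- c("ground_track", "data.frame")
  out
}

#' Save / load a calibration as JSON
#' @param calib a [planar_calibration()].
#' @param path file path.
#' @rdname calibration_io
#' @export
write_calibration <- function(calib, path) {
  jsonlite::write_json(
    list(H = as.numeric(t(calib$H)), k1 = calib$k1,
         center = calib$center, rms_error = calib$rms_error),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname calibration_io
#' @export
read_calibration <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  planar_calibration(matrix(j$H, 3, 3, byrow = TRUE), k1 = j$k1,
                     center = j$center, rms_error = j$rms_error %||% NA_real_)
}
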