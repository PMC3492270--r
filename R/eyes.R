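#' Body-to-burrow alignment angle series
#'
#' For every step between consecutive observed positions the walking
#' direction is the straight line between the two positions; alpha is the
#' signed smallest rotation from the walking direction to the bearing of the
#' burrow as seen from the step start. Convention: alpha is positive when the
#' burrow lies to the animal's right, in (-180, 180]; |alpha| supports
#' pooling of left and right sides. Spiders carry their eyes rigidly on the
#' prosoma, so walking direction fixes the viewing direction of every
#' fixed-field eye.
#'
#' @param track a `ground_track` (coincident consecutive samples skipped).
#' @param burrow burrow position `c(x, y)` in cm.
#' @return an `alpha_series` data.frame: `t_s`, `heading_deg` (walking
#'   direction, ground frame), `alpha_deg`, `abs_alpha_deg`; empty if the
#'   track never moves.
#' @export
alpha_series <- function(track, burrow = c(0, 0)) {
  xy <- as.matrix(track[, c("x_cm", "y_cm")])
  ok <- complete.cases(xy)
  xy <- xy[ok, , drop = FALSE]
  t <- track$t_s[ok]
  if (nrow(xy) < 2) stopf("need >= 2 observed samples")
  dx <- diff(xy[, 1]); dy <- diff(xy[, 2])
  move <- (dx^2 + dy^2) > 1e-18
  if (!any(move)) {
    return(structure(data.frame(t_s = numeric(0), heading_deg = numeric(0),
                                alpha_deg = numeric(0),
                                abs_alpha_deg = numeric(0)),
                     class = c("alpha_series", "data.frame")))
  }
  i <- which(move)
  heading <- rad2deg(atan2(dy[i], dx[i]))
  bearing <- rad2deg(atan2(burrow[2] - xy[i, 2], burrow[1] - xy[i, 1]))
  ## ground frame is counter-clockwise-positive; "to the right" is clockwise,
  ## so alpha = -(bearing - heading)
  alpha <- norm_angle_deg(-(bearing - heading))
  structure(data.frame(t_s = t[i], heading_deg = norm_angle_deg(heading),
                       alpha_deg = alpha, abs_alpha_deg = abs(alpha)),
            class = c("alpha_series", "data.frame"))
}

#' Azimuthal eye visual-field model
#'
#' Maps each eye (AME, ALE, PLE, and optionally the upwards-looking PME) and
#' side (L/R) to one or more azimuthal intervals in body-centred degrees
#' (0 = straight ahead, positive to the animal's right, range (-180, 180]).
#' When built from one side's entries the other side is mirrored
#' (interval [lo, hi] -> [-hi, -lo]).
#'
#' @param right named list: eye name -> list of `c(lo, hi)` intervals for the
#'   right side.
#' @param left optional explicit left-side entries; mirrored from `right`
#'   when omitted.
#' @return an `eye_field_model`: named list `<EYE>.<SIDE>` -> list of
#'   intervals.
#' @export
eye_field_model <- function(right, left = NULL) {
  norm_iv <- function(iv) {
    iv <- as.numeric(iv)
    if (length(iv) != 2 || iv[1] > iv[2]) stopf("intervals must be c(lo, hi)")
    if (iv[1] <= -180 || iv[2] > 180) {
      stopf("interval [%g, %g] outside (-180, 180]", iv[1], iv[2])
    }
    iv
  }
  model <- list()
  for (eye in names(right)) {
    ivs <- lapply(right[[eye]], norm_iv)
    model[[paste0(eye, ".R")]] <- ivs
    if (is.null(left)) {
      model[[paste0(eye, ".L")]] <- lapply(ivs, function(iv) c(-iv[2], -iv[1]))
    }
  }
  if (!is.null(left)) {
    for (eye in names(left)) {
      model[[paste0(eye, ".L")]] <- lapply(left[[eye]], norm_iv)
    }
  }
  structure(model, class = "eye_field_model")
}

#' Illustrative default eye-field compass
#'
#' An azimuth-only compass for the three forward/side-looking eye pairs (AME,
#' ALE, PLE; the upwards-looking PME is excluded). The interval boundaries
#' are illustrative placeholders shaped like the published field compass
#' (frontal AME overlap, lateral ALE, wide posterior-lateral PLE with an
#' ALE/PLE overlap zone); they are NOT authoritative measurements, and real
#' analyses should supply a model file.
#'
#' @return an `eye_field_model`.
#' @export
default_eye_model <- function() {
  eye_field_model(right = list(
    AME = list(c(-15, 15)),
    ALE = list(c(30, 110)),
    PLE = list(c(60, 160))
  ))
}

#' Which eyes see the burrow direction?
#'
#' Returns every (eye, side) whose azimuthal interval contains the
#' body-centred direction alpha; interval endpoints are inclusive.
#'
#' @param alpha body-to-burrow angle in degrees (normalized into
#'   (-180, 180]).
#' @param model an [eye_field_model()].
#' @return character vector of entries like `"ALE.R"` (possibly empty).
#' @export
eyes_viewing <- function(alpha, model = default_eye_model()) {
  if (!length(model)) stopf("eye model is empty")
  a <- norm_angle_deg(alpha)
  hit <- vapply(model, function(ivs) {
    any(vapply(ivs, function(iv) a >= iv[1] && a <= iv[2], logical(1)))
  }, logical(1))
  names(model)[hit]
}

#' Annotate an alpha series with viewing eyes
#'
#' @param series an [alpha_series()].
#' @param model an [eye_field_model()].
#' @return the series with an added `eyes` column (semicolon-separated).
#' @export
eyes_along_track <- function(series, model = default_eye_model()) {
  series$eyes <- vapply(series$alpha_deg, function(a) {
    paste(eyes_viewing(a, model), collapse = ";")
  }, character(1))
  series
}

#' Read / write an eye-field model as YAML
#'
#' The file maps `<EYE>.<SIDE>` to a list of `[lo, hi]` degree intervals.
#'
#' @param model an [eye_field_model()].
#' @param path file path.
#' @rdname eye_model_io
#' @export
write_eye_model <- function(model, path) {
  yaml::write_yaml(lapply(unclass(model), function(ivs) lapply(ivs, as.numeric)),
                   path)
  invisible(path)
}

#' @rdname eye_model_io
#' @export
read_eye_model <- function(path) {
  if (!file.exists(path)) stopf("eye model file not found: %s", path)
  raw <- yaml::read_yaml(path)
  structure(lapply(raw, function(ivs) lapply(ivs, as.numeric)),
            class = "eye_field_model")
}

#' Circular mean with bootstrap confidence interval
#'
#' The mean direction is the argument of the mean resultant vector of the
#' angles; the confidence interval comes from seeded bootstrap of the
#' circular mean (angles resampled with replacement; bootstrap deviations
#' taken on the circle around the observed mean, so wraparound is handled).
#' Plain percentile intervals are mildly anticonservative at moderate n, so
#' the expanded-percentile correction is applied: the deviation quantiles are
#' inflated by `sqrt(n/(n-1)) * t_{n-1} / z`, which restores close-to-nominal
#' coverage.
#'
#' @param angles angles in degrees.
#' @param confidence interval mass (default 0.95).
#' @param n_boot bootstrap resamples (default 2000).
#' @param seed integer seed.
#' @return a `circular_summary` list: `mean_deg`, `ci95` (`c(lo, hi)`, same
#'   wrapping as the mean), `R_bar` (mean resultant length), `n`.
#' @export
circular_summary <- function(angles, confidence = 0.95, n_boot = 2000,
                             seed = NULL) {
  a <- deg2rad(angles[!is.na(angles)])
  n <- length(a)
  if (n < 2) stopf("need >= 2 angles")
  C <- mean(cos(a)); S <- mean(sin(a))
  R <- sqrt(C^2 + S^2)
  if (R < 1e-9) stopf("mean direction undefined (resultant length ~ 0)")
  mu <- rad2deg(atan2(S, C))
  devs <- with_seed_opt(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
    cs <- matrix(cos(a)[idx], nrow = n_boot)
    sn <- matrix(sin(a)[idx], nrow = n_boot)
    bm <- rad2deg(atan2(rowMeans(sn), rowMeans(cs)))
    norm_angle_deg(bm - mu)
  })
  ## expanded percentile: wider-tailed type-6 quantiles plus the small-sample
  ## inflation factor sqrt(n/(n-1)) * t/z
  alpha2 <- (1 - confidence) / 2
  infl <- sqrt(n / (n - 1)) * stats::qt(1 - alpha2, n - 1) /
    stats::qnorm(1 - alpha2)
  qs <- quantile(devs, c(alpha2, 1 - alpha2), names = FALSE, type = 6) * infl
  structure(list(mean_deg = norm_angle_deg(mu), ci = norm_angle_deg(mu + qs),
                 ci_width_deg = qs[2] - qs[1], R_bar = R, n = n,
                 confidence = confidence),
            class = "circular_summary")
}

#' @export
print.circular_summary <- function(x, ...) {
  cat(sprintf("Circular mean %.2f deg, %d%% CI [%.2f, %.2f], R_bar = %.3f, n = %d\n",
              x$mean_deg, round(100 * x$confidence), x$ci[1], x$ci[2],
              x$R_bar, x$n))
  invisible(x)
}
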