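## orthogonal (principal-axis) line through a point cloud; sign aligned to ref
tls_line <- function(xy, ref_dir = NULL, net = NULL) {
  ctr <- colMeans(xy)
  ev <- eigen(stats::cov(xy), symmetric = TRUE)
  dir <- ev$vectors[, 1]
  al <- if (!is.null(ref_dir)) ref_dir else net
  if (!is.null(al) && sum(al * dir) < 0) dir <- -dir
  list(point = ctr, direction = dir)
}

## axis crossings of the deviation series d, with hysteresis: a crossing is
## registered only when d genuinely changes side, i.e. exceeds +/- eps on both
## sides (eps a fraction of the robust deviation scale). This keeps small
## positional noise near the axis from spawning spurious crossings. Returns a
## matrix of (bracket index i, interpolation fraction f): the crossing lies
## between samples i and i+1; a sample exactly on the axis counts once.
crossing_brackets <- function(d, hysteresis = 0.2) {
  n <- length(d)
  eps <- hysteresis * stats::quantile(abs(d), 0.95, names = FALSE)
  if (!is.finite(eps)) eps <- 0
  out <- NULL
  state <- 0L
  arm_idx <- 1L
  for (i in seq_len(n)) {
    s_i <- if (d[i] > eps) 1L else if (d[i] < -eps) -1L else 0L
    if (s_i != 0L && s_i != state) {
      if (state != 0L) {
        for (j in arm_idx:(i - 1L)) {         # locate the sign change
          if (d[j] == 0) {
            out <- rbind(out, c(j, 0))
            break
          }
          if (sign(d[j]) == state && sign(d[j + 1]) != state) {
            out <- rbind(out, if (d[j + 1] == 0) c(j + 1L, 0) else
              c(j, d[j] / (d[j] - d[j + 1])))
            break
          }
        }
      }
      state <- s_i
    }
    if (s_i == state && s_i != 0L) arm_idx <- i
  }
  out
}

## midpoints between consecutive half-cycle extrema of the path relative to a
## line; for an oscillation about an axis these midpoints lie on the axis
halfcycle_midpoints <- function(xy, point, direction) {
  nv <- c(-direction[2], direction[1])
  rel <- sweep(xy, 2, point)
  d <- as.numeric(rel %*% nv)
  br <- crossing_brackets(d)
  if (is.null(br) || nrow(br) < 3) return(NULL)
  ext <- NULL
  for (ci in seq_len(nrow(br) - 1)) {
    ## half-cycle = samples between consecutive crossings, in path order
    seg <- (br[ci, 1] + 1L):br[ci + 1, 1]
    if (!length(seg)) next
    ext <- rbind(ext, xy[seg[which.max(abs(d[seg]))], ])
  }
  if (is.null(ext) || nrow(ext) < 2) return(NULL)
  (ext[-nrow(ext), , drop = FALSE] + ext[-1, , drop = FALSE]) / 2
}

#' Fit the general-direction axis of a path
#'
#' Orthogonal (principal-axis / total least squares) regression through the
#' path centroid — unlike y-on-x least squares it is invariant to rotations
#' of the scene, which a "general direction of travel" must be. For an
#' oscillating path a finite sinusoid starting mid-phase correlates its
#' along-axis and cross-axis coordinates, which tilts the raw principal axis;
#' with `refine = TRUE` (default) the line is therefore iteratively refitted
#' through the midpoints between consecutive half-cycle extrema, points that
#' lie on the oscillation axis itself. The direction sign is chosen so the
#' track's net displacement projects positively.
#'
#' @param track a `ground_track` (columns `x_cm`, `y_cm`; NA rows dropped).
#' @param refine iterate the crossing-point refit (default TRUE).
#' @return list with `point` (cm), `direction` (unit vector) and
#'   `heading_deg`.
#' @export
fit_axis <- function(track, refine = TRUE) {
  xy <- as.matrix(track[, c("x_cm", "y_cm")])
  xy <- xy[complete.cases(xy), , drop = FALSE]
  if (nrow(xy) < 3) stopf("need >= 3 samples to fit an axis")
  if (max(apply(xy, 2, function(v) diff(range(v)))) < 1e-12) {
    stopf("all points coincident; axis undefined")
  }
  net <- xy[nrow(xy), ] - xy[1, ]
  ln <- tls_line(xy, net = net)
  if (refine && sqrt(sum(net^2)) > 1e-12) {
    ## a strong oscillation can out-weigh the axial spread and flip the raw
    ## principal axis sideways; the net-displacement chord is then the better
    ## starting line — pick whichever the path crosses more often
    chord <- list(point = colMeans(xy), direction = net / sqrt(sum(net^2)))
    n_cross <- vapply(list(ln, chord), function(l) {
      nv <- c(-l$direction[2], l$direction[1])
      br <- crossing_brackets(as.numeric(sweep(xy, 2, l$point) %*% nv))
      if (is.null(br)) 0L else nrow(br)
    }, integer(1))
    if (n_cross[2] > n_cross[1]) ln <- chord
  }
  if (refine) {
    for (it in 1:50) {
      mids <- halfcycle_midpoints(xy, ln$point, ln$direction)
      if (is.null(mids) || nrow(mids) < 2) break
      new <- if (nrow(mids) == 2) {
        dir <- mids[2, ] - mids[1, ]
        dir <- dir / sqrt(sum(dir^2))
        if (sum(dir * ln$direction) < 0) dir <- -dir
        list(point = colMeans(mids), direction = dir)
      } else {
        tls_line(mids, ref_dir = ln$direction)
      }
      delta <- acos(pmin(1, abs(sum(new$direction * ln$direction))))
      ln <- new
      if (delta < 1e-10) break
    }
  }
  list(point = ln$point, direction = ln$direction,
       heading_deg = norm_angle_deg(rad2deg(atan2(ln$direction[2],
                                                  ln$direction[1]))))
}

#' Sinusoidal path-shape metrics: axis crossings, wavelengths, amplitudes
#'
#' Projects the path into axis coordinates (s along the fitted axis, d the
#' signed perpendicular deviation), locates the crossings of the axis by
#' linear interpolation of sign changes of d, and derives the two shape
#' descriptors of the sinusoidal departure: wavelengths as the along-axis
#' distance between alternate crossings (one full period; consecutive
#' crossings of a sinusoid are half a period apart) and amplitudes as the
#' maximum |d| within each half-cycle between consecutive crossings.
#'
#' @param track a `ground_track`.
#' @param full_period if `TRUE` (default) a wavelength spans crossing i to
#'   i+2; if `FALSE`, consecutive crossings (half period).
#' @return a `sinusoid_metrics` list: `axis`, `crossings_s` (positions along
#'   the axis, cm), `wavelengths`, `amplitudes`, `mean_wavelength`,
#'   `mean_amplitude`, `sinusoidal` (FALSE when fewer than 3 crossings, in
#'   which case the metric lists are empty and means NA).
#' @export
extract_sinusoid_metrics <- function(track, full_period = TRUE) {
  axis <- fit_axis(track)
  xy <- as.matrix(track[, c("x_cm", "y_cm")])
  xy <- xy[complete.cases(xy), , drop = FALSE]
  rel <- sweep(xy, 2, axis$point)
  u <- axis$direction
  nv <- c(-u[2], u[1])                         # left normal
  s <- as.numeric(rel %*% u)
  d <- as.numeric(rel %*% nv)

  br <- crossing_brackets(d)
  cross_s <- if (is.null(br)) numeric(0) else {
    s[br[, 1]] + br[, 2] * (s[pmin(br[, 1] + 1, length(s))] - s[br[, 1]])
  }

  res <- list(axis = axis, crossings_s = cross_s)
  if (length(cross_s) < 3) {
    res$sinusoidal <- FALSE
    res$wavelengths <- numeric(0)
    res$amplitudes <- numeric(0)
    res$mean_wavelength <- NA_real_
    res$mean_amplitude <- NA_real_
    class(res) <- "sinusoid_metrics"
    return(res)
  }
  nc <- length(cross_s)
  wl <- if (full_period) {
    cross_s[seq(3, nc)] - cross_s[seq(1, nc - 2)]
  } else {
    diff(cross_s)
  }
  amps <- vapply(seq_len(nc - 1), function(ci) {
    in_seg <- (br[ci, 1] + 1L):br[ci + 1, 1]   # samples between crossings
    if (!length(in_seg)) return(NA_real_)
    max(abs(d[in_seg]))
  }, numeric(1))
  amps <- amps[!is.na(amps) & amps > 0]
  res$sinusoidal <- TRUE
  res$wavelengths <- as.numeric(wl)
  res$amplitudes <- as.numeric(amps)
  res$mean_wavelength <- mean(wl)
  res$mean_amplitude <- mean(amps)
  class(res) <- "sinusoid_metrics"
  res
}

#' @export
print.sinusoid_metrics <- function(x, ...) {
  if (!x$sinusoidal) {
    cat("Path not sinusoidal (fewer than 3 axis crossings)\n")
  } else {
    cat(sprintf(
      "Sinusoid metrics: %d crossings; mean wavelength %.2f cm (n=%d), mean amplitude %.2f cm (n=%d)\n",
      length(x$crossings_s), x$mean_wavelength, length(x$wavelengths),
      x$mean_amplitude, length(x$amplitudes)))
  }
  invisible(x)
}

## instantaneous speeds between consecutive observed samples
step_speeds <- function(track) {
  xy <- as.matrix(track[, c("x_cm", "y_cm")])
  ok <- complete.cases(xy)
  xy <- xy[ok, , drop = FALSE]
  t <- track$t_s[ok]
  if (nrow(xy) < 2) return(numeric(0))
  sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2) / diff(t)
}

#' Frame-wise walking speeds of a track
#'
#' @param track a `ground_track`.
#' @return numeric vector of per-step speeds (cm/s).
#' @export
track_speeds <- function(track) step_speeds(track)

#' Per-excursion summary: path length, duration, mean speed
#'
#' Path length is the sum of segment lengths, duration the elapsed time, mean
#' speed their ratio; `mean_speed_moving` recomputes the mean over segments
#' whose instantaneous speed exceeds `stillness_speed`, excluding pauses where
#' the animal stood still.
#'
#' @param track a `ground_track`.
#' @param stillness_speed pause threshold (cm/s), default 0.5.
#' @param direction_label,excursion_number optional labels carried into the
#'   summary row.
#' @return an `excursion_summary` one-row data.frame with columns
#'   `direction`, `excursion`, `path_length_cm`, `duration_s`,
#'   `mean_speed_cm_s`, `mean_speed_moving_cm_s`, `departure_rate_cm_s` (NA
#'   here; filled by [departure_rate()] users).
#' @export
excursion_summary <- function(track, stillness_speed = 0.5,
                              direction_label = NA_character_,
                              excursion_number = NA_integer_) {
  xy <- as.matrix(track[, c("x_cm", "y_cm")])
  ok <- complete.cases(xy)
  xy <- xy[ok, , drop = FALSE]
  t <- track$t_s[ok]
  if (nrow(xy) < 2) {
    return(structure(data.frame(
      direction = direction_label, excursion = excursion_number,
      path_length_cm = 0, duration_s = 0, mean_speed_cm_s = NA_real_,
      mean_speed_moving_cm_s = NA_real_), class = c("excursion_summary",
                                                    "data.frame")))
  }
  seg <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
  dt <- diff(t)
  len <- sum(seg)
  dur <- t[length(t)] - t[1]
  v <- seg / dt
  moving <- v > stillness_speed
  msm <- if (any(moving)) sum(seg[moving]) / sum(dt[moving]) else NA_real_
  structure(data.frame(
    direction = direction_label, excursion = excursion_number,
    path_length_cm = len, duration_s = dur,
    mean_speed_cm_s = len / dur, mean_speed_moving_cm_s = msm),
    class = c("excursion_summary", "data.frame"))
}

#' Rate of departure from the burrow
#'
#' The direct (straight-line) distance to the burrow as a function of time,
#' with its ordinary least-squares slope — departing animals increase this
#' distance at a roughly constant rate.
#'
#' @param track a `ground_track`.
#' @param burrow burrow position `c(x, y)` in cm (default origin).
#' @return list with `slope_cm_s`, `intercept_cm`, and `series` (data.frame
#'   `t_s`, `distance_cm`).
#' @export
departure_rate <- function(track, burrow = c(0, 0)) {
  xy <- as.matrix(track[, c("x_cm", "y_cm")])
  ok <- complete.cases(xy)
  xy <- xy[ok, , drop = FALSE]
  t <- track$t_s[ok]
  if (length(t) < 3) stopf("need >= 3 observed samples")
  if (diff(range(t)) < 1e-12) stopf("degenerate time span")
  d <- sqrt((xy[, 1] - burrow[1])^2 + (xy[, 2] - burrow[2])^2)
  fit <- lm(d ~ t)
  list(slope_cm_s = unname(coef(fit)[2]), intercept_cm = unname(coef(fit)[1]),
       series = data.frame(t_s = t, distance_cm = d))
}

#' Maximum-likelihood Rayleigh fit to walking speeds
#'
#' Fits Rayleigh(sigma) to non-negative frame-wise speeds by maximum
#' likelihood, `sigma_hat = sqrt(sum(v^2) / (2n))`, and reports the implied
#' distribution mean `sigma*sqrt(pi/2)` and variance `(4 - pi)*sigma^2/2`.
#'
#' @param speeds numeric vector of speeds (cm/s), all >= 0, length >= 2.
#' @return a `rayleigh_fit` list: `sigma`, `mean`, `variance`, `n`.
#' @export
fit_rayleigh <- function(speeds) {
  if (any(speeds < 0, na.rm = TRUE)) stopf("speeds must be >= 0")
  v <- speeds[!is.na(speeds)]
  if (length(v) < 2) stopf("need >= 2 speed samples")
  sigma <- sqrt(sum(v^2) / (2 * length(v)))
  structure(list(sigma = sigma, mean = sigma * sqrt(pi / 2),
                 variance = (4 - pi) * sigma^2 / 2, n = length(v)),
            class = "rayleigh_fit")
}

#' Rayleigh parameters implied by a distribution mean
#'
#' Moment inversion: a Rayleigh with mean m has `sigma = m / sqrt(pi/2)` and
#' variance `(4 - pi)*sigma^2/2`. Reproduces the mean/variance pairing used
#' when a speed distribution is reported as "mean +/- variance" of a Rayleigh
#' fit.
#'
#' @param mean_speed distribution mean (cm/s).
#' @return a `rayleigh_fit` list (with `n = NA`).
#' @export
rayleigh_from_mean <- function(mean_speed) {
  sigma <- mean_speed / sqrt(pi / 2)
  structure(list(sigma = sigma, mean = mean_speed,
                 variance = (4 - pi) * sigma^2 / 2, n = NA_integer_),
            class = "rayleigh_fit")
}

#' @export
print.rayleigh_fit <- function(x, ...) {
  cat(sprintf("Rayleigh fit: sigma = %.4g, mean = %.4g, variance = %.4g (n = %s)\n",
              x$sigma, x$mean, x$variance, format(x$n)))
  invisible(x)
}
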