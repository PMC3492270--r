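#' Tracker configuration
#'
#' Parameters of the batchwise background-subtraction tracker. Defaults follow
#' the published processing settings: 25-frame batches, a 300x300 px crop
#' continuously centred on the spider, and an intensity threshold of 8 (about
#' 3% of the 8-bit range) on the absolute deviation from the batch temporal
#' mean.
#'
#' @param batch_size frames per batch (>= 2).
#' @param crop_size side of the square analysis window in px.
#' @param threshold intensity threshold on |frame - temporal mean| (>= 1).
#' @param min_volume,max_volume voxel-count window for candidate components.
#' @param max_eccentricity maximum mean per-frame cross-section eccentricity
#'   of a candidate component (0 = circular, 1 = line). The default 0.99
#'   rejects pixel-thin streaks (eccentricity > 0.999) while keeping the
#'   animal blob even when slow motion leaves an elongated residual of the
#'   batch mean attached to it (eccentricity around 0.95).
#' @param connectivity spatiotemporal voxel connectivity, 6 or 26.
#' @return a `tracker_config` list.
#' @export
tracker_config <- function(batch_size = 25, crop_size = 300, threshold = 8,
                           min_volume = 50, max_volume = Inf,
                           max_eccentricity = 0.99, connectivity = 26) {
  if (batch_size < 2) stopf("batch_size must be >= 2")
  if (threshold < 1) stopf("threshold must be >= 1")
  if (!connectivity %in% c(6, 26)) stopf("connectivity must be 6 or 26")
  structure(list(batch_size = as.integer(batch_size),
                 crop_size = as.integer(crop_size), threshold = threshold,
                 min_volume = min_volume, max_volume = max_volume,
                 max_eccentricity = max_eccentricity,
                 connectivity = connectivity),
            class = "tracker_config")
}

#' Temporal-mean difference mask of a frame batch
#'
#' Subtracts the per-pixel temporal mean from every frame of the batch and
#' thresholds the absolute deviation: voxel (y, x, k) is TRUE iff
#' `|I_k(y,x) - mean_k I(y,x)| > threshold`. Invariant pixels thus stay small
#' while pixels the animal moves across light up in both sign directions.
#'
#' @param batch numeric array `[h, w, n]`, n >= 2.
#' @param threshold intensity threshold.
#' @return logical array `[h, w, n]`.
#' @export
temporal_diff_mask <- function(batch, threshold = 8) {
  d <- dim(batch)
  if (length(d) != 3 || d[3] < 2) {
    stopf("batch must be an [h, w, n] array with n >= 2 frames")
  }
  mu <- rowMeans(batch, dims = 2)
  abs(batch - as.vector(mu)) > threshold
}

## spatiotemporal connected-component labels of a logical [h, w, n] volume;
## returns integer labels for the TRUE voxels (in `which(mask)` order)
label_voxels <- function(mask, connectivity = 26) {
  d <- dim(mask)
  h <- d[1]; w <- d[2]; n <- d[3]
  idx <- which(mask)
  nv <- length(idx)
  if (nv == 0) return(list(idx = idx, labels = integer(0)))
  i0 <- idx - 1L
  y <- i0 %% h + 1L
  x <- (i0 %/% h) %% w + 1L
  k <- i0 %/% (h * w) + 1L
  offs <- if (connectivity == 6) {
    rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  } else {
    og <- as.matrix(expand.grid(dy = -1:1, dx = -1:1, dk = -1:1))
    og[og %*% c(1, 3, 9) > 0, , drop = FALSE]   # positive half of the 26-hood
  }
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(offs))) {
    y2 <- y + offs[r, 1]; x2 <- x + offs[r, 2]; k2 <- k + offs[r, 3]
    ok <- y2 >= 1 & y2 <= h & x2 >= 1 & x2 <= w & k2 >= 1 & k2 <= n
    key <- (k2[ok] - 1L) * (h * w) + (x2[ok] - 1L) * h + y2[ok]
    m <- match(key, idx)
    hit <- !is.na(m)
    from <- c(from, which(ok)[hit])
    to <- c(to, m[hit])
  }
  g <- igraph::make_empty_graph(nv, directed = FALSE)
  if (length(from)) g <- igraph::add_edges(g, rbind(from, to))
  list(idx = idx, labels = igraph::components(g)$membership,
       coords = cbind(y = y, x = x, k = k))
}

## eccentricity of a 2-D point cloud: sqrt(1 - l2/l1) of its covariance
cross_section_ecc <- function(xy) {
  if (nrow(xy) < 3) return(0)
  ev <- eigen(stats::cov(xy), symmetric = TRUE, only.values = TRUE)$values
  if (ev[1] <= 1e-12) return(0)
  sqrt(max(0, 1 - max(0, ev[2]) / ev[1]))
}

#' Select the spider component from a difference mask
#'
#' Labels the spatiotemporal connected components of the thresholded
#' difference volume, discards components outside the volume window or with
#' over-elongated per-frame cross-sections, and selects the largest survivor
#' as the spider. Its per-frame unweighted voxel centroid is returned for
#' every frame it spans.
#'
#' @param mask logical array `[h, w, n]` from [temporal_diff_mask()].
#' @param cfg a [tracker_config()].
#' @return list with `found` (logical), `centroids` (data.frame `k`, `x`, `y`
#'   in batch-local px; empty if `found` is FALSE), `n_components`,
#'   `n_candidates`, `volume` of the selected component.
#' @export
select_spider_component <- function(mask, cfg = tracker_config()) {
  lab <- label_voxels(mask, cfg$connectivity)
  none <- list(found = FALSE,
               centroids = data.frame(k = integer(0), x = numeric(0),
                                      y = numeric(0)),
               n_components = 0L, n_candidates = 0L, volume = NA_real_)
  if (length(lab$idx) == 0) return(none)
  vols <- tabulate(lab$labels)
  ncomp <- length(vols)
  keep <- which(vols >= cfg$min_volume & vols <= cfg$max_volume)
  if (length(keep)) {
    eccs <- vapply(keep, function(cid) {
      vox <- lab$coords[lab$labels == cid, , drop = FALSE]
      by_k <- split.data.frame(vox[, c("x", "y"), drop = FALSE], vox[, "k"])
      e <- vapply(by_k, function(m) cross_section_ecc(as.matrix(m)), numeric(1))
      if (length(e)) mean(e) else 0
    }, numeric(1))
    keep <- keep[eccs <= cfg$max_eccentricity]
  }
  if (!length(keep)) {
    none$n_components <- ncomp
    return(none)
  }
  sel <- keep[which.max(vols[keep])]
  vox <- lab$coords[lab$labels == sel, , drop = FALSE]
  agg <- split.data.frame(as.data.frame(vox), vox[, "k"])
  cent <- data.frame(
    k = as.integer(names(agg)),
    x = vapply(agg, function(m) mean(m$x), numeric(1)),
    y = vapply(agg, function(m) mean(m$y), numeric(1))
  )
  cent <- cent[order(cent$k), ]
  rownames(cent) <- NULL
  list(found = TRUE, centroids = cent, n_components = ncomp,
       n_candidates = length(keep), volume = vols[sel])
}

#' Track the spider through a frame stack
#'
#' Processes the stack in consecutive batches. Each batch is cropped to a
#' square window centred on the last known position (clamped at the frame
#' borders), the temporal-difference mask is computed, the spider component
#' selected, and its per-frame centroids mapped back to full-frame
#' coordinates. Batches with no surviving component are recorded as gaps and
#' the window is carried forward unchanged.
#'
#' @param stack a [frame_stack()] or a lazy [render_provider()] object.
#' @param init_position initial spider position `c(x, y)` in px.
#' @param cfg a [tracker_config()].
#' @return a `pixel_track`: data.frame with columns `frame`, `t_s`, `x_px`,
#'   `y_px` (NA for undetected frames), with attributes `gaps` (list of frame
#'   index runs with no detection) and `report` (config echo and per-batch
#'   diagnostics).
#' @export
track_video <- function(stack, init_position, cfg = tracker_config()) {
  lazy <- inherits(stack, "frame_provider")
  if (lazy) {
    w <- stack$frame_size[1]; h <- stack$frame_size[2]; n <- stack$n
  } else {
    d <- dim(stack$frames)
    h <- d[1]; w <- d[2]; n <- d[3]
  }
  if (init_position[1] < 1 || init_position[1] > w ||
      init_position[2] < 1 || init_position[2] > h) {
    stopf("init_position (%g, %g) outside the %dx%d frame",
          init_position[1], init_position[2], w, h)
  }
  cw <- min(cfg$crop_size, w)
  ch <- min(cfg$crop_size, h)
  pos <- init_position
  xs <- rep(NA_real_, n); ys <- rep(NA_real_, n)
  batch_starts <- seq(1, n, by = cfg$batch_size)
  batch_log <- vector("list", length(batch_starts))
  for (bi in seq_along(batch_starts)) {
    b0 <- batch_starts[bi]
    b1 <- min(b0 + cfg$batch_size - 1L, n)
    x_off <- max(1L, min(w - cw + 1L, round(pos[1]) - cw %/% 2L))
    y_off <- max(1L, min(h - ch + 1L, round(pos[2]) - ch %/% 2L))
    status <- "no detection"
    if (b1 > b0) {
      sub <- if (lazy) {
        ks <- b0:b1
        arr <- array(0, c(ch, cw, length(ks)))
        for (i in seq_along(ks)) {
          arr[, , i] <- stack$frame(ks[i])[y_off:(y_off + ch - 1L),
                                           x_off:(x_off + cw - 1L)]
        }
        arr
      } else {
        stack$frames[y_off:(y_off + ch - 1L),
                     x_off:(x_off + cw - 1L), b0:b1, drop = FALSE]
      }
      mask <- temporal_diff_mask(sub, cfg$threshold)
      sel <- select_spider_component(mask, cfg)
      if (sel$found) {
        kk <- b0 + sel$centroids$k - 1L
        xs[kk] <- sel$centroids$x + x_off - 1L
        ys[kk] <- sel$centroids$y + y_off - 1L
        pos <- c(xs[max(kk)], ys[max(kk)])
        status <- "ok"
      }
    } else {
      sel <- list(n_components = NA_integer_, volume = NA_real_)
      status <- "short batch (single frame)"
    }
    batch_log[[bi]] <- list(batch = bi, frames = c(b0, b1),
                            window = c(x = x_off, y = y_off),
                            n_components = sel$n_components,
                            volume = sel$volume, status = status)
  }
  track <- data.frame(frame = seq_len(n), t_s = stack$timestamps,
                      x_px = xs, y_px = ys)
  miss <- is.na(xs)
  gaps <- if (any(miss)) {
    r <- rle(miss)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    Map(c, starts[r$values], ends[r$values])
  } else list()
  attr(track, "gaps") <- gaps
  attr(track, "report") <- list(
    config = unclass(cfg),
    n_frames = n, n_detected = sum(!miss), n_batches = length(batch_starts),
    batches = batch_log
  )
  class(track) <- c("pixel_track", "data.frame")
  track
}
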