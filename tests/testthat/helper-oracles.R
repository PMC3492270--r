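# Independent oracles, samplers and fixture builders used across the suite.

## descriptor table with two iid groups (no true group effect)
null_table <- function(seed, n1 = 6, n2 = 6) {
  withr::with_seed(seed, data.frame(
    excursion_number = rep(1:2, c(n1, n2)),
    mean_wavelength_cm = rlnorm(n1 + n2, log(50), 0.3),
    mean_amplitude_cm = rlnorm(n1 + n2, log(20), 0.3)
  ))
}

## brute-force per-voxel recomputation of the temporal-difference mask
brute_force_mask <- function(batch, threshold) {
  d <- dim(batch)
  out <- array(FALSE, d)
  for (yy in seq_len(d[1])) {
    for (xx in seq_len(d[2])) {
      mu <- mean(batch[yy, xx, ])
      for (kk in seq_len(d[3])) {
        out[yy, xx, kk] <- abs(batch[yy, xx, kk] - mu) > threshold
      }
    }
  }
  out
}

## naive double-loop PERMANOVA pseudo-F (Anderson's distance-based one-way
## partition, written independently of the package implementation)
naive_pseudo_F <- function(D, groups) {
  D <- as.matrix(D)
  g <- as.character(groups)
  N <- nrow(D)
  levs <- unique(g)
  a <- length(levs)
  ss_t <- 0
  for (i in 1:(N - 1)) for (j in (i + 1):N) ss_t <- ss_t + D[i, j]^2
  ss_t <- ss_t / N
  ss_w <- 0
  for (lev in levs) {
    idx <- which(g == lev)
    if (length(idx) < 2) next
    acc <- 0
    for (ii in seq_along(idx)) {
      for (jj in seq_along(idx)) {
        if (ii < jj) acc <- acc + D[idx[ii], idx[jj]]^2
      }
    }
    ss_w <- ss_w + acc / length(idx)
  }
  ss_a <- ss_t - ss_w
  (ss_a / (a - 1)) / (ss_w / (N - a))
}

## von Mises sampler (Best & Fisher 1979 rejection scheme); mu in degrees
rvonmises_deg <- function(n, mu_deg, kappa) {
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1
  while (i <= n) {
    u1 <- runif(1); u2 <- runif(1); u3 <- runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      out[i] <- sign(u3 - 0.5) * acos(f)
      i <- i + 1
    }
  }
  spiderwalk::norm_angle_deg(mu_deg + out * 180 / pi)
}

## rigid rotation+translation of a ground track
transform_track <- function(track, theta_deg = 0, shift = c(0, 0)) {
  th <- theta_deg * pi / 180
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  xy <- as.matrix(track[, c("x_cm", "y_cm")]) %*% t(R)
  out <- track
  out$x_cm <- xy[, 1] + shift[1]
  out$y_cm <- xy[, 2] + shift[2]
  out
}
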