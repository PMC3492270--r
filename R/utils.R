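#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif lm coef prcomp quantile sd median var complete.cases
#' @importFrom utils read.csv head tail modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize angles to (-180, 180] degrees
#'
#' @param a numeric vector of angles in degrees.
#' @return angles wrapped into the half-open interval (-180, 180].
#' @export
norm_angle_deg <- function(a) {
  r <- a %% 360
  r[r > 180] <- r[r > 180] - 360
  r
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

## run expr under an explicit seed without disturbing global RNG state;
## seed = NULL means use the current stream (still reproducible if caller seeded)
with_seed_opt <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## fixed-format numeric for locale-independent, byte-stable CSV output
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.10g", v)
  }, character(1))
  out
}
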