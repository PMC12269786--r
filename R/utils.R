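# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Mean Earth radius used for every great-circle computation in the package.
EARTH_RADIUS_M <- 6371000
M_PER_DEG_LAT <- pi / 180 * EARTH_RADIUS_M

m_per_deg_lon <- function(lat) M_PER_DEG_LAT * cos(lat * pi / 180)

stopifnot_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  }
  invisible(x)
}

# Centred moving average; ends padded with zero (signals are zero-baseline).
moving_average <- function(x, w) {
  w <- as.integer(w)
  if (w <= 1L) return(as.numeric(x))
  y <- stats::filter(x, rep(1 / w, w), sides = 2)
  y[is.na(y)] <- 0
  as.numeric(y)
}

# Sub-sample peak refinement: parabola through (i-1, i, i+1) on a transformed
# scale. For Gaussian-enveloped pulses the log-envelope is exactly quadratic
# near the peak, so the fit is unbiased there.
parabolic_peak <- function(y, i, log_scale = TRUE) {
  n <- length(y)
  if (i <= 1L || i >= n) return(list(pos = i, value = y[i]))
  v <- y[(i - 1L):(i + 1L)]
  if (log_scale) {
    if (any(v <= 0)) return(list(pos = i, value = y[i]))
    v <- log(v)
  }
  denom <- v[1] - 2 * v[2] + v[3]
  if (!is.finite(denom) || denom >= 0) return(list(pos = i, value = y[i]))
  d <- 0.5 * (v[1] - v[3]) / denom
  d <- max(-0.5, min(0.5, d))
  list(pos = i + d, value = y[i])
}
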