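# Seeded synthetic data: multipulse clicks, click trains, bathymetry and
# whole survey scenes with retained ground truth. Everything here is a pure
# function of (spec, seed).

#' Specification of a synthetic sperm whale click
#'
#' A sperm whale click is a packet of transient pulses: a weak direct pulse
#' p0 followed by the dominant spermaceti-reverberation pulse p1 and decaying
#' repetitions p2, p3. The pulse spacing is the inter-pulse interval (IPI),
#' which scales with head (hence body) length. Each pulse is modelled as a
#' Gaussian-windowed tone burst whose energy sits above the 1 kHz analysis
#' high-pass.
#'
#' @param ipi_ms True inter-pulse interval in milliseconds (> 0).
#' @param pulse_amplitudes Relative amplitudes of p0..p3; p1 must be the
#'   maximum (it carries most of the emitted energy).
#' @param pulse_band Passband of each pulse transient, Hz (lo, hi). The burst
#'   carrier sits at the band centre.
#' @param snr_db Peak signal-to-noise ratio: p1 peak amplitude over ambient
#'   noise RMS, in dB. `Inf` means noise-free.
#' @param sample_rate Samples per second; must be at least twice the upper
#'   band edge.
#' @param pulse_dur_ms Effective duration of one pulse transient (ms).
#' @param vessel_snr_db Optional low-frequency (< 1 kHz) vessel-noise level,
#'   expressed like `snr_db`; `Inf` disables it. Exists to exercise the
#'   high-pass stage.
#' @return A validated `click_spec` list.
#' @export
click_spec <- function(ipi_ms = 4,
                       pulse_amplitudes = c(p0 = 0.3, p1 = 1, p2 = 0.45, p3 = 0.2),
                       pulse_band = c(2000, 8000),
                       snr_db = 20,
                       sample_rate = 96000,
                       pulse_dur_ms = 0.5,
                       vessel_snr_db = Inf) {
  stopifnot_scalar_num(ipi_ms, "ipi_ms", positive = TRUE)
  if (!is.numeric(pulse_amplitudes) || length(pulse_amplitudes) < 2L ||
      length(pulse_amplitudes) > 4L || any(pulse_amplitudes < 0)) {
    stop("`pulse_amplitudes` must give 2-4 non-negative amplitudes (p0, p1, ...)",
         call. = FALSE)
  }
  if (which.max(pulse_amplitudes) != 2L) {
    stop("p1 (second pulse) must carry the maximum amplitude", call. = FALSE)
  }
  if (length(pulse_band) != 2L || pulse_band[1] <= 0 || pulse_band[2] <= pulse_band[1]) {
    stop("`pulse_band` must be an increasing positive (lo, hi) pair", call. = FALSE)
  }
  stopifnot_scalar_num(sample_rate, "sample_rate", positive = TRUE)
  if (sample_rate < 2 * pulse_band[2]) {
    stop(sprintf(
      "sample_rate (%g Hz) is below the Nyquist requirement of 2 x %g Hz for the pulse passband",
      sample_rate, pulse_band[2]), call. = FALSE)
  }
  stopifnot_scalar_num(pulse_dur_ms, "pulse_dur_ms", positive = TRUE)
  structure(list(
    ipi_ms = ipi_ms, pulse_amplitudes = pulse_amplitudes,
    pulse_band = pulse_band, snr_db = snr_db, sample_rate = sample_rate,
    pulse_dur_ms = pulse_dur_ms, vessel_snr_db = vessel_snr_db
  ), class = "click_spec")
}

# Add one click (pulse packet) into `x` in place; p1 centred at time `t_p1`
# seconds. Pulses are evaluated on the continuous time grid (no snapping to
# samples) so generator truth is exact.
add_click_pulses <- function(x, fs, t_p1, spec) {
  amps <- spec$pulse_amplitudes
  f0 <- mean(spec$pulse_band)
  sigma <- spec$pulse_dur_ms / 1000 / 6
  offs <- (seq_along(amps) - 2L) * spec$ipi_ms / 1000   # p0 before p1
  for (k in seq_along(amps)) {
    if (amps[k] <= 0) next
    c_t <- t_p1 + offs[k]
    i0 <- max(1L, floor((c_t - 4 * sigma) * fs) + 1L)
    i1 <- min(length(x), ceiling((c_t + 4 * sigma) * fs) + 1L)
    if (i1 < i0) next
    tt <- (seq.int(i0, i1) - 1L) / fs - c_t
    x[i0:i1] <- x[i0:i1] + amps[k] * exp(-tt^2 / (2 * sigma^2)) * cos(2 * pi * f0 * tt)
  }
  x
}

add_ambient_noise <- function(x, fs, spec, p1_amp = max(spec$pulse_amplitudes)) {
  if (is.finite(spec$snr_db)) {
    sd_n <- p1_amp / 10^(spec$snr_db / 20)
    x <- x + stats::rnorm(length(x), 0, sd_n)
  }
  if (is.finite(spec$vessel_snr_db)) {
    sd_v <- p1_amp / 10^(spec$vessel_snr_db / 20)
    lp <- signal::butter(2, min(0.99, 1000 / (fs / 2)), type = "low")
    v <- as.numeric(signal::filter(lp, stats::rnorm(length(x), 0, 1)))
    x <- x + sd_v * v / max(stats::sd(v), 1e-12)
  }
  x
}

#' Synthesise one multipulse click
#'
#' Generates a click whose pulse k (k = 0..3) is centred at
#' `t0 + k * ipi_ms`, embedded in white Gaussian ambient noise at the
#' specified peak SNR. Deterministic for a fixed seed.
#'
#' @param spec A [click_spec()].
#' @param t0 Time of pulse p0 from segment start, seconds (>= 0).
#' @param seed Integer seed for the noise generator.
#' @param duration_s Optional total duration; defaults to the pulse packet
#'   plus a 5 ms tail.
#' @return An [audio_segment()] with a `truth` attribute: list with `p1_time`
#'   (s), `ipi_ms`, and the pulse centre times.
#' @export
synth_click <- function(spec, t0 = 0, seed = 1, duration_s = NULL) {
  stopifnot(inherits(spec, "click_spec"))
  if (t0 < 0) stop("`t0` must be >= 0", call. = FALSE)
  fs <- spec$sample_rate
  n_pulse <- length(spec$pulse_amplitudes)
  packet_end <- t0 + (n_pulse - 1) * spec$ipi_ms / 1000
  duration_s <- duration_s %||% (packet_end + 0.005)
  n <- ceiling(duration_s * fs)
  x <- numeric(n)
  t_p1 <- t0 + spec$ipi_ms / 1000
  x <- add_click_pulses(x, fs, t_p1, spec)
  x <- withr::with_seed(seed, add_ambient_noise(x, fs, spec))
  out <- audio_segment(x, fs)
  attr(out, "truth") <- list(
    p1_time = t_p1, ipi_ms = spec$ipi_ms,
    pulse_times = t0 + (seq_len(n_pulse) - 1L) * spec$ipi_ms / 1000
  )
  out
}

#' Specification of a synthetic click train
#'
#' Click trains fall into three inter-click-interval (ICI) regimes: regular
#' clicks (ICI 0.5-2 s, echolocation search), buzzes/creaks (ICI 0.02-0.2 s,
#' prey capture) and codas (3-20 clicks over 0.2-2 s, social). The spec is
#' validated against its regime.
#'
#' @param kind One of `"regular"`, `"buzz"`, `"coda"`.
#' @param n_clicks Number of clicks (>= 1).
#' @param ici_s Fixed ICI (length 1) or uniform ICI range (length 2), seconds.
#'   For codas it may be omitted when `duration_s` is given.
#' @param duration_s Coda total duration, seconds; implies a fixed ICI of
#'   `duration_s / (n_clicks - 1)`.
#' @return A validated `train_spec` list.
#' @export
train_spec <- function(kind = c("regular", "buzz", "coda"),
                       n_clicks, ici_s = NULL, duration_s = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(n_clicks) || length(n_clicks) != 1L || n_clicks < 1 ||
      n_clicks != round(n_clicks)) {
    stop("`n_clicks` must be a positive integer", call. = FALSE)
  }
  if (kind == "coda" && is.null(ici_s)) {
    if (is.null(duration_s)) stop("coda spec needs `ici_s` or `duration_s`", call. = FALSE)
    if (n_clicks < 2) stop("a coda needs at least 2 clicks to have a duration", call. = FALSE)
    ici_s <- duration_s / (n_clicks - 1)
  }
  if (is.null(ici_s) || !length(ici_s) %in% 1:2 || any(ici_s <= 0)) {
    stop("`ici_s` must be a positive scalar or (lo, hi) range", call. = FALSE)
  }
  rng <- range(ici_s)
  if (kind == "regular" && (rng[1] < 0.5 || rng[2] > 2)) {
    stop("regular clicks require ICI within [0.5, 2] s", call. = FALSE)
  }
  if (kind == "buzz" && (rng[1] < 0.02 || rng[2] > 0.2)) {
    stop("buzzes require ICI within [0.02, 0.2] s", call. = FALSE)
  }
  if (kind == "coda") {
    if (n_clicks < 3 || n_clicks > 20) {
      stop("codas have 3 to 20 clicks", call. = FALSE)
    }
    dur <- duration_s %||% ((n_clicks - 1) * mean(rng))
    if (dur < 0.2 || dur > 2) {
      stop("coda duration must lie in [0.2, 2] s", call. = FALSE)
    }
  }
  structure(list(kind = kind, n_clicks = as.integer(n_clicks), ici_s = ici_s,
                 duration_s = duration_s),
            class = "train_spec")
}

#' Synthesise a click train with known truth
#'
#' Draws ICIs from the train spec's distribution, places one multipulse click
#' per emission and returns both the rendered audio and the exact truth
#' (click p1 times, ICIs, kind).
#'
#' @param train A [train_spec()].
#' @param click A [click_spec()] shared by all clicks in the train.
#' @param seed Integer seed (ICI draws and noise).
#' @param t_start Time of the first click's p1, seconds.
#' @param render_audio If `FALSE`, only the truth is generated (fast path for
#'   large classification fixtures).
#' @return List with `audio` (or `NULL`), `truth` (a [click_train()] whose
#'   `kind` is the generating regime) and `icis_s`.
#' @export
synth_train <- function(train, click, seed = 1, t_start = 0.5, render_audio = TRUE) {
  stopifnot(inherits(train, "train_spec"), inherits(click, "click_spec"))
  n <- train$n_clicks
  icis <- withr::with_seed(seed, {
    if (n <= 1L) numeric(0)
    else if (length(train$ici_s) == 1L) rep(train$ici_s, n - 1L)
    else stats::runif(n - 1L, train$ici_s[1], train$ici_s[2])
  })
  times <- t_start + cumsum(c(0, icis))
  truth <- click_train(
    data.frame(time_s = times,
               peak_amplitude = rep(max(click$pulse_amplitudes), n),
               snr_db = rep(click$snr_db, n)),
    kind = train$kind
  )
  audio <- NULL
  if (render_audio) {
    fs <- click$sample_rate
    tail_s <- (length(click$pulse_amplitudes) - 1) * click$ipi_ms / 1000 + 0.05
    x <- numeric(ceiling((max(times) + tail_s) * fs))
    for (tc in times) x <- add_click_pulses(x, fs, tc, click)
    x <- withr::with_seed(seed + 1L, add_ambient_noise(x, fs, click))
    audio <- audio_segment(x, fs)
  }
  list(audio = audio, truth = truth, icis_s = icis)
}

# --- bathymetry --------------------------------------------------------------

#' Regular bathymetry grid
#'
#' Depths are metres below the sea surface (positive down); land cells are
#' `NA`. Rows run south-to-north from `origin["lat"]`, columns west-to-east
#' from `origin["lon"]`. Cells are square in degrees (`cell_m` metres along
#' a meridian, on a sphere of radius 6,371,000 m), which keeps the ESRI
#' ASCII export exact; every spatial query works in lat/lon, so the metric
#' anisotropy of a degree of longitude is handled at query time.
#'
#' @param depths Numeric matrix of depths (m), `NA` on land.
#' @param origin Named vector `c(lat = , lon = )` of the (1,1) cell centre.
#' @param cell_m Cell size in metres (> 0).
#' @return A `bathy_grid` object with `lat` and `lon` cell-centre vectors.
#' @export
bathy_grid <- function(depths, origin = c(lat = 14.5, lon = -61.3), cell_m = 250) {
  if (!is.matrix(depths) || !is.numeric(depths)) {
    stop("`depths` must be a numeric matrix", call. = FALSE)
  }
  if (any(depths < 0, na.rm = TRUE)) {
    stop("depths are positive-down metres; negative values are not allowed", call. = FALSE)
  }
  stopifnot_scalar_num(cell_m, "cell_m", positive = TRUE)
  lat <- origin[["lat"]] + (seq_len(nrow(depths)) - 1L) * cell_m / M_PER_DEG_LAT
  lon <- origin[["lon"]] + (seq_len(ncol(depths)) - 1L) * cell_m / M_PER_DEG_LAT
  structure(list(depths = depths, lat = lat, lon = lon, cell_m = cell_m,
                 origin = origin),
            class = "bathy_grid")
}

#' @export
print.bathy_grid <- function(x, ...) {
  cat(sprintf("<bathy_grid> %d x %d cells, %g m; depth %g-%g m\n",
              nrow(x$depths), ncol(x$depths), x$cell_m,
              min(x$depths, na.rm = TRUE), max(x$depths, na.rm = TRUE)))
  invisible(x)
}

#' Synthesise a shelf-slope-canyon bathymetry with its coastline
#'
#' Emulates a steep island margin: a shallow shelf, a ramp down to the
#' maximum depth, and an optional canyon (a Gaussian across-shore deepening).
#' Depth increases monotonically offshore (west to east in grid coordinates)
#' outside and inside the canyon; the zero-depth coastline is the western
#' grid edge.
#'
#' @param n_rows,n_cols Grid dimensions (> 1).
#' @param cell_m Cell size in metres.
#' @param profile List: `shelf_width_m`, `shelf_depth_m`, `ramp_width_m`,
#'   `max_depth_m` (> 0), optional `canyon = list(row_frac, width_m,
#'   extra_depth_m)`, optional `flat_depth_m` for a constant-depth test grid.
#' @param origin Named `c(lat=, lon=)` of the south-west cell centre.
#' @param seed Integer seed (kept for interface symmetry; the surface is
#'   deterministic).
#' @return List with `grid` (a [bathy_grid()]) and `coastline` (data frame of
#'   `lat`, `lon` tracing the zero-depth line).
#' @export
synth_bathymetry <- function(n_rows, n_cols, cell_m = 250,
                             profile = list(), origin = c(lat = 14.5, lon = -61.3),
                             seed = 1) {
  if (n_rows < 2 || n_cols < 2 || cell_m <= 0) {
    stop("grid dimensions and cell size must be positive (at least 2 x 2 cells)",
         call. = FALSE)
  }
  p <- utils::modifyList(list(shelf_width_m = 2000, shelf_depth_m = 100,
                              ramp_width_m = 10000, max_depth_m = 2500,
                              canyon = NULL, flat_depth_m = NULL), profile)
  if (!is.null(p$flat_depth_m)) {
    depths <- matrix(p$flat_depth_m, n_rows, n_cols)
  } else {
    if (p$max_depth_m <= 0) stop("`max_depth_m` must be > 0", call. = FALSE)
    # metric offshore distance of each column (cells are square in degrees,
    # so a column step spans cell_m * cos(lat) metres east-west)
    x <- (seq_len(n_cols) - 1L) * cell_m * cos(origin[["lat"]] * pi / 180)
    base <- ifelse(
      x <= p$shelf_width_m,
      p$shelf_depth_m * x / p$shelf_width_m,
      p$shelf_depth_m + (p$max_depth_m - p$shelf_depth_m) *
        pmin(1, (x - p$shelf_width_m) / p$ramp_width_m)
    )
    depths <- matrix(base, n_rows, n_cols, byrow = TRUE)
    if (!is.null(p$canyon)) {
      cy <- utils::modifyList(list(row_frac = 0.5, width_m = 2000,
                                   extra_depth_m = 500), p$canyon)
      y <- (seq_len(n_rows) - 1L) * cell_m
      y0 <- cy$row_frac * (n_rows - 1L) * cell_m
      gauss <- exp(-(y - y0)^2 / (2 * (cy$width_m / 2)^2))
      depths <- depths * (1 + outer(gauss, base / p$max_depth_m *
                                              cy$extra_depth_m / p$max_depth_m))
    }
  }
  grid <- bathy_grid(depths, origin = origin, cell_m = cell_m)
  coastline <- data.frame(lat = grid$lat, lon = rep(grid$lon[1], n_rows))
  list(grid = grid, coastline = coastline)
}
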