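# IPI measurement, per-individual summaries, piecewise length conversion and
# age/sex classing.

#' Piecewise IPI-to-body-length conversion
#'
#' Body length (animal size, AS, metres) from the inter-pulse interval (ms).
#' Two published regressions cover the size range: a quadratic for animals
#' under about 11 m,
#' \deqn{AS = 4.833 + 1.453\,IPI - 0.001\,IPI^2,}
#' and a linear one for larger animals,
#' \deqn{AS = 1.258\,IPI + 5.736.}
#' Their stated validity limits (IPI < 4.250 ms and IPI > 4.184 ms) overlap;
#' the automatic rule switches strictly at 4.250 ms (quadratic below, linear
#' at and above), where the two curves differ by under 0.11 m and both round
#' to 11 m.
#'
#' @param ipi_ms Inter-pulse interval(s) in milliseconds (> 0).
#' @param equation `"auto"` (piecewise switch), or force `"quadratic"` /
#'   `"linear"`.
#' @return Estimated body length(s) in metres.
#' @seealso [ipi_from_size()], [classify_individual()]
#' @export
size_from_ipi <- function(ipi_ms, equation = c("auto", "quadratic", "linear")) {
  equation <- match.arg(equation)
  if (!is.numeric(ipi_ms) || any(!is.finite(ipi_ms)) || any(ipi_ms <= 0)) {
    stop("`ipi_ms` must be positive and finite", call. = FALSE)
  }
  quad <- 4.833 + 1.453 * ipi_ms - 0.001 * ipi_ms^2
  lin <- 1.258 * ipi_ms + 5.736
  switch(equation,
    quadratic = quad,
    linear = lin,
    auto = ifelse(ipi_ms < 4.250, quad, lin)
  )
}

#' Invert the length conversion
#'
#' Exact inverse of [size_from_ipi()] (needed by the synthetic generator):
#' the quadratic branch is inverted on its physical (smaller) root, the
#' linear branch directly. The switch mirrors the forward rule: lengths below
#' the quadratic's value at 4.250 ms use the quadratic inverse. The forward
#' map jumps by about 0.09 m at the 4.250 ms switch, so lengths inside the
#' unattained band (about 10.99-11.08 m) have no exact preimage; they map to
#' the switch point itself.
#'
#' @param length_m Body length(s) in metres, within the invertible range
#'   (about 5.5-20 m).
#' @return IPI(s) in milliseconds such that
#'   `size_from_ipi(ipi_from_size(L)) == L` to within 1e-9 m for every
#'   attainable length.
#' @export
ipi_from_size <- function(length_m) {
  if (!is.numeric(length_m) || any(!is.finite(length_m)) ||
      any(length_m < 5.5) || any(length_m > 20)) {
    stop("`length_m` must lie in the invertible range [5.5, 20] m", call. = FALSE)
  }
  switch_len <- size_from_ipi(4.250, equation = "quadratic")
  disc <- 1.453^2 - 4 * 0.001 * (length_m - 4.833)
  quad_inv <- (1.453 - sqrt(pmax(disc, 0))) / (2 * 0.001)
  lin_inv <- pmax((length_m - 5.736) / 1.258, 4.250)
  ifelse(length_m < switch_len, quad_inv, lin_inv)
}

#' Assign age/sex class from IPI
#'
#' Three classes: IPI < 2.9 ms (AS < 9 m) is an immature; 2.9-5.0 ms
#' (9-12 m) a female or juvenile male; above 5.0 ms (> 12 m) an adult male.
#' Exact boundary values resolve downward-inclusive into the middle class.
#'
#' @param ipi_ms IPI(s) in milliseconds (> 0).
#' @return Character vector: `"immature"`, `"female_or_juvenile_male"` or
#'   `"adult_male"`.
#' @export
classify_individual <- function(ipi_ms) {
  if (!is.numeric(ipi_ms) || any(!is.finite(ipi_ms)) || any(ipi_ms <= 0)) {
    stop("`ipi_ms` must be positive and finite", call. = FALSE)
  }
  ifelse(ipi_ms < 2.9, "immature",
         ifelse(ipi_ms <= 5.0, "female_or_juvenile_male", "adult_male"))
}

no_ipi <- function(method, reason) {
  structure(list(ipi_ms = NA_real_, method = method, quality = NA_real_,
                 reason = reason),
            class = "ipi_measurement")
}

ipi_measurement <- function(ipi_ms, method, quality) {
  structure(list(ipi_ms = ipi_ms, method = method,
                 quality = max(min(quality, 1), .Machine$double.eps), reason = NULL),
            class = "ipi_measurement")
}

#' @export
print.ipi_measurement <- function(x, ...) {
  if (is.na(x$ipi_ms)) {
    cat(sprintf("<ipi_measurement> no IPI (%s, %s)\n", x$method, x$reason))
  } else {
    cat(sprintf("<ipi_measurement> %.3f ms (%s, quality %.2f)\n",
                x$ipi_ms, x$method, x$quality))
  }
  invisible(x)
}

extract_click_window <- function(audio, time_s, before_ms, after_ms, ch = 1L) {
  fs <- audio$sample_rate
  x <- channel_samples(audio, ch)
  i0 <- max(1L, floor((time_s - before_ms / 1000) * fs) + 1L)
  i1 <- min(length(x), ceiling((time_s + after_ms / 1000) * fs) + 1L)
  list(x = x[i0:i1], t0 = (i0 - 1L) / fs)
}

#' Envelope-method IPI measurement
#'
#' Measures the p1-to-p2 interval of one click: p1 is the dominant smoothed
#' envelope peak near the detection time; p2 the largest subsequent local
#' peak within the search window. Both peaks are refined to sub-sample
#' precision by a parabolic fit on the log-envelope (exact for Gaussian
#' pulses). Quality is the p2/p1 prominence ratio; below `quality_floor`
#' a no-IPI result is returned, never a fabricated value.
#'
#' @param audio High-passed [audio_segment()] containing the click.
#' @param click One detected click: list or one-row data frame with `time_s`.
#' @param search_ms Search window after p1 for p2, ms. The lower bound sits
#'   below the 2 ms acceptance floor so that visually confirmed calves
#'   (IPI down to about 1.9 ms) are still measurable; the floor itself is
#'   applied in [summarize_individual()]. The 10 ms upper bound is the head
#'   size limit.
#' @param smooth_ms Envelope smoothing for the p2 search, ms. Wider than the
#'   detection envelope to stabilise the secondary-peak pick in noise.
#' @param quality_floor Minimum p2/p1 ratio for a valid measurement.
#' @param prominence_k p2 must exceed the search-window envelope median by
#'   `prominence_k` MADs; this encodes the field protocol of measuring only
#'   clicks whose pulses are clearly visible, and makes the method return
#'   no-IPI rather than a noise peak when p2 is buried.
#' @return An `ipi_measurement`: `ipi_ms`, `method = "envelope"`, `quality`;
#'   `ipi_ms` is `NA` with a `reason` when no credible p2 exists.
#' @export
estimate_ipi_envelope <- function(audio, click, search_ms = c(1.5, 10),
                                  smooth_ms = 0.25, quality_floor = 0.1,
                                  prominence_k = 4) {
  stopifnot(inherits(audio, "audio_segment"))
  t_click <- if (is.list(click)) click$time_s[1] else click[1]
  if (search_ms[2] > 10) stop("search window must stay below 10 ms (head size bound)",
                              call. = FALSE)
  fs <- audio$sample_rate
  w <- extract_click_window(audio, t_click, before_ms = 1, after_ms = search_ms[2] + 2)
  env <- click_envelope(w$x, fs, smooth_ms = smooth_ms)
  i_p1 <- which.max(env)
  p1 <- parabolic_peak(env, i_p1)
  lo <- i_p1 + round(search_ms[1] / 1000 * fs)
  hi <- min(length(env), i_p1 + round(search_ms[2] / 1000 * fs))
  if (hi - lo < 2L) return(no_ipi("envelope", "search window outside segment"))
  seg <- env[lo:hi]
  n <- length(seg)
  loc <- which(seg[2:(n - 1L)] > seg[1:(n - 2L)] & seg[2:(n - 1L)] >= seg[3:n]) + 1L
  if (!length(loc)) return(no_ipi("envelope", "no secondary peak"))
  floor_p2 <- stats::median(seg) + prominence_k * stats::mad(seg)
  loc <- loc[seg[loc] >= floor_p2]
  if (!length(loc)) return(no_ipi("envelope", "no secondary peak above the noise floor"))
  i_p2 <- loc[which.max(seg[loc])]
  quality <- seg[i_p2] / p1$value
  if (quality < quality_floor) return(no_ipi("envelope", "secondary peak below quality floor"))
  p2 <- parabolic_peak(seg, i_p2)
  ipi_ms <- ((lo - 1L + p2$pos) - p1$pos) / fs * 1000
  ipi_measurement(ipi_ms, "envelope", quality)
}

#' Cepstrum-method IPI measurement
#'
#' Independent cross-check of the envelope method: the real cepstrum of a
#' multipulse click shows a peak at the pulse spacing (all p0..p3 spacings
#' are multiples of the IPI and reinforce it). The dominant cepstral peak in
#' the search band gives the IPI; quality is one minus the ratio of the
#' second-highest to the highest cepstral peak (peak dominance), so a
#' featureless (noise) cepstrum is rejected.
#'
#' @inheritParams estimate_ipi_envelope
#' @param search_ms Quefrency band searched, ms.
#' @param window_ms Analysis window around the click, ms.
#' @return An `ipi_measurement` with `method = "cepstrum"`.
#' @export
estimate_ipi_cepstrum <- function(audio, click, search_ms = c(1.5, 10),
                                  window_ms = 40, quality_floor = 0.1) {
  stopifnot(inherits(audio, "audio_segment"))
  t_click <- if (is.list(click)) click$time_s[1] else click[1]
  fs <- audio$sample_rate
  w <- extract_click_window(audio, t_click, before_ms = window_ms / 2,
                            after_ms = window_ms / 2)
  x <- w$x - mean(w$x)
  nfft <- stats::nextn(length(x), c(2, 3, 5))
  X <- stats::fft(c(x * signal::hanning(length(x)), numeric(nfft - length(x))))
  P <- Mod(X)^2
  ceps <- Re(stats::fft(log(P + 1e-12 * max(P, .Machine$double.eps)), inverse = TRUE)) / nfft
  q_ms <- (seq_len(nfft) - 1L) / fs * 1000
  band <- which(q_ms >= search_ms[1] & q_ms <= search_ms[2])
  if (length(band) < 5L) return(no_ipi("cepstrum", "band too narrow at this sample rate"))
  seg <- ceps[band]
  i_max <- which.max(seg)
  peak <- seg[i_max]
  if (!is.finite(peak) || peak <= 0) return(no_ipi("cepstrum", "no positive cepstral peak"))
  # second-highest peak outside +/- 0.5 ms of the main one
  excl <- abs(q_ms[band] - q_ms[band][i_max]) <= 0.5
  rest <- seg[!excl]
  second <- if (length(rest)) max(rest) else 0
  quality <- 1 - max(second, 0) / peak
  if (quality < quality_floor) return(no_ipi("cepstrum", "cepstral peak not dominant"))
  p <- parabolic_peak(seg, i_max, log_scale = FALSE)
  ipi_measurement(q_ms[band][1] + (p$pos - 1L) / fs * 1000, "cepstrum", quality)
}

#' Summarise repeated IPI measurements into a per-individual estimate
#'
#' The survey protocol measures the IPI about ten times per individual and
#' averages. Means below the 2 ms floor are rejected (falsely low IPIs from
#' prolonged p1 pulses) unless the presence of a calf was confirmed
#' visually. Warning flags mark short measurement series and high spread.
#'
#' @param measurements Numeric vector of IPI values (ms), or a list of
#'   `ipi_measurement` objects (failed measurements are dropped).
#' @param n_required Measurements expected per individual; fewer sets the
#'   `low_n` flag.
#' @param floor_ms Minimum acceptable mean IPI (ms).
#' @param sd_warn_ms Standard deviation above which the `high_sd` flag is set.
#' @param calf_confirmed Visual override admitting a sub-floor mean.
#' @return List of class `individual_estimate`: `ipi_mean_ms`, `ipi_sd_ms`,
#'   `n_measurements`, `length_m`, `class_label`, `calf_confirmed`,
#'   `accepted`, `flags`. Rejected estimates carry `accepted = FALSE` and
#'   `NA` length/class.
#' @export
summarize_individual <- function(measurements, n_required = 10, floor_ms = 2.0,
                                 sd_warn_ms = 0.2, calf_confirmed = FALSE) {
  if (is.list(measurements) && length(measurements) &&
      inherits(measurements[[1]], "ipi_measurement")) {
    measurements <- vapply(measurements, function(m) m$ipi_ms, numeric(1))
  }
  measurements <- measurements[is.finite(measurements)]
  if (!length(measurements)) stop("no valid IPI measurements supplied", call. = FALSE)
  m <- mean(measurements)
  s <- if (length(measurements) > 1L) stats::sd(measurements) else NA_real_
  flags <- character(0)
  if (length(measurements) < n_required) flags <- c(flags, "low_n")
  if (is.finite(s) && s > sd_warn_ms) flags <- c(flags, "high_sd")
  accepted <- m >= floor_ms || isTRUE(calf_confirmed)
  if (!accepted) flags <- c(flags, "below_ipi_floor")
  structure(list(
    ipi_mean_ms = m, ipi_sd_ms = s, n_measurements = length(measurements),
    length_m = if (accepted) size_from_ipi(m) else NA_real_,
    class_label = if (accepted) classify_individual(m) else NA_character_,
    calf_confirmed = isTRUE(calf_confirmed),
    accepted = accepted, flags = flags
  ), class = "individual_estimate")
}

#' @export
print.individual_estimate <- function(x, ...) {
  if (x$accepted) {
    cat(sprintf("<individual_estimate> IPI %.2f +/- %s ms (n=%d) -> %.2f m, %s%s\n",
                x$ipi_mean_ms,
                if (is.na(x$ipi_sd_ms)) "NA" else sprintf("%.2f", x$ipi_sd_ms),
                x$n_measurements, x$length_m, x$class_label,
                if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  } else {
    cat(sprintf("<individual_estimate> rejected (mean IPI %.2f ms below floor)\n",
                x$ipi_mean_ms))
  }
  invisible(x)
}

#' Group IPI measurements into putative individuals
#'
#' Clicks from one animal share an IPI; distinguishing IPI values is how the
#' number of vocal individuals in an aggregation is counted. Measurements
#' are grouped by single-linkage in IPI space: sorted values are split
#' wherever the gap to the next exceeds `tol_ms` (chaining allowed).
#'
#' @param ipi_ms Numeric vector of per-click IPI measurements (ms); `NA`s are
#'   dropped.
#' @param tol_ms Linkage tolerance, ms.
#' @return List of integer index vectors into `ipi_ms`, one per individual,
#'   ordered by increasing IPI. Empty input gives an empty list.
#' @export
cluster_individuals <- function(ipi_ms, tol_ms = 0.15) {
  keep <- which(is.finite(ipi_ms))
  if (!length(keep)) return(list())
  ord <- keep[order(ipi_ms[keep])]
  v <- ipi_ms[ord]
  grp <- cumsum(c(1, as.integer(diff(v) > tol_ms)))
  unname(split(ord, grp))
}
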