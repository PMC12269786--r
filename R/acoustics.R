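# Filtering, click detection, train segmentation, ICI classification and the
# acoustic ethogram.

#' Ordered click train
#'
#' @param clicks Data frame with at least `time_s` (strictly increasing);
#'   optional `peak_amplitude`, `snr_db`.
#' @param kind Train type: `"regular"`, `"buzz"`, `"coda"` or `"unknown"`.
#' @return A `click_train` with `icis_s` = successive time differences.
#' @export
click_train <- function(clicks, kind = "unknown") {
  stopifnot(is.data.frame(clicks), "time_s" %in% names(clicks))
  if (nrow(clicks) > 1L && any(diff(clicks$time_s) <= 0)) {
    stop("click times must be strictly increasing", call. = FALSE)
  }
  kind <- match.arg(kind, c("regular", "buzz", "coda", "unknown"))
  structure(list(clicks = clicks, icis_s = diff(clicks$time_s), kind = kind),
            class = "click_train")
}

#' @export
print.click_train <- function(x, ...) {
  cat(sprintf("<click_train> %d clicks, kind = %s", nrow(x$clicks), x$kind))
  if (length(x$icis_s)) cat(sprintf(", median ICI = %.3f s", stats::median(x$icis_s)))
  cat("\n")
  invisible(x)
}

#' Zero-phase high-pass filter
#'
#' Removes wave and vessel noise below the sperm whale click band. A 4th
#' order Butterworth applied forward-backward (`signal::filtfilt`), so click
#' times are not shifted; the effective roll-off is 8th order (about 48 dB
#' one octave below the cutoff).
#'
#' @param audio An [audio_segment()].
#' @param cutoff_hz Cutoff frequency, Hz; must be below Nyquist. The study
#'   protocol isolates the signal above 1 kHz.
#' @return Filtered [audio_segment()].
#' @export
highpass <- function(audio, cutoff_hz = 1000) {
  stopifnot(inherits(audio, "audio_segment"))
  nyq <- audio$sample_rate / 2
  if (cutoff_hz >= nyq) {
    stop(sprintf("cutoff (%g Hz) must be below Nyquist (%g Hz)", cutoff_hz, nyq),
         call. = FALSE)
  }
  bf <- signal::butter(4, cutoff_hz / nyq, type = "high")
  filt1 <- function(x) {
    if (all(x == 0)) return(x)
    as.numeric(signal::filtfilt(bf, x))
  }
  s <- audio$samples
  if (is.matrix(s)) {
    for (j in seq_len(ncol(s))) s[, j] <- filt1(s[, j])
  } else {
    s <- filt1(s)
  }
  audio_segment(s, audio$sample_rate, audio$channel_id)
}

# Detection on one channel. Events are local envelope maxima above a robust
# threshold (median + k * MAD); a refractory rule keeps the stronger of two
# peaks closer than refractory_ms; pulse-dominance suppression drops peaks
# with a >= dominance_ratio times larger peak within +/- pulse_window_ms,
# which collapses the p0/p2/p3 satellites of a multipulse click onto p1
# (distinct clicks, even in the fastest buzzes, have comparable amplitudes
# and survive).
detect_clicks_channel <- function(x, fs, threshold_k, refractory_ms, min_snr_db,
                                  pulse_window_ms, dominance_ratio, smooth_ms) {
  env <- click_envelope(x, fs, smooth_ms = smooth_ms)
  med <- stats::median(env)
  thr <- max(med + threshold_k * stats::mad(env), 1e-6 * max(env), .Machine$double.eps)
  n <- length(env)
  if (n < 3L) return(data.frame(time_s = numeric(0), peak_amplitude = numeric(0),
                                snr_db = numeric(0)))
  is_peak <- env[2:(n - 1L)] > env[1:(n - 2L)] & env[2:(n - 1L)] >= env[3:n] &
    env[2:(n - 1L)] > thr
  idx <- which(is_peak) + 1L
  if (!length(idx)) return(data.frame(time_s = numeric(0), peak_amplitude = numeric(0),
                                      snr_db = numeric(0)))
  amp <- env[idx]
  # refractory: greedy strongest-first, drop neighbours closer than refractory
  ref_n <- refractory_ms / 1000 * fs
  ord <- order(amp, decreasing = TRUE)
  keep <- logical(length(idx))
  taken <- rep(FALSE, length(idx))
  for (j in ord) {
    if (taken[j]) next
    keep[j] <- TRUE
    taken[abs(idx - idx[j]) < ref_n] <- TRUE
  }
  idx <- idx[keep]; amp <- env[idx]
  # pulse-dominance suppression
  win_n <- pulse_window_ms / 1000 * fs
  keep2 <- vapply(seq_along(idx), function(j) {
    near <- abs(idx - idx[j]) <= win_n
    all(amp[near] < dominance_ratio * amp[j])
  }, logical(1))
  idx <- idx[keep2]; amp <- amp[keep2]
  # local SNR against the Rayleigh noise floor of the envelope
  noise_rms <- med / sqrt(2 * log(2))
  snr <- 20 * log10(amp / max(noise_rms, 1e-12 * max(amp), .Machine$double.eps))
  ok <- snr >= min_snr_db
  data.frame(time_s = (idx[ok] - 1L) / fs, peak_amplitude = amp[ok], snr_db = snr[ok])
}

#' Detect clicks in high-passed audio
#'
#' Events are local maxima of the smoothed amplitude envelope exceeding
#' `median + threshold_k * MAD` (robust to the clicks themselves). Two rules
#' clean the raw maxima: a refractory rule (no two events closer than
#' `refractory_ms`, stronger wins) and pulse-dominance suppression, which
#' drops satellite pulses of the same multipulse click (any peak having a
#' 1.5x larger peak within `pulse_window_ms`), so each click is reported
#' once, at its dominant pulse p1. Stereo input is detected per channel and
#' deduplicated within 0.5 ms, keeping the higher-SNR event.
#'
#' @param audio High-passed [audio_segment()].
#' @param threshold_k MAD multiplier for the detection threshold.
#' @param refractory_ms Minimum event separation, ms.
#' @param min_snr_db Events below this local SNR estimate are discarded.
#' @param pulse_window_ms Half-width of the dominance window, ms; covers the
#'   p0..p3 packet for the largest IPIs (about 3 x 7.8 ms).
#' @param dominance_ratio Amplitude ratio above which a neighbour suppresses
#'   a peak.
#' @param smooth_ms Envelope smoothing window, ms.
#' @return Data frame of events sorted by time: `time_s`, `peak_amplitude`,
#'   `snr_db`. Empty when nothing exceeds the threshold.
#' @export
detect_clicks <- function(audio, threshold_k = 6, refractory_ms = 2,
                          min_snr_db = 6, pulse_window_ms = 25,
                          dominance_ratio = 1.5, smooth_ms = 0.1) {
  stopifnot(inherits(audio, "audio_segment"))
  fs <- audio$sample_rate
  per_ch <- lapply(seq_len(n_channels(audio)), function(ch) {
    d <- detect_clicks_channel(channel_samples(audio, ch), fs, threshold_k,
                               refractory_ms, min_snr_db, pulse_window_ms,
                               dominance_ratio, smooth_ms)
    if (nrow(d)) d$channel <- ch
    d
  })
  det <- do.call(rbind, per_ch[vapply(per_ch, nrow, 1L) > 0])
  if (is.null(det) || !nrow(det)) {
    return(data.frame(time_s = numeric(0), peak_amplitude = numeric(0),
                      snr_db = numeric(0)))
  }
  det <- det[order(det$time_s, -det$snr_db), , drop = FALSE]
  if (n_channels(audio) > 1L) {
    # cross-channel dedup within 0.5 ms, keep higher SNR
    keep <- rep(TRUE, nrow(det))
    last_t <- -Inf
    for (i in seq_len(nrow(det))) {
      if (det$time_s[i] - last_t < 0.0005) keep[i] <- FALSE else last_t <- det$time_s[i]
    }
    det <- det[keep, , drop = FALSE]
  }
  det$channel <- NULL
  rownames(det) <- NULL
  det
}

#' Segment a click sequence into trains
#'
#' A new train starts whenever the gap to the previous click exceeds
#' `gap_s` (2 s, the top of the regular-click ICI range, by default). Every
#' click belongs to exactly one train.
#'
#' @param clicks Data frame of detected clicks sorted by `time_s`.
#' @param gap_s Gap that terminates a train, seconds.
#' @return List of [click_train()] objects (classified via [classify_train()]).
#' @export
segment_trains <- function(clicks, gap_s = 2.0) {
  if (is.null(clicks) || !nrow(clicks)) return(list())
  if (is.unsorted(clicks$time_s, strictly = FALSE)) {
    stop("`clicks` must be sorted by time", call. = FALSE)
  }
  grp <- cumsum(c(1, as.integer(diff(clicks$time_s) > gap_s)))
  lapply(split(clicks, grp), function(d) {
    tr <- click_train(d)
    tr$kind <- classify_train(tr)
    tr
  })
}

#' Classify a click train by its ICI regime
#'
#' Decision rule, in priority order: (1) coda if 3-20 clicks, total duration
#' 0.2-2 s and median ICI < 0.5 s; (2) buzz if median ICI in \[0.02, 0.2\] s;
#' (3) regular if median ICI in \[0.5, 2\] s; (4) unknown otherwise. The coda
#' test runs first because a short fast series satisfies the buzz ICI bound
#' too; the click-count bound separates long buzzes from codas.
#'
#' @param train A [click_train()] with at least one click.
#' @return One of `"regular"`, `"buzz"`, `"coda"`, `"unknown"`.
#' @export
classify_train <- function(train) {
  stopifnot(inherits(train, "click_train"))
  n <- nrow(train$clicks)
  if (n < 1L) stop("train must contain at least one click", call. = FALSE)
  if (n == 1L) return("unknown")
  dur <- train$clicks$time_s[n] - train$clicks$time_s[1]
  med <- stats::median(train$icis_s)
  if (n >= 3L && n <= 20L && dur >= 0.2 && dur <= 2 && med < 0.5) return("coda")
  if (med >= 0.02 && med <= 0.2) return("buzz")
  if (med >= 0.5 && med <= 2) return("regular")
  "unknown"
}

#' Decode behaviours from click trains and visual notes
#'
#' The acoustic ethogram: hunting requires both regular clicks and buzzes on
#' the recording; socialising requires at least one coda. Moving and resting
#' have no acoustic signature and can only come from visual notes. Several
#' behaviours may co-occur in one aggregation.
#'
#' @param trains List of [click_train()] objects (possibly empty).
#' @param visual_notes Character vector of visual behaviour notes; entries
#'   `"moving"` and `"resting"` are recognised.
#' @return List with `behaviours` (character subset of hunting, socialising,
#'   moving, resting) and `evidence` (named list mapping each behaviour to
#'   its source).
#' @export
infer_behaviours <- function(trains = list(), visual_notes = character(0)) {
  kinds <- vapply(trains, function(tr) tr$kind, character(1))
  behaviours <- character(0)
  evidence <- list()
  if (any(kinds == "regular") && any(kinds == "buzz")) {
    behaviours <- c(behaviours, "hunting")
    evidence$hunting <- paste0("acoustic: trains ",
                               paste(which(kinds %in% c("regular", "buzz")), collapse = ","))
  }
  if (any(kinds == "coda")) {
    behaviours <- c(behaviours, "socialising")
    evidence$socialising <- paste0("acoustic: trains ",
                                   paste(which(kinds == "coda"), collapse = ","))
  }
  for (b in c("moving", "resting")) {
    if (any(grepl(b, tolower(visual_notes), fixed = TRUE))) {
      behaviours <- c(behaviours, b)
      evidence[[b]] <- "visual"
    }
  }
  list(behaviours = behaviours, evidence = evidence)
}
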