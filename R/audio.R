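#' Sampled audio segment
#'
#' Lightweight container for a sampled pressure series. Samples are stored as
#' a numeric vector (mono) or a matrix with one column per channel, in
#' normalised dimensionless amplitude; `sample_rate` is in samples per second.
#'
#' @param samples Numeric vector (mono) or matrix (columns = channels) of
#'   finite sample values.
#' @param sample_rate Sampling rate in Hz (> 0).
#' @param channel_id Optional channel label(s).
#' @return An object of class `audio_segment`.
#' @export
audio_segment <- function(samples, sample_rate, channel_id = NULL) {
  if (is.data.frame(samples)) samples <- as.matrix(samples)
  if (!is.numeric(samples)) stop("`samples` must be numeric", call. = FALSE)
  if (anyNA(samples) || !all(is.finite(samples))) {
    stop("`samples` must contain finite values only", call. = FALSE)
  }
  stopifnot_scalar_num(sample_rate, "sample_rate", positive = TRUE)
  structure(
    list(samples = samples, sample_rate = sample_rate, channel_id = channel_id),
    class = "audio_segment"
  )
}

#' @export
print.audio_segment <- function(x, ...) {
  cat(sprintf(
    "<audio_segment> %d samples x %d channel(s), %g Hz (%.3f s)\n",
    n_samples(x), n_channels(x), x$sample_rate, duration_s(x)
  ))
  invisible(x)
}

#' @rdname audio_segment
#' @param x An `audio_segment`.
#' @export
n_samples <- function(x) if (is.matrix(x$samples)) nrow(x$samples) else length(x$samples)

#' @rdname audio_segment
#' @export
n_channels <- function(x) if (is.matrix(x$samples)) ncol(x$samples) else 1L

#' @rdname audio_segment
#' @export
duration_s <- function(x) n_samples(x) / x$sample_rate

channel_samples <- function(x, ch = 1L) {
  if (is.matrix(x$samples)) x$samples[, ch] else x$samples
}

# --- analytic signal / envelope ---------------------------------------------

# FFT-based Hilbert transform (zero-padded to a 2-3-5 smooth length).
analytic_signal <- function(x) {
  n <- length(x)
  nfft <- stats::nextn(n, c(2, 3, 5))
  X <- stats::fft(c(x, numeric(nfft - n)))
  h <- numeric(nfft)
  if (nfft %% 2L == 0L) {
    h[1] <- 1; h[nfft / 2 + 1] <- 1; h[2:(nfft / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((nfft + 1) / 2)] <- 2
  }
  a <- stats::fft(X * h, inverse = TRUE) / nfft
  a[seq_len(n)]
}

#' Smoothed amplitude envelope
#'
#' Magnitude of the analytic (Hilbert) signal, smoothed with a centred moving
#' window. The 0.1 ms default preserves the sub-millisecond pulse structure of
#' sperm whale clicks while removing carrier ripple.
#'
#' @param x Numeric sample vector.
#' @param sample_rate Sampling rate in Hz.
#' @param smooth_ms Moving-average window length in milliseconds.
#' @return Numeric envelope, same length as `x`.
#' @export
click_envelope <- function(x, sample_rate, smooth_ms = 0.1) {
  e <- Mod(analytic_signal(x))
  w <- max(1L, round(smooth_ms / 1000 * sample_rate))
  moving_average(e, w)
}

# --- WAV I/O -----------------------------------------------------------------
# Minimal linear-PCM RIFF/WAVE support (16- or 24-bit, any channel count).

#' Write an audio segment to a PCM WAV file
#'
#' @param audio An [audio_segment()]. Samples are clipped to \[-1, 1\].
#' @param path Output file path.
#' @param bit_depth 16 or 24 (the study's recorders wrote 96 kHz / 24-bit).
#' @return `path`, invisibly.
#' @export
write_wav <- function(audio, path, bit_depth = 24) {
  stopifnot(inherits(audio, "audio_segment"), bit_depth %in% c(16, 24))
  s <- audio$samples
  if (!is.matrix(s)) s <- matrix(s, ncol = 1L)
  s[s > 1] <- 1; s[s < -1] <- -1
  n_ch <- ncol(s)
  n <- nrow(s)
  full <- 2^(bit_depth - 1) - 1
  v <- as.integer(round(t(s) * full))  # interleaved channel-major
  bytes_per <- bit_depth / 8
  data_size <- n * n_ch * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                 # PCM
  writeBin(as.integer(n_ch), con, size = 2, endian = "little")
  writeBin(as.integer(audio$sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(audio$sample_rate * n_ch * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(n_ch * bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bit_depth), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bit_depth == 16) {
    writeBin(v, con, size = 2, endian = "little")
  } else {
    u <- v + (v < 0L) * 16777216L
    b <- rbind(u %% 256L, (u %/% 256L) %% 256L, u %/% 65536L)
    writeBin(as.raw(b), con)
  }
  invisible(path)
}

#' Read a PCM WAV file
#'
#' @param path WAV file path (16- or 24-bit linear PCM).
#' @return An [audio_segment()]; stereo files give a two-column sample matrix.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        format = readBin(con, integer(), size = 2, endian = "little"),
        channels = readBin(con, integer(), size = 2, endian = "little"),
        rate = readBin(con, integer(), size = 4, endian = "little"),
        byte_rate = readBin(con, integer(), size = 4, endian = "little"),
        block_align = readBin(con, integer(), size = 2, endian = "little"),
        bits = readBin(con, integer(), size = 2, endian = "little")
      )
      if (size > 16) invisible(readBin(con, raw(), n = size - 16))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, raw(), n = size)
      break
    } else {
      invisible(readBin(con, raw(), n = size + size %% 2L))
    }
  }
  if (is.null(fmt) || is.null(data_raw)) stop("incomplete WAV file: ", path, call. = FALSE)
  if (fmt$format != 1L || !fmt$bits %in% c(16L, 24L)) {
    stop("only 16/24-bit linear PCM WAV is supported", call. = FALSE)
  }
  full <- 2^(fmt$bits - 1) - 1
  if (fmt$bits == 16L) {
    v <- readBin(data_raw, integer(), n = length(data_raw) / 2, size = 2,
                 signed = TRUE, endian = "little")
  } else {
    m <- matrix(as.integer(data_raw), nrow = 3L)
    u <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
    v <- u - (u >= 8388608) * 16777216
  }
  x <- v / full
  if (fmt$channels > 1L) {
    x <- t(matrix(x, nrow = fmt$channels))
  }
  audio_segment(x, fmt$rate)
}
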