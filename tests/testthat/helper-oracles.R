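# Independent oracles used against the package implementations.

# Brute-force connected components of the pairwise within-radius graph.
components_oracle <- function(lat, lon, radius_m) {
  n <- length(lat)
  if (n == 0) return(integer(0))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    adj[i, j] <- haversine(lat[i], lon[i], lat[j], lon[j]) <= radius_m
  }
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    k <- k + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- k
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# Textbook pooled-variance two-sample t.
pooled_t_oracle <- function(y1, y2) {
  n1 <- length(y1); n2 <- length(y2)
  sp2 <- ((n1 - 1) * var(y1) + (n2 - 1) * var(y2)) / (n1 + n2 - 2)
  t <- (mean(y2) - mean(y1)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = n1 + n2 - 2,
       p = 2 * pt(-abs(t), n1 + n2 - 2))
}

# Step-down Holm by direct loop (independent of stats::p.adjust).
holm_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  run <- 0
  for (i in seq_len(m)) {
    run <- max(run, min(1, (m - i + 1) * p[o[i]]))
    adj[o[i]] <- run
  }
  adj
}

# Envelope-peak oracle on noiseless audio: sample-grid argmax peak times.
noiseless_peak_times <- function(audio) {
  env <- click_envelope(channel_samples(audio), audio$sample_rate, smooth_ms = 0.1)
  thr <- 0.05 * max(env)
  n <- length(env)
  idx <- which(env[2:(n - 1)] > env[1:(n - 2)] & env[2:(n - 1)] >= env[3:n] &
                 env[2:(n - 1)] > thr) + 1L
  (idx - 1) / audio$sample_rate
}

clean_click <- function(ipi_ms, seed = 1, t0 = 0.01, duration_s = 0.06) {
  synth_click(click_spec(ipi_ms = ipi_ms, snr_db = Inf), t0 = t0, seed = seed,
              duration_s = duration_s)
}
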