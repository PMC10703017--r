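# Shared fixtures: all synthetic, built in code at test time.

# Small-band set usable at fs = 128 (gamma capped below Nyquist).
bands_128 <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13),
       beta = c(13, 30), gamma = c(30, 55))
}

# A small, fast cohort spec for pipeline-level tests.
tiny_cohort_spec <- function(n_pd = 3L, n_hc = 3L, duration = 10,
                             beta_ratio = 3, gain_sd = 0.1, seed = 1L,
                             ...) {
  cohort_spec(n_pd = n_pd, n_hc = n_hc, n_channels = 4L, fs = 128,
              duration = duration, bands = bands_128(),
              beta_ratio = beta_ratio, gain_sd = gain_sd, seed = seed, ...)
}

# Welch band power via stats::spec.pgram with smoothing — an independent
# spectral oracle (never the package's own code path).
welch_band_power <- function(x, fs, band) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), spans = 25,
                          plot = FALSE, detrend = TRUE, taper = 0.1)
  sel <- sp$freq >= band[1] & sp$freq <= band[2]
  mean(sp$spec[sel]) * diff(band)
}

# Literal, loop-by-loop transcription of the LSTM gate equations —
# deliberately scalar and index-based, independent of the package's
# vectorized implementation.
oracle_lstm_step <- function(x_t, h_prev, c_prev, p) {
  U <- length(h_prev)
  z <- c(h_prev, x_t)
  i <- f <- o <- chat <- numeric(U)
  for (u in seq_len(U)) {
    i[u] <- 1 / (1 + exp(-(sum(p$W_i[u, ] * z) + p$b_i[u])))
    f[u] <- 1 / (1 + exp(-(sum(p$W_f[u, ] * z) + p$b_f[u])))
    o[u] <- 1 / (1 + exp(-(sum(p$W_o[u, ] * z) + p$b_o[u])))
    chat[u] <- tanh(sum(p$W_c[u, ] * z) + p$b_c[u])
  }
  c_new <- f * c_prev + i * chat
  list(h = o * tanh(c_new), c = c_new)
}

oracle_lstm_forward <- function(X, p) {
  h <- numeric(p$units)
  cc <- numeric(p$units)
  H <- matrix(0, nrow(X), p$units)
  for (t in seq_len(nrow(X))) {
    st <- oracle_lstm_step(X[t, ], h, cc, p)
    h <- st$h
    cc <- st$c
    H[t, ] <- h
  }
  H
}

oracle_bilstm_forward <- function(X, p) {
  T_len <- nrow(X)
  Hf <- oracle_lstm_forward(X, p$forward)
  Hb <- matrix(0, T_len, p$backward$units)
  h <- numeric(p$backward$units)
  cc <- numeric(p$backward$units)
  for (t in rev(seq_len(T_len))) {
    st <- oracle_lstm_step(X[t, ], h, cc, p$backward)
    h <- st$h
    cc <- st$c
    Hb[t, ] <- h
  }
  cbind(Hf, Hb)
}

# Dense, untruncated brute-force evaluation of the Gabor sum.
oracle_gabor_dense <- function(x, fs, cfg) {
  n <- length(x)
  steps <- ((n - 1L) %/% cfg$hop) + 1L
  centers <- (seq_len(steps) - 1L) * cfg$hop
  out <- matrix(0i, steps, length(cfg$freqs))
  for (k in seq_len(steps)) {
    for (j in seq_along(cfg$freqs)) {
      f <- cfg$freqs[j]
      acc <- 0i
      for (tau in seq_len(n)) {
        dt <- (tau - 1L - centers[k]) / fs
        acc <- acc + x[tau] * exp(-dt^2 / (2 * cfg$sigma_t^2)) *
          exp(-1i * 2 * pi * f * dt)
      }
      out[k, j] <- acc / fs
    }
  }
  out
}

# Features + labels for a preprocessed tiny cohort, shared by the
# cross-validation tests.
tiny_features <- function(spec, amp_threshold = 200) {
  recs <- generate_cohort(spec)$recordings
  fcfg <- filter_config(band_high = 55)
  segs <- bind_segments(lapply(recs, function(r) {
    r <- bandpass_filter(r, fcfg)
    r <- notch_filter(r, fcfg)
    suppressMessages(reject_artifacts(segment(r, 256L, 256L),
                                      amp_threshold = amp_threshold))
  }))
  segments_to_features(segs, gabor_config(freqs = seq(2, 40, 2), hop = 16L))
}
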