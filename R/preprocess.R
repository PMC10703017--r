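# Preprocessing: band-pass and notch filtering, segmentation, artifact
# rejection (amplitude threshold, optionally ICA-assisted) and
# normalization.

#' Filter configuration
#'
#' @param band_low,band_high band-pass edges in Hz (defaults 0.5 and 100,
#'   the conventional EEG analysis band).
#' @param notch_freq mains frequency to notch, 50 or 60 Hz depending on
#'   region.
#' @param notch_q notch quality factor (center frequency / -3 dB width).
#' @param order Butterworth order for the band-pass.
#' @param zero_phase apply filters forward-backward (no group delay).
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(band_low = 0.5, band_high = 100, notch_freq = 50,
                          notch_q = 30, order = 4L, zero_phase = TRUE) {
  cfg <- structure(list(band_low = band_low, band_high = band_high,
                        notch_freq = notch_freq, notch_q = notch_q,
                        order = as.integer(order), zero_phase = zero_phase),
                   class = "filter_config")
  if (cfg$band_low <= 0 || cfg$band_high <= cfg$band_low) {
    fail_field("band_low/band_high", "need 0 < band_low < band_high")
  }
  if (cfg$order < 1) fail_field("order", "must be >= 1")
  if (cfg$notch_q <= 0) fail_field("notch_q", "must be > 0")
  cfg
}

check_cfg_vs_fs <- function(cfg, fs) {
  if (cfg$band_high >= fs / 2) {
    stop(sprintf("band_high (%g Hz) must be below the Nyquist frequency (%g Hz)",
                 cfg$band_high, fs / 2), call. = FALSE)
  }
  if (cfg$notch_freq >= fs / 2) {
    stop(sprintf("notch_freq (%g Hz) must be below the Nyquist frequency (%g Hz)",
                 cfg$notch_freq, fs / 2), call. = FALSE)
  }
}

apply_filt <- function(data, b, a, zero_phase) {
  flt <- signal::Arma(b = b, a = a)
  t(apply(data, 1L, function(x) {
    if (zero_phase) signal::filtfilt(flt, x) else
      as.numeric(signal::filter(flt, x))
  }))
}

# Butterworth band-pass as cascaded second-order sections. A high-order
# band-pass with edges far below Nyquist is numerically ill-conditioned in
# direct form (poles crowd the unit circle), so the design is factored
# into biquads, pairing each conjugate pole pair with the nearest zero
# pair (all band-pass zeros sit at z = +1 or z = -1) to keep every
# section's gain moderate.
butter_sos <- function(order, band, fs) {
  zp <- signal::as.Zpg(signal::butter(order, band / (fs / 2), type = "pass"))
  poles <- zp$pole[Im(zp$pole) > 1e-12]
  real_poles <- Re(zp$pole[abs(Im(zp$pole)) <= 1e-12])
  # available zero pairs: `order` double zeros at +1 and at -1
  n_pos <- sum(Re(zp$zero) > 0)
  n_neg <- length(zp$zero) - n_pos
  avail <- c(pos = n_pos %/% 2L, neg = n_neg %/% 2L)
  sections <- list()
  for (p in poles[order(-Mod(poles))]) {
    pick <- if (avail["pos"] > 0 &&
                (avail["neg"] == 0 || Mod(p - 1) <= Mod(p + 1))) "pos"
            else "neg"
    avail[pick] <- avail[pick] - 1L
    b <- if (pick == "pos") c(1, -2, 1) else c(1, 2, 1)
    sections[[length(sections) + 1L]] <-
      list(b = b, a = c(1, -2 * Re(p), Mod(p)^2))
  }
  for (p in real_poles) {      # odd orders only
    pick <- if (avail["pos"] > 0) "pos" else "neg"
    avail[pick] <- avail[pick] - 1L
    sections[[length(sections) + 1L]] <-
      list(b = if (pick == "pos") c(1, -1) else c(1, 1), a = c(1, -p))
  }
  list(sections = sections, gain = Re(zp$gain))
}

apply_sos <- function(data, sos, zero_phase) {
  g <- if (zero_phase) sos$gain^2 else sos$gain
  t(apply(data, 1L, function(x) {
    for (s in sos$sections) {
      flt <- signal::Arma(b = s$b, a = s$a)
      x <- if (zero_phase) signal::filtfilt(flt, x) else
        as.numeric(signal::filter(flt, x))
    }
    x * g
  }))
}

#' Band-pass filter a recording
#'
#' Per-channel Butterworth band-pass between `band_low` and `band_high`,
#' applied forward-backward when `zero_phase` (the default), so the filter
#' introduces no group delay. Shape is preserved.
#'
#' @param rec an [eeg_recording()].
#' @param cfg a [filter_config()].
#' @return the filtered [eeg_recording()].
#' @export
bandpass_filter <- function(rec, cfg = filter_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  check_cfg_vs_fs(cfg, rec$fs)
  sos <- butter_sos(cfg$order, c(cfg$band_low, cfg$band_high), rec$fs)
  rec$data <- apply_sos(rec$data, sos, cfg$zero_phase)
  rec
}

# Biquad notch coefficients (constrained second-order section with zeros on
# the unit circle at +/- the notch frequency).
notch_coeffs <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Notch filter a recording
#'
#' Narrowband IIR (biquad) rejection at `notch_freq` to suppress mains
#' interference; zero-phase when configured. Shape is preserved.
#'
#' @inheritParams bandpass_filter
#' @return the filtered [eeg_recording()].
#' @export
notch_filter <- function(rec, cfg = filter_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  check_cfg_vs_fs(cfg, rec$fs)
  co <- notch_coeffs(cfg$notch_freq, rec$fs, cfg$notch_q)
  rec$data <- apply_filt(rec$data, co$b, co$a, cfg$zero_phase)
  rec
}

#' Segment a recording into fixed-length windows
#'
#' Cuts `window_len`-sample windows every `hop` samples, yielding
#' `floor((samples - window_len)/hop) + 1` segments, each carrying the
#' source recording's subject id and label. A window longer than the
#' recording yields zero segments with a warning (not an error).
#'
#' @param rec an [eeg_recording()].
#' @param window_len window length in samples (default 1024, i.e. 2 s at
#'   512 Hz).
#' @param hop step between window starts in samples (default = window_len,
#'   non-overlapping).
#' @return an object of class `segment_set`: list with `segments`
#'   (n x channels x window array), `window_len`, `hop`, `fs`,
#'   `subject_ids`, `labels`, `starts` (0-based window start samples) and
#'   `kept_mask`.
#' @export
segment <- function(rec, window_len = 1024L, hop = window_len) {
  stopifnot(inherits(rec, "eeg_recording"))
  window_len <- as.integer(window_len)
  hop <- as.integer(hop)
  if (window_len < 1L || hop < 1L) {
    fail_field("window_len/hop", "must be >= 1")
  }
  n <- ncol(rec$data)
  if (window_len > n) {
    warning(sprintf("window_len (%d) exceeds recording length (%d); returning 0 segments",
                    window_len, n))
    n_seg <- 0L
  } else {
    n_seg <- (n - window_len) %/% hop + 1L
  }
  segs <- array(0, dim = c(n_seg, nrow(rec$data), window_len))
  starts <- integer(n_seg)
  for (i in seq_len(n_seg)) {
    s0 <- (i - 1L) * hop
    segs[i, , ] <- rec$data[, (s0 + 1L):(s0 + window_len), drop = FALSE]
    starts[i] <- s0
  }
  structure(
    list(segments = segs, window_len = window_len, hop = hop, fs = rec$fs,
         subject_ids = rep(rec$subject_id, n_seg),
         labels = rep(rec$label, n_seg), starts = starts,
         kept_mask = rep(TRUE, n_seg)),
    class = "segment_set"
  )
}

#' Combine segment sets from several recordings
#'
#' @param sets list of `segment_set` objects sharing window length, hop
#'   and sampling rate.
#' @return one pooled `segment_set`.
#' @export
bind_segments <- function(sets) {
  sets <- Filter(function(s) dim(s$segments)[1] > 0, sets)
  if (length(sets) == 0L) stop("no non-empty segment sets to bind", call. = FALSE)
  ref <- sets[[1]]
  for (s in sets[-1]) {
    if (s$window_len != ref$window_len || s$hop != ref$hop || s$fs != ref$fs) {
      stop("segment sets differ in window_len, hop or fs", call. = FALSE)
    }
  }
  all_segs <- do.call(abind3, lapply(sets, function(s) s$segments))
  structure(
    list(segments = all_segs, window_len = ref$window_len, hop = ref$hop,
         fs = ref$fs,
         subject_ids = unlist(lapply(sets, function(s) s$subject_ids)),
         labels = unlist(lapply(sets, function(s) s$labels)),
         starts = unlist(lapply(sets, function(s) s$starts)),
         kept_mask = unlist(lapply(sets, function(s) s$kept_mask))),
    class = "segment_set"
  )
}

# rbind for 3-d arrays along the first margin.
abind3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  total <- sum(vapply(parts, function(p) dim(p)[1], 0L))
  out <- array(0, dim = c(total, d[2], d[3]))
  at <- 0L
  for (p in parts) {
    k <- dim(p)[1]
    if (k > 0) out[at + seq_len(k), , ] <- p
    at <- at + k
  }
  out
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf(
    "<segment_set> %d segments (%d kept) x %d ch x %d samples @ %g Hz, %d subject(s)\n",
    dim(x$segments)[1], sum(x$kept_mask), dim(x$segments)[2], x$window_len,
    x$fs, length(unique(x$subject_ids))))
  invisible(x)
}

# Minimal symmetric FastICA (logcosh contrast) on a channels x samples
# matrix. Deterministic: the unmixing matrix is initialized from a fixed
# seeded draw. Returns sources S (components x samples), mixing matrix A
# and row means, with X ~ A %*% S + mean.
fastica_decompose <- function(X, max_iter = 200L, tol = 1e-6, seed = 1L) {
  n_comp <- nrow(X)
  mu <- rowMeans(X)
  Xc <- X - mu
  C <- Xc %*% t(Xc) / ncol(Xc)
  eig <- eigen(C, symmetric = TRUE)
  pos <- pmax(eig$values, max(eig$values) * 1e-12)
  K <- diag(1 / sqrt(pos), n_comp) %*% t(eig$vectors)   # whitening
  Z <- K %*% Xc
  W <- with_seed(seed, matrix(stats::rnorm(n_comp^2), n_comp))
  sym_orth <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_orth(W)
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    Gp <- 1 - G^2
    W1 <- G %*% t(Z) / ncol(Z) - diag(rowMeans(Gp), n_comp) %*% W
    W1 <- sym_orth(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) break
  }
  S <- W %*% Z
  A <- solve(W %*% K)        # mixing: X ~ A S + mu
  list(S = S, A = A, mean = mu)
}

#' Reject artifact-contaminated segments
#'
#' Marks `kept_mask = FALSE` for every segment whose peak absolute
#' amplitude exceeds `amp_threshold`. With `use_ica = TRUE`, each segment is
#' first decomposed by ICA and any component whose time course has excess
#' kurtosis-like peakedness above `kurtosis_threshold` (blinks and spikes
#' are strongly super-Gaussian) is zeroed before the amplitude rule is
#' applied; kept segments are returned with those components removed.
#' Without ICA, kept segments' samples are never modified.
#'
#' @param segs a `segment_set`.
#' @param amp_threshold peak-amplitude rejection threshold (microvolt).
#' @param use_ica apply ICA-based component removal first.
#' @param kurtosis_threshold kurtosis above which a component is zeroed
#'   (default 5; a Gaussian time course has kurtosis 3).
#' @return the `segment_set` with updated `kept_mask` (and, under ICA,
#'   cleaned samples), plus attribute `n_rejected`.
#' @export
reject_artifacts <- function(segs, amp_threshold = 100, use_ica = FALSE,
                             kurtosis_threshold = 5) {
  stopifnot(inherits(segs, "segment_set"))
  if (amp_threshold <= 0) fail_field("amp_threshold", "must be > 0")
  n_seg <- dim(segs$segments)[1]
  for (i in seq_len(n_seg)) {
    x <- segs$segments[i, , , drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
    if (use_ica && nrow(x) > 1L) {
      dec <- fastica_decompose(x)
      kurt <- apply(dec$S, 1L, function(s) {
        s <- s - mean(s)
        v <- mean(s^2)
        if (v < .Machine$double.eps) 0 else mean(s^4) / v^2
      })
      bad <- kurt > kurtosis_threshold
      if (any(bad)) {
        dec$S[bad, ] <- 0
        x <- dec$A %*% dec$S + dec$mean
        segs$segments[i, , ] <- x
      }
    }
    if (max(abs(x)) > amp_threshold) segs$kept_mask[i] <- FALSE
  }
  n_rejected <- sum(!segs$kept_mask)
  if (n_seg > 0L && n_rejected == n_seg) {
    stop(sprintf(
      "all %d segments exceed amp_threshold = %g; review the threshold",
      n_seg, amp_threshold), call. = FALSE)
  }
  message(sprintf("reject_artifacts: removed %d of %d segments",
                  n_rejected, n_seg))
  attr(segs, "n_rejected") <- n_rejected
  segs
}

#' Normalize segments to zero mean and unit variance per channel
#'
#' Either standardizes each kept segment independently (`per_segment`) or
#' computes per-channel statistics over the kept segments once
#' (`train_only`) for reuse on held-out data via the `stats` argument —
#' the route that avoids information leaking from test to train.
#' Zero-variance channels are floored at machine epsilon with a warning.
#'
#' @param segs a `segment_set`.
#' @param stats_source `"train_only"` or `"per_segment"`.
#' @param stats optional precomputed statistics (as returned in `$stats`)
#'   to apply instead of estimating new ones; only meaningful with
#'   `"train_only"`.
#' @return list with `segments` (the normalized `segment_set`) and `stats`
#'   (`NULL` for `per_segment`; otherwise list of per-channel `mean`, `sd`).
#' @export
normalize_segments <- function(segs, stats_source = c("train_only",
                                                      "per_segment"),
                               stats = NULL) {
  stopifnot(inherits(segs, "segment_set"))
  stats_source <- match.arg(stats_source)
  kept <- which(segs$kept_mask)
  if (length(kept) == 0L) stop("no kept segments to normalize", call. = FALSE)
  n_ch <- dim(segs$segments)[2]
  floor_sd <- function(s) {
    if (any(s < .Machine$double.eps)) {
      warning("zero-variance channel encountered; variance floored")
      s <- pmax(s, .Machine$double.eps)
    }
    s
  }
  if (stats_source == "per_segment") {
    for (i in kept) {
      for (ch in seq_len(n_ch)) {
        v <- segs$segments[i, ch, ]
        segs$segments[i, ch, ] <- (v - mean(v)) / floor_sd(stats::sd(v))
      }
    }
    return(list(segments = segs, stats = NULL))
  }
  if (is.null(stats)) {
    mu <- numeric(n_ch)
    sdv <- numeric(n_ch)
    for (ch in seq_len(n_ch)) {
      v <- as.vector(segs$segments[kept, ch, ])
      mu[ch] <- mean(v)
      sdv[ch] <- stats::sd(v)
    }
    sdv <- floor_sd(sdv)
    stats <- list(mean = mu, sd = sdv)
  }
  for (ch in seq_len(n_ch)) {
    segs$segments[, ch, ] <-
      (segs$segments[, ch, ] - stats$mean[ch]) / stats$sd[ch]
  }
  list(segments = segs, stats = stats)
}
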