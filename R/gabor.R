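# Gaussian-windowed (Gabor) time-frequency analysis.
#
# The transform evaluates, at each analysis time t on a hop grid and each
# analysis frequency f, the inner product of the signal with a translated,
# modulated Gaussian atom:
#
#   X(t, f) = (1/fs) * sum_tau x(tau) * exp(-(t - tau)^2 / (2 sigma_t^2))
#                                     * exp(-i 2 pi f (tau - t))
#
# i.e. a Riemann-sum discretization of the continuous Gaussian-window
# transform, phase-referenced to the window center so that a tone at f0
# produces its magnitude peak at the f0 analysis bin. The kernel is
# truncated at +/- truncation * sigma_t and the signal is zero-padded at
# the edges.

#' Gabor analysis configuration
#'
#' @param sigma_t Gaussian window standard deviation in seconds
#'   (default 0.1 s; wider windows sharpen frequency resolution at the cost
#'   of temporal resolution).
#' @param freqs analysis frequencies in Hz, strictly ascending (default
#'   1-45 Hz in 1 Hz steps).
#' @param hop step between analysis instants, in samples.
#' @param truncation kernel half-support in multiples of `sigma_t`
#'   (default 6; must be >= 3).
#' @param log_magnitude return log-scaled magnitudes from
#'   [to_feature_sequence()].
#' @param log_floor additive floor inside the log (keeps zero magnitudes
#'   finite).
#' @return an object of class `gabor_config`.
#' @export
gabor_config <- function(sigma_t = 0.1, freqs = 1:45, hop = 6L,
                         truncation = 6, log_magnitude = TRUE,
                         log_floor = 1e-8) {
  cfg <- structure(list(sigma_t = sigma_t, freqs = as.numeric(freqs),
                        hop = as.integer(hop), truncation = truncation,
                        log_magnitude = log_magnitude, log_floor = log_floor),
                   class = "gabor_config")
  if (!is.finite(cfg$sigma_t) || cfg$sigma_t <= 0) {
    fail_field("sigma_t", "must be > 0")
  }
  if (length(cfg$freqs) < 1L || any(diff(cfg$freqs) <= 0) ||
      any(cfg$freqs <= 0)) {
    fail_field("freqs", "must be positive and strictly ascending")
  }
  if (cfg$hop < 1L) fail_field("hop", "must be >= 1")
  if (cfg$truncation < 3) fail_field("truncation", "must be >= 3")
  if (cfg$log_floor <= 0) fail_field("log_floor", "must be > 0")
  cfg
}

#' The Gabor kernel
#'
#' Complex-exponential-modulated Gaussian atom
#' `g(t, f) = exp(-t^2 / (2 sigma_t^2)) * exp(i 2 pi f t)`.
#'
#' @param t time offset(s) in seconds.
#' @param f frequency in Hz.
#' @param sigma_t Gaussian window standard deviation in seconds.
#' @return complex value(s) of the kernel.
#' @export
#' @examples
#' gabor_kernel(0, 10, 0.1)          # 1 + 0i
#' Mod(gabor_kernel(0.1, 7, 0.1))    # exp(-1/2), independent of f
gabor_kernel <- function(t, f, sigma_t) {
  if (!is.finite(sigma_t) || sigma_t <= 0) {
    fail_field("sigma_t", "must be > 0")
  }
  exp(-t^2 / (2 * sigma_t^2)) * exp(1i * 2 * pi * f * t)
}

#' Gabor transform of a single-channel signal
#'
#' Computes the discrete Gaussian-window transform on the hop grid of
#' analysis times (`t_k = (k-1) * hop / fs` for
#' `k = 1 .. floor((n-1)/hop) + 1`) and the configured frequency grid,
#' with the kernel truncated at `truncation * sigma_t` and the signal
#' zero-padded at the edges. Scaled by `1/fs` (Riemann sum in tau).
#'
#' @param x numeric vector, the signal.
#' @param fs sampling rate in Hz.
#' @param cfg a [gabor_config()]; all `freqs` must lie below `fs/2`.
#' @param channel optional source channel label carried on the output.
#' @return an object of class `spectrogram`: list with `values`
#'   (time x frequency complex matrix), `times` (s), `freqs` (Hz),
#'   `channel`.
#' @export
gabor_transform <- function(x, fs, cfg = gabor_config(), channel = NA) {
  if (length(x) < 1L) stop("empty signal", call. = FALSE)
  if (!all(is.finite(x))) stop("signal must be finite", call. = FALSE)
  if (any(cfg$freqs >= fs / 2)) {
    stop(sprintf("analysis frequencies must lie below Nyquist (%g Hz)",
                 fs / 2), call. = FALSE)
  }
  n <- length(x)
  half <- ceiling(cfg$truncation * cfg$sigma_t * fs)
  offs <- (-half):half                       # sample offsets tau - t
  tau_rel <- offs / fs
  gauss <- exp(-tau_rel^2 / (2 * cfg$sigma_t^2))
  # atom matrix: window sample x frequency; conjugated modulation so the
  # transform demodulates content at +f to zero frequency
  M <- gauss * exp(-1i * 2 * pi * outer(tau_rel, cfg$freqs)) / fs
  steps <- ((n - 1L) %/% cfg$hop) + 1L
  centers <- (seq_len(steps) - 1L) * cfg$hop # 0-based sample index of t
  xp <- c(rep(0, half), x, rep(0, half))     # zero padding
  values <- matrix(0i, nrow = steps, ncol = length(cfg$freqs))
  for (k in seq_len(steps)) {
    win <- xp[centers[k] + seq_along(offs)]  # x[center + offs], padded
    values[k, ] <- win %*% M
  }
  structure(
    list(values = values, times = centers / fs, freqs = cfg$freqs,
         channel = channel),
    class = "spectrogram"
  )
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf(
    "<spectrogram> %d time steps x %d frequencies (%.3g-%.3g s, %g-%g Hz)%s\n",
    nrow(x$values), ncol(x$values), min(x$times), max(x$times),
    min(x$freqs), max(x$freqs),
    if (is.na(x$channel)) "" else paste0(", channel ", x$channel)))
  invisible(x)
}

#' Magnitude of a spectrogram
#'
#' @param spec a `spectrogram`.
#' @return nonnegative time x frequency matrix `Mod(values)`.
#' @export
spectrogram_magnitude <- function(spec) {
  stopifnot(inherits(spec, "spectrogram"))
  Mod(spec$values)
}

#' Stack per-channel spectrograms into a classifier feature sequence
#'
#' Concatenates the per-channel magnitude spectrograms along the frequency
#' axis, yielding a `T x (channels * n_freqs)` real sequence; with
#' `cfg$log_magnitude`, magnitudes are mapped through
#' `log(m + log_floor)`.
#'
#' @param specs list of `spectrogram` objects (one per channel) sharing the
#'   same time axis.
#' @param cfg the [gabor_config()] used to produce them.
#' @return numeric matrix, time steps x total features, in channel order.
#' @export
to_feature_sequence <- function(specs, cfg = gabor_config()) {
  if (length(specs) < 1L) stop("no spectrograms supplied", call. = FALSE)
  times <- specs[[1]]$times
  for (s in specs) {
    if (length(s$times) != length(times) ||
        any(abs(s$times - times) > 1e-12)) {
      stop("spectrograms have mismatched time axes", call. = FALSE)
    }
  }
  mats <- lapply(specs, spectrogram_magnitude)
  out <- do.call(cbind, mats)
  if (cfg$log_magnitude) out <- log(out + cfg$log_floor)
  out
}

#' Convert a segment set to classifier feature sequences
#'
#' Runs [gabor_transform()] on every channel of every kept segment and
#' stacks the results, producing the 3-d feature array consumed by
#' the model: kept segments x time steps x (channels * frequencies).
#'
#' @param segs a `segment_set`.
#' @param cfg a [gabor_config()].
#' @return list with `x` (n_kept x T x F array), `y` (labels),
#'   `subject_ids` (per kept segment).
#' @export
segments_to_features <- function(segs, cfg = gabor_config()) {
  stopifnot(inherits(segs, "segment_set"))
  kept <- which(segs$kept_mask)
  if (length(kept) == 0L) stop("no kept segments", call. = FALSE)
  n_ch <- dim(segs$segments)[2]
  first <- NULL
  out <- NULL
  for (j in seq_along(kept)) {
    i <- kept[j]
    specs <- lapply(seq_len(n_ch), function(ch) {
      gabor_transform(segs$segments[i, ch, ], segs$fs, cfg, channel = ch)
    })
    feat <- to_feature_sequence(specs, cfg)
    if (is.null(out)) {
      out <- array(0, dim = c(length(kept), nrow(feat), ncol(feat)))
    }
    out[j, , ] <- feat
  }
  list(x = out, y = segs$labels[kept], subject_ids = segs$subject_ids[kept])
}
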