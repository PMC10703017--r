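# Synthetic EEG cohort generator.
#
# Produces band-structured oscillatory multichannel recordings with a
# controllable class-dependent spectral difference, mains interference and
# blink-like frontal transients, so the whole classification pipeline can be
# exercised and validated without any external recordings.

#' Canonical EEG frequency bands
#'
#' Delta 0.5-4, theta 4-8, alpha 8-13, beta 13-30, gamma 30-100 Hz.
#'
#' @return named list of `c(low, high)` band edges in Hz.
#' @export
eeg_bands <- function() {
  list(
    delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13),
    beta = c(13, 30), gamma = c(30, 100)
  )
}

#' Specify a synthetic EEG cohort
#'
#' Defines a two-class cohort of "PD-like" and "control-like" subjects. Each
#' recording is a sum of band-limited Gaussian oscillations (one per
#' frequency band, with per-class relative power), broadband noise, a mains
#' sinusoid and blink transients. The class effect defaults to elevated beta
#' power in the PD-like class, controlled by `beta_ratio`; pass `band_powers`
#' explicitly for any other spectral contrast.
#'
#' @param n_pd,n_hc subject counts per class.
#' @param n_channels number of channels.
#' @param fs sampling rate in Hz; must exceed twice the highest band edge.
#' @param duration recording length in seconds.
#' @param bands named list of `c(low, high)` Hz band edges
#'   (default [eeg_bands()]).
#' @param band_powers optional list with elements `control` and `pd`, each a
#'   named numeric vector of relative oscillatory power per band. When
#'   omitted, both classes share `base_powers` except that the PD-like beta
#'   power is multiplied by `beta_ratio`.
#' @param beta_ratio PD/control beta-band power ratio (default 2).
#' @param base_powers named relative power vector used to build the default
#'   `band_powers`.
#' @param noise_sd additive broadband noise standard deviation (microvolt).
#' @param line_freq,line_amp mains interference frequency (Hz) and amplitude
#'   (microvolt); amplitude 0 disables it.
#' @param blink_rate expected blink transients per minute.
#' @param gain_sd half-width of the uniform per-subject, per-channel
#'   multiplicative gain (0.1 means every channel of a subject is scaled by
#'   its own factor drawn from \[0.9, 1.1\]); creates between-subject
#'   variability with a multichannel amplitude signature per subject.
#' @param amplitude overall oscillation scale in microvolt (a band with
#'   relative power 1 contributes this standard deviation).
#' @param seed master RNG seed for cohort generation.
#' @return an object of class `cohort_spec`.
#' @export
#' @examples
#' spec <- cohort_spec(n_pd = 2, n_hc = 2, n_channels = 4, fs = 128,
#'                     duration = 10, bands = eeg_bands()[1:4])
cohort_spec <- function(n_pd = 15L, n_hc = 16L, n_channels = 32L, fs = 512,
                        duration = 180, bands = eeg_bands(),
                        band_powers = NULL, beta_ratio = 2,
                        base_powers = c(delta = 1, theta = 0.7, alpha = 1,
                                        beta = 0.5, gamma = 0.2),
                        noise_sd = 2, line_freq = 50, line_amp = 1,
                        blink_rate = 6, gain_sd = 0.1, amplitude = 10,
                        seed = 1L) {
  if (is.null(band_powers)) {
    keep <- intersect(names(base_powers), names(bands))
    ctrl <- base_powers[keep]
    pd <- ctrl
    if ("beta" %in% names(pd)) pd[["beta"]] <- pd[["beta"]] * beta_ratio
    band_powers <- list(control = ctrl, pd = pd)
  }
  spec <- structure(
    list(
      n_pd = as.integer(n_pd), n_hc = as.integer(n_hc),
      n_channels = as.integer(n_channels), fs = fs, duration = duration,
      bands = bands, band_powers = band_powers, noise_sd = noise_sd,
      line_freq = line_freq, line_amp = line_amp, blink_rate = blink_rate,
      gain_sd = gain_sd, amplitude = amplitude, seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
  validate_cohort_spec(spec)
  spec
}

#' @keywords internal
validate_cohort_spec <- function(spec) {
  if (spec$n_pd < 0) fail_field("n_pd", "must be >= 0")
  if (spec$n_hc < 0) fail_field("n_hc", "must be >= 0")
  if (spec$n_channels < 1) fail_field("n_channels", "must be >= 1")
  if (!is.finite(spec$fs) || spec$fs <= 0) fail_field("fs", "must be > 0")
  if (!is.finite(spec$duration) || spec$duration <= 0) {
    fail_field("duration", "must be > 0")
  }
  edges <- unlist(spec$bands)
  if (any(edges <= 0) || any(vapply(spec$bands, function(b) b[2] <= b[1],
                                    logical(1)))) {
    fail_field("bands", "each band needs 0 < low < high")
  }
  if (spec$fs <= 2 * max(edges)) {
    fail_field("fs", sprintf("must exceed twice the highest band edge (%g Hz)",
                             max(edges)))
  }
  for (cls in c("control", "pd")) {
    pw <- spec$band_powers[[cls]]
    if (is.null(pw) || is.null(names(pw)) ||
        !all(names(pw) %in% names(spec$bands))) {
      fail_field("band_powers", sprintf(
        "element `%s` must be named after entries of `bands`", cls))
    }
    if (any(pw < 0)) fail_field("band_powers", "powers must be >= 0")
  }
  if (spec$noise_sd < 0) fail_field("noise_sd", "must be >= 0")
  if (spec$line_amp < 0) fail_field("line_amp", "must be >= 0")
  if (spec$line_freq <= 0 || spec$line_freq >= spec$fs / 2) {
    fail_field("line_freq", "must lie in (0, fs/2)")
  }
  if (spec$blink_rate < 0) fail_field("blink_rate", "must be >= 0")
  if (spec$gain_sd < 0 || spec$gain_sd >= 1) {
    fail_field("gain_sd", "must lie in [0, 1)")
  }
  if (spec$amplitude < 0) fail_field("amplitude", "must be >= 0")
  invisible(spec)
}

#' Construct an EEG recording object
#'
#' Container for a multichannel EEG signal: a channels x samples matrix in
#' microvolt plus sampling rate, channel names, subject identity, class
#' label (0 = control, 1 = PD) and optional ground-truth artifact intervals
#' (0-based, half-open `[start, end)` sample indices).
#'
#' @param data numeric matrix, channels x samples.
#' @param fs sampling rate (Hz).
#' @param channel_names character vector, one per row of `data`.
#' @param subject_id subject identifier string.
#' @param label class label, 0 (control) or 1 (PD), or NA when unknown.
#' @param artifact_truth optional list of `c(start, end)` sample intervals.
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_names = NULL,
                          subject_id = "unknown", label = NA_integer_,
                          artifact_truth = NULL) {
  data <- as.matrix(data)
  if (is.null(channel_names)) {
    channel_names <- sprintf("ch%02d", seq_len(nrow(data)))
  }
  if (nrow(data) != length(channel_names)) {
    fail_field("channel_names", "length must equal the number of data rows")
  }
  if (!all(is.finite(data))) fail_field("data", "all values must be finite")
  if (!is.finite(fs) || fs <= 0) fail_field("fs", "must be > 0")
  n <- ncol(data)
  for (iv in artifact_truth) {
    if (length(iv) != 2 || iv[1] < 0 || iv[2] > n || iv[1] >= iv[2]) {
      fail_field("artifact_truth", "intervals must satisfy 0 <= start < end <= samples")
    }
  }
  structure(
    list(data = data, fs = fs, channel_names = channel_names,
         subject_id = subject_id, label = label,
         artifact_truth = artifact_truth),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %s: %d ch x %d samples @ %g Hz (%.1f s), label=%s, %d artifact interval(s)\n",
    x$subject_id, nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
    ifelse(is.na(x$label), "NA", x$label), length(x$artifact_truth)))
  invisible(x)
}

# Band-limited Gaussian noise with unit standard deviation.
band_noise <- function(n, fs, band, order = 2L) {
  w <- pmin(pmax(band / (fs / 2), 1e-6), 1 - 1e-6)
  bf <- signal::butter(order, w, type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n))
  s <- stats::sd(x)
  if (s < .Machine$double.eps) return(numeric(n))
  x / s
}

# Exponentially decaying blink pulse of `dur` seconds, peak first.
blink_pulse <- function(fs, dur = 0.3, tau = 0.075) {
  k <- seq_len(max(2L, round(dur * fs))) - 1L
  exp(-k / (tau * fs))
}

#' Generate one synthetic EEG recording
#'
#' Synthesizes a single subject's recording under a cohort specification:
#' per-band filtered Gaussian oscillations scaled by the class's relative
#' band powers, broadband noise, a mains sinusoid (random phase per channel)
#' and blink transients. Blinks are one-sided exponential bumps of about
#' 0.3 s, 5-10 times the background standard deviation, applied to the first
#' quarter of channels ("frontal"), and every blink interval is recorded in
#' `artifact_truth`. A per-subject uniform gain in
#' `[1 - gain_sd, 1 + gain_sd]` scales the whole recording. Output is
#' bit-identical for identical `(spec, label, subject_id, seed)`.
#'
#' @param spec a [cohort_spec()].
#' @param label class label: 0 (control-like) or 1 (PD-like).
#' @param subject_id subject identifier.
#' @param seed RNG seed for this recording.
#' @return an [eeg_recording()].
#' @export
generate_recording <- function(spec, label, subject_id, seed) {
  validate_cohort_spec(spec)
  if (!label %in% c(0L, 1L)) fail_field("label", "must be 0 or 1")
  n <- round(spec$fs * spec$duration)
  powers <- spec$band_powers[[if (label == 1L) "pd" else "control"]]
  with_seed(seed, {
    data <- matrix(0, nrow = spec$n_channels, ncol = n)
    for (ch in seq_len(spec$n_channels)) {
      sig <- numeric(n)
      for (bn in names(powers)) {
        if (powers[[bn]] > 0) {
          sig <- sig + sqrt(powers[[bn]]) * spec$amplitude *
            band_noise(n, spec$fs, spec$bands[[bn]])
        }
      }
      if (spec$noise_sd > 0) sig <- sig + stats::rnorm(n, sd = spec$noise_sd)
      if (spec$line_amp > 0) {
        tt <- (seq_len(n) - 1L) / spec$fs
        sig <- sig + spec$line_amp *
          sin(2 * pi * spec$line_freq * tt + stats::runif(1, 0, 2 * pi))
      }
      data[ch, ] <- sig
    }
    # blink transients: shared timing across the frontal channel group
    artifact_truth <- list()
    n_front <- max(1L, ceiling(spec$n_channels / 4))
    n_blinks <- stats::rpois(1, spec$blink_rate * spec$duration / 60)
    pulse <- blink_pulse(spec$fs)
    bg_sd <- mean(apply(data[seq_len(n_front), , drop = FALSE], 1, stats::sd))
    if (n_blinks > 0 && n > length(pulse)) {
      starts <- sort(sample.int(n - length(pulse), n_blinks))
      # blinks do not overlap: enforce a refractory gap of two pulse widths
      keep <- c(TRUE, diff(starts) >= 2L * length(pulse))
      while (!all(keep)) {
        starts <- starts[keep]
        keep <- c(TRUE, diff(starts) >= 2L * length(pulse))
      }
      # ground truth covers the portion of the pulse above 10% of its
      # peak; beyond that the transient has decayed into the background
      len_eff <- min(length(pulse), ceiling(0.075 * spec$fs * log(10)))
      for (s0 in starts) {
        amp <- stats::runif(1, 5, 10) * bg_sd
        idx <- s0 + seq_along(pulse) - 1L
        for (ch in seq_len(n_front)) data[ch, idx] <- data[ch, idx] + amp * pulse
        artifact_truth[[length(artifact_truth) + 1L]] <-
          c(s0 - 1L, s0 - 1L + len_eff)        # 0-based half-open
      }
    }
    # per-channel subject gains (electrode contact and impedance vary by
    # site); gives each subject a multichannel amplitude signature
    gain <- stats::runif(spec$n_channels, 1 - spec$gain_sd, 1 + spec$gain_sd)
    data <- data * gain
    eeg_recording(data, spec$fs,
                  sprintf("ch%02d", seq_len(spec$n_channels)),
                  subject_id, as.integer(label), artifact_truth)
  })
}

#' Generate a synthetic cohort
#'
#' Generates `n_pd` PD-like and `n_hc` control-like recordings with unique
#' subject ids, deriving one reproducible sub-seed per subject from the
#' spec's master seed. When `dir` is given, each recording is written as an
#' EDF file (see [write_eeg()]) along with `manifest.csv`
#' (subject_id, label, path) and `cohort.json` recording the full spec.
#'
#' @param spec a [cohort_spec()].
#' @param dir optional output directory; created if missing.
#' @param format on-disk format passed to [write_eeg()] (`"edf"`, `"bdf"`
#'   or `"rds"`).
#' @return list with `recordings` (list of [eeg_recording()]), `manifest`
#'   (data.frame subject_id, label, path) and `spec`.
#' @export
generate_cohort <- function(spec, dir = NULL, format = "edf") {
  validate_cohort_spec(spec)
  n_total <- spec$n_pd + spec$n_hc
  if (n_total < 1) fail_field("n_pd + n_hc", "cohort must contain at least one subject")
  ids <- c(sprintf("pd%02d", seq_len(spec$n_pd)),
           sprintf("hc%02d", seq_len(spec$n_hc)))
  labels <- c(rep(1L, spec$n_pd), rep(0L, spec$n_hc))
  seeds <- derive_seeds(spec$seed, n_total)
  recordings <- vector("list", n_total)
  paths <- rep(NA_character_, n_total)
  for (i in seq_len(n_total)) {
    recordings[[i]] <- generate_recording(spec, labels[i], ids[i], seeds[i])
  }
  names(recordings) <- ids
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (i in seq_len(n_total)) {
      paths[i] <- file.path(dir, paste0(ids[i], ".", format))
      write_eeg(recordings[[i]], paths[i], format = format)
    }
  }
  manifest <- data.frame(subject_id = ids, label = labels, path = paths,
                         stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(spec = unclass(spec)[setdiff(names(spec), "band_powers")],
           band_powers = lapply(spec$band_powers, as.list),
           seeds = seeds),
      file.path(dir, "cohort.json"), auto_unbox = TRUE, digits = NA)
  }
  list(recordings = recordings, manifest = manifest, spec = spec)
}
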