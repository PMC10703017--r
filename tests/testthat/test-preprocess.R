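# Filtering, segmentation, artifact rejection and normalization.

tone_rec <- function(freq, fs = 512, dur = 4, ch = 1L) {
  tt <- (seq_len(fs * dur) - 1L) / fs
  eeg_recording(matrix(rep(sin(2 * pi * freq * tt), each = ch), nrow = ch),
                fs = fs, subject_id = "tone", label = 0L)
}

rms <- function(x) sqrt(mean(x^2))

test_that("band-pass attenuates out-of-band tones by >= 20 dB and passes in-band tones", {
  cfg <- filter_config(band_low = 0.5, band_high = 100)
  hi <- bandpass_filter(tone_rec(200), cfg)
  interior <- 512:1536
  db_hi <- 20 * log10(rms(hi$data[1, interior]) /
                        rms(tone_rec(200)$data[1, interior]))
  expect_lt(db_hi, -20)
  lo <- bandpass_filter(tone_rec(10), cfg)
  db_lo <- 20 * log10(rms(lo$data[1, interior]) /
                        rms(tone_rec(10)$data[1, interior]))
  expect_lt(abs(db_lo), 1)
  # zero in, zero out; shape preserved
  z <- eeg_recording(matrix(0, 2, 1024), fs = 512)
  expect_equal(bandpass_filter(z, cfg)$data, z$data)
  expect_equal(dim(hi$data), dim(tone_rec(200)$data))
})

test_that("notch removes the mains tone and leaves distant tones untouched", {
  cfg <- filter_config(notch_freq = 50)
  at50 <- notch_filter(tone_rec(50), cfg)
  interior <- 512:1536
  db50 <- 20 * log10(rms(at50$data[1, interior]) /
                       rms(tone_rec(50)$data[1, interior]))
  expect_lt(db50, -20)
  at10 <- notch_filter(tone_rec(10), cfg)
  db10 <- 20 * log10(rms(at10$data[1, interior]) /
                       rms(tone_rec(10)$data[1, interior]))
  expect_lt(abs(db10), 1)
  z <- eeg_recording(matrix(0, 1, 512), fs = 512)
  expect_equal(notch_filter(z, cfg)$data, z$data)
})

test_that("filters are linear and zero-phase", {
  cfg <- filter_config(band_low = 1, band_high = 40)
  set.seed(8)
  x <- matrix(rnorm(2048), 1)
  y <- matrix(rnorm(2048), 1)
  fa <- function(m) bandpass_filter(eeg_recording(m, 512), cfg)$data
  expect_equal(fa(2 * x + 3 * y), 2 * fa(x) + 3 * fa(y), tolerance = 1e-9)
  # zero group delay: cross-correlation of a band-limited input with its
  # filtered output peaks at lag 0
  bl <- fa(x)                       # already inside the passband
  out <- fa(bl)
  cc <- stats::ccf(drop(bl), drop(out), lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("nyquist violations are configuration errors", {
  expect_error(bandpass_filter(tone_rec(10, fs = 128),
                               filter_config(band_high = 100)), "Nyquist")
  expect_error(notch_filter(tone_rec(10, fs = 80),
                            filter_config(notch_freq = 50)), "Nyquist")
})

test_that("segmentation yields floor((n - w)/hop) + 1 windows with provenance", {
  rec <- eeg_recording(matrix(0, 1, 92160), fs = 512, subject_id = "s9",
                       label = 1L)
  s <- segment(rec, 1024L, 1024L)
  expect_equal(dim(s$segments)[1], 90L)
  expect_true(all(s$subject_ids == "s9"))
  expect_true(all(s$labels == 1L))
  s2 <- segment(eeg_recording(matrix(0, 1, 2048), 512), 1024L, 512L)
  expect_equal(dim(s2$segments)[1], 3L)
  expect_warning(s0 <- segment(eeg_recording(matrix(0, 1, 1000), 512),
                               1024L),
                 "0 segments")
  expect_equal(dim(s0$segments)[1], 0L)
  # sample ranges stay inside the recording
  expect_true(all(s2$starts + s2$window_len <= 2048L))
})

test_that("segment samples reproduce the recording slices exactly", {
  set.seed(2)
  rec <- eeg_recording(matrix(rnorm(2 * 600), 2), fs = 100,
                       subject_id = "a", label = 0L)
  s <- segment(rec, 200L, 100L)
  for (i in seq_len(dim(s$segments)[1])) {
    expect_identical(s$segments[i, , ],
                     rec$data[, (s$starts[i] + 1L):(s$starts[i] + 200L)])
  }
})

test_that("amplitude thresholding flags only the spiked segment and never edits kept ones", {
  set.seed(5)
  rec <- eeg_recording(matrix(rnorm(2 * 1000, sd = 10), 2), fs = 100)
  rec$data[1, 450] <- 500
  s <- segment(rec, 200L, 200L)
  before <- s$segments
  out <- suppressMessages(reject_artifacts(s, amp_threshold = 100))
  expect_equal(which(!out$kept_mask), 3L)
  expect_identical(out$segments, before)
  all_ok <- suppressMessages(reject_artifacts(s, amp_threshold = 1000))
  expect_true(all(all_ok$kept_mask))
  expect_error(suppressMessages(reject_artifacts(s, amp_threshold = 1)),
               "review the threshold")
})

test_that("threshold rejection catches >= 90% of blink-contaminated segments", {
  hits <- total <- 0
  for (sd in 1:10) {
    spec <- tiny_cohort_spec(n_pd = 1L, n_hc = 0L, duration = 30,
                             blink_rate = 10, seed = sd)
    rec <- generate_recording(spec, 1L, "s", 100L + sd)
    bg <- stats::sd(rec$data[2, ])   # a channel without frontal blinks
    s <- segment(rec, 256L, 256L)
    out <- suppressMessages(reject_artifacts(s, amp_threshold = 5 * bg))
    overlaps <- vapply(seq_along(out$starts), function(i) {
      a <- out$starts[i]
      b <- a + out$window_len
      any(vapply(rec$artifact_truth,
                 function(iv) iv[1] < b && iv[2] > a, TRUE))
    }, TRUE)
    hits <- hits + sum(!out$kept_mask[overlaps])
    total <- total + sum(overlaps)
  }
  expect_gt(total, 10)
  expect_gte(hits / total, 0.9)
})

test_that("ICA-based cleaning suppresses a spiky source mixed across channels", {
  set.seed(12)
  n <- 1024
  gaussians <- matrix(rnorm(3 * n), 3)
  spiky <- rep(0, n)
  spiky[sample(n, 12)] <- 40            # strongly super-Gaussian component
  A <- matrix(runif(16, 0.5, 1.5), 4)
  X <- A %*% rbind(gaussians, spiky)
  s <- segment(eeg_recording(X, 256), 1024L)
  cleaned <- suppressMessages(
    reject_artifacts(s, amp_threshold = 1e6, use_ica = TRUE,
                     kurtosis_threshold = 5))
  expect_lt(max(abs(cleaned$segments[1, , ])), max(abs(X)) * 0.6)
  expect_true(all(cleaned$kept_mask))
})

test_that("per-segment normalization standardizes every kept segment", {
  set.seed(3)
  s <- segment(eeg_recording(matrix(rnorm(2 * 800, mean = 5, sd = 7), 2),
                             100), 200L, 200L)
  out <- normalize_segments(s, "per_segment")
  for (i in seq_len(4)) {
    for (ch in 1:2) {
      v <- out$segments$segments[i, ch, ]
      expect_lt(abs(mean(v)), 1e-9)
      expect_equal(stats::sd(v), 1, tolerance = 1e-6)
    }
  }
})

test_that("train-only statistics apply to held-out segments as (x - mu)/sigma", {
  # 2-channel, 4-sample toy: hand-computable
  tr <- segment(eeg_recording(matrix(c(1, 2, 3, 4,
                                       10, 20, 30, 40), 2, byrow = TRUE),
                              4), 4L)
  held <- segment(eeg_recording(matrix(c(5, 6, 7, 8,
                                         50, 60, 70, 80), 2, byrow = TRUE),
                                4), 4L)
  fit <- normalize_segments(tr, "train_only")
  mu <- c(mean(1:4), mean(c(10, 20, 30, 40)))
  sg <- c(stats::sd(1:4), stats::sd(c(10, 20, 30, 40)))
  expect_equal(fit$stats$mean, mu)
  expect_equal(fit$stats$sd, sg)
  out <- normalize_segments(held, "train_only", stats = fit$stats)
  expect_equal(out$segments$segments[1, 1, ], (5:8 - mu[1]) / sg[1])
  expect_equal(out$segments$segments[1, 2, ],
               (c(50, 60, 70, 80) - mu[2]) / sg[2])
})

test_that("constant channels are floored to zero with a warning", {
  s <- segment(eeg_recording(rbind(rep(2, 100), rnorm(100)), 50), 100L)
  expect_warning(out <- normalize_segments(s, "per_segment"), "floored")
  expect_true(all(out$segments$segments[1, 1, ] == 0))
})
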