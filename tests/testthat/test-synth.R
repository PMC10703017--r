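# Synthetic EEG cohort generator.

test_that("recordings have the requested geometry and are deterministic", {
  spec <- tiny_cohort_spec(duration = 5)
  r1 <- generate_recording(spec, label = 1L, subject_id = "s1", seed = 42L)
  expect_equal(dim(r1$data), c(4L, round(128 * 5)))
  expect_equal(r1$fs, 128)
  expect_equal(length(r1$channel_names), 4L)
  expect_equal(r1$label, 1L)
  r2 <- generate_recording(spec, label = 1L, subject_id = "s1", seed = 42L)
  expect_identical(r1$data, r2$data)
  expect_identical(r1$artifact_truth, r2$artifact_truth)
  r3 <- generate_recording(spec, label = 1L, subject_id = "s1", seed = 43L)
  expect_false(identical(r1$data, r3$data))
})

test_that("full-scale geometry: 32 channels at 512 Hz for 180 s gives 92160 samples", {
  # shape contract only; checked via the sample-count arithmetic the
  # generator uses, not by allocating the full recording
  spec <- cohort_spec(n_pd = 1L, n_hc = 0L)
  expect_equal(round(spec$fs * spec$duration), 92160)
  small <- cohort_spec(n_pd = 1L, n_hc = 0L, n_channels = 32L, fs = 512,
                       duration = 2)
  r <- generate_recording(small, 1L, "s", 1L)
  expect_equal(dim(r$data), c(32L, 1024L))
})

test_that("class beta-power contrast matches the requested ratio (Welch oracle)", {
  ratios <- vapply(1:20, function(sd) {
    spec <- tiny_cohort_spec(duration = 20, beta_ratio = 2, gain_sd = 0,
                             blink_rate = 0, seed = sd)
    pd <- generate_recording(spec, 1L, "pd", seed = 1000L + sd)
    hc <- generate_recording(spec, 0L, "hc", seed = 2000L + sd)
    welch_band_power(pd$data[2, ], 128, c(13, 30)) /
      welch_band_power(hc$data[2, ], 128, c(13, 30))
  }, 0)
  expect_equal(mean(ratios), 2, tolerance = 0.1)
})

test_that("bands with zero requested power carry less power than active bands", {
  spec <- cohort_spec(n_pd = 1L, n_hc = 1L, n_channels = 2L, fs = 128,
                      duration = 20, bands = bands_128(),
                      band_powers = list(
                        control = c(alpha = 1, gamma = 0),
                        pd = c(alpha = 1, gamma = 0)),
                      noise_sd = 0, line_amp = 0, blink_rate = 0, seed = 3L)
  r <- generate_recording(spec, 0L, "s", 9L)
  p_alpha <- welch_band_power(r$data[1, ], 128, c(8, 13))
  p_gamma <- welch_band_power(r$data[1, ], 128, c(30, 55))
  expect_gt(p_alpha, p_gamma)
})

test_that("dominant line noise produces the largest spectral peak at the line frequency", {
  spec <- cohort_spec(n_pd = 1L, n_hc = 0L, n_channels = 1L, fs = 128,
                      duration = 20, bands = bands_128(),
                      noise_sd = 0.5, amplitude = 1, line_freq = 50,
                      line_amp = 30, blink_rate = 0, seed = 4L)
  r <- generate_recording(spec, 1L, "s", 5L)
  sp <- stats::spec.pgram(stats::ts(r$data[1, ], frequency = 128),
                          plot = FALSE, taper = 0)
  expect_equal(sp$freq[which.max(sp$spec)], 50, tolerance = 0.2)
})

test_that("every blink interval contains the local amplitude maximum", {
  spec <- tiny_cohort_spec(duration = 30, blink_rate = 12, seed = 6L)
  r <- generate_recording(spec, 0L, "s", 7L)
  expect_gt(length(r$artifact_truth), 0L)
  for (iv in r$artifact_truth) {
    lo <- max(1L, iv[1] + 1L - 64L)
    hi <- min(ncol(r$data), iv[2] + 64L)
    local <- abs(r$data[1, lo:hi])
    peak_at <- lo - 1L + which.max(local)   # 1-based sample
    expect_true(peak_at > iv[1] && peak_at <= iv[2])
  }
})

test_that("cohorts have exact class counts, unique ids and a manifest", {
  spec <- cohort_spec(n_pd = 15L, n_hc = 16L, n_channels = 2L, fs = 128,
                      duration = 1, bands = bands_128(), seed = 2L)
  co <- generate_cohort(spec)
  expect_length(co$recordings, 31L)
  expect_equal(sum(co$manifest$label == 1L), 15L)
  expect_equal(sum(co$manifest$label == 0L), 16L)
  expect_false(any(duplicated(co$manifest$subject_id)))
  # degenerate single-subject cohort
  co1 <- generate_cohort(cohort_spec(n_pd = 0L, n_hc = 1L, n_channels = 2L,
                                     fs = 128, duration = 1,
                                     bands = bands_128()))
  expect_length(co1$recordings, 1L)
  expect_equal(co1$manifest$label, 0L)
  # zero subjects is an error
  expect_error(generate_cohort(cohort_spec(n_pd = 0L, n_hc = 0L,
                                           n_channels = 2L, fs = 128,
                                           duration = 1,
                                           bands = bands_128())),
               "at least one subject")
})

test_that("different master seeds change samples but not manifest structure", {
  mk <- function(sd) generate_cohort(tiny_cohort_spec(n_pd = 1L, n_hc = 1L,
                                                      duration = 2,
                                                      seed = sd))
  a <- mk(1L)
  b <- mk(2L)
  expect_identical(a$manifest[c("subject_id", "label")],
                   b$manifest[c("subject_id", "label")])
  expect_false(identical(a$recordings[[1]]$data, b$recordings[[1]]$data))
})

test_that("invalid specs are rejected with the field named", {
  expect_error(cohort_spec(n_pd = -1L), "n_pd")
  expect_error(cohort_spec(fs = 150), "fs")       # below twice the gamma edge
  expect_error(cohort_spec(duration = 0), "duration")
  expect_error(cohort_spec(noise_sd = -1), "noise_sd")
  expect_error(cohort_spec(blink_rate = -2), "blink_rate")
  expect_error(tiny_cohort_spec(gain_sd = 1.5), "gain_sd")
  expect_error(generate_recording(tiny_cohort_spec(), label = 2L,
                                  subject_id = "s", seed = 1L), "label")
})
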