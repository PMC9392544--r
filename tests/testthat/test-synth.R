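test_that("generated recordings have the requested geometry and are deterministic", {
  rec <- tiny_recording(seed = 3, duration = 2)
  expect_s3_class(rec, "eeg_recording")
  expect_equal(dim(rec$data), c(19, 1000))
  expect_identical(rownames(rec$data), montage_1020()$channel_names)

  rec2 <- tiny_recording(seed = 3, duration = 2)
  expect_identical(rec$data, rec2$data)

  rec3 <- tiny_recording(seed = 4, duration = 2)
  expect_false(identical(rec$data, rec3$data))
})

test_that("recording_spec rejects invalid geometry", {
  expect_error(recording_spec(duration = -1), "positive")
  expect_error(recording_spec(sampling_rate = 500, duration = 1.0015),
               "integer sample count")
  expect_error(artifact_spec(blink_rate = -1), ">= 0")
})

test_that("line-noise injection puts a spectral peak at 50 Hz", {
  rec <- generate_recording(
    tiny_profile(),
    recording_spec(duration = 10,
                   artifacts = artifact_spec(blink_rate = 0,
                                             line_noise_amp = 5,
                                             muscle_burst_rate = 0,
                                             drift_amp = 0)),
    seed = 7)
  for (ch in c(1, 10, 19)) {
    x <- rec$data[ch, ]
    at50 <- band_power(x, 500, 49.5, 50.5)
    flank <- (band_power(x, 500, 45, 49) + band_power(x, 500, 51, 55)) / 8
    expect_gt(at50, 10 * flank)  # sharp local maximum at 50 Hz
  }
})

test_that("the injected class effect monotonically increases alpha separation", {
  bp <- vapply(c(0, 0.5, 1), function(eff) {
    rec <- tiny_recording(seed = 21, duration = 6, effect = eff)
    mean(apply(rec$data, 1, band_power, fs = 500, low = 8, high = 12))
  }, numeric(1))
  expect_true(all(diff(bp) > 0))
})

test_that("cohort generation honours responder fractions and the 50% rule", {
  spec <- recording_spec(duration = 1, conditions = "eyes_closed")
  coh <- generate_cohort(25, 25,
                         c(female = 11 / 25, male = 18 / 25),
                         spec = spec, seed = 5, sessions = "pre")
  subj <- coh$subjects
  expect_equal(nrow(subj), 50)
  expect_equal(sum(subj$sex == "female"), 25)

  lab <- label_response(subj$bdi_pre, subj$bdi_post)
  expect_equal(sum(lab == "responder" & subj$sex == "female"), 11)
  expect_equal(sum(lab == "responder" & subj$sex == "male"), 18)
  # intended flag and realised rule agree for every subject
  expect_identical(subj$responder, lab == "responder")
})

test_that("responder fraction 0 yields no responders; cohorts are reproducible", {
  spec <- recording_spec(duration = 1, conditions = "eyes_closed")
  coh0 <- generate_cohort(4, 4, c(female = 0, male = 0), spec = spec,
                          seed = 9, sessions = "pre")
  expect_false(any(coh0$subjects$bdi_post <= 0.5 * coh0$subjects$bdi_pre))

  coh1 <- generate_cohort(4, 4, c(female = 0.5, male = 0.5), spec = spec,
                          seed = 13, sessions = "pre")
  coh2 <- generate_cohort(4, 4, c(female = 0.5, male = 0.5), spec = spec,
                          seed = 13, sessions = "pre")
  expect_identical(coh1$subjects, coh2$subjects)
  expect_identical(coh1$recordings[[3]]$data, coh2$recordings[[3]]$data)

  expect_error(generate_cohort(0, 0, spec = spec, seed = 1), "positive")
  expect_error(generate_cohort(2, 2, c(female = 1.5, male = 0), spec = spec,
                               seed = 1), "\\[0, 1\\]")
})
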