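test_that("segment counts follow floor division", {
  expect_equal(count_segments(13841500, 500), 27683)
  expect_equal(count_segments(c(1000, 999), 500), 3)

  rec <- tiny_recording(seed = 1, duration = 2)      # 1000 samples
  expect_equal(dim(segment_recording(rec, 500))[1], 2)
  t999 <- rec
  t999$data <- t999$data[, 1:999]
  expect_equal(dim(segment_recording(t999, 500))[1], 1)
  expect_warning(out <- segment_recording(rec, 5000), "shorter")
  expect_equal(dim(out)[1], 0)
})

test_that("segments are time-major windows of the source recording", {
  rec <- tiny_recording(seed = 2, duration = 2)
  tens <- segment_recording(rec, 500, label = "pre")
  expect_equal(dim(tens$segments), c(2, 500, 19))
  expect_equal(tens$segments[1, , ], unname(t(rec$data[, 1:500])))
  expect_equal(tens$segments[2, , ], unname(t(rec$data[, 501:1000])))
  expect_equal(tens$info$source_offset, c(0L, 500L))
  # conservation: n * len <= samples < (n + n_recordings) * len
  n <- dim(tens)[1]
  expect_lte(n * 500, ncol(rec$data))
  expect_lt(ncol(rec$data), (n + 1) * 500)
})

test_that("the responder rule is a sharp 50% threshold and scale-invariant", {
  expect_equal(as.character(label_response(30, 15)), "responder")
  expect_equal(as.character(label_response(30, 16)), "nonresponder")
  # group means of the male nonresponder stratum: 23% mean reduction
  expect_equal(as.character(label_response(35.42, 27.14)), "nonresponder")

  set.seed(3)
  pre <- sample(10:50, 50, replace = TRUE)
  post <- sample(0:50, 50, replace = TRUE)
  for (k in c(0.5, 2, 7)) {
    expect_identical(label_response(pre, post),
                     label_response(k * pre, k * post))
  }
  expect_error(label_response(0, 5), "bdi_pre")
})

make_mini_cohort <- function(seed = 31) {
  spec <- recording_spec(duration = 2)
  generate_cohort(2, 2, c(female = 0.5, male = 0.5), spec = spec,
                  seed = seed, sessions = c("pre", "post"))
}

test_that("task assembly selects the right recordings and classes", {
  coh <- make_mini_cohort()
  recs <- coh$recordings
  for (i in seq_along(recs)) {
    recs[[i]]$session <- coh$index$session[i]
    recs[[i]]$condition <- coh$index$condition[i]
  }

  m3 <- assemble_dataset(recs, coh$subjects, 3)
  expect_setequal(unique(m3$info$session), "pre")
  f_ids <- coh$subjects$subject_id[coh$subjects$sex == "female"]
  expect_true(all(m3$info$subject_id %in% f_ids))
  expect_setequal(levels(m3$labels), c("nonresponder", "responder"))
  expect_true(all(table(m3$labels) > 0))

  m1 <- assemble_dataset(recs, coh$subjects, 1)
  # every selected subject contributes segments to BOTH classes
  for (s in unique(m1$info$subject_id)) {
    expect_setequal(unique(as.character(m1$labels[m1$info$subject_id == s])),
                    c("pre", "post"))
  }

  m5 <- assemble_dataset(recs, coh$subjects, 5)
  sex_of <- coh$subjects$sex[match(m5$info$subject_id,
                                   coh$subjects$subject_id)]
  expect_setequal(unique(sex_of), c("female", "male"))

  expect_error(assemble_dataset(recs, coh$subjects, 6), "1..5")
})

test_that("an empty class is an error, not a silent degenerate dataset", {
  spec <- recording_spec(duration = 2)
  coh <- generate_cohort(2, 2, c(female = 0, male = 0), spec = spec,
                         seed = 37, sessions = "pre")
  expect_error(assemble_dataset(coh$recordings, coh$subjects, 5),
               "empty class")
})

test_that("segment tensors round-trip through their array + provenance files", {
  tens <- random_tensor(n = 10, len = 16, ch = 3)
  base <- file.path(tempdir(), "tensor_rt")
  write_segments(tens, base)
  back <- read_segments(base)
  expect_equal(back$segments, tens$segments)
  expect_identical(as.character(back$labels), as.character(tens$labels))
  expect_equal(nrow(back$info), dim(tens)[1])
})
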