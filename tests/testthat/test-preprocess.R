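make_tone_rec <- function(f, fs = 256, dur = 8) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  eeg_recording(matrix(sin(2 * pi * f * t), nrow = 1), fs, "Oz")
}

# RMS of the middle of the signal, away from filter edge transients.
mid_rms <- function(x) {
  n <- length(x)
  i <- seq(floor(n / 4), floor(3 * n / 4))
  sqrt(mean(x[i]^2))
}

test_that("the filter chain preserves shape and passes zero through", {
  rec <- eeg_recording(matrix(0, 2, 1000), 256, c("Oz", "O1"))
  out <- filter_chain(rec)
  expect_identical(dim(out$data), dim(rec$data))
  expect_true(all(out$data == 0))
  expect_identical(out$annotations, rec$annotations)
})

test_that("line-noise frequencies are strongly attenuated, the passband is flat", {
  out50 <- filter_chain(make_tone_rec(50))
  att50 <- 20 * log10(mid_rms(out50$data[1, ]) / (1 / sqrt(2)))
  expect_lt(att50, -20)
  out10 <- filter_chain(make_tone_rec(10))
  att10 <- 20 * log10(mid_rms(out10$data[1, ]) / (1 / sqrt(2)))
  expect_lt(abs(att10), 1)
  # zero-phase application: filtering twice moves a passband tone < 1 dB
  twice <- filter_chain(out10)
  expect_lt(abs(20 * log10(mid_rms(twice$data[1, ]) /
                             mid_rms(out10$data[1, ]))), 1)
})

test_that("low sampling rates and non-finite data are rejected", {
  expect_error(filter_chain(make_tone_rec(10, fs = 100)), "120")
  rec <- make_tone_rec(10)
  rec$data[1, 5] <- NA
  expect_error(filter_chain(rec), "non-finite")
})

test_that("epoch extraction follows the half-open window convention", {
  fs <- 256
  n <- 40 * fs
  rec <- eeg_recording(matrix(seq_len(n), nrow = 1), fs, "Oz",
                       data.frame(onset = 30, duration = 3,
                                  label = "ssvep_5"))
  p1 <- protocol_spec(1)
  ep <- extract_epochs(rec, p1)
  expect_length(ep, 1L)
  expect_equal(ncol(ep$epochs[[1]]$data), 256)       # 1 s at 256 Hz
  # window [31.8, 32.8) s; sample index floor(t * fs), 0-based
  i0 <- floor(31.8 * fs)
  expect_equal(as.numeric(ep$epochs[[1]]$data[1, ]),
               as.numeric(rec$data[1, i0 + 1:256]))
})

test_that("step 3 and step 4 epochs have the protocol window lengths", {
  prof <- make_subject_profile(1)
  for (spec in list(list(step = 3, secs = 6), list(step = 4, secs = 3))) {
    p <- protocol_spec(spec$step, c(5, 9), reps_per_class = 1)
    rec <- simulate_recording(p, prof, seed = 1, fs = 128)
    ep <- extract_epochs(rec, p)
    expect_equal(length(ep), nrow(rec$annotations))
    expect_true(all(vapply(ep$epochs, function(e) ncol(e$data),
                           numeric(1)) == spec$secs * 128))
    expect_equal(sort(epoch_labels(ep)), sort(rec$annotations$label))
  }
})

test_that("windows that do not fit inside the event are refused", {
  rec <- eeg_recording(matrix(0, 1, 256 * 10), 256, "Oz",
                       data.frame(onset = 1, duration = 2, label = "ssvep_5"))
  p <- protocol_spec(1)   # window [1.8, 2.8) needs a 3 s event
  expect_error(extract_epochs(rec, p), "exceeds")
})

test_that("annotation invariants are enforced at construction", {
  d <- matrix(0, 1, 1000)
  expect_error(eeg_recording(d, 100, "Oz",
                             data.frame(onset = 9, duration = 2,
                                        label = "x")), "span")
  expect_error(eeg_recording(d, 100, "Oz",
                             data.frame(onset = c(5, 1),
                                        duration = c(1, 1),
                                        label = c("a", "b"))), "sorted")
  expect_error(eeg_recording(d, 100, "Oz",
                             data.frame(onset = c(1, 1.5),
                                        duration = c(1, 1),
                                        label = c("a", "b"))), "overlap")
})
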