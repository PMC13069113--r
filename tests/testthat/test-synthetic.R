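test_that("subject profiles are reproducible and validated", {
  cfg <- list(response_gain_range = list(`5` = c(1, 3), `9` = c(1, 3)))
  expect_identical(make_subject_profile(7, cfg), make_subject_profile(7, cfg))
  p2 <- make_subject_profile(8, cfg)
  expect_false(identical(make_subject_profile(7, cfg)$response_gain,
                         p2$response_gain))
  expect_error(make_subject_profile(1, list(response_gain_range =
                                              list(`5` = c(-1, 2)))),
               "0 <= lo <= hi")
  expect_error(make_subject_profile(1, list(response_gain = c(`6` = 1))),
               "keys must lie")
  expect_error(make_subject_profile(1, list(vi_attenuation = 0)),
               "vi_attenuation")
  expect_error(make_subject_profile(1, list(bogus = 1)), "unknown")
})

test_that("simulated recordings are deterministic in all inputs", {
  prof <- make_subject_profile(3)
  p3 <- protocol_spec(3, c(5, 9), reps_per_class = 2)
  a <- simulate_recording(p3, prof, seed = 11, fs = 128)
  b <- simulate_recording(p3, prof, seed = 11, fs = 128)
  expect_identical(a, b)
  c <- simulate_recording(p3, prof, seed = 12, fs = 128)
  expect_false(identical(a$data, c$data))
})

test_that("offline and online sessions match the protocol timing", {
  prof <- make_subject_profile(1)
  rec3 <- simulate_recording(protocol_spec(3, c(5, 9)), prof, seed = 1,
                             fs = 128)
  expect_equal(nrow(rec3$annotations), 60)            # 3 classes x 20 reps
  expect_equal(sum(rec3$annotations$duration), 540)   # 9 minutes of events
  rec4 <- simulate_recording(protocol_spec(4, c(5, 9)), prof, seed = 1,
                             fs = 128)
  expect_equal(nrow(rec4$annotations), 60)
  expect_equal(sum(rec4$annotations$duration), 300)   # 5-minute session
  expect_equal(rec4$annotations$label[1:3], c("vi_5", "rest", "vi_9"))
  expect_equal(unique(table(rec4$annotations$label)), 20L,
               ignore_attr = TRUE)
})

test_that("unsupported class frequencies and low rates are rejected", {
  prof <- make_subject_profile(1)
  p3 <- protocol_spec(3, c(5, 9), reps_per_class = 1)
  expect_error(simulate_recording(p3, prof, fs = 30), "too low")
  p_bad <- protocol_spec(3, c(5, 9), reps_per_class = 1)
  p_bad$classes[1] <- "vi_6"
  expect_error(simulate_recording(p_bad, prof, fs = 128), "response gain")
})

test_that("SSVEP events place their spectral peak at the driven frequency", {
  prof <- planted_profile(strong = c(9), gain = 3)
  p1 <- protocol_spec(1, reps_per_class = 3, epoch_window = c(0, 3))
  rec <- simulate_recording(p1, prof, seed = 5, fs = 128)
  ep <- extract_epochs(rec, p1)
  labs <- epoch_labels(ep)
  avg <- NULL
  for (i in which(labs == "ssvep_9")) {
    p <- welch_psd(ep$epochs[[i]]$data["Oz", ], 128)
    avg <- if (is.null(avg)) p$power else avg + p$power
  }
  p <- welch_psd(ep$epochs[[which(labs == "ssvep_9")[1]]]$data["Oz", ], 128)
  band <- p$freqs >= 3 & p$freqs <= 36
  peak <- p$freqs[band][which.max(avg[band])]
  expect_lt(abs(peak - 9), 0.5 + 1e-9)
})

test_that("zero response gains leave task and rest spectra indistinguishable", {
  # two-sample t-test on 8.5-9.5 Hz band power, task vs rest epochs:
  # with no planted response it should be non-significant at the 1%
  # level in nearly all runs
  runs <- 100
  nonsig <- 0
  p3 <- protocol_spec(3, c(5, 9), reps_per_class = 4)
  for (s in seq_len(runs)) {
    prof <- zero_gain_profile()
    rec <- simulate_recording(p3, prof, seed = 5000 + s, fs = 128)
    ep <- extract_epochs(rec, p3)
    labs <- epoch_labels(ep)
    bp <- vapply(ep$epochs, function(e) {
      p <- welch_psd(e$data["Oz", ], 128)
      sum(p$power[p$freqs >= 8.5 & p$freqs <= 9.5])
    }, numeric(1))
    pv <- stats::t.test(bp[labs == "vi_9"], bp[labs == "rest"])$p.value
    if (pv > 0.01) nonsig <- nonsig + 1
  }
  expect_gte(nonsig, 95)
})

test_that("imagery peaks score lower than perception peaks at the same frequency", {
  # imagery attenuation + frequency smearing must lower the
  # peak-sharpness score relative to the evoked response
  p2 <- protocol_spec(2, c(5, 9), reps_per_class = 3)
  d_vi <- d_vp <- 0
  runs <- 50
  for (s in seq_len(runs)) {
    prof <- make_subject_profile(s)
    rec <- filter_chain(simulate_recording(p2, prof, seed = 300 + s,
                                           fs = 128))
    ep <- extract_epochs(rec, p2)
    labs <- epoch_labels(ep)
    sc <- function(i, f) {
      psd <- highres_psd(ep$epochs[[i]]$data["Oz", ], 128)
      peak_score(psd, f)$S
    }
    for (f in c(5, 9)) {
      for (i in which(labs == paste0("vi_", f))) d_vi <- d_vi + sc(i, f)
      for (i in which(labs == paste0("ssvep_", f))) d_vp <- d_vp + sc(i, f)
    }
  }
  expect_lt(d_vi, d_vp)
})
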