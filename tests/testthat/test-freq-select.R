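test_that("one-sided prominences match the analytic triangle", {
  f <- 9; h <- 4; w <- 0.4; b <- 1.5
  psd <- triangle_psd(f, h, w, b)
  for (side in c("left", "right")) {
    d <- side_delta(psd, f, side)
    expect_equal(d$M, b + h, tolerance = 0.01)
    expect_equal(d$m, b, tolerance = 0.01)
    expect_equal(d$dp, h, tolerance = 0.01)
  }
  # flat spectrum: no prominence
  fl <- flat_psd(2.5)
  expect_equal(side_delta(fl, 9, "left")$dp, 0)
  expect_equal(side_delta(fl, 9, "right")$dp, 0)
  # linearity in amplitude
  psd2 <- psd; psd2$power <- 3 * psd$power
  expect_equal(side_delta(psd2, f, "left")$dp,
               3 * side_delta(psd, f, "left")$dp, tolerance = 1e-12)
})

test_that("half-height width matches the closed-form triangle crossing", {
  # apex h above zero baseline: half height sits halfway down each
  # flank, so the width equals the base half-width w
  for (w in c(0.2, 0.3, 0.5)) {
    psd <- triangle_psd(9, 4, w)
    expect_equal(half_height_width(psd, 9), w, tolerance = 0.01)
  }
  # amplitude invariance
  psd <- triangle_psd(9, 4, 0.3)
  psd2 <- psd; psd2$power <- 7 * psd$power
  expect_equal(half_height_width(psd2, 9), half_height_width(psd, 9))
  # peak broader than the search window clamps at +/- 0.5 Hz
  broad <- triangle_psd(9, 4, 3)
  expect_equal(half_height_width(broad, 9), 1.0, tolerance = 1e-9)
  # degenerate zero spectrum floors at one grid step
  expect_equal(half_height_width(flat_psd(0), 9), 0.025)
})

test_that("the peak score behaves like prominence over width", {
  f <- 9; h <- 4
  s1 <- peak_score(triangle_psd(f, h, 0.2), f)
  s2 <- peak_score(triangle_psd(f, h, 0.4), f)
  expect_equal(s1$S, h / 0.2, tolerance = 0.01)
  expect_equal(s1$S / s2$S, 2, tolerance = 0.02)   # narrower peak scores 2x
  # amplitude equivariance of S, invariance of iota
  psd <- triangle_psd(f, h, 0.3, b = 1)
  psd5 <- psd; psd5$power <- 5 * psd$power
  a <- peak_score(psd, f); b5 <- peak_score(psd5, f)
  expect_equal(b5$S, 5 * a$S, tolerance = 1e-9)
  expect_equal(b5$iota, a$iota)
  expect_equal(peak_score(flat_psd(3), f)$S, 0)
})

test_that("scores are stable under grid refinement", {
  coarse <- peak_score(triangle_psd(9, 4, 0.3, b = 1, res = 0.025), 9)$S
  fine <- peak_score(triangle_psd(9, 4, 0.3, b = 1, res = 0.0125), 9)$S
  expect_lt(abs(fine / coarse - 1), 0.05)
})

test_that("coarse grids and out-of-range neighbourhoods are refused", {
  expect_error(side_delta(triangle_psd(9, 1, 0.3, res = 0.5), 9, "left"),
               "resolution")
  expect_error(side_delta(triangle_psd(9, 1, 0.3, fmax = 9.2), 9, "left"),
               "outside")
})

test_that("harmonic conflicts are flagged only for 2:1 relations", {
  expect_true(harmonic_conflict(5, 10))
  expect_true(harmonic_conflict(4.5, 9.0))
  expect_false(harmonic_conflict(5, 9))
  expect_false(harmonic_conflict(9, 5))
  expect_true(harmonic_conflict(5, 10.2))      # within 0.25 Hz default
  expect_false(harmonic_conflict(5, 10.3))
  expect_error(harmonic_conflict(5, 5), "differ")
  # every pair in the candidate set is conflict-free
  cand <- candidate_frequencies()
  for (i in 1:3) for (j in (i + 1):4)
    expect_false(harmonic_conflict(cand[i], cand[j]))
})

test_that("couple selection takes the top two scores with tie and conflict rules", {
  expect_equal(as.numeric(select_couple(c(`5` = 10, `7` = 1, `9` = 8,
                                          `12` = 2))), c(5, 9))
  # full tie breaks toward the lower frequencies
  expect_equal(as.numeric(select_couple(c(`5` = 10, `7` = 10, `9` = 10,
                                          `12` = 10))), c(5, 7))
  # with a widened tolerance the (5, 9) near-harmonic conflict forces
  # the lower-scoring member to be replaced by the next-best candidate
  expect_equal(as.numeric(select_couple(c(`5` = 9, `7` = 8, `9` = 10,
                                          `12` = 1), tol = 2)), c(7, 9))
  expect_error(select_couple(c(`5` = 1, `7` = 2)), "candidate set")
})

test_that("scoring aggregates repetitions and occipital electrodes and needs them", {
  prof <- planted_profile()
  p1 <- protocol_spec(1, reps_per_class = 2)
  rec <- filter_chain(simulate_recording(p1, prof, seed = 4, fs = 128))
  ep <- extract_epochs(rec, p1)
  sc <- score_candidates(ep)
  expect_named(sc$total, c("5", "7", "9", "12"))
  expect_true(all(sc$total >= 0))
  # per frequency: reps x 3 electrodes rows of detail
  expect_equal(nrow(sc$detail), 4 * 2 * 3)
  # scaling every epoch by c scales PSDs (and hence totals) by c^2
  # and leaves the selected couple unchanged
  ep2 <- ep
  for (i in seq_along(ep2$epochs)) ep2$epochs[[i]]$data <-
      ep2$epochs[[i]]$data * 3
  sc2 <- score_candidates(ep2)
  expect_equal(sc2$total, 9 * sc$total, tolerance = 1e-6)
  expect_equal(as.numeric(select_couple(sc2)),
               as.numeric(select_couple(sc)))
  # occipital channels are mandatory
  ep3 <- ep
  ep3$channel_labels <- setdiff(ep3$channel_labels, "Oz")
  expect_error(score_candidates(ep3), "occipital")
})

test_that("planted dominant frequencies are recovered from calibration data", {
  hits <- 0
  for (s in 1:10) {
    prof <- planted_profile()
    p1 <- protocol_spec(1)
    rec <- filter_chain(simulate_recording(p1, prof, seed = 40 + s,
                                           fs = 128))
    cp <- select_couple(score_candidates(extract_epochs(rec, p1)))
    if (all(as.numeric(cp) == c(5, 9))) hits <- hits + 1
  }
  expect_gte(hits, 9)
})
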