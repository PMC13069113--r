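# Analytic PSD fixture: symmetric triangular peak of height `h` above a
# flat baseline `b`, apex at `f`, base half-width `w`, on a uniform grid.
triangle_psd <- function(f, h, w, b = 0, res = 0.025, fmax = 40) {
  freqs <- seq(0, fmax, by = res)
  power <- b + pmax(0, h * (1 - abs(freqs - f) / w))
  structure(list(freqs = freqs, power = power, resolution = res),
            class = "psd")
}

flat_psd <- function(c0, res = 0.025, fmax = 40) {
  freqs <- seq(0, fmax, by = res)
  structure(list(freqs = freqs, power = rep(c0, length(freqs)),
                 resolution = res),
            class = "psd")
}

# Small synthetic feature blocks with three well-separated Gaussian
# class clusters; one block per "recording".
cluster_blocks <- function(n_blocks = 10, per_class = 2, d = 6, sep = 10,
                           seed = 42) {
  classes <- c("vi_5", "rest", "vi_9")
  centers <- rbind(c(sep, 0, 0, 0, 0, 0),
                   c(0, sep, 0, 0, 0, 0),
                   c(0, 0, sep, 0, 0, 0))[, seq_len(d), drop = FALSE]
  set.seed(seed)
  lapply(seq_len(n_blocks), function(b) {
    labs <- rep(classes, each = per_class)
    x <- t(vapply(labs, function(l)
      centers[match(l, classes), ] + stats::rnorm(d), numeric(d)))
    dimnames(x) <- list(NULL, paste0("f", seq_len(d)))
    structure(list(x = x, labels = labs,
                   recording_id = rep(sprintf("rec%02d", b), length(labs))),
              class = "feature_matrix")
  })
}

# Profile whose response gains are all zero (background only).
zero_gain_profile <- function(seed = 1) {
  make_subject_profile(seed, list(
    response_gain = c(`5` = 0, `7` = 0, `9` = 0, `12` = 0)))
}

# Profile with strong, equal responses planted at two frequencies and
# weak responses elsewhere.
planted_profile <- function(seed = 1, strong = c(5, 9), gain = 2.5,
                            weak = 0.3) {
  g <- stats::setNames(rep(weak, 4), as.character(candidate_frequencies()))
  g[as.character(strong)] <- gain
  make_subject_profile(seed, list(response_gain = g))
}

# Reduced-size offline (step-3-shaped) subject for Monte-Carlo checks:
# 10 recordings at fs 128 with `reps` repetitions per class.
simulate_offline_blocks <- function(profile, couple = c(5, 9), reps = 5,
                                    fs = 128, seed = 1) {
  p3 <- protocol_spec(3, couple, reps_per_class = reps)
  lapply(1:10, function(i) {
    rec <- filter_chain(simulate_recording(p3, profile,
                                           seed = seed * 1000L + i, fs = fs,
                                           id = sprintf("rec%02d", i)))
    build_features(extract_epochs(rec, p3))
  })
}
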