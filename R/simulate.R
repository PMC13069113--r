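# Gaussian 1/f^alpha process of length n, unit variance, synthesized in
# the frequency domain (power ~ f^-alpha; DC removed).
.noise_1f <- function(n, alpha) {
  nh <- floor(n / 2)
  k <- seq_len(nh)
  amp <- k^(-alpha / 2)
  re <- stats::rnorm(nh) * amp
  im <- stats::rnorm(nh) * amp
  spec <- complex(real = re, imaginary = im)
  if (n %% 2 == 0) spec[nh] <- complex(real = re[nh], imaginary = 0)
  full <- complex(length.out = n)
  full[1 + k] <- spec
  full[n + 1 - seq_len(nh - (n %% 2 == 0))] <-
    Conj(spec[seq_len(nh - (n %% 2 == 0))])
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

# Parse a class label into (kind, frequency): rest -> NA frequency.
.label_freq <- function(label) {
  if (label == "rest") return(list(kind = "rest", f = NA_real_))
  m <- regmatches(label, regexec("^(ssvep|vi)_([0-9.]+)$", label))[[1]]
  if (length(m) != 3L) stop("unrecognized class label: ", label)
  list(kind = m[2], f = as.numeric(m[3]))
}

#' Simulate one protocol recording
#'
#' Generates a continuous multichannel EEG recording for one step of the
#' protocol. Each channel carries a Gaussian 1/f^alpha background scaled
#' by the channel's spatial gain; during non-rest events a sinusoid at
#' the class frequency f and an attenuated one at 2f (relative amplitude
#' `harmonic_ratio`) are added with a random phase per event. Imagery
#' (`vi_*`) events are further attenuated by `vi_attenuation` and their
#' frequency offset per event by N(0, `vi_jitter_sd`), giving the lower
#' and broader spectral peaks characteristic of imagined flicker. Rest
#' events contain background only.
#'
#' The task sequence is drawn from `seed` for randomized steps and is
#' the fixed block (low frequency, rest, high frequency) repeated for
#' step 4. Identical (protocol, profile, seed, fs) give an identical
#' recording.
#'
#' @param protocol A [protocol_spec()] (carries the frequency couple for
#'   steps 2-4).
#' @param profile A [make_subject_profile()] object.
#' @param seed Integer seed for sequence, phases, jitter and noise.
#' @param fs Sampling rate in Hz (default 256).
#' @param channels Channel labels to synthesize (default the ten
#'   analysis channels).
#' @param id Recording identifier; defaults to `"step<k>_seed<seed>"`.
#' @return An [eeg_recording()].
#' @export
simulate_recording <- function(protocol, profile, seed = 1L, fs = 256,
                               channels = analysis_channels(), id = NULL) {
  stopifnot(inherits(protocol, "protocol_spec"),
            inherits(profile, "subject_profile"))
  freqs <- stats::na.omit(vapply(protocol$classes,
                                 function(l) .label_freq(l)$f, numeric(1)))
  if (length(freqs) && fs <= 4 * max(freqs))
    stop(sprintf("fs = %g Hz too low for the second harmonic of %g Hz",
                 fs, max(freqs)))
  miss <- setdiff(as.character(freqs), names(profile$response_gain))
  if (length(miss))
    stop("no response gain for class frequency ", paste(miss, collapse = ", "),
         " Hz")
  spat <- profile$spatial_gain[channels]
  spat[is.na(spat)] <- 0.25
  names(spat) <- channels

  .with_seed(seed, {
    seq_labels <- .task_sequence(protocol)
    n_ev <- length(seq_labels)
    m_ev <- round(protocol$event_duration * fs)
    n <- n_ev * m_ev
    data <- matrix(0, nrow = length(channels), ncol = n,
                   dimnames = list(channels, NULL))
    for (ch in seq_along(channels))
      data[ch, ] <- .noise_1f(n, profile$noise_exponent) *
        profile$noise_scale * spat[ch]
    t_rel <- (seq_len(m_ev) - 1L) / fs
    for (ev in seq_len(n_ev)) {
      info <- .label_freq(seq_labels[ev])
      if (info$kind == "rest") next
      f <- info$f
      a <- profile$response_gain[[as.character(f)]]
      if (info$kind == "vi") {
        a <- a * profile$vi_attenuation
        f <- f + stats::rnorm(1, 0, profile$vi_jitter_sd)
      }
      ph <- stats::runif(2, 0, 2 * pi)
      base <- a * sin(2 * pi * f * t_rel + ph[1]) +
        a * profile$harmonic_ratio * sin(2 * pi * 2 * f * t_rel + ph[2])
      idx <- (ev - 1L) * m_ev + seq_len(m_ev)
      data[, idx] <- data[, idx] + outer(spat, base)
    }
    ann <- data.frame(onset = (seq_len(n_ev) - 1L) * protocol$event_duration,
                      duration = protocol$event_duration,
                      label = seq_labels)
    if (is.null(id)) id <- sprintf("step%d_seed%d", protocol$step_id, seed)
    eeg_recording(data, fs, channels, ann, id = id)
  })
}
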