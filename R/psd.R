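# Hamming window of length n.
.hamming <- function(n) 0.54 - 0.46 * cos(2 * pi * seq(0, n - 1) / (n - 1))

# One-sided density-scaled periodogram of a windowed (already tapered)
# segment zero-padded to nfft. Scaling 1/(fs * sum(w^2)) gives uV^2/Hz;
# interior bins are doubled to fold negative frequencies in.
.periodogram <- function(xw, w, fs, nfft) {
  X <- stats::fft(c(xw, rep(0, nfft - length(xw))))
  nb <- floor(nfft / 2) + 1L
  p <- (Mod(X[seq_len(nb)])^2) / (fs * sum(w^2))
  last_double <- if (nfft %% 2 == 0) nb - 1L else nb
  if (last_double >= 2L) p[2:last_double] <- 2 * p[2:last_double]
  p
}

#' Welch power spectral density
#'
#' Welch's averaged-periodogram estimate with 2-second Hamming-windowed
#' segments and 50% overlap, matching the feature-extraction convention
#' of the pipeline: the grid spacing is 1/2 s = 0.5 Hz regardless of
#' epoch length. Segment means are removed before windowing; scaling is
#' one-sided density (uV^2/Hz).
#'
#' @param x Single-channel numeric signal (uV), at least 2 s long.
#' @param fs Sampling rate in Hz.
#' @return An object of class `psd`: list with `freqs` (Hz), `power`
#'   (uV^2/Hz), `resolution` (Hz) and `n_segments` (averaged segment
#'   count).
#' @export
welch_psd <- function(x, fs) {
  nseg <- round(2 * fs)
  if (length(x) < nseg)
    stop("signal shorter than one 2 s segment; use highres_psd() for short epochs")
  step <- nseg / 2
  starts <- seq(1, length(x) - nseg + 1, by = step)
  w <- .hamming(nseg)
  acc <- 0
  for (s in starts) {
    seg <- x[s + seq_len(nseg) - 1L]
    seg <- seg - mean(seg)
    acc <- acc + .periodogram(seg * w, w, fs, nseg)
  }
  nb <- floor(nseg / 2) + 1L
  structure(list(freqs = (seq_len(nb) - 1L) * fs / nseg,
                 power = acc / length(starts),
                 resolution = fs / nseg,
                 n_segments = length(starts)),
            class = "psd")
}

#' High-resolution zero-padded periodogram
#'
#' Single Hamming-windowed periodogram evaluated on a fine zero-padded
#' grid. Used by the frequency-scoring stage, whose +/-0.05 Hz peak
#' neighbourhoods are narrower than the native resolution of a 1-second
#' calibration epoch.
#'
#' @param x Single-channel numeric signal (uV), at least 1 s long.
#' @param fs Sampling rate in Hz.
#' @param resolution Requested grid spacing in Hz (default 0.025).
#' @return A `psd` object with grid spacing `fs / round(fs/resolution)`.
#' @export
highres_psd <- function(x, fs, resolution = 0.025) {
  if (resolution <= 0) stop("`resolution` must be positive")
  if (length(x) < fs) stop("signal must be at least 1 s long")
  nfft <- round(fs / resolution)
  if (nfft < length(x)) nfft <- length(x)
  w <- .hamming(length(x))
  xd <- x - mean(x)
  p <- .periodogram(xd * w, w, fs, nfft)
  nb <- floor(nfft / 2) + 1L
  structure(list(freqs = (seq_len(nb) - 1L) * fs / nfft,
                 power = p,
                 resolution = fs / nfft),
            class = "psd")
}

#' @export
print.psd <- function(x, ...) {
  cat(sprintf("<psd> %d bins, %g-%g Hz, resolution %g Hz\n",
              length(x$freqs), min(x$freqs), max(x$freqs), x$resolution))
  invisible(x)
}

#' @export
plot.psd <- function(x, flim = c(3, 36), log = "y", ...) {
  i <- x$freqs >= flim[1] & x$freqs <= flim[2]
  graphics::plot(x$freqs[i], pmax(x$power[i], .Machine$double.xmin),
                 type = "l", log = log, xlab = "frequency (Hz)",
                 ylab = expression(PSD ~ (mu * V^2 / Hz)), ...)
  invisible(x)
}
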