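# Filter designs for the offline chain. The band edges follow the
# acquisition setup: 60 Hz low-pass, 48-52 Hz notch against line noise,
# 3-36 Hz 8th-order Butterworth band-pass. Designs not pinned down by
# the band list use conventional choices: 4th-order Butterworth
# low-pass and a 2nd-order IIR notch with -3 dB edges at 48/52 Hz.
.design_chain <- function(fs) {
  nyq <- fs / 2
  lp <- signal::butter(4, 60 / nyq, type = "low")
  # Biquad notch (bilinear design): -3 dB bandwidth bw centred on f0.
  f0 <- 50; bw <- 4
  beta <- tan(pi * bw / fs)
  c0 <- 2 * cos(2 * pi * f0 / fs)
  notch <- list(b = c(1, -c0, 1) / (1 + beta),
                a = c(1, -c0 / (1 + beta), (1 - beta) / (1 + beta)))
  bp <- signal::butter(4, c(3, 36) / nyq, type = "pass")
  list(lp = lp, notch = notch, bp = bp)
}

#' Apply the offline filter chain
#'
#' Filters every channel of a recording with, in order, a 60 Hz
#' low-pass, a 48-52 Hz notch, and a 3-36 Hz 8th-order Butterworth
#' band-pass. All three are applied forward-backward (zero phase), so
#' event onsets stay aligned between raw and filtered data; annotations
#' are carried over unchanged.
#'
#' @param rec An [eeg_recording()]; `fs` must exceed 120 Hz so the 60 Hz
#'   low-pass edge lies below Nyquist.
#' @return The filtered [eeg_recording()].
#' @export
filter_chain <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$fs <= 120)
    stop("`fs` must exceed 120 Hz for the 60 Hz low-pass edge")
  if (!all(is.finite(rec$data))) stop("recording contains non-finite samples")
  d <- .design_chain(rec$fs)
  out <- rec$data
  for (ch in seq_len(nrow(out))) {
    x <- signal::filtfilt(d$lp, out[ch, ])
    x <- signal::filtfilt(d$notch$b, d$notch$a, x)
    out[ch, ] <- signal::filtfilt(d$bp, x)
  }
  rec$data <- out
  rec
}

#' Cut analysis epochs from an annotated recording
#'
#' Extracts one epoch per annotation using the protocol's analysis
#' window, taken relative to each event onset. Windows are half-open
#' [start, end) with the sample at time t indexed as floor(t * fs), so
#' an epoch holds exactly round((end - start) * fs) samples.
#'
#' @param rec An annotated [eeg_recording()].
#' @param protocol The [protocol_spec()] that produced the recording
#'   (supplies the epoch window and step id).
#' @return An object of class `eeg_epochs`: a list with `epochs` (each a
#'   list with `label`, `data` channels x samples, `window`, `step_id`,
#'   `recording_id`, `fs`), plus shared `fs`, `channel_labels` and
#'   `step_id`.
#' @export
extract_epochs <- function(rec, protocol) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(protocol, "protocol_spec"))
  win <- protocol$epoch_window
  fs <- rec$fs
  nsmp <- round(diff(win) * fs)
  eps <- vector("list", nrow(rec$annotations))
  for (i in seq_len(nrow(rec$annotations))) {
    a <- rec$annotations[i, ]
    if (win[2] > a$duration + 1e-9)
      stop(sprintf("epoch window [%g, %g) exceeds the %g s event '%s' at %g s",
                   win[1], win[2], a$duration, a$label, a$onset))
    i0 <- floor((a$onset + win[1]) * fs)   # 0-based sample of window start
    if (i0 + nsmp > ncol(rec$data))
      stop("epoch extends past the end of the recording")
    eps[[i]] <- list(label = a$label,
                     data = rec$data[, i0 + seq_len(nsmp), drop = FALSE],
                     window = win, step_id = protocol$step_id,
                     recording_id = rec$id, fs = fs)
  }
  structure(list(epochs = eps, fs = fs, channel_labels = rec$channel_labels,
                 step_id = protocol$step_id),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  labs <- vapply(x$epochs, `[[`, character(1), "label")
  cat(sprintf("<eeg_epochs> %d epochs (step %d) @ %g Hz\n",
              length(x$epochs), x$step_id, x$fs))
  tab <- table(labs)
  cat(" ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.eeg_epochs <- function(x) length(x$epochs)

#' Class labels of an epoch set
#' @param x An `eeg_epochs` object.
#' @return Character vector of per-epoch labels.
#' @export
epoch_labels <- function(x) {
  stopifnot(inherits(x, "eeg_epochs"))
  vapply(x$epochs, `[[`, character(1), "label")
}
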