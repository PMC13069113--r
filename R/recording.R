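#' Construct a continuous multichannel EEG recording
#'
#' Container for a continuous EEG signal with labelled event annotations.
#' Annotations must be sorted by onset, non-overlapping, and lie entirely
#' within the recorded span.
#'
#' @param data Numeric matrix, channels x samples, in microvolts; row
#'   names are taken as channel labels when `channel_labels` is missing.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character vector of 10-20-system channel names.
#' @param annotations Data frame with columns `onset` (s), `duration`
#'   (s) and `label` (character); may have zero rows.
#' @param id Optional recording identifier (character).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_labels = rownames(data),
                          annotations = NULL, id = NULL) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric channels x samples matrix")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a positive scalar (Hz)")
  if (is.null(channel_labels) || length(channel_labels) != nrow(data))
    stop("`channel_labels` must name every row of `data`")
  if (is.null(annotations))
    annotations <- data.frame(onset = numeric(0), duration = numeric(0),
                              label = character(0))
  annotations <- as.data.frame(annotations)
  stopifnot(all(c("onset", "duration", "label") %in% names(annotations)))
  annotations$label <- as.character(annotations$label)
  if (nrow(annotations)) {
    span <- ncol(data) / fs
    if (any(annotations$onset < 0) ||
        any(annotations$onset + annotations$duration > span + 1e-9))
      stop("annotations must lie within the recording span")
    if (is.unsorted(annotations$onset, strictly = FALSE))
      stop("annotations must be sorted by onset")
    if (nrow(annotations) > 1L) {
      ends <- annotations$onset + annotations$duration
      if (any(annotations$onset[-1L] < ends[-nrow(annotations)] - 1e-9))
        stop("annotations must not overlap")
    }
  }
  rownames(data) <- channel_labels
  structure(list(channel_labels = channel_labels, fs = fs, data = data,
                 annotations = annotations, id = id),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat(sprintf("  channels: %s\n", paste(x$channel_labels, collapse = ", ")))
  n <- nrow(x$annotations)
  cat(sprintf("  annotations: %d event%s", n, if (n == 1) "" else "s"))
  if (n) {
    tab <- table(x$annotations$label)
    cat(" (", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), ")",
        sep = "")
  }
  cat("\n")
  invisible(x)
}
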