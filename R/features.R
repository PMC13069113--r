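#' Build the classifier feature matrix from imagery epochs
#'
#' For every epoch and every analysis electrode, the Welch PSD is
#' computed ([welch_psd()]: 2 s Hamming segments, 50% overlap, 0.5 Hz
#' grid) and restricted to the closed band [3, 36] Hz; the per-electrode
#' vectors are concatenated electrode-major in the fixed channel order
#' of [analysis_channels()], giving 10 x 67 = 670 columns at the native
#' 0.5 Hz grid.
#'
#' @param epochs An `eeg_epochs` set (epochs of at least 2 s; steps 3-4).
#' @param channels Electrodes to use, default [analysis_channels()].
#' @param band Closed frequency band in Hz, default `c(3, 36)`.
#' @return An object of class `feature_matrix`: list with `x` (trials x
#'   features matrix, columns named `<electrode>_<freq>`), `labels`
#'   (class per trial) and `recording_id` (per trial).
#' @export
build_features <- function(epochs, channels = analysis_channels(),
                           band = c(3, 36)) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (!length(epochs$epochs)) stop("no epochs to featurize")
  fs <- unique(vapply(epochs$epochs, `[[`, numeric(1), "fs"))
  if (length(fs) != 1L) stop("epochs mix sampling rates")
  miss <- setdiff(channels, epochs$channel_labels)
  if (length(miss)) stop("missing channels: ", paste(miss, collapse = ", "))
  tol <- 1e-9
  ref <- welch_psd(epochs$epochs[[1]]$data[channels[1], ], fs)
  keep <- which(ref$freqs >= band[1] - tol & ref$freqs <= band[2] + tol)
  cols <- as.vector(t(outer(channels, ref$freqs[keep],
                            function(ch, f) sprintf("%s_%g", ch, f))))
  x <- matrix(NA_real_, nrow = length(epochs$epochs),
              ncol = length(channels) * length(keep),
              dimnames = list(NULL, cols))
  for (i in seq_along(epochs$epochs)) {
    ep <- epochs$epochs[[i]]
    row <- lapply(channels, function(ch)
      welch_psd(ep$data[ch, ], fs)$power[keep])
    x[i, ] <- unlist(row, use.names = FALSE)
  }
  structure(list(x = x,
                 labels = vapply(epochs$epochs, `[[`, character(1), "label"),
                 recording_id = vapply(epochs$epochs, function(e)
                   if (is.null(e$recording_id)) NA_character_
                   else e$recording_id, character(1))),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d trials x %d features\n",
              nrow(x$x), ncol(x$x)))
  tab <- table(x$labels)
  cat(" ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

# Row-bind feature matrices (shared columns required).
.rbind_features <- function(blocks) {
  stopifnot(length(blocks) >= 1L)
  cn <- colnames(blocks[[1]]$x)
  for (b in blocks)
    if (!identical(colnames(b$x), cn)) stop("feature columns differ")
  structure(list(x = do.call(rbind, lapply(blocks, `[[`, "x")),
                 labels = unlist(lapply(blocks, `[[`, "labels")),
                 recording_id = unlist(lapply(blocks, `[[`, "recording_id"))),
            class = "feature_matrix")
}

#' Write / read a feature matrix as CSV plus a JSON label manifest
#'
#' The CSV holds one row per trial with the electrode-major PSD-bin
#' columns; labels and recording ids go to `<path>.labels.json`.
#'
#' @param fm A `feature_matrix`.
#' @param path CSV path.
#' @return `write_features` returns `path` invisibly; `read_features`
#'   the restored `feature_matrix`.
#' @export
write_features <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  utils::write.csv(as.data.frame(fm$x), path, row.names = FALSE)
  jsonlite::write_json(list(labels = fm$labels,
                            recording_id = fm$recording_id),
                       paste0(path, ".labels.json"))
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  x <- as.matrix(utils::read.csv(path, check.names = FALSE))
  man <- jsonlite::read_json(paste0(path, ".labels.json"),
                             simplifyVector = TRUE)
  structure(list(x = x, labels = man$labels,
                 recording_id = man$recording_id),
            class = "feature_matrix")
}
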