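#' Write or read a recording (EDF+ or CSV dialect)
#'
#' The format follows the file extension: `.edf` uses the EDF+ writer
#' ([write_edf()], 16-bit quantization); `.csv` writes a plain-text
#' matrix with a `# fs=<Hz>` comment line, one column per channel and
#' full-precision samples (bit-identical round trip), plus an events
#' sidecar `<stem>_events.csv` with columns `onset_s`, `duration_s`,
#' `label`.
#'
#' @param rec An [eeg_recording()].
#' @param path Destination (`.edf` or `.csv`).
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   the restored [eeg_recording()].
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  # re-validate so recordings mutated after construction cannot be
  # written with out-of-span or overlapping annotations
  rec <- eeg_recording(rec$data, rec$fs, rec$channel_labels,
                       rec$annotations, id = rec$id)
  ext <- tolower(tools::file_ext(path))
  if (ext == "edf") return(write_edf(rec, path))
  if (ext != "csv") stop("unsupported extension: .", ext)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.17g", rec$fs), con)
  writeLines(paste(rec$channel_labels, collapse = ","), con)
  writeLines(apply(rec$data, 2, function(col)
    paste(sprintf("%.17g", col), collapse = ",")), con)
  ev <- rec$annotations
  names(ev) <- c("onset_s", "duration_s", "label")
  utils::write.csv(ev, .events_path(path), row.names = FALSE)
  invisible(path)
}

.events_path <- function(path) sub("\\.csv$", "_events.csv", path)

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "edf") return(read_edf(path))
  if (ext != "csv") stop("unsupported extension: .", ext)
  lines <- readLines(path)
  if (!grepl("^# fs=", lines[1]))
    stop("malformed recording CSV (line 1): expected '# fs=<Hz>' in ", path)
  fs <- as.numeric(sub("^# fs=", "", lines[1]))
  labels <- strsplit(lines[2], ",")[[1]]
  data <- vapply(lines[-(1:2)],
                 function(l) as.numeric(strsplit(l, ",")[[1]]),
                 numeric(length(labels)))
  if (is.null(dim(data))) data <- matrix(data, nrow = 1L)
  dimnames(data) <- NULL
  ann <- NULL
  if (file.exists(.events_path(path))) {
    ev <- utils::read.csv(.events_path(path))
    ann <- data.frame(onset = ev$onset_s, duration = ev$duration_s,
                      label = ev$label)
  }
  eeg_recording(data, fs, labels, ann)
}
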