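# Minimal EDF+C reader/writer: 16-bit samples, 1-second data records,
# one EDF Annotations signal carrying the event list as TALs. Covers
# what this package writes; not a general-purpose EDF parser.

.edf_pad <- function(s, width) {
  s <- as.character(s)
  if (nchar(s) > width) stop("EDF header field too wide: ", s)
  formatC(s, width = -width, flag = " ")
}

# Format a number into at most 8 ASCII chars (EDF numeric field).
.edf_num8 <- function(x) {
  for (d in 7:1) {
    s <- formatC(x, digits = d, format = "g", width = -1)
    if (nchar(s) <= 8) return(s)
  }
  stop("cannot format ", x, " in 8 chars")
}

#' Write a recording as EDF+
#'
#' Writes an EDF+C file with 1-second data records, each ordinary
#' channel quantized to 16 bits over its own physical range, and the
#' annotation list stored as time-stamped annotation lists (TALs) on an
#' `EDF Annotations` signal. The sampling rate must be a whole number of
#' samples per second.
#'
#' @param rec An [eeg_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  nch <- nrow(rec$data)
  n <- ncol(rec$data)
  nrec <- ceiling(n / fs)
  datap <- if (nrec * fs > n)
    cbind(rec$data, matrix(0, nch, nrec * fs - n)) else rec$data

  pmin <- apply(datap, 1, min); pmax <- apply(datap, 1, max)
  pmax[pmax <= pmin] <- pmin[pmax <= pmin] + 1
  # use the printed (8-char) physical range for digitization so that
  # read-back reproduces values to quantization accuracy
  pmin_s <- vapply(pmin, .edf_num8, character(1))
  pmax_s <- vapply(pmax, .edf_num8, character(1))
  pmin <- as.numeric(pmin_s); pmax <- as.numeric(pmax_s)
  pmax[pmax <= pmin] <- pmin[pmax <= pmin] + 1
  dmin <- -32768; dmax <- 32767

  # TAL payload per record: a timestamp keep-alive TAL plus one TAL per
  # annotation starting in that second; every TAL is nul-terminated
  payloads <- lapply(seq_len(nrec) - 1L, function(r) {
    tals <- sprintf("+%d\x14\x14", r)
    ann <- rec$annotations
    if (nrow(ann)) {
      here <- which(floor(ann$onset) == r)
      for (i in here)
        tals <- c(tals, sprintf("+%.6g\x15%.6g\x14%s\x14",
                                ann$onset[i], ann$duration[i], ann$label[i]))
    }
    unlist(lapply(tals, function(s) c(charToRaw(s), as.raw(0))))
  })
  ann_bytes <- max(lengths(payloads)) + 1L
  ann_samples <- ceiling(ann_bytes / 2)

  ns <- nch + 1L
  header_bytes <- 256L + 256L * ns
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, width) writeChar(.edf_pad(s, width), con, nchars = width,
                                     eos = NULL)
  wr("0", 8)
  wr("X X X X", 80)
  wr(paste("Startdate 01-JAN-2000 X X", if (is.null(rec$id)) "X" else rec$id),
     80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(header_bytes, 8)
  wr("EDF+C", 44)
  wr(nrec, 8)
  wr("1", 8)
  wr(ns, 4)
  labs <- c(rec$channel_labels, "EDF Annotations")
  for (l in labs) wr(l, 16)
  for (i in seq_len(ns)) wr("", 80)                      # transducer
  for (i in seq_len(ns)) wr(if (i <= nch) "uV" else "", 8)
  for (i in seq_len(ns)) wr(if (i <= nch) .edf_num8(pmin[i]) else "-1", 8)
  for (i in seq_len(ns)) wr(if (i <= nch) .edf_num8(pmax[i]) else "1", 8)
  for (i in seq_len(ns)) wr(dmin, 8)
  for (i in seq_len(ns)) wr(dmax, 8)
  for (i in seq_len(ns)) wr("", 80)                      # prefiltering
  for (i in seq_len(ns)) wr(if (i <= nch) fs else ann_samples, 8)
  for (i in seq_len(ns)) wr("", 32)

  for (r in seq_len(nrec)) {
    idx <- (r - 1L) * fs + seq_len(fs)
    for (ch in seq_len(nch)) {
      dig <- round((datap[ch, idx] - pmin[ch]) / (pmax[ch] - pmin[ch]) *
                     (dmax - dmin) + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2,
               endian = "little")
    }
    payload <- payloads[[r]]
    payload <- c(payload, raw(2L * ann_samples - length(payload)))
    writeBin(payload, con)
  }
  invisible(path)
}

#' Read an EDF+ recording
#'
#' Reads EDF/EDF+C files with equal per-channel sampling rates, parsing
#' TAL annotations (keep-alive timestamps are dropped).
#'
#' @param path EDF file path.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) {
    s <- readChar(con, width, useBytes = TRUE)
    if (nchar(s, type = "bytes") < width)
      stop("truncated EDF header in ", path)
    trimws(s)
  }
  rd(8); rd(80); rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8))
  rd(44)
  nrec <- as.integer(rd(8))
  recdur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labs <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(80)
  nsamp <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(32)

  is_ann <- labs == "EDF Annotations"
  chans <- which(!is_ann)
  fs <- unique(nsamp[chans]) / recdur
  if (length(fs) != 1L) stop("unequal channel sampling rates not supported")
  data <- matrix(0, length(chans), nrec * nsamp[chans[1]])
  ann <- list()
  for (r in seq_len(nrec)) {
    for (i in seq_len(ns)) {
      if (is_ann[i]) {
        payload <- readBin(con, "raw", 2L * nsamp[i])
        # split at nul separators, then parse each TAL
        grp <- cumsum(c(0L, as.integer(utils::head(payload, -1L) == as.raw(0))))
        tals <- vapply(split(payload, grp),
                       function(b) rawToChar(b[b != as.raw(0)]), character(1))
        for (tal in tals) {
          if (!nchar(tal)) next
          parts <- strsplit(tal, "\x14")[[1]]
          if (length(parts) < 2L || !nchar(parts[2])) next  # keep-alive
          od <- strsplit(parts[1], "\x15")[[1]]
          ann[[length(ann) + 1L]] <-
            data.frame(onset = as.numeric(od[1]),
                       duration = if (length(od) > 1) as.numeric(od[2]) else 0,
                       label = parts[2])
        }
      } else {
        ci <- match(i, chans)
        dig <- readBin(con, "integer", nsamp[i], size = 2, endian = "little")
        phys <- (dig - dmin[i]) * (pmax[i] - pmin[i]) / (dmax[i] - dmin[i]) +
          pmin[i]
        data[ci, (r - 1L) * nsamp[i] + seq_len(nsamp[i])] <- phys
      }
    }
  }
  ann <- if (length(ann)) do.call(rbind, ann) else NULL
  if (!is.null(ann)) ann <- ann[order(ann$onset), , drop = FALSE]
  eeg_recording(data, fs, labs[chans], ann,
                id = NULL)
}
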