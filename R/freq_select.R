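# Indices of PSD grid points inside [lo, hi] (closed, with float slack).
.band_idx <- function(psd, lo, hi) {
  which(psd$freqs >= lo - 1e-9 & psd$freqs <= hi + 1e-9)
}

.check_score_grid <- function(psd, f) {
  if (psd$resolution > 0.025 + 1e-9)
    stop("PSD grid too coarse for peak scoring; need resolution <= 0.025 Hz")
  if (f - 0.5 < min(psd$freqs) - 1e-9 || f + 0.5 > max(psd$freqs) + 1e-9)
    stop(sprintf("neighbourhood [%g, %g] Hz outside the PSD grid",
                 f - 0.5, f + 0.5))
}

#' One-sided peak prominence of a PSD peak
#'
#' For a peak centred at `f`, one side's prominence is the maximum of
#' the PSD in the close neighbourhood (within 0.05 Hz of `f`, that side)
#' minus the minimum in the larger neighbourhood (within 0.5 Hz, same
#' side); both neighbourhoods share the centre point `f`.
#'
#' @param psd A `psd` with grid spacing at most 0.025 Hz covering
#'   `[f - 0.5, f + 0.5]`.
#' @param f Peak centre frequency in Hz.
#' @param side `"left"` or `"right"`.
#' @return List with `M` (close-window maximum), `m` (large-window
#'   minimum) and `dp = M - m`, all in uV^2/Hz.
#' @export
side_delta <- function(psd, f, side = c("left", "right")) {
  side <- match.arg(side)
  .check_score_grid(psd, f)
  if (side == "left") {
    M <- max(psd$power[.band_idx(psd, f - 0.05, f)])
    m <- min(psd$power[.band_idx(psd, f - 0.5, f)])
  } else {
    M <- max(psd$power[.band_idx(psd, f, f + 0.05)])
    m <- min(psd$power[.band_idx(psd, f, f + 0.5)])
  }
  list(M = M, m = m, dp = M - m)
}

#' Width of a PSD peak at half height
#'
#' The apex is the PSD maximum within 0.05 Hz of `f`. On each side the
#' first crossing of apex/2, searched outward from the apex within the
#' +/-0.5 Hz neighbourhood, is located by linear interpolation between
#' grid points; a side with no crossing is clamped at the 0.5 Hz
#' boundary. The width is floored at one grid step so degenerate
#' single-bin peaks cannot produce a zero divisor.
#'
#' @inheritParams side_delta
#' @return Peak width iota in Hz.
#' @export
half_height_width <- function(psd, f) {
  .check_score_grid(psd, f)
  close_i <- .band_idx(psd, f - 0.05, f + 0.05)
  apex_i <- close_i[which.max(psd$power[close_i])]
  apex <- psd$power[apex_i]
  if (apex <= 0) return(psd$resolution)
  half <- apex / 2
  lo_i <- min(.band_idx(psd, f - 0.5, f + 0.5))
  hi_i <- max(.band_idx(psd, f - 0.5, f + 0.5))
  cross <- function(from, to, step) {
    i <- from
    while (i != to) {
      j <- i + step
      if (psd$power[j] < half) {
        # interpolate between grid points i (>= half) and j (< half)
        frac <- (psd$power[i] - half) / (psd$power[i] - psd$power[j])
        return(psd$freqs[i] + frac * (psd$freqs[j] - psd$freqs[i]))
      }
      i <- j
    }
    psd$freqs[to]   # clamp at the boundary
  }
  left <- cross(apex_i, lo_i, -1L)
  right <- cross(apex_i, hi_i, +1L)
  max(right - left, psd$resolution)
}

#' Peak sharpness score of a PSD peak
#'
#' The score of the peak at `f` is the larger of the two one-sided
#' prominences ([side_delta()]) divided by the width of the peak at half
#' height ([half_height_width()]): tall narrow peaks score high, broad
#' or shallow bumps score low. Scaling the PSD by c scales the score by
#' c; the width is amplitude-invariant.
#'
#' @inheritParams side_delta
#' @return An object of class `peak_score` with fields `f`, `M_minus`,
#'   `m_minus`, `dp_minus`, `M_plus`, `m_plus`, `dp_plus`, `iota`, `S`.
#' @export
peak_score <- function(psd, f) {
  l <- side_delta(psd, f, "left")
  r <- side_delta(psd, f, "right")
  iota <- half_height_width(psd, f)
  structure(list(f = f, M_minus = l$M, m_minus = l$m, dp_minus = l$dp,
                 M_plus = r$M, m_plus = r$m, dp_plus = r$dp,
                 iota = iota, S = max(r$dp, l$dp) / iota),
            class = "peak_score")
}

#' @export
print.peak_score <- function(x, ...) {
  cat(sprintf("<peak_score> f = %g Hz: dp- = %.4g, dp+ = %.4g, iota = %.4g Hz, S = %.4g\n",
              x$f, x$dp_minus, x$dp_plus, x$iota, x$S))
  invisible(x)
}

#' Score the candidate frequencies from SSVEP calibration epochs
#'
#' For each candidate frequency, sums the peak score at the stimulation
#' frequency and at its second harmonic, over the occipital electrodes
#' Oz, O1, O2 and over every calibration repetition of that frequency's
#' class. Scoring uses the high-resolution periodogram
#' ([highres_psd()]); rest epochs do not contribute.
#'
#' @param step1_epochs `eeg_epochs` from the SSVEP calibration step,
#'   labelled `ssvep_<f>`; channels must include Oz, O1 and O2.
#' @param resolution PSD grid spacing in Hz for scoring (default 0.025).
#' @return An object of class `freq_scores`: list with `total` (named
#'   numeric over the candidates) and `detail` (data frame of
#'   per-repetition, per-electrode, per-peak scores).
#' @export
score_candidates <- function(step1_epochs, resolution = 0.025) {
  stopifnot(inherits(step1_epochs, "eeg_epochs"))
  miss <- setdiff(.OCCIPITAL, step1_epochs$channel_labels)
  if (length(miss))
    stop("missing occipital channel(s): ", paste(miss, collapse = ", "))
  labs <- epoch_labels(step1_epochs)
  total <- stats::setNames(numeric(length(.CANDIDATES)),
                           as.character(.CANDIDATES))
  detail <- list()
  for (fc in .CANDIDATES) {
    cls <- paste0("ssvep_", fc)
    reps <- which(labs == cls)
    for (r in reps) {
      ep <- step1_epochs$epochs[[r]]
      for (ch in .OCCIPITAL) {
        psd <- highres_psd(ep$data[ch, ], ep$fs, resolution)
        s1 <- peak_score(psd, fc)$S
        s2 <- peak_score(psd, 2 * fc)$S
        total[[as.character(fc)]] <- total[[as.character(fc)]] + s1 + s2
        detail[[length(detail) + 1L]] <-
          data.frame(frequency = fc, repetition = r, electrode = ch,
                     S_fundamental = s1, S_harmonic = s2)
      }
    }
  }
  structure(list(total = total,
                 detail = do.call(rbind, detail)),
            class = "freq_scores")
}

#' @export
print.freq_scores <- function(x, ...) {
  cat("<freq_scores> candidate totals:\n")
  for (f in names(x$total))
    cat(sprintf("  %4s Hz: %.4g\n", f, x$total[[f]]))
  invisible(x)
}

#' @export
plot.freq_scores <- function(x, ...) {
  graphics::barplot(x$total, xlab = "candidate frequency (Hz)",
                    ylab = "total peak score", ...)
  invisible(x)
}

#' Harmonic conflict between two stimulation frequencies
#'
#' Two frequencies conflict when the second harmonic of the lower one
#' falls on the fundamental of the higher one (within `tol`), which
#' would make their spectral signatures ambiguous.
#'
#' @param f1,f2 Frequencies in Hz, distinct.
#' @param tol Tolerance in Hz (default 0.25).
#' @return Logical.
#' @export
harmonic_conflict <- function(f1, f2, tol = 0.25) {
  if (f1 == f2) stop("frequencies must differ")
  if (tol < 0) stop("`tol` must be >= 0")
  abs(2 * min(f1, f2) - max(f1, f2)) <= tol
}

#' Select the subject's primary frequency couple
#'
#' Takes the two highest-scoring candidates, subject to the harmonic
#' conflict rule: if the top two conflict, the lower-scoring member is
#' replaced by the best remaining non-conflicting candidate. Score ties
#' break toward the lower frequency.
#'
#' @param scores A `freq_scores` table (or named numeric of totals over
#'   the candidate set).
#' @param tol Harmonic-conflict tolerance in Hz.
#' @return An object of class `freq_couple`: numeric `c(f_low, f_high)`.
#' @export
select_couple <- function(scores, tol = 0.25) {
  total <- if (inherits(scores, "freq_scores")) scores$total else scores
  f <- as.numeric(names(total))
  if (!setequal(f, .CANDIDATES)) stop("score table must cover exactly the candidate set")
  ord <- order(-unname(total), f)
  first <- f[ord[1]]
  rest <- f[ord[-1]]
  second <- rest[!vapply(rest, harmonic_conflict, logical(1), f2 = first,
                         tol = tol)]
  if (!length(second)) stop("no conflict-free couple exists")
  couple <- sort(c(first, second[1]))
  structure(couple, class = "freq_couple")
}

#' @export
print.freq_couple <- function(x, ...) {
  cat(sprintf("<freq_couple> (%g Hz, %g Hz)\n", x[1], x[2]))
  invisible(x)
}
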