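#' Experimental protocol specification
#'
#' Describes one step of the four-step recording protocol: the ordered
#' class labels, repetitions per class, event duration, the analysis
#' window cut from each event, and whether the task sequence is
#' randomized or fixed.
#'
#' Defaults follow the standardized protocol:
#' \describe{
#'   \item{Step 1}{SSVEP calibration: 4 flicker classes (5, 7, 9, 12 Hz)
#'     plus rest, 15 repetitions of 3 s, analysis window [1.8, 2.8) s.}
#'   \item{Step 2}{Mixed training: SSVEP and imagery tasks at the two
#'     selected frequencies plus rest, 18 repetitions, repeated over
#'     3 blocks; not consumed by the classifier.}
#'   \item{Step 3}{Offline imagery: the two imagery classes plus rest,
#'     20 repetitions of 9 s, window [1, 7) s.}
#'   \item{Step 4}{Online imagery: same classes, 20 repetitions of 5 s,
#'     window [1, 4) s, fixed sequence (low frequency, rest, high
#'     frequency) repeated.}
#' }
#'
#' Class labels are `"rest"`, `"ssvep_<f>"` and `"vi_<f>"` with `<f>` the
#' stimulation frequency in Hz.
#'
#' @param step Protocol step, 1-4.
#' @param couple Numeric length-2 frequency couple (Hz), required for
#'   steps 2-4; ignored for step 1.
#' @param reps_per_class Repetitions per class; default per step.
#' @param event_duration Event duration in seconds; default per step.
#' @param epoch_window Length-2 numeric, analysis window [start, end) in
#'   seconds from event onset; default per step.
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(step, couple = NULL, reps_per_class = NULL,
                          event_duration = NULL, epoch_window = NULL) {
  if (!step %in% 1:4) stop("`step` must be 1, 2, 3 or 4")
  if (step >= 2) {
    if (is.null(couple) || length(couple) != 2L)
      stop("steps 2-4 need a frequency `couple` of length 2")
    couple <- sort(as.numeric(couple))
  }
  def <- switch(step,
    `1` = list(classes = c(paste0("ssvep_", .CANDIDATES), "rest"),
               reps = 15L, dur = 3, win = c(1.8, 2.8), mode = "randomized"),
    `2` = list(classes = c(paste0("ssvep_", couple), paste0("vi_", couple),
                           "rest"),
               reps = 54L, dur = 3, win = c(1.8, 2.8), mode = "randomized"),
    `3` = list(classes = c(paste0("vi_", couple[1]), "rest",
                           paste0("vi_", couple[2])),
               reps = 20L, dur = 9, win = c(1, 7), mode = "randomized"),
    `4` = list(classes = c(paste0("vi_", couple[1]), "rest",
                           paste0("vi_", couple[2])),
               reps = 20L, dur = 5, win = c(1, 4), mode = "fixed"))
  if (!is.null(reps_per_class)) def$reps <- as.integer(reps_per_class)
  if (!is.null(event_duration)) def$dur <- event_duration
  if (!is.null(epoch_window)) def$win <- epoch_window
  if (def$reps < 1L) stop("`reps_per_class` must be positive")
  if (diff(def$win) <= 0 || def$win[1] < 0 || def$win[2] > def$dur)
    stop("`epoch_window` must be a non-empty interval inside the event")
  structure(list(step_id = as.integer(step), classes = def$classes,
                 reps_per_class = def$reps, event_duration = def$dur,
                 epoch_window = def$win, sequence_mode = def$mode,
                 couple = couple),
            class = "protocol_spec")
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat(sprintf("<protocol_spec> step %d: %d classes x %d reps, %g s events, window [%g, %g) s, %s sequence\n",
              x$step_id, length(x$classes), x$reps_per_class,
              x$event_duration, x$epoch_window[1], x$epoch_window[2],
              x$sequence_mode))
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  invisible(x)
}

# Ordered task sequence for one recording. Step 4 uses the fixed block
# (low frequency, rest, high frequency) repeated; randomized steps draw
# a balanced shuffle from the active RNG stream.
.task_sequence <- function(protocol) {
  if (protocol$sequence_mode == "fixed") {
    stopifnot(length(protocol$classes) == 3L)
    rep(protocol$classes, times = protocol$reps_per_class)
  } else {
    sample(rep(protocol$classes, each = protocol$reps_per_class))
  }
}
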