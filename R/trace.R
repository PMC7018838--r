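#' Construct a gaze trace
#'
#' A `gaze_trace` holds a synchronized head-free recording: per-sample
#' eye-in-head (EiH) unit direction vectors, head orientation quaternions in
#' the world frame, timestamps, and the tracker's per-sample confidence.
#' All downstream computation (velocity extraction, classification) consumes
#' this container.
#'
#' @param timestamps numeric vector of sample times in seconds, strictly
#'   increasing.
#' @param eih n x 3 matrix of eye-in-head unit direction vectors.
#' @param head n x 4 matrix of unit quaternions (w, x, y, z), head
#'   orientation in the world frame.
#' @param confidence per-sample confidence in `[0, 1]`.
#' @param fs sampling rate in Hz. Defaults to the reciprocal median sampling
#'   interval.
#' @param subject_id,task_id opaque identifier strings.
#' @return object of class `gaze_trace`.
#' @export
gaze_trace <- function(timestamps, eih, head, confidence,
                       fs = NULL, subject_id = "", task_id = "") {
  timestamps <- as.numeric(timestamps)
  eih <- as.matrix(eih); head <- as.matrix(head)
  confidence <- as.numeric(confidence)
  n <- length(timestamps)
  if (n < 2) stop("a gaze trace needs at least two samples")
  if (nrow(eih) != n || ncol(eih) != 3) stop("eih must be n x 3")
  if (nrow(head) != n || ncol(head) != 4) stop("head must be n x 4")
  if (length(confidence) != n) stop("confidence length mismatch")
  dt <- diff(timestamps)
  if (any(dt <= 0)) {
    bad <- which(dt <= 0)[1] + 1L
    stop(sprintf("timestamps not strictly increasing at sample %d", bad))
  }
  if (is.null(fs)) fs <- 1 / median(dt)
  if (fs <= 0) stop("fs must be positive")
  if (abs(median(dt) - 1 / fs) > 0.01 / fs)
    stop("median sampling interval inconsistent with fs (>1%)")
  # renormalize near-unit vectors; reject the rest
  en <- sqrt(rowSums(eih^2))
  if (any(abs(en - 1) > 1e-3))
    stop(sprintf("eih vector at sample %d deviates from unit norm by more than 1e-3",
                 which(abs(en - 1) > 1e-3)[1]))
  eih <- eih / en
  qn <- sqrt(rowSums(head^2))
  if (any(abs(qn - 1) > 1e-3))
    stop(sprintf("head quaternion at sample %d deviates from unit norm by more than 1e-3",
                 which(abs(qn - 1) > 1e-3)[1]))
  head <- head / qn
  if (any(confidence < -1e-9 | confidence > 1 + 1e-9))
    stop("confidence outside [0, 1]")
  confidence <- pmin(pmax(confidence, 0), 1)
  structure(list(timestamps = timestamps, fs = fs, eih = eih, head = head,
                 confidence = confidence,
                 subject_id = as.character(subject_id),
                 task_id = as.character(task_id)),
            class = "gaze_trace")
}

#' @export
print.gaze_trace <- function(x, ...) {
  cat(sprintf("gaze_trace: %d samples @ %.6g Hz (%.4gs)\n",
              length(x$timestamps), x$fs,
              x$timestamps[length(x$timestamps)] - x$timestamps[1]))
  if (nzchar(x$subject_id)) cat("  subject:", x$subject_id, "\n")
  if (nzchar(x$task_id)) cat("  task:   ", x$task_id, "\n")
  cat(sprintf("  confidence: median %.2f, %.1f%% below 0.3\n",
              median(x$confidence), 100 * mean(x$confidence < 0.3)))
  invisible(x)
}

#' @export
length.gaze_trace <- function(x) length(x$timestamps)

#' Construct a label sequence
#'
#' Per-sample gaze-event classes over the alphabet `FIX`, `PUR`, `SAC`,
#' `NONE`. `NONE` marks blinks, unlabelled spans and low-confidence samples;
#' it is never scored by any metric. Both stationary fixation and fixation
#' under translation (VOR) are stored as `FIX`.
#'
#' @param labels character vector (or factor) of per-sample classes.
#' @param fs sampling rate in Hz.
#' @param source_id identifier of the labeller or classifier that produced
#'   the sequence.
#' @return object of class `label_sequence` (a factor with attributes).
#' @export
label_sequence <- function(labels, fs, source_id = "") {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), GAZE_ALPHABET)
  if (length(bad))
    stop("unknown label token(s): ", paste(bad, collapse = ", "))
  structure(factor(labels, levels = GAZE_ALPHABET),
            fs = as.numeric(fs), source_id = as.character(source_id),
            class = c("label_sequence", "factor"))
}

#' @export
print.label_sequence <- function(x, ...) {
  tab <- table(unclass(x))
  names(tab) <- GAZE_ALPHABET
  cat(sprintf("label_sequence: %d samples @ %.6g Hz", length(x), attr(x, "fs")))
  sid <- attr(x, "source_id")
  if (nzchar(sid)) cat(" [", sid, "]", sep = "")
  cat("\n  ")
  cat(paste(sprintf("%s: %d", names(tab), as.integer(tab)), collapse = "  "), "\n")
  invisible(x)
}

as_label_chr <- function(seq) as.character(seq)

label_fs <- function(seq) {
  fs <- attr(seq, "fs")
  if (is.null(fs)) stop("label sequence has no sampling rate")
  fs
}
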