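#' Convert a label sequence to an event list
#'
#' Maximal runs of identical non-`NONE` labels become events; `NONE` runs
#' are omitted (gaps between events are implicitly `NONE`). Events use
#' half-open sample ranges `[start, end)` with 1-based `start`.
#'
#' @param seq a [label_sequence].
#' @return an `event_list`: data frame with columns `cls`, `start`, `end`,
#'   `start_t`, `end_t`, plus attributes `fs` and `total_samples`.
#' @export
labels_to_events <- function(seq) {
  lab <- as_label_chr(seq)
  fs <- label_fs(seq)
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != "NONE" & !is.na(r$values)
  ev <- data.frame(cls = r$values[keep],
                   start = starts[keep],
                   end = ends[keep] + 1L,
                   stringsAsFactors = FALSE)
  ev$start_t <- (ev$start - 1) / fs
  ev$end_t <- (ev$end - 1) / fs
  structure(ev, fs = fs, total_samples = length(lab),
            class = c("event_list", "data.frame"))
}

#' @export
print.event_list <- function(x, ...) {
  cat(sprintf("event_list: %d events over %d samples @ %.6g Hz\n",
              nrow(x), attr(x, "total_samples"), attr(x, "fs")))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}

event_list_new <- function(df, fs, total_samples) {
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  if (nrow(df) > 1 && any(df$start[-1] < df$end[-nrow(df)]))
    stop("overlapping events")
  df$start_t <- (df$start - 1) / fs
  df$end_t <- (df$end - 1) / fs
  structure(df, fs = fs, total_samples = total_samples,
            class = c("event_list", "data.frame"))
}

#' Convert an event list back to a label sequence
#'
#' Inverse of [labels_to_events]; gaps are filled with `NONE`.
#'
#' @param evts an `event_list`.
#' @param source_id identifier for the produced sequence.
#' @return a [label_sequence].
#' @export
events_to_labels <- function(evts, source_id = "") {
  fs <- attr(evts, "fs")
  n <- attr(evts, "total_samples")
  lab <- rep("NONE", n)
  if (nrow(evts)) {
    o <- order(evts$start)
    if (nrow(evts) > 1 && any(evts$start[o][-1] < evts$end[o][-nrow(evts)]))
      stop("overlapping events")
    for (i in seq_len(nrow(evts)))
      lab[evts$start[i]:(evts$end[i] - 1L)] <- evts$cls[i]
  }
  label_sequence(lab, fs = fs, source_id = source_id)
}

event_durations_ms <- function(evts) {
  (evts$end - evts$start) / attr(evts, "fs") * 1000
}

#' Clean an event list
#'
#' Applies the labelling post-processing rules, in order: (1) merge pairs of
#' fixations separated by less than `merge_gap_ms` whose mean gaze
#' directions are within `merge_sep_deg` (the gap, which must contain no
#' other event, is relabelled `FIX`); (2) drop fixations shorter than 50 ms;
#' (3) drop saccades longer than 150 ms; (4) drop any event shorter than
#' 10 ms. Dropped spans become `NONE`. The ordered pass is iterated to a
#' fixed point, so the result is idempotent. Merged fixations are duration
#' tested after merging. All duration comparisons are strict.
#'
#' When `gaze` is `NULL` the angular-separation criterion cannot be
#' evaluated; merging then uses the temporal criterion alone, with a
#' warning.
#'
#' @param evts an `event_list`.
#' @param gaze optional n x 3 matrix of gaze-in-world unit vectors aligned
#'   with the underlying samples; used for the fixation-merge separation.
#' @param merge_gap_ms,merge_sep_deg fixation-merge thresholds.
#' @param min_fix_ms,max_sac_ms,min_event_ms duration thresholds.
#' @return cleaned `event_list`.
#' @export
clean_events <- function(evts, gaze = NULL,
                         merge_gap_ms = 75, merge_sep_deg = 0.5,
                         min_fix_ms = 50, max_sac_ms = 150, min_event_ms = 10) {
  fs <- attr(evts, "fs")
  n <- attr(evts, "total_samples")
  if (is.null(gaze)) {
    warning("no gaze vectors supplied; fixation merge uses the ",
            merge_gap_ms, " ms criterion alone")
  } else {
    gaze <- as.matrix(gaze)
    if (nrow(gaze) != n) stop("gaze vectors do not span the sample range")
  }
  ev <- as.data.frame(evts)[, c("cls", "start", "end")]
  repeat {
    before <- ev
    ev <- merge_fix_pass(ev, gaze, fs, merge_gap_ms, merge_sep_deg)
    dur <- (ev$end - ev$start) / fs * 1000
    drop <- (ev$cls == "FIX" & dur < min_fix_ms) |
            (ev$cls == "SAC" & dur > max_sac_ms) |
            (dur < min_event_ms)
    ev <- ev[!drop, , drop = FALSE]
    if (identical(dim(ev), dim(before)) && nrow(ev) &&
        all(ev$start == before$start & ev$end == before$end &
            ev$cls == before$cls)) break
    if (nrow(ev) == 0) break
  }
  event_list_new(ev, fs, n)
}

merge_fix_pass <- function(ev, gaze, fs, gap_ms, sep_deg) {
  if (nrow(ev) < 2) return(ev)
  ev <- ev[order(ev$start), , drop = FALSE]
  i <- 1L
  while (i < nrow(ev)) {
    a <- ev[i, ]; b <- ev[i + 1L, ]
    gap <- (b$start - a$end) / fs * 1000
    if (a$cls == "FIX" && b$cls == "FIX" && gap >= 0 && gap <= gap_ms &&
        fix_separation_ok(a, b, gaze, sep_deg)) {
      ev$end[i] <- b$end
      ev <- ev[-(i + 1L), , drop = FALSE]
      # stay on i: the merged fixation may chain with the next one
    } else {
      i <- i + 1L
    }
  }
  rownames(ev) <- NULL
  ev
}

fix_separation_ok <- function(a, b, gaze, sep_deg) {
  if (is.null(gaze)) return(TRUE)
  ma <- colMeans(gaze[a$start:(a$end - 1L), , drop = FALSE])
  mb <- colMeans(gaze[b$start:(b$end - 1L), , drop = FALSE])
  ma <- ma / sqrt(sum(ma^2)); mb <- mb / sqrt(sum(mb^2))
  ang <- acos(pmin(1, pmax(-1, sum(ma * mb)))) * 180 / pi
  ang < sep_deg
}
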