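# Event Level Cross-category (ELC) metric: window-based transition
# matching, l2/overlap alignment statistics, timing-offset correction, and
# an event confusion matrix with kappa*/F1. Asymmetric by construction;
# optionally applied in both directions and averaged (inter-coder use).

#' ELC configuration
#'
#' Transition-match window half-widths: gaze-shift related transitions
#' (either adjacent event is a saccade) use the tighter window because
#' saccade boundaries are easy to localize.
#'
#' @param window_shift_ms half-width for saccade-adjacent transitions (ms).
#' @param window_other_ms half-width for all other transitions (ms).
#' @param count_detached_as_matched score detached events as matches
#'   (inflates scores; off by default).
#' @return object of class `elc_config`.
#' @export
elc_config <- function(window_shift_ms = 25, window_other_ms = 35,
                       count_detached_as_matched = FALSE) {
  if (window_shift_ms <= 0 || window_other_ms <= 0)
    stop("windows must be positive")
  structure(list(window_shift_ms = window_shift_ms,
                 window_other_ms = window_other_ms,
                 count_detached_as_matched = count_detached_as_matched),
            class = "elc_config")
}

#' Extract transition points from a label sequence
#'
#' Every non-`NONE` event contributes exactly two transition points: an
#' onset at its first sample index and an offset one past its last sample
#' index. `NONE` spans separate events but own no transitions.
#'
#' @param seq a [label_sequence].
#' @return data frame with columns `event` (row in [labels_to_events]
#'   output), `side` (`"onset"`/`"offset"`), `index` (sample boundary),
#'   `cls`, ordered by index with onsets before offsets at ties.
#' @export
extract_transitions <- function(seq) {
  ev <- labels_to_events(seq)
  if (nrow(ev) == 0)
    return(data.frame(event = integer(0), side = character(0),
                      index = integer(0), cls = character(0)))
  tr <- rbind(
    data.frame(event = seq_len(nrow(ev)), side = "onset",
               index = ev$start, cls = ev$cls),
    data.frame(event = seq_len(nrow(ev)), side = "offset",
               index = ev$end, cls = ev$cls))
  tr[order(tr$index, match(tr$side, c("onset", "offset"))), , drop = FALSE]
}

# TRUE where a transition is "gaze-shift related": its own event or the
# event touching it at that boundary is a saccade
shift_related <- function(tr, evts) {
  own_sac <- tr$cls == "SAC"
  touch_sac <- logical(nrow(tr))
  for (i in seq_len(nrow(tr))) {
    if (tr$side[i] == "onset") {
      j <- which(evts$end == tr$index[i])
    } else {
      j <- which(evts$start == tr$index[i])
    }
    touch_sac[i] <- length(j) > 0 && any(evts$cls[j] == "SAC")
  }
  own_sac | touch_sac
}

#' Window-based transition matching
#'
#' For every reference transition, a window (half-width per
#' [elc_config]: saccade-adjacent transitions get the shift window) is
#' extended onto the test sequence; the transition is matched with the
#' first-in-time test transition inside the window whose adjacent event
#' type on the relevant side equals the reference event type (onsets match
#' onsets of the same class, offsets match offsets). A test transition
#' serves at most one reference transition, claimed in reference order.
#' An event is matched when both its transitions are; an unmatched
#' reference event lying completely inside a same-class test event is
#' flagged detached.
#'
#' @param ref,test [label_sequence]s on the same timeline.
#' @param cfg an [elc_config].
#' @return list with `pairs` (matched transition pairs), `ref_events`,
#'   `test_events`, per-event `status` (`matched`/`unmatched`/`detached`),
#'   and the per-test-event count of matched transitions.
#' @export
window_match <- function(ref, test, cfg = elc_config()) {
  fs <- label_fs(ref)
  ref_ev <- labels_to_events(ref)
  test_ev <- labels_to_events(test)
  ref_tr <- extract_transitions(ref)
  test_tr <- extract_transitions(test)
  ref_tr$window_ms <- ifelse(shift_related(ref_tr, ref_ev),
                             cfg$window_shift_ms, cfg$window_other_ms)
  used <- logical(nrow(test_tr))
  pairs <- data.frame(ref_row = integer(0), test_row = integer(0))
  for (i in seq_len(nrow(ref_tr))) {
    d_ms <- abs(test_tr$index - ref_tr$index[i]) / fs * 1000
    cand <- which(!used &
                    test_tr$side == ref_tr$side[i] &
                    test_tr$cls == ref_tr$cls[i] &
                    d_ms <= ref_tr$window_ms[i] + 1e-9)
    if (length(cand)) {
      j <- cand[which.min(test_tr$index[cand])]   # first in time
      used[j] <- TRUE
      pairs <- rbind(pairs, data.frame(ref_row = i, test_row = j))
    }
  }
  # per-reference-event status
  matched_tr <- logical(nrow(ref_tr))
  matched_tr[pairs$ref_row] <- TRUE
  status <- character(nrow(ref_ev))
  for (e in seq_len(nrow(ref_ev))) {
    rows <- which(ref_tr$event == e)
    if (all(matched_tr[rows])) {
      status[e] <- "matched"
    } else {
      inside <- any(test_ev$cls == ref_ev$cls[e] &
                      test_ev$start <= ref_ev$start[e] &
                      test_ev$end >= ref_ev$end[e])
      status[e] <- if (inside) "detached" else "unmatched"
    }
  }
  test_matched_count <- integer(nrow(test_ev))
  if (nrow(pairs))
    for (j in pairs$test_row) {
      e <- test_tr$event[j]
      test_matched_count[e] <- test_matched_count[e] + 1L
    }
  list(pairs = pairs, ref_tr = ref_tr, test_tr = test_tr,
       ref_events = ref_ev, test_events = test_ev, status = status,
       test_matched_count = test_matched_count, fs = fs)
}

#' Alignment statistics for matched events
#'
#' For each matched reference event the test-side interval is delimited by
#' the test transitions its onset and offset matched (for fragmented
#' events this spans the fragments). `l2` is the Euclidean boundary offset
#' in ms, `O_r` the intersection-over-union of the two sample sets.
#'
#' @param wm result of [window_match].
#' @return data frame (one row per matched reference event) with `cls`,
#'   `l2_ms`, `overlap`, plus attribute `summary` (per-class and overall
#'   mean/sd).
#' @export
l2_and_overlap <- function(wm) {
  fs <- wm$fs
  rows <- which(wm$status == "matched")
  out <- data.frame(event = integer(0), cls = character(0),
                    l2_ms = numeric(0), overlap = numeric(0))
  for (e in rows) {
    tr_rows <- which(wm$ref_tr$event == e)
    on_row <- tr_rows[wm$ref_tr$side[tr_rows] == "onset"]
    off_row <- tr_rows[wm$ref_tr$side[tr_rows] == "offset"]
    t_on <- wm$test_tr$index[wm$pairs$test_row[wm$pairs$ref_row == on_row]]
    t_off <- wm$test_tr$index[wm$pairs$test_row[wm$pairs$ref_row == off_row]]
    ds <- (t_on - wm$ref_events$start[e]) / fs * 1000
    de <- (t_off - wm$ref_events$end[e]) / fs * 1000
    ov <- overlap_ratio_idx(wm$ref_events$start[e], wm$ref_events$end[e],
                            t_on, t_off)
    out <- rbind(out, data.frame(event = e, cls = wm$ref_events$cls[e],
                                 l2_ms = sqrt(ds^2 + de^2), overlap = ov))
  }
  summ <- do.call(rbind, lapply(c(GAZE_CLASSES, "overall"), function(cl) {
    sel <- if (cl == "overall") rep(TRUE, nrow(out)) else out$cls == cl
    data.frame(class = cl, n = sum(sel),
               l2_mean = if (any(sel)) mean(out$l2_ms[sel]) else NA_real_,
               l2_sd = if (sum(sel) > 1) sd(out$l2_ms[sel]) else 0,
               Or_mean = if (any(sel)) mean(out$overlap[sel]) else NA_real_,
               Or_sd = if (sum(sel) > 1) sd(out$overlap[sel]) else 0)
  }))
  attr(out, "summary") <- summ
  out
}

#' Timing-offset correction
#'
#' Every matched transition pair (regardless of its event's match status)
#' is replaced by a single representative transition at the rounded mean of
#' the two sample indices (ties round toward the reference index); both
#' sequences move the paired boundary to the same representative index.
#' Each sequence is then rebuilt from its corrected event extents: a
#' boundary moving away from the event's centre extends the event's class
#' over the displaced samples (including previously unlabelled ones, which
#' thereby inherit the class the correction dictates); a boundary moving
#' inwards cedes them to the neighbouring event, whose own corrected
#' boundary takes them over -- or leaves them unlabelled when the two sides
#' of a shared boundary were matched to different test transitions.
#' Overlapping corrected events are resolved left-to-right (the earlier
#' event keeps contested samples).
#'
#' @param ref,test the original [label_sequence]s.
#' @param wm result of [window_match] on them.
#' @return list with corrected `ref` and `test` sequences.
#' @export
correct_offsets <- function(ref, test, wm) {
  fs <- wm$fs
  if (nrow(wm$pairs) == 0) return(list(ref = ref, test = test))
  # representative index for every matched pair
  m_idx <- mapply(function(i, j) {
    round_toward((wm$ref_tr$index[i] + wm$test_tr$index[j]) / 2,
                 wm$ref_tr$index[i])
  }, wm$pairs$ref_row, wm$pairs$test_row)
  ref_new <- rebuild_corrected(wm$ref_events, wm$ref_tr,
                               wm$pairs$ref_row, m_idx, length(ref))
  test_new <- rebuild_corrected(wm$test_events, wm$test_tr,
                                wm$pairs$test_row, m_idx, length(test))
  list(ref = label_sequence(ref_new, fs = fs,
                            source_id = attr(ref, "source_id")),
       test = label_sequence(test_new, fs = fs,
                             source_id = attr(test, "source_id")))
}

round_toward <- function(x, anchor) {
  lo <- floor(x); hi <- ceiling(x)
  if (lo == hi) return(as.integer(lo))
  if (abs(x - lo) < abs(x - hi)) return(as.integer(lo))
  if (abs(x - hi) < abs(x - lo)) return(as.integer(hi))
  as.integer(if (abs(anchor - lo) <= abs(anchor - hi)) lo else hi)
}

# repaint a label vector from event extents whose matched boundaries moved
# to the representative indices; left-to-right painting keeps the earlier
# event's claim on contested samples
rebuild_corrected <- function(evts, trs, matched_rows, m_idx, n) {
  start_new <- evts$start
  end_new <- evts$end
  for (p in seq_along(matched_rows)) {
    row <- matched_rows[p]
    e <- trs$event[row]
    if (trs$side[row] == "onset") start_new[e] <- m_idx[p]
    else end_new[e] <- m_idx[p]
  }
  lab <- rep("NONE", n)
  painted <- logical(n)
  o <- order(start_new)
  for (e in o) {
    s <- max(1L, start_new[e]); t <- min(n + 1L, end_new[e])
    if (t <= s) next                       # collapsed by opposing moves
    span <- s:(t - 1L)
    span <- span[!painted[span]]
    lab[span] <- evts$cls[e]
    painted[span] <- TRUE
  }
  lab
}

#' ELC event confusion matrix with kappa* and F1
#'
#' Matched reference events fall on the diagonal (the matching criterion
#' enforces class equality). Unmatched reference events fill their class
#' row's `unmatched` column. Test events with no matched transition at all
#' are charged to the modal non-`NONE` reference class beneath them (the
#' cross-category counts, e.g. a spurious saccade inside a fixation
#' increments F/S). Detached events are omitted by default; counting them
#' as matches can only inflate per-class scores.
#'
#' @param wm result of [window_match].
#' @param ref the reference [label_sequence] (for locating unmatched test
#'   events).
#' @param cfg an [elc_config].
#' @return list with `confusion` (rows = reference classes, columns =
#'   classes + `unmatched`), `kappa_star` overall, `per_class` data frame
#'   of kappa*/F1, and the status counts.
#' @export
elc_confusion <- function(wm, ref, cfg = elc_config()) {
  classes <- GAZE_CLASSES
  conf <- matrix(0L, length(classes), length(classes) + 1L,
                 dimnames = list(classes, c(classes, "unmatched")))
  for (e in seq_len(nrow(wm$ref_events))) {
    cls <- wm$ref_events$cls[e]
    st <- wm$status[e]
    if (st == "matched" || (st == "detached" && cfg$count_detached_as_matched)) {
      conf[cls, cls] <- conf[cls, cls] + 1L
    } else if (st == "unmatched") {
      conf[cls, "unmatched"] <- conf[cls, "unmatched"] + 1L
    }                                   # detached omitted by default
  }
  r_lab <- as_label_chr(ref)
  for (e in which(wm$test_matched_count == 0L)) {
    seg <- r_lab[wm$test_events$start[e]:(wm$test_events$end[e] - 1L)]
    seg <- seg[seg != "NONE"]
    if (!length(seg)) next
    under <- names(which.max(table(factor(seg, levels = classes))))
    tcls <- wm$test_events$cls[e]
    conf[under, tcls] <- conf[under, tcls] + 1L
  }
  sq <- rbind(conf, unmatched = 0L)
  kappa_star <- if (sum(conf) > 0) suppressWarnings(cohen_kappa(sq)) else NA_real_
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    tp <- conf[cl, cl]
    fp <- sum(conf[, cl]) - tp
    fn <- sum(conf[cl, ]) - tp
    f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
    data.frame(class = cl, kappa_star = class_kappa(sq, cl), f1 = f1)
  }))
  list(confusion = conf, kappa_star = kappa_star, per_class = per_class,
       n_matched = sum(wm$status == "matched"),
       n_unmatched = sum(wm$status == "unmatched"),
       n_detached = sum(wm$status == "detached"))
}

#' Evaluate the ELC metric between two label sequences
#'
#' Composes transition extraction, window matching, l2/overlap statistics,
#' timing-offset correction and the event confusion matrix. ELC is
#' asymmetric; with `bidirectional = TRUE` (inter-coder use) it is applied
#' in both directions and the scalar metrics averaged. Classifier output
#' should be evaluated single-direction against the human reference.
#'
#' @param ref,test [label_sequence]s of equal length.
#' @param cfg an [elc_config].
#' @param bidirectional apply in both directions and average.
#' @return object of class `elc_result`.
#' @export
elc_evaluate <- function(ref, test, cfg = elc_config(), bidirectional = FALSE) {
  if (length(ref) != length(test)) stop("sequences differ in length")
  fwd <- elc_one_direction(ref, test, cfg)
  if (!bidirectional) {
    out <- c(fwd, list(direction = "ref->test", bidirectional = FALSE))
    class(out) <- "elc_result"
    return(out)
  }
  rev <- elc_one_direction(test, ref, cfg)
  avg <- list(
    kappa_star = mean(c(fwd$kappa_star, rev$kappa_star)),
    per_class = data.frame(
      class = fwd$per_class$class,
      kappa_star = (fwd$per_class$kappa_star + rev$per_class$kappa_star) / 2,
      f1 = (fwd$per_class$f1 + rev$per_class$f1) / 2),
    l2_mean = mean(c(fwd$alignment_summary$l2_mean[fwd$alignment_summary$class == "overall"],
                     rev$alignment_summary$l2_mean[rev$alignment_summary$class == "overall"])),
    Or_mean = mean(c(fwd$alignment_summary$Or_mean[fwd$alignment_summary$class == "overall"],
                     rev$alignment_summary$Or_mean[rev$alignment_summary$class == "overall"])))
  out <- list(forward = fwd, reverse = rev, averaged = avg,
              direction = "averaged", bidirectional = TRUE)
  class(out) <- "elc_result"
  out
}

elc_one_direction <- function(ref, test, cfg) {
  wm <- window_match(ref, test, cfg)
  al <- l2_and_overlap(wm)
  corr <- correct_offsets(ref, test, wm)
  cm <- elc_confusion(wm, ref, cfg)
  c(cm, list(alignment = al, alignment_summary = attr(al, "summary"),
             corrected = corr, match = wm))
}

#' @export
print.elc_result <- function(x, ...) {
  cat("ELC evaluation (", x$direction, ")\n", sep = "")
  if (isTRUE(x$bidirectional)) {
    cat(sprintf("  averaged kappa* %.3f, l2 %.2f ms, O_r %.3f\n",
                x$averaged$kappa_star, x$averaged$l2_mean, x$averaged$Or_mean))
    cat(sprintf("  forward:  %d matched / %d unmatched / %d detached\n",
                x$forward$n_matched, x$forward$n_unmatched, x$forward$n_detached))
    cat(sprintf("  reverse:  %d matched / %d unmatched / %d detached\n",
                x$reverse$n_matched, x$reverse$n_unmatched, x$reverse$n_detached))
  } else {
    cat(sprintf("  kappa* %.3f; %d matched / %d unmatched / %d detached\n",
                x$kappa_star, x$n_matched, x$n_unmatched, x$n_detached))
    ov <- x$alignment_summary[x$alignment_summary$class == "overall", ]
    cat(sprintf("  l2 %.2f +- %.2f ms, O_r %.3f +- %.3f\n",
                ov$l2_mean, ov$l2_sd, ov$Or_mean, ov$Or_sd))
  }
  invisible(x)
}
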