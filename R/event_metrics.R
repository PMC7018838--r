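# Prior event-level agreement metrics that the window-based ELC metric is
# compared against: sample-majority vote, earliest-overlap event F1 with
# relative timing offset/deviation, largest-overlap event kappa, and the
# length-normalized event error rate.

#' Majority-vote event score
#'
#' For each reference event, the modal test label among the samples inside
#' its bounds decides correctness. `NONE` test samples are ignored in the
#' vote; modal ties break in the fixed class order `FIX < PUR < SAC`. The
#' metric gives no penalty to short spurious events that fragment a longer
#' one without flipping the majority.
#'
#' @param ref_events reference `event_list`.
#' @param test_labels test [label_sequence] on the same timeline.
#' @return list with `per_class` fractions correct and `overall` fraction.
#' @export
majority_vote_score <- function(ref_events, test_labels) {
  lab <- as_label_chr(test_labels)
  if (attr(ref_events, "total_samples") != length(lab))
    stop("event list and label sequence span different sample counts")
  hit <- logical(nrow(ref_events))
  for (i in seq_len(nrow(ref_events))) {
    seg <- lab[ref_events$start[i]:(ref_events$end[i] - 1L)]
    seg <- seg[seg != "NONE"]
    if (!length(seg)) { hit[i] <- FALSE; next }
    counts <- table(factor(seg, levels = GAZE_CLASSES))
    modal <- GAZE_CLASSES[which.max(counts)]
    hit[i] <- modal == ref_events$cls[i]
  }
  per_class <- vapply(GAZE_CLASSES, function(cl) {
    sel <- ref_events$cls == cl
    if (!any(sel)) NA_real_ else mean(hit[sel])
  }, 1)
  list(per_class = per_class, overall = mean(hit), n_events = nrow(ref_events))
}

#' Event-level F1 with relative timing offsets (earliest-overlap matching)
#'
#' One-vs-rest for a single class: every other category is treated as a
#' common opposite. Each reference event of the class is matched to the
#' earliest-onset overlapping test event of the same class; matched test
#' events are consumed. F1 = 2TP / (2TP + FP + FN). The relative timing
#' offset (RTO) is the mean signed boundary offset of matched pairs
#' (test - ref, in ms) and the relative timing deviation (RTD) its standard
#' deviation, reported separately for onsets and offsets. Earliest-overlap
#' matching is known to produce large offsets when a test event's onset
#' nearly coincides with the reference offset.
#'
#' @param ref,test `event_list`s on the same timeline.
#' @param cls class to score.
#' @return list with `f1`, `rto_onset`, `rto_offset`, `rtd_onset`,
#'   `rtd_offset` (ms), and the match counts.
#' @export
hooge_event_f1 <- function(ref, test, cls) {
  fs <- attr(ref, "fs")
  r <- ref[ref$cls == cls, , drop = FALSE]
  s <- test[test$cls == cls, , drop = FALSE]
  s <- s[order(s$start), , drop = FALSE]
  used <- logical(nrow(s))
  on_off <- off_off <- numeric(0)
  tp <- 0L
  for (i in seq_len(nrow(r))) {
    cand <- which(!used & s$start < r$end[i] & s$end > r$start[i])
    if (length(cand)) {
      j <- cand[1]   # earliest onset among overlapping
      used[j] <- TRUE
      tp <- tp + 1L
      on_off <- c(on_off, (s$start[j] - r$start[i]) / fs * 1000)
      off_off <- c(off_off, (s$end[j] - r$end[i]) / fs * 1000)
    }
  }
  fn <- nrow(r) - tp
  fp <- nrow(s) - tp
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 1
  list(f1 = f1,
       rto_onset = if (length(on_off)) mean(on_off) else NA_real_,
       rto_offset = if (length(off_off)) mean(off_off) else NA_real_,
       rtd_onset = if (length(on_off) > 1) sd(on_off) else 0,
       rtd_offset = if (length(off_off) > 1) sd(off_off) else 0,
       tp = tp, fp = fp, fn = fn)
}

overlap_ratio_idx <- function(s1, e1, s2, e2) {
  inter <- max(0L, min(e1, e2) - max(s1, s2))
  uni <- (e1 - s1) + (e2 - s2) - inter
  if (uni <= 0) 0 else inter / uni
}

#' Largest-overlap event kappa
#'
#' For each reference event, the test event with the highest overlap ratio
#' (intersection over union of sample sets, any class) is its match and
#' fills the event confusion matrix; ties break toward the earlier test
#' onset. Reference events overlapping nothing are recorded in an
#' `unmatched` column. Kappa is computed from the resulting event confusion
#' matrix, overall and per class (one-vs-rest collapse).
#'
#' @param ref,test `event_list`s on the same timeline.
#' @return list with the `confusion` matrix (classes + unmatched column),
#'   `kappa` overall and `per_class` kappas.
#' @export
zemblys_event_kappa <- function(ref, test) {
  classes <- GAZE_CLASSES
  conf <- matrix(0L, length(classes), length(classes) + 1L,
                 dimnames = list(classes, c(classes, "unmatched")))
  for (i in seq_len(nrow(ref))) {
    ors <- vapply(seq_len(nrow(test)), function(j)
      overlap_ratio_idx(ref$start[i], ref$end[i], test$start[j], test$end[j]), 1)
    if (length(ors) && max(ors) > 0) {
      j <- which(ors == max(ors))
      if (length(j) > 1) j <- j[which.min(test$start[j])]
      conf[ref$cls[i], test$cls[j]] <- conf[ref$cls[i], test$cls[j]] + 1L
    } else {
      conf[ref$cls[i], "unmatched"] <- conf[ref$cls[i], "unmatched"] + 1L
    }
  }
  sq <- rbind(conf, unmatched = 0L)       # square it for the kappa marginals
  k <- suppressWarnings(cohen_kappa(sq))
  per_class <- vapply(classes, function(cl) class_kappa(sq, cl), 1)
  list(confusion = conf, kappa = k, per_class = per_class)
}

#' Event error rate
#'
#' Length-normalized Levenshtein distance between the class strings of two
#' event lists: the edit distance divided by the reference string length.
#' Purely symbolic -- no matching, no timing.
#'
#' @param ref,test `event_list`s.
#' @return non-negative error rate.
#' @export
event_error_rate <- function(ref, test) {
  if (nrow(ref) == 0) stop("empty reference event list")
  code <- c(FIX = "F", PUR = "P", SAC = "S")
  a <- paste(code[ref$cls], collapse = "")
  b <- paste(code[test$cls], collapse = "")
  as.integer(adist(a, b)) / nchar(a)
}
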