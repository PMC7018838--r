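# Leave-one-subject-out evaluation and input ablations for the two
# classifier families.

#' Select classifier input channels from a velocity trace
#'
#' `full` = all six channels; `eyes_only` = the three eye channels (no head
#' information); `absolute_only` = the two unsigned magnitudes (no
#' directional information, no eye/head coordinate alignment required).
#'
#' @param vel a [velocity_trace].
#' @param mode `"full"`, `"eyes_only"` or `"absolute_only"`.
#' @return numeric matrix (samples x channels).
#' @export
vel_channels <- function(vel, mode = c("full", "eyes_only", "absolute_only")) {
  mode <- match.arg(mode)
  switch(mode,
    full = cbind(we = vel$we, wh = vel$wh, we_az = vel$we_az,
                 wh_az = vel$wh_az, we_el = vel$we_el, wh_el = vel$wh_el),
    eyes_only = cbind(we = vel$we, we_az = vel$we_az, we_el = vel$we_el),
    absolute_only = cbind(we = vel$we, wh = vel$wh))
}

# assign whole events to n_folds folds, balancing FIX and SAC event counts
# (round-robin within a shuffled class) and distributing pursuit events
# whole; returns a per-sample fold index (0 = unassigned / NONE)
build_folds <- function(labels_list, n_folds = 5, seed = 1L) {
  set.seed(seed)
  ev_all <- list()
  for (s in seq_along(labels_list)) {
    ev <- labels_to_events(labels_list[[s]])
    if (nrow(ev)) {
      ev <- as.data.frame(ev)
      ev$subj <- s
      ev_all[[length(ev_all) + 1L]] <- ev[, c("cls", "start", "end", "subj")]
    }
  }
  ev_all <- do.call(rbind, ev_all)
  ev_all$fold <- 0L
  for (cl in c("FIX", "SAC", "PUR")) {
    rows <- which(ev_all$cls == cl)
    rows <- sample(rows)
    ev_all$fold[rows] <- rep(seq_len(n_folds), length.out = length(rows))
  }
  fold_idx <- lapply(labels_list, function(l) integer(length(l)))
  for (i in seq_len(nrow(ev_all))) {
    s <- ev_all$subj[i]
    fold_idx[[s]][ev_all$start[i]:(ev_all$end[i] - 1L)] <- ev_all$fold[i]
  }
  list(per_sample = fold_idx, events = ev_all)
}

sample_kappa <- function(ref, test) {
  cm <- sample_confusion(ref, test)
  if (attr(cm, "total") == 0) return(NA_real_)
  suppressWarnings(cohen_kappa(cm))
}

fit_fold_rf <- function(feat_list, labels_list, train_sel, window_s, seed) {
  X <- do.call(rbind, lapply(seq_along(feat_list), function(s)
    feat_list[[s]]$X[train_sel[[s]], , drop = FALSE]))
  y <- unlist(lapply(seq_along(labels_list), function(s)
    as_label_chr(labels_list[[s]])[train_sel[[s]]]))
  w <- unlist(lapply(seq_along(feat_list), function(s)
    feat_list[[s]]$weights[train_sel[[s]]]))
  gaze_rf(X, y, seed = seed)
}

#' Leave-one-subject-out cross-validation
#'
#' For each holdout subject, the remaining subjects' events are split into
#' five folds with balanced fixation and saccade event counts (pursuit
#' events assigned whole); five models are trained, each on four folds
#' (for the GRU models the held-in folds define the loss support on the
#' otherwise intact sequences), the best model on its validation fold is
#' kept and evaluated on the holdout subject. Classifier output is never
#' scored on `NONE` or low-confidence samples.
#'
#' @param data cohort list as produced by [generate_cohort]: per subject a
#'   list with `vel`, `labels`, `subject`.
#' @param model `"rf"`, `"frnn"` or `"birnn"`.
#' @param channels input-channel mode, see [vel_channels].
#' @param window_ms feature window for the forest, ms.
#' @param epochs,batch_size GRU training parameters.
#' @param n_folds inner folds.
#' @param seed base RNG seed.
#' @param elc also compute single-direction ELC metrics per holdout.
#' @return object of class `loso_result`: per-subject metrics and pooled
#'   summaries.
#' @export
crossvalidate_loso <- function(data, model = c("rf", "frnn", "birnn"),
                               channels = "full", window_ms = 100,
                               epochs = 30, batch_size = 4, n_folds = 5,
                               seed = 1L, elc = TRUE) {
  model <- match.arg(model)
  S <- length(data)
  if (S < 2) stop("need at least two subjects")
  has_labels <- vapply(data, function(d) !is.null(d$labels), TRUE)
  if (any(!has_labels)) {
    message("skipping subject(s) without labels: ",
            paste(which(!has_labels), collapse = ", "))
    data <- data[has_labels]
    S <- length(data)
  }
  fs <- data[[1]]$vel$fs
  if (model == "rf") {
    s_half <- max(1L, round(window_ms / 1000 * fs / 2))
    feats <- lapply(data, function(d) {
      f <- extract_window_features(d$vel, s_half)
      attr(f, "fs") <- d$vel$fs
      f
    })
  } else {
    xmats <- lapply(data, function(d) vel_channels(d$vel, channels))
  }
  per_subject <- list()
  for (hold in seq_len(S)) {
    train_ids <- setdiff(seq_len(S), hold)
    folds <- build_folds(lapply(data[train_ids], `[[`, "labels"),
                         n_folds = n_folds, seed = seed + hold)
    best <- NULL; best_kappa <- -Inf
    for (v in seq_len(n_folds)) {
      if (model == "rf") {
        train_sel <- lapply(seq_along(train_ids), function(si) {
          d <- data[[train_ids[si]]]
          folds$per_sample[[si]] != v & folds$per_sample[[si]] != 0L &
            d$vel$mask & as_label_chr(d$labels) != "NONE"
        })
        fit <- fit_fold_rf(feats[train_ids],
                           lapply(data[train_ids], `[[`, "labels"),
                           train_sel, s_half, seed + 100 * hold + v)
        # pooled validation kappa over the held-in subjects' fold-v samples
        val_sel <- lapply(seq_along(train_ids), function(si) {
          d <- data[[train_ids[si]]]
          folds$per_sample[[si]] == v & d$vel$mask &
            as_label_chr(d$labels) != "NONE"
        })
        Xv <- do.call(rbind, lapply(seq_along(train_ids), function(si)
          feats[[train_ids[si]]]$X[val_sel[[si]], , drop = FALSE]))
        yv <- unlist(lapply(seq_along(train_ids), function(si)
          as_label_chr(data[[train_ids[si]]]$labels)[val_sel[[si]]]))
        pv <- as.character(predict(fit$forest, data = Xv,
                                   num.threads = 1L)$predictions)
        cmv <- table(factor(yv, levels = GAZE_CLASSES),
                     factor(pv, levels = GAZE_CLASSES))
        val_kap <- suppressWarnings(cohen_kappa(cmv))
      } else {
        wts <- lapply(seq_along(train_ids), function(si) {
          d <- data[[train_ids[si]]]
          w <- d$vel$conf
          w[folds$per_sample[[si]] == v | folds$per_sample[[si]] == 0L |
              !d$vel$mask] <- 0
          w
        })
        fit <- gaze_rnn(xmats[train_ids],
                        lapply(data[train_ids], function(d) as_label_chr(d$labels)),
                        variant = if (model == "birnn") "bidirectional" else "forward",
                        weights = wts, epochs = epochs, batch_size = batch_size,
                        seed = seed + 100 * hold + v)
        val_kap <- mean(vapply(seq_along(train_ids), function(si) {
          d <- data[[train_ids[si]]]
          pred <- predict(fit, xmats[[train_ids[si]]], mask = d$vel$mask, fs = fs)
          sel <- folds$per_sample[[si]] == v
          ref <- as_label_chr(d$labels); ref[!sel] <- "NONE"
          sample_kappa(label_sequence(ref, fs), pred)
        }, 1), na.rm = TRUE)
      }
      if (!is.na(val_kap) && val_kap > best_kappa) {
        best_kappa <- val_kap; best <- fit
      }
    }
    d <- data[[hold]]
    if (model == "rf") {
      pred <- predict(best, feats[[hold]])
    } else {
      pred <- predict(best, xmats[[hold]], mask = d$vel$mask, fs = fs)
    }
    cm <- sample_confusion(d$labels, pred)
    res <- list(subject = d$subject, val_kappa = best_kappa,
                kappa = suppressWarnings(cohen_kappa(cm)),
                per_class_kappa = vapply(GAZE_CLASSES, function(cl)
                  class_kappa(cm, cl), 1),
                confusion = cm)
    if (elc) {
      ref_sc <- as_label_chr(d$labels)
      ref_sc[!d$vel$mask] <- "NONE"
      res$elc <- elc_evaluate(label_sequence(ref_sc, fs), pred)
    }
    per_subject[[d$subject]] <- res
  }
  kap <- vapply(per_subject, `[[`, 1, "kappa")
  pk <- do.call(rbind, lapply(per_subject, `[[`, "per_class_kappa"))
  structure(list(per_subject = per_subject, model = model, channels = channels,
                 kappa_mean = mean(kap, na.rm = TRUE),
                 kappa_sd = sd(kap),
                 per_class_kappa_mean = colMeans(pk, na.rm = TRUE)),
            class = "loso_result")
}

#' @export
print.loso_result <- function(x, ...) {
  cat(sprintf("LOSO (%s, %s channels): %d subjects\n",
              x$model, x$channels, length(x$per_subject)))
  cat(sprintf("  overall sample kappa %.3f +- %.3f\n", x$kappa_mean, x$kappa_sd))
  pc <- x$per_class_kappa_mean
  cat(sprintf("  per-class kappa: FIX %.3f  PUR %.3f  SAC %.3f\n",
              pc["FIX"], pc["PUR"], pc["SAC"]))
  invisible(x)
}

#' Input-channel ablation study
#'
#' Retrains the same classifier with reduced input (`eyes_only`: no head
#' stream; `absolute_only`: unsigned magnitudes only, i.e. no directional
#' information and no eye/head alignment) on a fixed train/test split and
#' reports per-class sample kappa side by side. The expected pattern on
#' head-rich data: removing head information hurts pursuit markedly while
#' fixation/saccade detection survives; absolute-only retains most overall
#' performance.
#'
#' @param data cohort list (see [crossvalidate_loso]).
#' @param modes character vector of channel modes to compare.
#' @param model `"birnn"`, `"frnn"` or `"rf"`.
#' @param test_subjects indices held out for testing; default the last
#'   subject.
#' @param epochs,seed training parameters.
#' @return data frame of per-mode overall and per-class kappa.
#' @export
ablate <- function(data, modes = c("full", "eyes_only", "absolute_only"),
                   model = "birnn", test_subjects = length(data),
                   epochs = 30, seed = 1L) {
  train_ids <- setdiff(seq_along(data), test_subjects)
  fs <- data[[1]]$vel$fs
  out <- list()
  for (mode in modes) {
    if (model == "rf") {
      stop("ablation is defined on the GRU classifiers' channel input")
    }
    xm <- lapply(data, function(d) vel_channels(d$vel, mode))
    wts <- lapply(data[train_ids], function(d) {
      w <- d$vel$conf
      w[!d$vel$mask] <- 0
      w
    })
    fit <- gaze_rnn(xm[train_ids],
                    lapply(data[train_ids], function(d) as_label_chr(d$labels)),
                    variant = if (model == "birnn") "bidirectional" else "forward",
                    weights = wts, epochs = epochs, seed = seed)
    kaps <- vapply(test_subjects, function(ts) {
      d <- data[[ts]]
      pred <- predict(fit, xm[[ts]], mask = d$vel$mask, fs = fs)
      cm <- sample_confusion(d$labels, pred)
      c(suppressWarnings(cohen_kappa(cm)),
        vapply(GAZE_CLASSES, function(cl) class_kappa(cm, cl), 1))
    }, numeric(4))
    km <- rowMeans(kaps, na.rm = TRUE)
    out[[mode]] <- data.frame(mode = mode, kappa = km[1],
                              kappa_fix = km[2], kappa_pur = km[3],
                              kappa_sac = km[4])
  }
  do.call(rbind, out)
}
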