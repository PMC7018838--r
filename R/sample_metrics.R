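#' Sample-level confusion matrix
#'
#' Counts over the three scored classes (`FIX`, `PUR`, `SAC`). A sample is
#' scored only when neither sequence marks it `NONE` -- blinks and
#' unlabelled spans never enter any metric.
#'
#' @param ref,test [label_sequence]s of equal length; `ref` indexes rows.
#' @return `sample_confusion`: 3 x 3 integer matrix with attributes `total`
#'   (jointly scored samples) and `normalized` (row-normalized view).
#' @export
sample_confusion <- function(ref, test) {
  if (length(ref) != length(test))
    stop("sequences differ in length: ", length(ref), " vs ", length(test))
  r <- as_label_chr(ref); s <- as_label_chr(test)
  ok <- r != "NONE" & s != "NONE"
  m <- table(factor(r[ok], levels = GAZE_CLASSES),
             factor(s[ok], levels = GAZE_CLASSES))
  m <- unclass(m)
  rs <- rowSums(m)
  norm <- sweep(m, 1, ifelse(rs > 0, rs, 1), "/")
  structure(m, total = sum(ok), normalized = norm,
            class = c("sample_confusion", "matrix"))
}

#' @export
print.sample_confusion <- function(x, ...) {
  cat("sample_confusion (", attr(x, "total"), " jointly scored samples)\n", sep = "")
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)`, the expected
#' agreement `p_e` computed from the row and column marginals. When chance
#' agreement is total (`p_e = 1`) the statistic is defined as 1 for perfect
#' observed agreement and 0 otherwise, with a warning.
#'
#' @param conf square count matrix (e.g. a [sample_confusion]).
#' @return kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(conf) {
  m <- unclass(as.matrix(conf))
  total <- sum(m)
  if (total <= 0) stop("empty confusion matrix")
  po <- sum(diag(m)) / total
  pe <- sum(rowSums(m) * colSums(m)) / total^2
  if (abs(1 - pe) < 1e-12) {
    warning("chance agreement is 1; kappa degenerate")
    return(if (abs(1 - po) < 1e-12) 1 else 0)
  }
  (po - pe) / (1 - pe)
}

#' Precision, recall and F1 for one class
#'
#' One-vs-rest on a confusion matrix whose rows are the reference: precision
#' is the fraction of retrieved (column) samples that are correct, recall
#' the fraction of relevant (row) samples retrieved, F1 their harmonic
#' mean. Zero denominators yield 0 with a warning.
#'
#' @param conf square count matrix with named rows/columns.
#' @param cls class name.
#' @return named numeric vector `c(precision, recall, f1)`.
#' @export
precision_recall_f1 <- function(conf, cls) {
  m <- unclass(as.matrix(conf))
  if (!cls %in% rownames(m)) stop("class not in matrix: ", cls)
  tp <- m[cls, cls]
  retrieved <- sum(m[, cls])
  relevant <- sum(m[cls, ])
  p <- if (retrieved > 0) tp / retrieved else { warning("no retrieved samples for ", cls); 0 }
  r <- if (relevant > 0) tp / relevant else { warning("no relevant samples for ", cls); 0 }
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1)
}

#' Labeller-versus-group agreement
#'
#' Scores each labeller against the rest of the group as the mean of
#' pairwise comparisons (both orientations averaged), then averages over
#' labellers. Averaging the two orientations of each pair makes the
#' reported precision and recall identical by construction, the signature
#' property of this scheme.
#'
#' @param seqs list of two or more [label_sequence]s of equal length.
#' @return list with `overall` (mean/sd of kappa, p, r, f1 over labellers)
#'   and `per_class` (the same per scored class).
#' @export
labeller_vs_group <- function(seqs) {
  if (length(seqs) < 2) stop("need at least two label sequences")
  n <- unique(vapply(seqs, length, 1L))
  if (length(n) != 1) stop("label sequences differ in length")
  L <- length(seqs)
  per_lab <- vector("list", L)
  for (i in seq_len(L)) {
    rows <- list()
    for (j in setdiff(seq_len(L), i)) {
      cij <- sample_confusion(seqs[[i]], seqs[[j]])
      cji <- sample_confusion(seqs[[j]], seqs[[i]])
      k <- (cohen_kappa(cij) + cohen_kappa(cji)) / 2
      cls_rows <- lapply(GAZE_CLASSES, function(cl) {
        a <- precision_recall_f1(cij, cl)
        b <- precision_recall_f1(cji, cl)
        (a + b) / 2
      })
      names(cls_rows) <- GAZE_CLASSES
      ko <- vapply(GAZE_CLASSES, function(cl) {
        (class_kappa(cij, cl) + class_kappa(cji, cl)) / 2
      }, 1)
      rows[[length(rows) + 1L]] <- list(kappa = k, cls = cls_rows, cls_kappa = ko)
    }
    per_lab[[i]] <- list(
      kappa = mean(vapply(rows, `[[`, 1, "kappa")),
      cls = lapply(GAZE_CLASSES, function(cl)
        Reduce(`+`, lapply(rows, function(r) r$cls[[cl]])) / length(rows)),
      cls_kappa = Reduce(`+`, lapply(rows, `[[`, "cls_kappa")) / length(rows))
    names(per_lab[[i]]$cls) <- GAZE_CLASSES
  }
  kap <- vapply(per_lab, `[[`, 1, "kappa")
  overall <- data.frame(
    metric = c("kappa", "precision", "recall", "f1"),
    mean = c(mean(kap),
             mean(vapply(per_lab, function(x) mean(vapply(x$cls, `[`, 1, "precision")), 1)),
             mean(vapply(per_lab, function(x) mean(vapply(x$cls, `[`, 1, "recall")), 1)),
             mean(vapply(per_lab, function(x) mean(vapply(x$cls, `[`, 1, "f1")), 1))),
    sd = c(sd(kap),
           sd(vapply(per_lab, function(x) mean(vapply(x$cls, `[`, 1, "precision")), 1)),
           sd(vapply(per_lab, function(x) mean(vapply(x$cls, `[`, 1, "recall")), 1)),
           sd(vapply(per_lab, function(x) mean(vapply(x$cls, `[`, 1, "f1")), 1))))
  per_class <- do.call(rbind, lapply(GAZE_CLASSES, function(cl) {
    pk <- vapply(per_lab, function(x) x$cls_kappa[[cl]], 1)
    pp <- vapply(per_lab, function(x) x$cls[[cl]][["precision"]], 1)
    rr <- vapply(per_lab, function(x) x$cls[[cl]][["recall"]], 1)
    ff <- vapply(per_lab, function(x) x$cls[[cl]][["f1"]], 1)
    data.frame(class = cl,
               kappa_mean = mean(pk), kappa_sd = sd(pk),
               precision_mean = mean(pp), precision_sd = sd(pp),
               recall_mean = mean(rr), recall_sd = sd(rr),
               f1_mean = mean(ff), f1_sd = sd(ff))
  }))
  list(overall = overall, per_class = per_class, n_labellers = L)
}

# per-class kappa: collapse to a 2x2 one-vs-rest table
class_kappa <- function(conf, cls) {
  m <- unclass(as.matrix(conf))
  others_r <- setdiff(rownames(m), cls)
  others_c <- setdiff(colnames(m), cls)
  b <- matrix(c(m[cls, cls], sum(m[cls, others_c]),
                sum(m[others_r, cls]), sum(m[others_r, others_c])),
              2, 2, byrow = TRUE)
  if (sum(b) == 0) return(NA_real_)
  suppressWarnings(cohen_kappa(b))
}
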