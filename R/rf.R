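#' Random Forest gaze-event classifier
#'
#' Fits a sample-weighted random forest on windowed velocity features over
#' the three scored classes. Defaults follow the reference configuration:
#' 40 trees, minimum leaf size 30, `floor(sqrt(g))` candidate features per
#' split. Training rows labelled `NONE` or masked by confidence are
#' excluded; duplicate rows (equal to two decimals, same label) are
#' collapsed and upweighted.
#'
#' @param features a [window_features] object (or plain feature matrix).
#' @param labels a [label_sequence] (or character vector) aligned with the
#'   feature rows.
#' @param n_trees,min_leaf forest size and minimum node size.
#' @param mtry candidate features per split; default `floor(sqrt(g))`.
#' @param seed RNG seed for the forest bootstrap.
#' @param collapse collapse duplicate training rows (on by default).
#' @return object of class `gaze_rf`.
#' @export
gaze_rf <- function(features, labels, n_trees = 40, min_leaf = 30,
                    mtry = NULL, seed = 1L, collapse = TRUE) {
  if (inherits(features, "window_features")) {
    X <- features$X
    w <- features$weights
    keep <- features$mask
  } else {
    X <- as.matrix(features)
    w <- rep(1, nrow(X))
    keep <- rep(TRUE, nrow(X))
  }
  y <- as.character(labels)
  if (length(y) != nrow(X)) stop("labels do not align with features")
  keep <- keep & y != "NONE"
  X <- X[keep, , drop = FALSE]; y <- y[keep]; w <- w[keep]
  present <- sort(unique(y))
  if (!all(GAZE_CLASSES %in% present))
    warning("training data lacks class(es): ",
            paste(setdiff(GAZE_CLASSES, present), collapse = ", "),
            "; they can never be predicted")
  if (any(table(y) < min_leaf))
    warning("fewer than min_leaf samples in some class")
  if (collapse) {
    dd <- collapse_duplicates(X, y, w)
    X <- dd$X; y <- dd$y; w <- dd$weights
  }
  if (is.null(colnames(X)))
    colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  fit <- ranger::ranger(x = X, y = factor(y, levels = GAZE_CLASSES),
                        num.trees = n_trees, min.node.size = min_leaf,
                        mtry = mtry, case.weights = w, seed = seed,
                        num.threads = 1L, classification = TRUE)
  structure(list(forest = fit, n_trees = n_trees, min_leaf = min_leaf,
                 mtry = mtry, seed = seed, g = ncol(X),
                 n_train = nrow(X)),
            class = "gaze_rf")
}

#' @export
print.gaze_rf <- function(x, ...) {
  cat(sprintf("gaze_rf: %d trees, min leaf %d, mtry %d, g = %d (%d training rows)\n",
              x$n_trees, x$min_leaf, x$mtry, x$g, x$n_train))
  cat(sprintf("  OOB error: %.3f\n", x$forest$prediction.error))
  invisible(x)
}

#' Predict gaze events with a fitted forest
#'
#' Masked samples (low confidence) are passed through unscored as `NONE`.
#'
#' @param object a [gaze_rf] model.
#' @param features a [window_features] object or feature matrix.
#' @param ... unused.
#' @return a [label_sequence] (fs taken from `fs` attribute when available,
#'   else `NA`).
#' @export
predict.gaze_rf <- function(object, features, ...) {
  if (inherits(features, "window_features")) {
    X <- features$X
    mask <- features$mask
  } else {
    X <- as.matrix(features)
    mask <- rep(TRUE, nrow(X))
  }
  out <- rep("NONE", nrow(X))
  if (is.null(colnames(X)))
    colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (any(mask)) {
    pr <- predict(object$forest, data = X[mask, , drop = FALSE],
                  num.threads = 1L)
    out[mask] <- as.character(pr$predictions)
  }
  fs <- attr(features, "fs")
  label_sequence(out, fs = if (is.null(fs)) NA_real_ else fs,
                 source_id = "gaze_rf")
}
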