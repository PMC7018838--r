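#' Generalized Dice loss
#'
#' `1 - 2 * sum_c wc sum_n p*g / sum_c wc sum_n (p+g)` with class weights
#' `wc = 1/(sum_n g)^2`; classes absent from the targets get zero weight.
#' Zero for exact one-hot predictions, invariant to permuting the classes.
#'
#' @param probs n x C matrix of class probabilities (rows sum to 1).
#' @param targets n x C one-hot matrix (or class-index vector).
#' @return scalar loss in `[0, 1]`.
#' @export
generalized_dice_loss <- function(probs, targets) {
  probs <- as.matrix(probs)
  if (is.null(dim(targets)) || ncol(as.matrix(targets)) == 1) {
    ti <- as.integer(targets)
    targets <- matrix(0, length(ti), ncol(probs))
    targets[cbind(seq_along(ti), ti)] <- 1
  }
  targets <- as.matrix(targets)
  if (any(abs(rowSums(probs) - 1) > 1e-6))
    stop("probability rows must sum to 1")
  gs <- colSums(targets)
  wc <- ifelse(gs > 0, 1 / gs^2, 0)
  num <- sum(wc * colSums(probs * targets))
  den <- sum(wc * colSums(probs + targets))
  if (den <= 0) return(0)
  1 - 2 * num / den
}

rnn_widths <- function(d_in, k, h, fc_width = 32) {
  list(fc = c(d_in, rep(fc_width, k)), h = h)
}

# He-style initialization; GRU recurrent matrices orthogonal-ish via QR
rnn_init_params <- function(d_in, k = 3, h = 24, bidir = TRUE, fc_width = 32) {
  p <- list()
  widths <- c(d_in, rep(fc_width, k))
  for (l in seq_len(k)) {
    p[[paste0("fc_W", l)]] <- matrix(rnorm(widths[l + 1] * widths[l],
                                           sd = sqrt(2 / widths[l])),
                                     widths[l + 1], widths[l])
    p[[paste0("fc_b", l)]] <- numeric(widths[l + 1])
  }
  dirs <- if (bidir) c("f", "b") else "f"
  for (l in seq_len(k)) {
    in_l <- if (l == 1) fc_width else h * length(dirs)
    for (d in dirs) {
      pre <- paste0("gru", l, "_", d, "_")
      p[[paste0(pre, "Wx")]] <- matrix(rnorm(3 * h * in_l, sd = sqrt(1 / in_l)),
                                       3 * h, in_l)
      q <- qr.Q(qr(matrix(rnorm(h * h), h, h)))
      p[[paste0(pre, "Wh")]] <- rbind(qr.Q(qr(matrix(rnorm(h * h), h, h))),
                                      qr.Q(qr(matrix(rnorm(h * h), h, h))), q)
      p[[paste0(pre, "bx")]] <- numeric(3 * h)
      p[[paste0(pre, "bh")]] <- numeric(3 * h)
    }
  }
  hd <- h * length(dirs)
  p[["out_W"]] <- matrix(rnorm(3 * hd, sd = sqrt(1 / hd)), 3, hd)
  p[["out_b"]] <- numeric(3)
  p
}

adam_state_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       t = 0L)
}

adam_update <- function(params, grads, state, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gmat <- grads[[nm]]
    if (is.null(gmat)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gmat
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gmat^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# stack a list of T_i x d matrices into a (d x B x L) array, zero padded;
# returns the array plus per-sequence lengths
stack_sequences <- function(xs) {
  d <- ncol(xs[[1]])
  B <- length(xs)
  L <- max(vapply(xs, nrow, 1L))
  arr <- array(0, dim = c(d, B, L))
  for (b in seq_len(B)) {
    Tb <- nrow(xs[[b]])
    arr[, b, seq_len(Tb)] <- t(xs[[b]])
  }
  list(arr = arr, lengths = vapply(xs, nrow, 1L), d = d, B = B, L = L)
}

# flatten per-sequence label/weight lists to the b + B*(t-1) column order
flatten_targets <- function(ys, ws, B, L) {
  y <- rep(-1L, B * L)
  w <- rep(0, B * L)
  for (b in seq_len(B)) {
    Tb <- length(ys[[b]])
    idx <- b + B * (seq_len(Tb) - 1L)
    y[idx] <- ys[[b]]
    w[idx] <- ws[[b]]
  }
  list(y = y, w = w)
}

#' GRU gaze-event sequence classifier
#'
#' Trains a stacked GRU network on per-sample 6-channel velocity input:
#' `k` fully connected ReLU feature-extraction layers (width 32), a stack
#' of `k` GRU layers (24 units per direction, so the bidirectional variant
#' feeds a 48-dimensional representation to the 3-class output layer; the
#' forward variant feeds 24), 10% dropout, and a combined cross-entropy +
#' generalized Dice loss optimized with Adam under a linearly decaying
#' learning rate. The forward variant (`"forward"`) sees only past and
#' present samples -- suitable for real-time use; the bidirectional variant
#' uses the full sequence. Sequences in a batch are zero-padded to the
#' longest; padded, `NONE`-labelled and masked samples carry zero loss
#' weight. Channels are standardized by training-set statistics.
#'
#' @param x list of per-sequence input matrices (samples x channels).
#' @param y list of per-sequence label vectors (characters over the gaze
#'   alphabet), aligned with `x`.
#' @param variant `"bidirectional"` or `"forward"`.
#' @param weights optional list of per-sample loss weights (e.g. tracker
#'   confidence, or zero to hold samples out of the loss).
#' @param k number of FC layers and of GRU layers.
#' @param hidden GRU units per direction.
#' @param epochs training epochs.
#' @param lr,lr_end Adam learning rate, decayed linearly from `lr` to
#'   `lr_end` over the epochs.
#' @param dropout dropout probability (0 disables).
#' @param lambda_dice weight of the Dice term in the loss.
#' @param batch_size sequences per gradient step.
#' @param seed RNG seed (initialization, shuffling, dropout).
#' @param verbose print per-epoch loss every 25 epochs.
#' @return object of class `gaze_rnn`.
#' @export
gaze_rnn <- function(x, y, variant = c("bidirectional", "forward"),
                     weights = NULL, k = 3, hidden = 24, epochs = 175,
                     lr = 1e-3, lr_end = 1e-4, dropout = 0.10,
                     lambda_dice = 1, batch_size = 4, seed = 1L,
                     verbose = FALSE) {
  variant <- match.arg(variant)
  bidir <- variant == "bidirectional"
  if (length(x) != length(y)) stop("x and y differ in length")
  x <- lapply(x, as.matrix)
  if (is.null(weights)) weights <- lapply(x, function(m) rep(1, nrow(m)))
  d <- ncol(x[[1]])
  # channel standardization from the training pool
  pool <- do.call(rbind, x)
  mu <- colMeans(pool); sg <- apply(pool, 2, sd)
  sg[sg < 1e-8] <- 1
  xs <- lapply(x, function(m) sweep(sweep(m, 2, mu), 2, sg, "/"))
   yi <- lapply(seq_along(y), function(i) {
    lab <- as.character(y[[i]])
    if (length(lab) != nrow(x[[i]])) stop("labels misaligned in sequence ", i)
    cl <- match(lab, GAZE_CLASSES) - 1L
    cl[is.na(cl)] <- -1L                       # NONE / unknown: unscored
    cl
  })
  wl <- lapply(seq_along(weights), function(i) {
    w <- weights[[i]]
    w[yi[[i]] < 0] <- 0
    w
  })
  set.seed(seed)
  params <- rnn_init_params(d, k = k, h = hidden, bidir = bidir)
  st <- adam_state_init(params)
  B_all <- length(xs)
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    lr_ep <- lr + (lr_end - lr) * (ep - 1) / max(1, epochs - 1)
    ord <- sample(B_all)
    ep_loss <- 0; nb <- 0
    for (start in seq(1, B_all, by = batch_size)) {
      sel <- ord[start:min(B_all, start + batch_size - 1)]
      sx <- stack_sequences(xs[sel])
      tg <- flatten_targets(yi[sel], wl[sel], sx$B, sx$L)
      res <- rnn_grad_cpp(params, sx$arr, tg$y, tg$w, k, hidden, bidir,
                          dropout, TRUE, lambda_dice)
      upd <- adam_update(params, res$grads, st, lr_ep)
      params <- upd$params; st <- upd$state
      ep_loss <- ep_loss + res$loss; nb <- nb + 1
    }
    history[ep] <- ep_loss / nb
    if (verbose && (ep %% 25 == 0 || ep == 1))
      message(sprintf("epoch %d: loss %.4f (lr %.2g)", ep, history[ep], lr_ep))
  }
  structure(list(params = params, k = k, hidden = hidden, bidir = bidir,
                 variant = variant, d = d, mu = mu, sigma = sg,
                 lambda_dice = lambda_dice, epochs = epochs, seed = seed,
                 history = history),
            class = "gaze_rnn")
}

#' @export
print.gaze_rnn <- function(x, ...) {
  cat(sprintf("gaze_rnn (%s): k = %d, %d units/direction, %d input channels\n",
              x$variant, x$k, x$hidden, x$d))
  cat(sprintf("  trained %d epochs, final loss %.4f\n",
              x$epochs, tail(x$history, 1)))
  invisible(x)
}

#' Predict per-sample gaze events with a trained GRU model
#'
#' @param object a [gaze_rnn] model.
#' @param x a single input matrix or a list of them.
#' @param mask optional logical vector/list; `FALSE` samples are returned
#'   as `NONE` unscored.
#' @param fs sampling rate recorded on the returned sequences.
#' @param probs return class probability matrices instead of labels.
#' @param ... unused.
#' @return a [label_sequence] (or list of them); with `probs = TRUE`,
#'   per-sequence n x 3 probability matrices.
#' @export
predict.gaze_rnn <- function(object, x, mask = NULL, fs = NA_real_,
                             probs = FALSE, ...) {
  single <- is.matrix(x) || is.data.frame(x)
  if (single) x <- list(as.matrix(x))
  if (!is.null(mask) && !is.list(mask)) mask <- list(mask)
  out <- vector("list", length(x))
  for (i in seq_along(x)) {
    m <- sweep(sweep(as.matrix(x[[i]]), 2, object$mu), 2, object$sigma, "/")
    arr <- array(t(m), dim = c(ncol(m), 1, nrow(m)))
    p <- rnn_predict_cpp(object$params, arr, object$k, object$hidden,
                         object$bidir)
    p <- t(p)                                  # n x 3
    colnames(p) <- GAZE_CLASSES
    if (probs) { out[[i]] <- p; next }
    lab <- GAZE_CLASSES[max.col(p, ties.method = "first")]
    if (!is.null(mask)) lab[!mask[[i]]] <- "NONE"
    out[[i]] <- label_sequence(lab, fs = fs, source_id = paste0("gaze_rnn_", object$variant))
  }
  if (single) out[[1]] else out
}
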