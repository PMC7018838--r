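#' Windowed feature extraction for the moving-window classifier
#'
#' For each sample n, aggregates the six velocity channels over the window
#' `n-s ... n+s` and appends four summary features: the angular distance in
#' degrees between the mean eye-in-head (and head-forward) vector of the s
#' samples before versus after n (`dtheta_e`, `dtheta_h`), and the standard
#' deviation of the absolute eye/head velocity within the window
#' (`sigma_e`, `sigma_h`). Feature dimension is `g = 6(2s+1) + 4` (the six
#' aggregated channels plus the four summaries). Boundary windows are
#' truncated, not padded. Tracker confidence is carried as a per-sample
#' weight, not as a feature.
#'
#' @param vel a [velocity_trace] produced by [velocity_pipeline] (direction
#'   vectors attached).
#' @param s window half-size in samples (>= 1).
#' @return object of class `window_features`: list with matrix `X`
#'   (n x g), `weights`, `mask`, `s`.
#' @export
extract_window_features <- function(vel, s) {
  stopifnot(inherits(vel, "velocity_trace"))
  if (s < 1) stop("s must be >= 1")
  n <- length(vel$timestamps)
  if (n <= 2 * s + 1) stop("trace shorter than the feature window")
  chans <- cbind(we = vel$we, wh = vel$wh, we_az = vel$we_az, wh_az = vel$wh_az,
                 we_el = vel$we_el, wh_el = vel$wh_el)
  w <- 2L * s + 1L
  g <- 6L * w + 4L
  X <- matrix(0, n, g)
  offs <- -s:s
  for (k in seq_along(offs)) {
    src <- pmin(pmax(seq_len(n) + offs[k], 1L), n)   # truncated = clamped
    X[, (k - 1L) * 6L + 1:6] <- chans[src, ]
  }
  eih <- vel$eih
  fwd <- vel$head_forward
  if (is.null(eih) || is.null(fwd))
    stop("velocity trace lacks direction vectors; run velocity_pipeline")
  X[, 6L * w + 1L] <- mean_vector_angle(eih, s)
  X[, 6L * w + 2L] <- mean_vector_angle(fwd, s)
  X[, 6L * w + 3L] <- running_sd(vel$we, s)
  X[, 6L * w + 4L] <- running_sd(vel$wh, s)
  colnames(X) <- c(paste0(rep(colnames(chans), w), "_",
                          rep(offs, each = 6)),
                   "dtheta_e", "dtheta_h", "sigma_e", "sigma_h")
  structure(list(X = X, weights = vel$conf, mask = vel$mask, s = s, g = g),
            class = "window_features")
}

# angle (deg) between the mean of the s vectors before and after each sample
mean_vector_angle <- function(v, s) {
  n <- nrow(v)
  cs <- apply(rbind(0, v), 2, cumsum)    # cs[i+1,] = sum of rows 1..i
  out <- numeric(n)
  for (i in seq_len(n)) {
    b0 <- max(1L, i - s); b1 <- i - 1L
    a0 <- i + 1L; a1 <- min(n, i + s)
    if (b1 < b0 || a1 < a0) { out[i] <- 0; next }
    mb <- (cs[b1 + 1L, ] - cs[b0, ]) / (b1 - b0 + 1L)
    ma <- (cs[a1 + 1L, ] - cs[a0, ]) / (a1 - a0 + 1L)
    nb <- sqrt(sum(mb^2)); na_ <- sqrt(sum(ma^2))
    if (nb < 1e-12 || na_ < 1e-12) { out[i] <- 0; next }
    out[i] <- acos(pmin(1, pmax(-1, sum(mb * ma) / (nb * na_)))) * 180 / pi
  }
  out
}

running_sd <- function(x, s) {
  n <- length(x)
  c1 <- cumsum(c(0, x)); c2 <- cumsum(c(0, x^2))
  out <- numeric(n)
  for (i in seq_len(n)) {
    a <- max(1L, i - s); b <- min(n, i + s)
    m <- b - a + 1L
    mu <- (c1[b + 1L] - c1[a]) / m
    v <- (c2[b + 1L] - c2[a]) / m - mu^2
    out[i] <- sqrt(max(0, v))
  }
  out
}

#' Collapse duplicate feature rows (training only)
#'
#' Rows identical after rounding to two decimals and sharing a label are
#' merged into a single row whose weight is the sum of the duplicates'
#' weights. Total weight is conserved. Never applied to test data.
#'
#' @param X feature matrix.
#' @param y label vector (same length as rows of `X`).
#' @param weights per-row weights (default 1).
#' @return list with deduplicated `X`, `y`, `weights`.
#' @export
collapse_duplicates <- function(X, y, weights = NULL) {
  X <- as.matrix(X)
  y <- as.character(y)
  if (is.null(weights)) weights <- rep(1, nrow(X))
  key <- do.call(paste, c(as.data.frame(round(X, 2)), list(y, sep = "|")))
  first <- !duplicated(key)
  idx <- match(key, key[first])
  w <- as.numeric(tapply(weights, idx, sum))
  list(X = X[first, , drop = FALSE], y = y[first], weights = w)
}
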