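#' Filter configuration for the velocity pipeline
#'
#' Defaults follow the head-free gaze processing chain: a Kaiser-window FIR
#' anti-alias low-pass at 58 Hz applied with zero phase, then bilateral
#' smoothing of the velocity channels (window 50 ms, temporal sigma 18 ms,
#' range sigma 8.75 deg/s). Samples with tracker confidence below 0.3 are
#' masked out of all computation.
#'
#' @param antialias_cutoff anti-alias cutoff in Hz.
#' @param bilateral_window bilateral filter window length in ms.
#' @param bilateral_sigma_t temporal (domain) sigma in ms.
#' @param bilateral_sigma_r range sigma in deg/s.
#' @param confidence_threshold samples below this confidence are masked.
#' @return object of class `filter_config`.
#' @export
filter_config <- function(antialias_cutoff = 58,
                          bilateral_window = 50,
                          bilateral_sigma_t = 18,
                          bilateral_sigma_r = 8.75,
                          confidence_threshold = 0.3) {
  cfg <- list(antialias_cutoff = antialias_cutoff,
              antialias_window = "Kaiser",
              bilateral_window = bilateral_window,
              bilateral_sigma_t = bilateral_sigma_t,
              bilateral_sigma_r = bilateral_sigma_r,
              confidence_threshold = confidence_threshold)
  if (any(unlist(cfg[c(1, 3, 4, 5)]) <= 0)) stop("filter parameters must be positive")
  structure(cfg, class = "filter_config")
}

#' Construct a velocity trace
#'
#' Six filtered angular-velocity channels: absolute eye-in-head and head
#' speed (`we`, `wh`, deg/s, non-negative) and signed azimuth/elevation
#' components for each (`*_az`, `*_el`; positive = clockwise looking along
#' the rotation axis). The mask is FALSE wherever confidence fell below the
#' configured threshold.
#'
#' @param timestamps sample times in s.
#' @param fs sampling rate, Hz.
#' @param we,wh absolute eye/head angular speed, deg/s.
#' @param we_az,wh_az,we_el,wh_el signed azimuth/elevation components, deg/s.
#' @param conf per-sample confidence.
#' @param confidence_threshold threshold defining the mask.
#' @param eih,head_forward optional filtered direction vectors retained for
#'   windowed feature extraction.
#' @return object of class `velocity_trace`.
#' @export
velocity_trace <- function(timestamps, fs, we, wh, we_az, wh_az, we_el, wh_el,
                           conf, confidence_threshold = 0.3,
                           eih = NULL, head_forward = NULL) {
  n <- length(timestamps)
  chans <- list(we = we, wh = wh, we_az = we_az, wh_az = wh_az,
                we_el = we_el, wh_el = wh_el, conf = conf)
  if (any(vapply(chans, length, 1L) != n)) stop("channel length mismatch")
  if (any(we < -1e-9, na.rm = TRUE) || any(wh < -1e-9, na.rm = TRUE))
    stop("absolute velocities must be non-negative")
  structure(c(list(timestamps = timestamps, fs = fs), chans,
              list(mask = conf >= confidence_threshold,
                   confidence_threshold = confidence_threshold,
                   eih = eih, head_forward = head_forward)),
            class = "velocity_trace")
}

#' @export
print.velocity_trace <- function(x, ...) {
  cat(sprintf("velocity_trace: %d samples @ %.6g Hz, %d masked (conf < %.2g)\n",
              length(x$timestamps), x$fs, sum(!x$mask), x$confidence_threshold))
  ok <- x$mask
  cat(sprintf("  |we| median %.2f deg/s  |wh| median %.2f deg/s\n",
              median(x$we[ok]), median(x$wh[ok])))
  invisible(x)
}

unit_rows <- function(v) {
  n <- sqrt(rowSums(v^2))
  v / n
}

#' Two-point central-difference angular speed
#'
#' For interior samples the speed is `fs * angle(v[n+1], v[n-1]) / 2`, the
#' angle computed robustly as `atan2(|v1 x v2|, v1 . v2)`. The two endpoint
#' samples use a one-sided difference over a single sampling interval so the
#' output has the same length as the input.
#'
#' @param directions n x 3 matrix of unit direction vectors.
#' @param fs sampling rate in Hz.
#' @return non-negative angular speed in deg/s, length n.
#' @export
two_point_velocity <- function(directions, fs) {
  v <- as.matrix(directions)
  n <- nrow(v)
  if (n < 3) stop("two_point_velocity needs at least 3 samples")
  v <- unit_rows(v)
  ang <- pair_angles(v[1:(n - 2), , drop = FALSE], v[3:n, , drop = FALSE])
  out <- numeric(n)
  out[2:(n - 1)] <- fs * ang / 2
  out[1] <- fs * pair_angles(v[1, , drop = FALSE], v[2, , drop = FALSE])
  out[n] <- fs * pair_angles(v[n - 1, , drop = FALSE], v[n, , drop = FALSE])
  out * 180 / pi
}

# angle between paired rows via atan2(|cross|, dot); radians
pair_angles <- function(a, b) {
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  atan2(sqrt(rowSums(cr^2)), rowSums(a * b))
}

#' Signed azimuth/elevation velocity components (small-angle)
#'
#' Decomposes the two-point rotation between `v[n-1]` and `v[n+1]` into a
#' component about the world up-axis (azimuth) and about the instantaneous
#' horizontal axis `z x v` (elevation). The small-angle form arises
#' naturally from the cross product: the rotation's sine, not its angle, is
#' projected onto each axis (about 1% low at a 14 deg step). Positive values
#' are clockwise looking along the rotation axis, so a rightward gaze sweep
#' (viewed from above) is positive azimuth.
#'
#' @param directions n x 3 matrix of unit direction vectors; world z is up.
#' @param fs sampling rate in Hz.
#' @param warn_step_deg warn when any two-sample angular step exceeds this.
#' @return list with numeric vectors `az` and `el`, deg/s, length n.
#' @export
small_angle_components <- function(directions, fs, warn_step_deg = 14) {
  v <- unit_rows(as.matrix(directions))
  n <- nrow(v)
  if (n < 3) stop("need at least 3 samples")
  i0 <- c(1, 1:(n - 2), n - 1)   # replicate-pad pairing for endpoints
  i1 <- c(2, 3:n, n)
  a <- v[i0, , drop = FALSE]
  b <- v[i1, , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  step <- asin(pmin(1, sqrt(rowSums(cr^2)))) * 180 / pi
  if (any(step > warn_step_deg))
    warning(sprintf("%d two-sample steps exceed %g deg; small-angle error > 1%%",
                    sum(step > warn_step_deg), warn_step_deg))
  # endpoints span one interval, interior spans two
  denom <- c(1, rep(2, n - 2), 1)
  az <- -fs * cr[, 3] / denom                      # clockwise-positive about +z
  h <- cbind(-v[, 2], v[, 1], 0)                   # z x v, horizontal axis
  hn <- sqrt(rowSums(h^2))
  hn[hn < 1e-12] <- Inf                            # gaze at the pole: undefined, zero out
  h <- h / hn
  el <- -fs * rowSums(cr * h) / denom
  list(az = az * 180 / pi, el = el * 180 / pi)
}

# Kaiser FIR design: 60 dB stopband (beta 5.653), 4 Hz transition band
# centred on the cutoff. Order from the Kaiser formula, forced odd.
kaiser_fir <- function(fs, cutoff, transition = 4, atten_db = 60) {
  if (cutoff >= fs / 2) stop("cutoff must be below Nyquist")
  beta <- 0.1102 * (atten_db - 8.7)
  dw <- 2 * pi * transition / fs
  ntaps <- ceiling((atten_db - 7.95) / (2.285 * dw)) + 1
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1
  wc <- min(cutoff / (fs / 2), 0.999)
  signal::fir1(ntaps - 1, wc, type = "low", window = signal::kaiser(ntaps, beta))
}

# zero-phase FIR application with reflection padding; tolerates series much
# shorter than the classic 3x-filter-length rule
zp_filter_padded <- function(x, b) {
  nb <- length(b)
  n <- length(x)
  pad <- nb
  # reflect about the endpoints, tiling if the series is shorter than pad
  refl <- function(idx) {
    m <- n - 1L
    if (m == 0L) return(rep(1L, length(idx)))
    r <- (idx - 1L) %% (2L * m)
    ifelse(r < m, r + 1L, 2L * m - r + 1L)
  }
  left <- 2 * x[1] - x[refl(1L + seq_len(pad))]
  right <- 2 * x[n] - x[refl(n - 1L + seq_len(pad)) ]
  xp <- c(rev(left), x, right)
  y <- stats::filter(xp, b, method = "convolution", sides = 2)
  y <- rev(stats::filter(rev(y), b, method = "convolution", sides = 2))
  as.numeric(y[pad + seq_len(n)])
}

#' Zero-phase Kaiser-window anti-alias low-pass
#'
#' Forward-backward application of a linear-phase Kaiser FIR (60 dB
#' stopband, 4 Hz transition band), giving zero net group delay and squared
#' magnitude response.
#'
#' @param series numeric vector.
#' @param fs sampling rate, Hz.
#' @param cfg a [filter_config].
#' @param pad reflect-pad short series instead of erroring. Without padding
#'   the series must be at least three filter lengths long.
#' @return filtered series, same length.
#' @export
antialias_lowpass <- function(series, fs, cfg = filter_config(), pad = FALSE) {
  if (!all(is.finite(series))) stop("series must be finite")
  b <- kaiser_fir(fs, cfg$antialias_cutoff)
  if (!pad && length(series) < 3 * length(b))
    stop(sprintf(paste("series (%d samples) shorter than 3x filter length (%d);",
                       "call with pad = TRUE to reflect-pad"),
                 length(series), 3 * length(b)))
  zp_filter_padded(series, b)
}

#' Bilateral smoothing of a velocity series
#'
#' Edge-preserving smoothing: each output sample is a normalized weighted
#' mean over a temporal window, weights the product of a Gaussian in time
#' (`sigma_t`) and a Gaussian in signal value (`sigma_r`). Large excursions
#' such as saccade peaks receive almost no support from dissimilar
#' neighbours and are preserved, while low-amplitude noise (much smaller
#' than `sigma_r`) is smoothed as by a plain Gaussian.
#'
#' @param series numeric velocity series, deg/s.
#' @param fs sampling rate, Hz.
#' @param cfg a [filter_config] (window and sigmas in ms / deg/s).
#' @return smoothed series, bounded by the local window range.
#' @export
bilateral_smooth <- function(series, fs, cfg = filter_config()) {
  if (!all(is.finite(series))) stop("series must be finite")
  n <- length(series)
  half <- max(1L, floor(cfg$bilateral_window / 1000 * fs / 2))
  st <- cfg$bilateral_sigma_t / 1000
  sr <- cfg$bilateral_sigma_r
  num <- numeric(n)
  den <- numeric(n)
  for (k in -half:half) {
    src <- seq_len(n) + k
    ok <- src >= 1 & src <= n
    wt <- exp(-(k / fs)^2 / (2 * st^2))
    xs <- series[src[ok]]
    w <- wt * exp(-(series[ok] - xs)^2 / (2 * sr^2))
    num[ok] <- num[ok] + w * xs
    den[ok] <- den[ok] + w
  }
  num / den
}

#' Rotate eye-in-head vectors into the world frame
#'
#' `giw[n, ] = R(head[n, ]) %*% eih[n, ]` -- the head-compensated
#' gaze-in-world direction. Under perfect VOR (eye counter-rotating the
#' head) the result is constant.
#'
#' @param eih n x 3 eye-in-head unit vectors.
#' @param head n x 4 head quaternions.
#' @return n x 3 matrix of unit gaze-in-world vectors.
#' @export
gaze_in_world <- function(eih, head) {
  eih <- as.matrix(eih); head <- as.matrix(head)
  if (nrow(eih) != nrow(head)) stop("eih and head lengths differ")
  unit_rows(quat_rotate(quat_normalize(head), unit_rows(eih)))
}

#' Per-sample angular displacement
#'
#' The angular step a rotation at `speed` deg/s covers in one sampling
#' interval; at the physiological ceiling of 900 deg/s and 120 Hz this is
#' 7.5 deg, comfortably inside the ~8 deg small-angle regime.
#'
#' @param speed angular speed, deg/s.
#' @param fs sampling rate, Hz.
#' @return displacement in degrees.
#' @export
per_sample_displacement <- function(speed, fs) speed / fs

# contiguous runs of TRUE in a logical vector -> list of index ranges
mask_segments <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  Map(function(s, e) s:e, starts[keep], ends[keep])
}

#' Full velocity-extraction pipeline
#'
#' Order of operations: mask samples with confidence below threshold;
#' anti-alias the eye direction components and head quaternion components
#' per contiguous unmasked segment (renormalizing afterwards); two-point
#' magnitudes and small-angle azimuth/elevation components for the eye
#' (eye-in-head) and the head; bilateral smoothing of each of the six
#' velocity channels. Filters never cross masked gaps (no interpolation
#' across blinks); segments shorter than 9 samples pass through the
#' anti-alias stage unfiltered.
#'
#' Head magnitude uses the full relative-quaternion angle (capturing roll);
#' the signed head components are computed from the rotated forward vector.
#'
#' @param trace a [gaze_trace].
#' @param cfg a [filter_config].
#' @return a [velocity_trace] aligned with the input timestamps.
#' @export
velocity_pipeline <- function(trace, cfg = filter_config()) {
  stopifnot(inherits(trace, "gaze_trace"))
  n <- length(trace$timestamps)
  fs <- trace$fs
  mask <- trace$confidence >= cfg$confidence_threshold
  if (!any(mask)) stop("no samples left after confidence masking")
  if (mean(!mask) > 0.5)
    warning(sprintf("%.0f%% of samples masked by confidence threshold",
                    100 * mean(!mask)))
  b <- kaiser_fir(fs, cfg$antialias_cutoff)
  segs <- mask_segments(mask)

  eih <- trace$eih
  head <- trace$head
  for (seg in segs) {
    if (length(seg) >= 9) {
      for (j in 1:3) eih[seg, j] <- zp_filter_padded(eih[seg, j], b)
      for (j in 1:4) head[seg, j] <- zp_filter_padded(head[seg, j], b)
    }
  }
  eih <- unit_rows(eih)
  head <- quat_normalize(head)
  fwd <- quat_rotate(head, matrix(rep(c(1, 0, 0), n), ncol = 3, byrow = TRUE))

  we <- numeric(n); wh <- numeric(n)
  we_az <- numeric(n); we_el <- numeric(n)
  wh_az <- numeric(n); wh_el <- numeric(n)
  for (seg in segs) {
    m <- length(seg)
    if (m < 3) next   # too short for a central difference; stays 0, masked below
    we[seg] <- two_point_velocity(eih[seg, , drop = FALSE], fs)
    # head magnitude from relative quaternion over the two-sample window
    q <- head[seg, , drop = FALSE]
    ang <- quat_angle(q[1:(m - 2), , drop = FALSE], q[3:m, , drop = FALSE])
    wh[seg][2:(m - 1)] <- fs * ang / 2 * 180 / pi
    wh[seg][1] <- fs * quat_angle(q[1, , drop = FALSE], q[2, , drop = FALSE]) * 180 / pi
    wh[seg][m] <- fs * quat_angle(q[m - 1, , drop = FALSE], q[m, , drop = FALSE]) * 180 / pi
    ce <- small_angle_components(eih[seg, , drop = FALSE], fs)
    ch <- small_angle_components(fwd[seg, , drop = FALSE], fs)
    we_az[seg] <- ce$az; we_el[seg] <- ce$el
    wh_az[seg] <- ch$az; wh_el[seg] <- ch$el
  }
  for (seg in segs) {
    if (length(seg) < 3) next
    we[seg] <- bilateral_smooth(we[seg], fs, cfg)
    wh[seg] <- bilateral_smooth(wh[seg], fs, cfg)
    we_az[seg] <- bilateral_smooth(we_az[seg], fs, cfg)
    wh_az[seg] <- bilateral_smooth(wh_az[seg], fs, cfg)
    we_el[seg] <- bilateral_smooth(we_el[seg], fs, cfg)
    wh_el[seg] <- bilateral_smooth(wh_el[seg], fs, cfg)
  }
  we <- pmax(we, 0); wh <- pmax(wh, 0)
  velocity_trace(trace$timestamps, fs, we, wh, we_az, wh_az, we_el, wh_el,
                 trace$confidence,
                 confidence_threshold = cfg$confidence_threshold,
                 eih = eih, head_forward = fwd)
}
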