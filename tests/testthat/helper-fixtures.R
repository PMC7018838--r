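# shared fixture builders (everything generated in code)

# paint an explicit event list onto a NONE canvas
mk_labels <- function(events, n, fs = 120) {
  lab <- rep("NONE", n)
  for (e in events) lab[e[[2]]:(e[[3]] - 1L)] <- e[[1]]
  label_sequence(lab, fs = fs)
}

# random label sequence of well-formed runs
rand_labels <- function(n, fs = 120, lens = 2:30,
                        probs = c(FIX = .4, PUR = .15, SAC = .3, NONE = .15)) {
  lab <- character(0)
  while (length(lab) < n) {
    cl <- sample(names(probs), 1, prob = probs)
    lab <- c(lab, rep(cl, sample(lens, 1)))
  }
  label_sequence(lab[seq_len(n)], fs = fs)
}

# smooth random unit-direction walk (small angular steps, degrees/sample)
rand_directions <- function(n, step_deg = 0.5) {
  az <- cumsum(rnorm(n, 0, step_deg)) * pi / 180
  el <- cumsum(rnorm(n, 0, step_deg / 2)) * pi / 180
  cbind(cos(el) * cos(az), cos(el) * sin(az), sin(el))
}

identity_quats <- function(n) matrix(rep(c(1, 0, 0, 0), n), ncol = 4, byrow = TRUE)

# random unit quaternions
rand_quats <- function(n) {
  q <- matrix(rnorm(4 * n), n, 4)
  q / sqrt(rowSums(q^2))
}

# quaternion -> rotation matrix, independent of the package's quat_rotate
rotmat_from_quat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# a small synthetic gaze trace with benign head motion
rand_trace <- function(n = 600, fs = 120, seed = 1) {
  set.seed(seed)
  eih <- rand_directions(n, step_deg = 0.3)
  yaw <- cumsum(rnorm(n, 0, 0.05))
  head <- quat_from_euler(yaw, yaw * 0)
  gaze_trace((seq_len(n) - 1) / fs, eih, head, runif(n, 0.6, 1), fs = fs)
}

# ELC walkthrough fixture: long reference fixation fragmented in the test
# by a spurious saccade, reference saccades labelled away by the test, and
# a blink-adjacent fixation fully inside a longer same-class test event.
# fs = 200 so one sample is 5 ms.
elc_walkthrough <- function() {
  fs <- 200
  ref <- mk_labels(list(list("FIX", 1, 41), list("SAC", 41, 47),
                        list("FIX", 47, 141), list("FIX", 151, 191),
                        list("SAC", 191, 197), list("FIX", 197, 240)),
                   240, fs)
  test <- mk_labels(list(list("FIX", 1, 41), list("FIX", 49, 90),
                         list("SAC", 90, 96), list("FIX", 96, 139),
                         list("FIX", 149, 200), list("FIX", 210, 240)),
                    240, fs)
  list(ref = ref, test = test, fs = fs)
}

# independent dynamic-programming Levenshtein distance
dp_levenshtein <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  la <- length(a); lb <- length(b)
  d <- matrix(0L, la + 1, lb + 1)
  d[, 1] <- 0:la; d[1, ] <- 0:lb
  for (i in seq_len(la)) for (j in seq_len(lb))
    d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                           d[i, j] + (a[i] != b[j]))
  d[la + 1, lb + 1]
}
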