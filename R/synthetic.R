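# Seeded generator of labelled head-free recordings. Emulates the
# statistical structure of natural eye+head coordination: near-unity-gain
# VOR fixations with residual gaze-in-world tremor, saccades with
# bell-shaped (minimum-jerk) velocity profiles, pursuits where eye and head
# jointly track a moving target, and blink/low-confidence gaps.

#' Specification for a synthetic head-free recording
#'
#' Defaults describe a plausible naturalistic recording: 120 Hz sampling,
#' event mix dominated by fixations, saccade durations 20-150 ms (the
#' plausibility band also used by the cleaning rules), head-compensated
#' gaze tremor with mean 0.55 deg/s and SD 0.32 deg/s, and VOR gain 1.
#'
#' @param fs sampling rate, Hz.
#' @param duration recording length, s.
#' @param mix named event-mix proportions over `fix_stationary`, `fix_vor`,
#'   `pur`, `sac`, `blink`; normalized to sum to 1.
#' @param fixation_ms,pursuit_ms,saccade_ms,blink_ms duration ranges (ms).
#' @param saccade_peak_vel peak-velocity range, deg/s.
#' @param pursuit_vel pursuit target velocity range, deg/s.
#' @param vor_gain eye/head compensation gain during VOR fixations (~1).
#' @param tremor_mean,tremor_sd gaze-in-world tremor speed statistics, deg/s.
#' @param head_vel_scale stationary SD of the head angular velocity during
#'   VOR fixations, deg/s.
#' @param head_split fraction range of pursuit velocity carried by the head.
#' @param dropout_rate probability of a spurious low-confidence sample.
#' @param seed RNG seed; every generated recording is a deterministic
#'   function of the spec.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(fs = 120, duration = 60,
                           mix = c(fix_stationary = 0.25, fix_vor = 0.20,
                                   pur = 0.06, sac = 0.41, blink = 0.08),
                           fixation_ms = c(150, 800),
                           pursuit_ms = c(500, 2000),
                           saccade_ms = c(20, 150),
                           blink_ms = c(100, 400),
                           saccade_peak_vel = c(120, 500),
                           pursuit_vel = c(5, 30),
                           vor_gain = 1,
                           tremor_mean = 0.55, tremor_sd = 0.32,
                           head_vel_scale = 10,
                           head_split = c(0.2, 0.6),
                           dropout_rate = 0.005,
                           seed = 1L) {
  need <- c("fix_stationary", "fix_vor", "pur", "sac", "blink")
  if (!all(need %in% names(mix))) stop("mix needs proportions for: ",
                                       paste(need, collapse = ", "))
  mix <- mix[need]
  if (any(mix < 0) || sum(mix) <= 0) stop("invalid mix")
  mix <- mix / sum(mix)
  if (sum(mix[c("fix_stationary", "fix_vor", "pur")]) <= 0)
    stop("infeasible mix: recording cannot consist of saccades/blinks only")
  spec <- list(fs = fs, duration = duration, mix = mix,
               fixation_ms = fixation_ms, pursuit_ms = pursuit_ms,
               saccade_ms = saccade_ms, blink_ms = blink_ms,
               saccade_peak_vel = saccade_peak_vel, pursuit_vel = pursuit_vel,
               vor_gain = vor_gain, tremor_mean = tremor_mean,
               tremor_sd = tremor_sd, head_vel_scale = head_vel_scale,
               head_split = head_split, dropout_rate = dropout_rate,
               seed = as.integer(seed))
  structure(spec, class = "synthetic_spec")
}

# AR(1) (discrete Ornstein-Uhlenbeck) process with stationary sd and
# correlation time tau (s)
ou_process <- function(n, sd, tau, fs) {
  if (n == 0) return(numeric(0))
  a <- exp(-1 / (tau * fs))
  e <- rnorm(n, sd = sd * sqrt(1 - a^2))
  x <- numeric(n)
  x[1] <- rnorm(1, sd = sd)
  for (i in seq_len(n - 1L)) x[i + 1L] <- a * x[i] + e[i + 1L]
  x
}

# Tremor velocity: two independent OU component processes (Rayleigh-like
# speed) modulated by a slow lognormal amplitude envelope so both the mean
# and the SD of the measured speed are controllable. The 1.03 / 1.21
# factors pre-compensate the attenuation of the two-point + anti-alias +
# bilateral chain on this band, so the statistics measured through the
# velocity pipeline land on the requested values.
tremor_velocity <- function(n, fs, mean_speed, sd_speed) {
  m <- mean_speed * 1.03
  s <- sd_speed * 1.21
  ratio2 <- (s / m)^2
  sz2 <- max(0, log((ratio2 + 1) * (pi / 2) / 2))
  env <- exp(sqrt(sz2) * ou_process(n, 1, 0.5, fs) - sz2 / 2)
  sc <- m / sqrt(pi / 2)
  list(az = env * ou_process(n, sc, 0.08, fs),
       el = env * ou_process(n, sc, 0.08, fs))
}

min_jerk_steps <- function(n_samples, amplitude) {
  tau <- seq_len(n_samples) / n_samples
  pos <- amplitude * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
  diff(c(0, pos))
}

#' Generate a labelled synthetic recording
#'
#' Samples an event schedule from the spec's mix, then integrates gaze and
#' head kinematics per event: fixations hold the gaze-in-world point (the
#' head wandering under an Ornstein-Uhlenbeck velocity law during VOR
#' fixations, the eye counter-rotating at the VOR gain) with tremor noise
#' on the gaze point; pursuits move a virtual target at a sampled constant
#' velocity, tracked jointly by eye and head; saccades relocate gaze along
#' a minimum-jerk profile whose peak velocity is drawn from the spec;
#' blinks drop confidence below 0.3 and are labelled `NONE`. Output is
#' deterministic under a fixed spec (including its seed).
#'
#' @param spec a [synthetic_spec].
#' @param subject_id,task_id identifiers stamped on the trace.
#' @return list with `trace` (a [gaze_trace]), `labels` (a
#'   [label_sequence]), and `truth` (per-sample fine-grained event type).
#' @export
generate_recording <- function(spec, subject_id = "synthetic", task_id = "sim") {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  fs <- spec$fs
  n_total <- round(spec$duration * fs)
  types <- names(spec$mix)

  # Event schedule: draw type counts proportional to the mix, then arrange
  # them with no two equal-label events adjacent (same-label neighbours
  # would merge into one run, distorting the event-count proportions).
  mean_dur <- c(fix_stationary = mean(spec$fixation_ms),
                fix_vor = mean(spec$fixation_ms),
                pur = mean(spec$pursuit_ms),
                sac = mean(spec$saccade_ms),
                blink = mean(spec$blink_ms)) / 1000
  n_events <- max(3L, ceiling(spec$duration / sum(spec$mix * mean_dur[types])) + 2L)
  counts <- round(n_events * spec$mix)
  counts[counts < 0] <- 0
  lab_of <- c(fix_stationary = "FIX", fix_vor = "FIX", pur = "PUR",
              sac = "SAC", blink = "NONE")
  order_types <- character(0)
  prev <- ""
  while (sum(counts) > 0) {
    ok <- counts > 0 & lab_of[types] != prev
    if (!any(ok)) {
      # only same-label types remain: insert at a compatible interior slot
      ty <- types[which(counts > 0)[1]]
      L <- length(order_types)
      labs <- lab_of[order_types]
      slots <- Filter(function(p) {
        (p == 0 || labs[p] != lab_of[ty]) && (p == L || labs[p + 1] != lab_of[ty])
      }, 0:L)
      pos <- if (length(slots)) slots[[sample.int(length(slots), 1)]] else L
      order_types <- append(order_types, ty, after = pos)
      counts[ty] <- counts[ty] - 1L
      next
    }
    ty <- sample(types[ok], 1, prob = spec$mix[ok])
    order_types <- c(order_types, ty)
    counts[ty] <- counts[ty] - 1L
    prev <- lab_of[ty]
  }
  sched <- list()
  n_done <- 0L
  for (ty in order_types) {
    if (n_done >= n_total) break
    dur_ms <- switch(ty,
      fix_stationary = runif(1, spec$fixation_ms[1], spec$fixation_ms[2]),
      fix_vor = runif(1, spec$fixation_ms[1], spec$fixation_ms[2]),
      pur = runif(1, spec$pursuit_ms[1], spec$pursuit_ms[2]),
      sac = runif(1, spec$saccade_ms[1], spec$saccade_ms[2]),
      blink = runif(1, spec$blink_ms[1], spec$blink_ms[2]))
    n_ev <- max(1L, as.integer(round(dur_ms / 1000 * fs)))
    sched[[length(sched) + 1L]] <- list(type = ty, n = n_ev)
    n_done <- n_done + n_ev
  }

  n <- sum(vapply(sched, `[[`, 1L, "n"))
  gaze_az <- numeric(n); gaze_el <- numeric(n)     # gaze-in-world, degrees
  head_yaw <- numeric(n); head_pitch <- numeric(n) # head orientation, degrees
  conf <- numeric(n); lab <- character(n); truth <- character(n)

  az <- 0; el <- 0; yaw <- 0; pitch <- 0
  dt <- 1 / fs
  trem <- tremor_velocity(n, fs, spec$tremor_mean, spec$tremor_sd)
  i <- 1L
  for (ev in sched) {
    idx <- i:(i + ev$n - 1L)
    ty <- ev$type
    if (ty %in% c("fix_stationary", "fix_vor")) {
      hs <- if (ty == "fix_vor") spec$head_vel_scale else 0.5
      hv_y <- ou_process(ev$n, hs, 0.5, fs)
      hv_p <- ou_process(ev$n, hs * 0.5, 0.5, fs)
      # weak orienting spring: the head re-centres on the gaze direction,
      # keeping the eye near its primary position as in natural behaviour
      k_orient <- 1.5
      for (j in seq_len(ev$n)) {
        yaw <- yaw + (hv_y[j] + k_orient * (az - yaw)) * dt
        pitch <- pitch + (hv_p[j] + k_orient * (-el - pitch)) * dt
        # imperfect VOR lets a fraction of head motion leak into gaze
        az <- az + (1 - spec$vor_gain) * hv_y[j] * dt + trem$az[idx[j]] * dt
        el <- el + (1 - spec$vor_gain) * (-hv_p[j]) * dt + trem$el[idx[j]] * dt
        gaze_az[idx[j]] <- az; gaze_el[idx[j]] <- el
        head_yaw[idx[j]] <- yaw; head_pitch[idx[j]] <- pitch
      }
      lab[idx] <- "FIX"
      truth[idx] <- if (ty == "fix_vor") "fix_vor" else "fix_stationary"
      conf[idx] <- runif(ev$n, 0.75, 1)
    } else if (ty == "pur") {
      v <- runif(1, spec$pursuit_vel[1], spec$pursuit_vel[2])
      phi <- runif(1, 0, 2 * pi)
      split <- runif(1, spec$head_split[1], spec$head_split[2])
      # steer back toward primary position to keep eccentricity bounded
      if (abs(az) > 25 || abs(el) > 20) phi <- atan2(-el, -az)
      redraw <- max(1L, as.integer(round(0.4 * fs)))   # target path curves
      for (j in seq_len(ev$n)) {
        if (j %% redraw == 0) {
          phi <- if (abs(az) > 25 || abs(el) > 20) atan2(-el, -az)
                 else phi + rnorm(1, 0, 0.9)
          v <- runif(1, spec$pursuit_vel[1], spec$pursuit_vel[2])
          split <- runif(1, spec$head_split[1], spec$head_split[2])
        }
        vaz <- v * cos(phi); vel_ <- v * sin(phi)
        az <- az + vaz * dt + trem$az[idx[j]] * dt
        el <- el + vel_ * dt + trem$el[idx[j]] * dt
        yaw <- yaw + split * vaz * dt
        pitch <- pitch - split * vel_ * dt
        gaze_az[idx[j]] <- az; gaze_el[idx[j]] <- el
        head_yaw[idx[j]] <- yaw; head_pitch[idx[j]] <- pitch
      }
      lab[idx] <- "PUR"; truth[idx] <- "pur"
      conf[idx] <- runif(ev$n, 0.75, 1)
    } else if (ty == "sac") {
      vpk <- runif(1, spec$saccade_peak_vel[1], spec$saccade_peak_vel[2])
      dur_s <- ev$n / fs
      amp <- min(vpk * dur_s / 1.875, 40)
      phi <- runif(1, 0, 2 * pi)
      if (abs(az) > 25 || abs(el) > 20) phi <- atan2(-el, -az)
      steps <- min_jerk_steps(ev$n, amp)
      for (j in seq_len(ev$n)) {
        az <- az + steps[j] * cos(phi)
        el <- el + steps[j] * sin(phi)
        gaze_az[idx[j]] <- az; gaze_el[idx[j]] <- el
        head_yaw[idx[j]] <- yaw; head_pitch[idx[j]] <- pitch
      }
      lab[idx] <- "SAC"; truth[idx] <- "sac"
      conf[idx] <- runif(ev$n, 0.75, 1)
    } else {                             # blink
      gaze_az[idx] <- az; gaze_el[idx] <- el
      head_yaw[idx] <- yaw; head_pitch[idx] <- pitch
      lab[idx] <- "NONE"; truth[idx] <- "blink"
      conf[idx] <- runif(ev$n, 0.05, 0.25)
    }
    i <- i + ev$n
  }

  # spurious tracking-loss samples
  glitch <- runif(n) < spec$dropout_rate
  conf[glitch] <- runif(sum(glitch), 0.05, 0.29)
  lab[glitch] <- "NONE"

  d2r <- pi / 180
  giw <- cbind(cos(gaze_el * d2r) * cos(gaze_az * d2r),
               cos(gaze_el * d2r) * sin(gaze_az * d2r),
               sin(gaze_el * d2r))
  head_q <- quat_from_euler(head_yaw, head_pitch, 0)
  eih <- quat_rotate(quat_conjugate(head_q), giw)
  trace <- gaze_trace((seq_len(n) - 1L) / fs, eih, head_q, conf, fs = fs,
                      subject_id = subject_id, task_id = task_id)
  list(trace = trace,
       labels = label_sequence(lab, fs = fs, source_id = "truth"),
       truth = truth)
}

#' Simulate an imperfect human labeller
#'
#' Perturbs a ground-truth label sequence the way human coders disagree:
#' event boundaries jittered by truncated Gaussian noise, whole events
#' relabelled according to a class-confusion matrix, and optional
#' fragmentation of long events by short spurious saccades.
#'
#' @param truth the ground-truth [label_sequence].
#' @param jitter_sd_ms boundary jitter SD in ms (truncated at 2 SD and at
#'   half the shorter adjacent event).
#' @param confusion 3 x 3 row-stochastic matrix (rows/cols in `FIX`, `PUR`,
#'   `SAC` order): probability an event of the row class is labelled as the
#'   column class. Default identity (no confusion).
#' @param frag_rate probability a long (>250 ms) event gets fragmented by a
#'   short spurious saccade.
#' @param seed RNG seed.
#' @return a [label_sequence].
#' @export
generate_labeller <- function(truth, jitter_sd_ms = 0, confusion = diag(3),
                              frag_rate = 0, seed = 1L) {
  set.seed(seed)
  fs <- label_fs(truth)
  if (jitter_sd_ms < 0) stop("jitter SD must be non-negative")
  confusion <- as.matrix(confusion)
  if (any(confusion < 0) || any(abs(rowSums(confusion) - 1) > 1e-9))
    stop("confusion must be row-stochastic")
  ev <- labels_to_events(truth)
  n <- attr(ev, "total_samples")
  ev <- as.data.frame(ev)
  # jitter interior boundaries
  if (jitter_sd_ms > 0 && nrow(ev) > 0) {
    sd_s <- jitter_sd_ms / 1000 * fs
    for (i in seq_len(nrow(ev))) {
      for (fld in c("start", "end")) {
        j <- rnorm(1, 0, sd_s)
        j <- max(-2 * sd_s, min(2 * sd_s, j))
        lim <- floor((ev$end[i] - ev$start[i]) / 2)
        j <- round(max(-lim, min(lim, j)))
        ev[[fld]][i] <- ev[[fld]][i] + j
      }
      if (ev$end[i] <= ev$start[i]) ev$end[i] <- ev$start[i] + 1L
      ev$start[i] <- max(1L, ev$start[i]); ev$end[i] <- min(n + 1L, ev$end[i])
    }
    # enforce ordering: clip each event at its successor's start
    ev <- ev[order(ev$start), , drop = FALSE]
    for (i in seq_len(nrow(ev) - 1L))
      if (ev$end[i] > ev$start[i + 1L]) ev$end[i] <- ev$start[i + 1L]
    ev <- ev[ev$end > ev$start, , drop = FALSE]
  }
  # event relabelling
  for (i in seq_len(nrow(ev))) {
    r <- match(ev$cls[i], GAZE_CLASSES)
    ev$cls[i] <- sample(GAZE_CLASSES, 1, prob = confusion[r, ])
  }
  lab <- rep("NONE", n)
  for (i in seq_len(nrow(ev)))
    lab[ev$start[i]:(ev$end[i] - 1L)] <- ev$cls[i]
  # fragmentation
  if (frag_rate > 0) {
    long_min <- round(0.25 * fs)
    frag_len <- max(2L, round(0.03 * fs))
    for (i in seq_len(nrow(ev))) {
      if (ev$end[i] - ev$start[i] > long_min && runif(1) < frag_rate &&
          ev$cls[i] != "SAC") {
        mid <- floor((ev$start[i] + ev$end[i]) / 2)
        lab[mid:(mid + frag_len - 1L)] <- "SAC"
      }
    }
  }
  label_sequence(lab, fs = fs, source_id = sprintf("labeller_seed%d", seed))
}

#' Generate a cohort of synthetic subjects
#'
#' Convenience wrapper running [generate_recording] and [velocity_pipeline]
#' for several subjects with derived seeds.
#'
#' @param n_subjects number of subjects.
#' @param spec base [synthetic_spec]; each subject reuses it with seed
#'   `spec$seed + subject`.
#' @param cfg [filter_config] for the velocity pipeline.
#' @return list of per-subject lists with `trace`, `vel`, `labels`,
#'   `subject`.
#' @export
generate_cohort <- function(n_subjects, spec = synthetic_spec(),
                            cfg = filter_config()) {
  lapply(seq_len(n_subjects), function(s) {
    sp <- spec
    sp$seed <- spec$seed + s
    rec <- generate_recording(sp, subject_id = sprintf("S%02d", s))
    vel <- velocity_pipeline(rec$trace, cfg)
    list(trace = rec$trace, vel = vel, labels = rec$labels,
         subject = sprintf("S%02d", s))
  })
}
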