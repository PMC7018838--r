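test_that("generation is deterministic under a fixed spec", {
  r1 <- generate_recording(synthetic_spec(duration = 5, seed = 3))
  r2 <- generate_recording(synthetic_spec(duration = 5, seed = 3))
  expect_identical(r1$trace$eih, r2$trace$eih)
  expect_identical(r1$trace$head, r2$trace$head)
  expect_identical(as.character(r1$labels), as.character(r2$labels))
  r3 <- generate_recording(synthetic_spec(duration = 5, seed = 4))
  expect_false(identical(as.character(r1$labels), as.character(r3$labels)))
})

test_that("infeasible mixes are rejected", {
  expect_error(synthetic_spec(mix = c(fix_stationary = 0, fix_vor = 0, pur = 0,
                                      sac = 1, blink = 0)), "infeasible")
  expect_error(synthetic_spec(mix = c(fix_stationary = 1, fix_vor = 0)), "mix")
})

test_that("blink events lower confidence below threshold and are NONE", {
  spec <- synthetic_spec(duration = 30, dropout_rate = 0, seed = 6)
  rec <- generate_recording(spec)
  blink <- rec$truth == "blink"
  expect_true(any(blink))
  expect_true(all(rec$trace$confidence[blink] < 0.3))
  expect_true(all(as.character(rec$labels)[blink] == "NONE"))
  expect_true(all(as.character(rec$labels)[!blink] != "NONE"))
})

test_that("event-class proportions converge to the requested mix", {
  spec <- synthetic_spec(duration = 600, dropout_rate = 0, seed = 5)
  rec <- generate_recording(spec)
  ev <- labels_to_events(rec$labels)
  tab <- table(factor(ev$cls, levels = c("FIX", "PUR", "SAC")))
  prop <- as.numeric(tab / sum(tab))
  target <- c(spec$mix[["fix_stationary"]] + spec$mix[["fix_vor"]],
              spec$mix[["pur"]], spec$mix[["sac"]])
  target <- target / sum(target)
  expect_true(all(abs(prop - target) < 0.02))
})

test_that("saccade samples are faster than fixation samples in gaze space", {
  spec <- synthetic_spec(duration = 60, seed = 21)
  rec <- generate_recording(spec)
  giw <- gaze_in_world(rec$trace$eih, rec$trace$head)
  n <- nrow(giw)
  tr <- gaze_trace(rec$trace$timestamps, giw, identity_quats(n),
                   rec$trace$confidence, fs = rec$trace$fs)
  vel <- velocity_pipeline(tr)
  lab <- as.character(rec$labels)
  sacv <- vel$we[lab == "SAC" & vel$mask]
  fixv <- vel$we[lab == "FIX" & vel$mask]
  set.seed(1)
  i <- sample(length(sacv), 4000, replace = TRUE)
  j <- sample(length(fixv), 4000, replace = TRUE)
  expect_gte(mean(sacv[i] > fixv[j]), 0.99)
})

test_that("pipeline recovers generated pursuit velocity within filter tolerance", {
  spec <- synthetic_spec(duration = 40, seed = 31, dropout_rate = 0,
                         mix = c(fix_stationary = 0.3, fix_vor = 0, pur = 0.4,
                                 sac = 0.3, blink = 0),
                         tremor_mean = 0.05, tremor_sd = 0.02)
  rec <- generate_recording(spec)
  giw <- gaze_in_world(rec$trace$eih, rec$trace$head)
  tr <- gaze_trace(rec$trace$timestamps, giw, identity_quats(nrow(giw)),
                   rec$trace$confidence, fs = rec$trace$fs)
  vel <- velocity_pipeline(tr)
  ev <- labels_to_events(rec$labels)
  pur <- ev[ev$cls == "PUR", ]
  # interior samples of each pursuit: measured gaze speed vs target speed
  for (i in seq_len(min(5, nrow(pur)))) {
    idx <- (pur$start[i] + 8):(pur$end[i] - 9)
    if (length(idx) < 10) next
    measured <- median(vel$we[idx])
    expect_gt(measured, 4)   # pursuit band lower edge minus tolerance
    expect_lt(measured, 32)
  }
})

test_that("simulated labellers degrade gracefully and controllably", {
  set.seed(81)
  truth <- rand_labels(2000, lens = 10:40)
  # zero perturbation reproduces the truth and perfect agreement
  same <- generate_labeller(truth, jitter_sd_ms = 0, seed = 1)
  expect_identical(as.character(same), as.character(truth))
  expect_equal(cohen_kappa(sample_confusion(truth, same)), 1)

  # jitter within the match windows: all events still matched, l2 > 0
  jit <- generate_labeller(truth, jitter_sd_ms = 10, seed = 2)
  wm <- window_match(truth, jit)
  expect_equal(sum(wm$status == "unmatched"), 0)
  al <- l2_and_overlap(wm)
  expect_gt(mean(al$l2_ms), 0)

  # event-level confusion shows up at the configured rate
  conf <- matrix(c(.8, .2, 0, 0, 1, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  big <- generate_recording(synthetic_spec(duration = 500, dropout_rate = 0,
                                           seed = 9))$labels
  noisy <- generate_labeller(big, confusion = conf, seed = 3)
  cm <- attr(sample_confusion(big, noisy), "normalized")
  expect_equal(unname(cm["FIX", "PUR"]), 0.2, tolerance = 0.05)
})
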