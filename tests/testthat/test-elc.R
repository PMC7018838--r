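test_that("transition extraction: two points per event, NONE owns none", {
  fs <- 100
  tr1 <- extract_transitions(mk_labels(list(list("FIX", 3, 10)), 12, fs))
  expect_equal(nrow(tr1), 2)
  expect_equal(tr1$side, c("onset", "offset"))
  expect_equal(tr1$index, c(3, 10))

  # FFSSPP: three touching events, six transition points
  s <- label_sequence(c("FIX", "FIX", "SAC", "SAC", "PUR", "PUR"), fs = fs)
  tr2 <- extract_transitions(s)
  expect_equal(nrow(tr2), 6)
  expect_equal(tr2$index[tr2$cls == "FIX"], c(1, 3))
  expect_equal(tr2$index[tr2$cls == "SAC"], c(3, 5))
  expect_equal(tr2$index[tr2$cls == "PUR"], c(5, 7))

  # FIX-NONE-FIX: four transitions, the gap belongs to no event
  s2 <- mk_labels(list(list("FIX", 1, 4), list("FIX", 8, 12)), 12, fs)
  tr3 <- extract_transitions(s2)
  expect_equal(nrow(tr3), 4)
  expect_equal(tr3$index, c(1, 4, 8, 12))
})

test_that("ELC identity is perfect on random sequences", {
  set.seed(51)
  for (i in 1:50) {
    s <- rand_labels(sample(100:400, 1))
    r <- elc_evaluate(s, s)
    expect_equal(r$n_unmatched, 0)
    expect_equal(r$n_detached, 0)
    if (r$n_matched > 0) {
      expect_equal(r$kappa_star, 1)
      ov <- r$alignment_summary[r$alignment_summary$class == "overall", ]
      expect_equal(ov$l2_mean, 0)
      expect_equal(ov$Or_mean, 1)
    }
  }
})

test_that("walkthrough fixture reproduces the matched/unmatched/detached partition", {
  fx <- elc_walkthrough()
  wm <- window_match(fx$ref, fx$test)
  # fragmented long fixation matched via first/last fragment boundaries
  expect_equal(wm$status, c("matched", "unmatched", "matched",
                            "detached", "unmatched", "unmatched"))
  expect_equal(wm$ref_events$cls[wm$status == "detached"], "FIX")
  # spurious saccade inside the fixation charges the F/S counter
  cm <- elc_confusion(wm, fx$ref)
  expect_equal(unname(cm$confusion["FIX", "SAC"]), 1)
  expect_equal(unname(cm$confusion["FIX", "FIX"]), 2)
  expect_equal(unname(cm$confusion["SAC", "unmatched"]), 2)
  expect_equal(cm$n_matched, 2)
  expect_equal(cm$n_detached, 1)

  # reversing the direction changes the partition: the fragments and the
  # spurious saccade are no longer matched, and the detached count changes
  wm_r <- window_match(fx$test, fx$ref)
  frag_status <- wm_r$status[wm_r$ref_events$start %in% c(49, 90, 96)]
  expect_true(all(frag_status != "matched"))
  expect_false(sum(wm_r$status == "detached") == sum(wm$status == "detached"))
})

test_that("detached requires full same-class overlap with an unmatched transition", {
  fs <- 200
  # blink-bounded reference event inside a longer same-class test event
  # whose offset lies outside the window
  ref <- mk_labels(list(list("FIX", 51, 91)), 140, fs)
  test <- mk_labels(list(list("FIX", 49, 120)), 140, fs)
  wm <- window_match(ref, test)
  expect_equal(wm$status, "detached")
  # different class: merely unmatched
  ref2 <- mk_labels(list(list("PUR", 51, 91)), 140, fs)
  expect_equal(window_match(ref2, test)$status, "unmatched")
})

test_that("l2 and overlap: 3-4-5 triangle and set oracle", {
  fs <- 1000   # 1 sample = 1 ms
  ref <- mk_labels(list(list("FIX", 101, 201)), 400, fs)
  test <- mk_labels(list(list("FIX", 104, 205)), 400, fs)
  wm <- window_match(ref, test)
  al <- l2_and_overlap(wm)
  expect_equal(al$l2_ms, 5)   # start offset 3 ms, end offset 4 ms
  inter <- length(intersect(101:200, 104:204))
  uni <- length(union(101:200, 104:204))
  expect_equal(al$overlap, inter / uni)
})

test_that("window bound and partition invariants hold on jittered sequences", {
  set.seed(52)
  bound <- sqrt(2) * 35 + 1e-9
  for (i in 1:30) {
    a <- rand_labels(500, lens = 10:40)
    b <- generate_labeller(a, jitter_sd_ms = 10, seed = i)
    wm <- window_match(a, b)
    expect_equal(length(wm$status), nrow(wm$ref_events))
    expect_setequal(unique(wm$status),
                    intersect(c("matched", "unmatched", "detached"),
                              unique(wm$status)))
    al <- l2_and_overlap(wm)
    if (nrow(al)) {
      expect_true(all(al$l2_ms <= bound))
      expect_true(all(al$overlap > 0 & al$overlap <= 1))
    }
  }
})

test_that("shrinking windows never increases the matched count", {
  set.seed(53)
  for (i in 1:15) {
    a <- rand_labels(400, lens = 8:30)
    b <- generate_labeller(a, jitter_sd_ms = 12, seed = 100 + i)
    wide <- window_match(a, b, elc_config(25, 35))
    narrow <- window_match(a, b, elc_config(10, 15))
    expect_lte(sum(narrow$status == "matched"), sum(wide$status == "matched"))
  }
})

test_that("offset correction averages boundaries and relabels displaced samples", {
  fs <- 1000
  # matched onsets at samples 10 (ref) and 14 (test) move to 12
  ref <- mk_labels(list(list("FIX", 10, 100)), 150, fs)
  test <- mk_labels(list(list("FIX", 14, 100)), 150, fs)
  wm <- window_match(ref, test)
  co <- correct_offsets(ref, test, wm)
  expect_equal(labels_to_events(co$ref)$start, 12)
  expect_equal(labels_to_events(co$test)$start, 12)
  # displaced samples 12-13 in the test were NONE; the correction assigns
  # them the event class
  expect_identical(as.character(co$test)[12:13], c("FIX", "FIX"))
  # ref samples 10-11 fell outside the corrected event; test had NONE there
  expect_identical(as.character(co$ref)[10:11], c("NONE", "NONE"))

  # aligned sequences are untouched
  co2 <- correct_offsets(ref, ref, window_match(ref, ref))
  expect_identical(as.character(co2$ref), as.character(ref))
  expect_identical(as.character(co2$test), as.character(ref))
})

test_that("re-matching after correction leaves zero residual timing error", {
  set.seed(54)
  for (i in 1:25) {
    a <- rand_labels(600, lens = 15:40)
    b <- generate_labeller(a, jitter_sd_ms = 8, seed = i)
    wm <- window_match(a, b)
    co <- correct_offsets(a, b, wm)
    al <- l2_and_overlap(window_match(co$ref, co$test))
    if (nrow(al)) expect_lt(max(al$l2_ms), 1e-9)
  }
})

test_that("counting detached as matched never lowers per-class F1", {
  set.seed(55)
  for (i in 1:15) {
    a <- rand_labels(400, lens = 5:25)
    b <- generate_labeller(a, jitter_sd_ms = 20, frag_rate = 0.3, seed = i)
    wm <- window_match(a, b)
    f_off <- elc_confusion(wm, a, elc_config())$per_class
    f_on <- elc_confusion(wm, a, elc_config(count_detached_as_matched = TRUE))$per_class
    ok <- !is.na(f_off$f1) & !is.na(f_on$f1)
    expect_true(all(f_on$f1[ok] >= f_off$f1[ok] - 1e-12))
  }
})

test_that("bidirectional evaluation averages the two directions", {
  fx <- elc_walkthrough()
  fwd <- elc_evaluate(fx$ref, fx$test)
  rev <- elc_evaluate(fx$test, fx$ref)
  both <- elc_evaluate(fx$ref, fx$test, bidirectional = TRUE)
  expect_equal(both$averaged$kappa_star,
               mean(c(fwd$kappa_star, rev$kappa_star)))
  expect_equal(both$forward$n_detached, fwd$n_detached)
  expect_equal(both$reverse$n_detached, rev$n_detached)
})
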