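test_that("majority vote scores by the modal label inside each reference event", {
  fs <- 100
  ref_lab <- mk_labels(list(list("FIX", 1, 11), list("SAC", 11, 15)), 20, fs)
  ref <- labels_to_events(ref_lab)
  expect_equal(majority_vote_score(ref, ref_lab)$overall, 1)

  # 10-sample FIX with 6 FIX + 4 SAC test samples: majority holds
  test <- mk_labels(list(list("FIX", 1, 7), list("SAC", 7, 15)), 20, fs)
  mv <- majority_vote_score(ref, test)
  expect_equal(unname(mv$per_class["FIX"]), 1)
  expect_equal(unname(mv$per_class["SAC"]), 1)

  # fragmentation with an intact majority is not penalized (known weakness)
  ref2_lab <- mk_labels(list(list("FIX", 1, 31)), 40, fs)
  test2 <- mk_labels(list(list("FIX", 1, 14), list("SAC", 14, 17),
                          list("FIX", 17, 31)), 40, fs)
  expect_equal(majority_vote_score(labels_to_events(ref2_lab), test2)$overall, 1)
})

test_that("hooge event F1 and timing offsets under earliest-overlap matching", {
  fs <- 100
  ref <- labels_to_events(mk_labels(list(list("FIX", 1, 21), list("SAC", 25, 31),
                                         list("FIX", 35, 60)), 70, fs))
  res <- hooge_event_f1(ref, ref, "FIX")
  expect_equal(res$f1, 1)
  expect_equal(res$rto_onset, 0)
  expect_equal(res$rtd_onset, 0)

  # all test events shifted +2 samples at fs = 100 -> +20 ms on both bounds
  test <- labels_to_events(mk_labels(list(list("FIX", 3, 23), list("SAC", 27, 33),
                                          list("FIX", 37, 62)), 70, fs))
  res2 <- hooge_event_f1(ref, test, "FIX")
  expect_equal(res2$f1, 1)
  expect_equal(res2$rto_onset, 20)
  expect_equal(res2$rto_offset, 20)
  expect_equal(res2$rtd_onset, 0)

  # earliest-overlap pathology: a test event beginning near the reference
  # offset still matches first, inflating RTO
  ref3 <- labels_to_events(mk_labels(list(list("FIX", 1, 50)), 120, fs))
  test3 <- labels_to_events(mk_labels(list(list("FIX", 48, 110)), 120, fs))
  res3 <- hooge_event_f1(ref3, test3, "FIX")
  expect_equal(res3$f1, 1)
  expect_equal(res3$rto_onset, 470)   # 47 samples late
})

test_that("zemblys event kappa matches by largest overlap ratio", {
  fs <- 100
  ref <- labels_to_events(mk_labels(list(list("FIX", 1, 41)), 60, fs))
  # identity
  z0 <- zemblys_event_kappa(ref, ref)
  expect_equal(z0$kappa, 1)
  expect_equal(unname(z0$confusion["FIX", "FIX"]), 1)

  # a saccade maximally overlapping a reference fixation -> FIX/SAC entry
  test <- labels_to_events(mk_labels(list(list("SAC", 1, 35), list("FIX", 35, 41)),
                                     60, fs))
  z1 <- zemblys_event_kappa(ref, test)
  expect_equal(unname(z1$confusion["FIX", "SAC"]), 1)

  # fragmented fixation matches its largest fragment
  ref2 <- labels_to_events(mk_labels(list(list("FIX", 1, 61)), 80, fs))
  test2 <- labels_to_events(mk_labels(list(list("FIX", 1, 21), list("SAC", 21, 25),
                                           list("FIX", 25, 61)), 80, fs))
  z2 <- zemblys_event_kappa(ref2, test2)
  expect_equal(unname(z2$confusion["FIX", "FIX"]), 1)   # largest fragment, same class

  # nothing overlapping -> unmatched column
  test3 <- labels_to_events(mk_labels(list(list("SAC", 70, 75)), 80, fs))
  z3 <- zemblys_event_kappa(ref2, test3)
  expect_equal(unname(z3$confusion["FIX", "unmatched"]), 1)
})

test_that("event error rate equals a dynamic-programming Levenshtein oracle", {
  fs <- 100
  ref <- labels_to_events(mk_labels(list(list("FIX", 1, 10), list("SAC", 10, 13),
                                         list("FIX", 13, 25), list("PUR", 25, 40)),
                                    45, fs))
  expect_equal(event_error_rate(ref, ref), 0)

  # one insertion into a 4-event reference -> 1/4
  test <- labels_to_events(mk_labels(list(list("FIX", 1, 10), list("SAC", 10, 13),
                                          list("FIX", 13, 20), list("SAC", 20, 23),
                                          list("PUR", 25, 40)), 45, fs))
  expect_equal(event_error_rate(ref, test), 0.25)

  set.seed(41)
  for (i in 1:25) {
    a <- rand_labels(sample(50:150, 1), lens = 2:8)
    b <- rand_labels(sample(50:150, 1), lens = 2:8)
    ea <- labels_to_events(a); eb <- labels_to_events(b)
    if (nrow(ea) == 0) next
    code <- c(FIX = "F", PUR = "P", SAC = "S")
    oracle <- dp_levenshtein(paste(code[ea$cls], collapse = ""),
                             paste(code[eb$cls], collapse = "")) / nrow(ea)
    expect_equal(event_error_rate(ea, eb), oracle)
  }
  expect_error(event_error_rate(labels_to_events(label_sequence(rep("NONE", 5), fs = 100)),
                                ref), "empty reference")
})

test_that("all event metrics are perfect on identical inputs", {
  set.seed(42)
  s <- rand_labels(400, lens = 5:30)
  ev <- labels_to_events(s)
  expect_equal(majority_vote_score(ev, s)$overall, 1)
  for (cl in intersect(unique(ev$cls), c("FIX", "PUR", "SAC")))
    expect_equal(hooge_event_f1(ev, ev, cl)$f1, 1)
  expect_equal(zemblys_event_kappa(ev, ev)$kappa, 1)
  expect_equal(event_error_rate(ev, ev), 0)
})
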