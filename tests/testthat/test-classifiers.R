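# shared small cohort for the classifier tests (built once per file)
cls_cohort <- generate_cohort(4, synthetic_spec(duration = 12, seed = 900))

test_that("random forest separates synthetic gaze dynamics on a held-out subject", {
  s <- 6
  feats <- lapply(cls_cohort, function(d) {
    f <- extract_window_features(d$vel, s); attr(f, "fs") <- d$vel$fs; f
  })
  X <- do.call(rbind, lapply(1:3, function(i) feats[[i]]$X))
  y <- unlist(lapply(1:3, function(i) as.character(cls_cohort[[i]]$labels)))
  fit <- gaze_rf(X, y, seed = 5)
  expect_equal(fit$n_trees, 40)
  expect_equal(fit$min_leaf, 30)
  expect_equal(fit$mtry, floor(sqrt(fit$g)))
  pred <- predict(fit, feats[[4]])
  cm <- sample_confusion(cls_cohort[[4]]$labels, pred)
  expect_gte(cohen_kappa(cm), 0.9)
  # masked samples pass through unscored
  expect_true(all(as.character(pred)[!feats[[4]]$mask] == "NONE"))
})

test_that("single-class training yields constant predictions", {
  set.seed(71)
  X <- matrix(rnorm(200), 100, 2)
  fit <- suppressWarnings(gaze_rf(X, rep("FIX", 100), seed = 1))
  pred <- predict(fit, matrix(rnorm(40), 20, 2))
  expect_true(all(as.character(pred) == "FIX"))
})

test_that("generalized Dice loss: zero at perfection, hand value, permutation symmetric", {
  targets <- diag(3)[rep(1:3, each = 4), ]
  expect_equal(generalized_dice_loss(targets, targets), 0)
  uniform <- matrix(1 / 3, 12, 3)
  # balanced classes, uniform predictions: 1 - 2*(1/3)/2 = 2/3
  expect_equal(generalized_dice_loss(uniform, targets), 2 / 3)
  set.seed(72)
  p <- matrix(runif(30), 10, 3); p <- p / rowSums(p)
  g <- diag(3)[sample(1:3, 10, replace = TRUE), ]
  perm <- c(3, 1, 2)
  expect_equal(generalized_dice_loss(p, g),
               generalized_dice_loss(p[, perm], g[, perm]), tolerance = 1e-12)
  expect_gte(generalized_dice_loss(p, g), 0)
  expect_lte(generalized_dice_loss(p, g), 1)
})

test_that("C++ GRU gradients agree with finite differences", {
  set.seed(73)
  k <- 2; h <- 3; d <- 4; B <- 2; Tn <- 6
  X <- array(rnorm(d * B * Tn), dim = c(d, B, Tn))
  y <- sample(c(0:2, -1L), B * Tn, replace = TRUE)
  w <- runif(B * Tn)
  for (bidir in c(TRUE, FALSE)) {
    params <- gazekit:::rnn_init_params(d, k = k, h = h, bidir = bidir,
                                        fc_width = 5)
    res <- gazekit:::rnn_grad_cpp(params, X, y, w, k, h, bidir, 0, FALSE, 1.0)
    for (nm in names(params)) {
      g <- res$grads[[nm]]
      for (ii in sample(length(params[[nm]]), min(3, length(params[[nm]])))) {
        eps <- 1e-6
        p1 <- params; p1[[nm]][ii] <- p1[[nm]][ii] + eps
        p2 <- params; p2[[nm]][ii] <- p2[[nm]][ii] - eps
        fd <- (gazekit:::rnn_grad_cpp(p1, X, y, w, k, h, bidir, 0, FALSE, 1.0)$loss -
               gazekit:::rnn_grad_cpp(p2, X, y, w, k, h, bidir, 0, FALSE, 1.0)$loss) /
          (2 * eps)
        expect_equal(g[ii], fd, tolerance = 1e-4)
      }
    }
  }
})

test_that("GRU model: output shape, overfitting capacity, determinism", {
  set.seed(74)
  xs <- lapply(1:2, function(i) vel_channels(cls_cohort[[i]]$vel, "full")[1:400, ])
  ys <- lapply(1:2, function(i) as.character(cls_cohort[[i]]$labels)[1:400])
  fit <- gaze_rnn(xs, ys, variant = "bidirectional", epochs = 60,
                  dropout = 0, batch_size = 1, seed = 7)
  pr <- predict(fit, xs[[1]], probs = TRUE)
  expect_equal(dim(pr), c(400, 3))
  expect_equal(rowSums(pr), rep(1, 400), tolerance = 1e-9)
  # capacity: training accuracy without dropout
  acc <- mean(vapply(1:2, function(i) {
    lab <- as.character(predict(fit, xs[[i]], fs = 120))
    sel <- ys[[i]] != "NONE"
    mean(lab[sel] == ys[[i]][sel])
  }, 1))
  expect_gte(acc, 0.97)
  # same seed, same data -> identical parameters
  fit2 <- gaze_rnn(xs, ys, variant = "bidirectional", epochs = 5,
                   dropout = 0, batch_size = 1, seed = 7)
  fit3 <- gaze_rnn(xs, ys, variant = "bidirectional", epochs = 5,
                   dropout = 0, batch_size = 1, seed = 7)
  expect_identical(fit2$params, fit3$params)
})

test_that("forward GRU is causal: later inputs cannot change earlier predictions", {
  set.seed(75)
  xs <- lapply(1:2, function(i) vel_channels(cls_cohort[[i]]$vel, "full")[1:300, ])
  ys <- lapply(1:2, function(i) as.character(cls_cohort[[i]]$labels)[1:300])
  fit <- gaze_rnn(xs, ys, variant = "forward", epochs = 3, batch_size = 1,
                  seed = 2)
  x <- xs[[1]]
  p1 <- predict(fit, x, probs = TRUE)
  x2 <- x; x2[201:300, ] <- 1e3
  p2 <- predict(fit, x2, probs = TRUE)
  expect_equal(p1[1:200, ], p2[1:200, ], tolerance = 1e-12)
  # the bidirectional variant is not causal
  fitb <- gaze_rnn(xs, ys, variant = "bidirectional", epochs = 3,
                   batch_size = 1, seed = 2)
  q1 <- predict(fitb, x, probs = TRUE)
  q2 <- predict(fitb, x2, probs = TRUE)
  expect_gt(max(abs(q1[1:200, ] - q2[1:200, ])), 1e-6)
})

test_that("LOSO: run count, fold balance, holdout isolation, no NONE scoring", {
  res <- crossvalidate_loso(cls_cohort[1:2], model = "rf", window_ms = 100,
                            seed = 3, elc = FALSE)
  expect_length(res$per_subject, 2)   # exactly one run per subject

  folds <- gazekit:::build_folds(lapply(cls_cohort, `[[`, "labels"),
                                 n_folds = 5, seed = 4)
  for (cl in c("FIX", "SAC")) {
    counts <- table(factor(folds$events$fold[folds$events$cls == cl],
                           levels = 1:5))
    expect_lte(max(counts) - min(counts), max(1, ceiling(0.1 * mean(counts))))
  }
  # pursuit events are assigned whole: every PUR event sits in one fold
  pur <- folds$events[folds$events$cls == "PUR", ]
  if (nrow(pur)) expect_true(all(pur$fold %in% 1:5))

  # classifier output is never scored on NONE samples: the confusion total
  # cannot exceed the count of non-NONE reference samples
  d <- cls_cohort[[2]]
  pred <- res$per_subject[[d$subject]]
  expect_lte(sum(pred$confusion), sum(as.character(d$labels) != "NONE"))
})
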