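test_that("relu satisfies its defining identities", {
  expect_equal(relu(-2), 0)
  expect_equal(relu(3), 3)
  set.seed(1)
  x <- rnorm(50)
  expect_equal(relu(x) + relu(-x), abs(x))
})

test_that("conv2d matches the brute-force flip-and-slide sum", {
  set.seed(2)
  X <- matrix(rnorm(64), 8, 8)
  k <- matrix(rnorm(9), 3, 3)
  full <- conv2d(X, k, mode = "full")
  brute <- matrix(0, 10, 10)
  for (l in 1:10) for (b in 1:10) {
    s <- 0
    for (m in 1:3) for (n in 1:3) {
      i <- l - m + 1; j <- b - n + 1
      if (i >= 1 && i <= 8 && j >= 1 && j <= 8) s <- s + X[i, j] * k[m, n]
    }
    brute[l, b] <- s
  }
  expect_lt(max(abs(full - brute)), 1e-12)
  # identity kernel
  ident <- matrix(0, 3, 3); ident[2, 2] <- 1
  expect_equal(conv2d(X, ident), X)
  # linearity
  Y <- matrix(rnorm(64), 8, 8)
  expect_lt(max(abs(conv2d(2 * X + 3 * Y, k) -
                    (2 * conv2d(X, k) + 3 * conv2d(Y, k)))), 1e-9)
  expect_error(conv2d(matrix(0, 2, 2), k), "larger")
})

test_that("max pooling halves each dimension taking block maxima", {
  X <- matrix(1:16, 4, 4, byrow = TRUE)
  expect_equal(maxpool(X), matrix(c(6, 14, 8, 16), 2, 2))
  expect_equal(maxpool(matrix(7, 4, 4)), matrix(7, 2, 2))
  set.seed(3)
  Z <- matrix(rnorm(64), 8, 8)
  expect_equal(dim(maxpool(Z)), c(4L, 4L))
  brute <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4)
    brute[i, j] <- max(Z[2 * i - 1:0, 2 * j - 1:0])
  expect_equal(maxpool(Z), brute)
  expect_warning(maxpool(matrix(0, 3, 4)), "padded")
})

test_that("softmax is a shift-invariant probability vector", {
  expect_equal(softmax(c(0, 0)), c(0.5, 0.5))
  set.seed(4)
  for (i in 1:5) {
    a <- rnorm(10)
    p <- softmax(a)
    expect_lt(abs(sum(p) - 1), 1e-12)
    expect_lt(max(abs(softmax(a + 3.7) - p)), 1e-12)
  }
  expect_equal(which.max(softmax(c(1, 5, 2))), 2L)
})

test_that("i-AlexNet builds with the 50-unit head and valid forward pass", {
  cfg <- model_config(input_length = 24, n_classes = 2, seed = 5)
  m <- build_ialexnet(cfg)
  expect_equal(ncol(m$params$fc_head_W), 50)
  expect_equal(length(m$params$fc_head_b), 50)
  set.seed(6)
  X <- matrix(rnorm(4 * 24), 4, 24)
  P <- predict(m, X)
  expect_equal(dim(P), c(4L, 2L))
  expect_lt(max(abs(rowSums(P) - 1)), 1e-9)
  # deterministic initialization
  m2 <- build_ialexnet(cfg)
  expect_identical(m$params, m2$params)
  # too-short input names the minimal admissible length
  expect_error(build_ialexnet(model_config(input_length = 4)), "minimum 8")
})

test_that("SGD-momentum step follows the update rule exactly", {
  # quadratic G = delta^2, gradient 2*delta, alpha = 0
  st <- list(params = list(d = 1), prev_params = list(d = 1))
  st <- sgd_momentum_step(st, list(d = 2 * st$params$d), beta = 0.1, alpha = 0)
  expect_equal(st$params$d, 0.8)
  # zero gradient, no momentum: parameters unchanged
  st0 <- list(params = list(d = 0.3), prev_params = list(d = 0.3))
  st0 <- sgd_momentum_step(st0, list(d = 0), beta = 0.1, alpha = 0)
  expect_equal(st0$params$d, 0.3)
  # with momentum the quadratic recurrence converges
  st2 <- list(params = list(d = 1), prev_params = list(d = 1))
  for (i in 1:200)
    st2 <- sgd_momentum_step(st2, list(d = 2 * st2$params$d),
                             beta = 0.1, alpha = 0.5)
  expect_lt(abs(st2$params$d), 1e-6)
  # independent oracle: the same scalar recurrence written directly
  d <- 1; dp <- 1
  for (i in 1:200) { dn <- d - 0.1 * 2 * d + 0.5 * (d - dp); dp <- d; d <- dn }
  expect_equal(st2$params$d, d)
})

test_that("training separates a 3-sigma fixture and is reproducible", {
  fx <- make_separable_features(seed = 7)
  cfg <- model_config(input_length = 16, n_classes = 2, epochs = 30, seed = 8)
  m <- train_ialexnet(build_ialexnet(cfg), fx$X, fx$y)
  P <- predict(m, fx$X)
  acc <- mean(colnames(P)[max.col(P, ties.method = "first")] == fx$y)
  expect_gte(acc, 0.99)
  # descent
  expect_lte(m$history$train_loss[10], m$history$train_loss[1])
  # bit-identical loss history for the same seed and data
  m2 <- train_ialexnet(build_ialexnet(cfg), fx$X, fx$y)
  expect_identical(m$history$train_loss, m2$history$train_loss)
})

test_that("training rejects degenerate inputs and diverging rates", {
  fx <- make_separable_features(n = 40, seed = 9)
  cfg <- model_config(input_length = 16, n_classes = 2, epochs = 2, seed = 1)
  expect_error(train_ialexnet(build_ialexnet(cfg), fx$X, rep("one", 40)),
               "two classes")
  # without the (stabilizing) response normalization an absurd rate overflows
  cfg_bad <- model_config(input_length = 16, n_classes = 2, epochs = 20,
                          lr = 1e4, seed = 1, norm = "none")
  expect_error(train_ialexnet(build_ialexnet(cfg_bad), fx$X, fx$y),
               "learning rate|diverged")
})

test_that("metrics match hand-computed values on a known confusion matrix", {
  truth <- c(rep("a", 50), rep("b", 50))
  pred <- c(rep("a", 50), rep("a", 10), rep("b", 40))
  m <- compute_metrics(truth, pred)
  expect_equal(unname(m$confusion["a", "a"]), 50)
  expect_equal(unname(m$confusion["b", "a"]), 10)
  expect_equal(m$accuracy, 90)
  expect_equal(100 * m$confusion["b", "b"] / sum(m$confusion["b", ]), 80)
  expect_equal(sum(m$confusion), 100)
  # perfect prediction
  mp <- compute_metrics(truth, truth)
  expect_equal(mp$accuracy, 100)
  expect_equal(mp$f1, 100)
  expect_true(all(mp$confusion[upper.tri(mp$confusion)] == 0))
})

test_that("macro F1 equals the brute-force per-class harmonic mean", {
  set.seed(10)
  for (i in 1:5) {
    truth <- sample(letters[1:3], 120, replace = TRUE)
    pred <- sample(letters[1:3], 120, replace = TRUE)
    m <- compute_metrics(truth, pred)
    f1s <- vapply(letters[1:3], function(cl) {
      tp <- sum(truth == cl & pred == cl)
      fp <- sum(truth != cl & pred == cl)
      fn <- sum(truth == cl & pred != cl)
      prec <- if (tp + fp > 0) tp / (tp + fp) else 0
      rec <- if (tp + fn > 0) tp / (tp + fn) else 0
      if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    }, numeric(1))
    expect_equal(m$f1, 100 * mean(f1s))
  }
})

test_that("two-stage decision applies the confirmation rules", {
  probs_anom <- c(normal = 0.1, anomalous = 0.9)
  probs_norm <- c(normal = 0.9, anomalous = 0.1)
  tmpl <- sin(seq(0, pi, length.out = 50))
  beat_good <- tmpl + rnorm(50, 0, 0.01)
  rr <- c(0.85, 0.8, 0.82, 0.81)
  # anomalous stage-1 verdict passes through regardless of evidence
  expect_equal(two_stage_decision(probs_anom, rr, beat_good, tmpl), "anomalous")
  # confirmed normal
  expect_equal(two_stage_decision(probs_norm, rr, beat_good, tmpl), "normal")
  # premature beat: preceding RR 50% short escalates
  rr_prem <- c(0.85, 0.8, 0.82, 0.41)
  expect_equal(two_stage_decision(probs_norm, rr_prem, beat_good, tmpl),
               "anomalous")
  # template mismatch escalates
  set.seed(11)
  expect_equal(two_stage_decision(probs_norm, rr, rnorm(50), tmpl), "anomalous")
  # too little context: stage-1 verdict alone
  expect_equal(two_stage_decision(probs_norm, c(0.4), rnorm(50), tmpl), "normal")
})

test_that("two-stage decision flags premature beats in a synthetic record", {
  cfg <- synth_config(fs = 360, duration = 60, heart_rate = 70,
                      anomaly_fraction = 0.15, seed = 12)
  rec <- generate_clean_ecg(cfg)
  segs <- segment_beats(rec, rec$r_peaks)
  labs <- vapply(segs$beats, `[[`, character(1), "label")
  rr_all <- diff(rec$r_peaks) / rec$fs
  norm_idx <- which(labs == "normal")
  tmpl <- Reduce(`+`, lapply(segs$beats[norm_idx[1:5]], `[[`, "samples")) / 5
  # a classifier that always says "normal": the evidence stage alone must
  # still catch most premature beats
  verdicts <- vapply(6:length(segs$beats), function(i) {
    two_stage_decision(c(normal = 1, anomalous = 0),
                       rr_all[seq_len(i - 1)],
                       segs$beats[[i]]$samples, tmpl)
  }, character(1))
  truth <- labs[6:length(segs$beats)]
  caught <- mean(verdicts[truth == "anomalous"] == "anomalous")
  expect_gte(caught, 0.7)
})
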