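test_that("fractional DCT reduces to the classical transform at a = 1", {
  cfg <- feature_config(fdct_order = 1, fdct_coeffs = 8)
  # constant beat: only the k = 0 coefficient is nonzero
  f <- fdct_features(rep(2, 32), cfg)
  expect_gt(f[1], 0)
  expect_true(all(abs(f[-1]) < 1e-9))
  # Parseval / orthonormality
  set.seed(1)
  x <- rnorm(64)
  C <- cardiosift:::dct2_matrix(64)
  expect_lt(abs(sqrt(sum((C %*% x)^2)) - sqrt(sum(x^2))), 1e-9)
  expect_lt(max(abs(crossprod(C) - diag(64))), 1e-9)
})

test_that("fractional DCT endpoints: a = 0 is the identity", {
  set.seed(2)
  x <- rnorm(32)
  f <- fdct_features(x, feature_config(fdct_order = 0, fdct_coeffs = 32))
  expect_lt(max(abs(f - abs(x))), 1e-9)
  expect_error(fdct_features(x, feature_config(fdct_order = 2)), "\\[0, 1\\]")
})

test_that("fractional DCT power interpolates the transform (matrix property)", {
  Ch <- cardiosift:::fdct_matrix(24, 0.5)
  C1 <- cardiosift:::fdct_matrix(24, 1)
  expect_lt(max(Mod(Ch %*% Ch - C1)), 1e-8)   # C^0.5 %*% C^0.5 == C
})

test_that("scalogram is zero for zero input, localizes impulses, scales linearly", {
  cfg <- feature_config(radon_scales = 12)
  z <- beat_scalogram(numeric(48), cfg)
  expect_true(all(z == 0))
  expect_equal(dim(z), c(48, 48))
  # impulse: each row's energy peak stays near the impulse column
  x <- numeric(48); x[24] <- 1
  sg <- beat_scalogram(x, cfg)
  peaks <- apply(sg, 1, which.max)
  expect_true(all(abs(peaks - 24) <= 2))
  # |a|-homogeneity
  set.seed(3)
  b <- rnorm(48)
  expect_lt(max(abs(beat_scalogram(-2 * b, cfg) - 2 * beat_scalogram(b, cfg))),
            1e-9)
})

test_that("radon projection conserves mass and matches column sums at 0 deg", {
  img <- matrix(0, 65, 65)
  img[33, 33] <- 1
  for (ang in c(0, 13, 45, 90, 117)) {
    expect_lt(abs(sum(radon_projection(img, ang)) - 1), 1e-9)
  }
  # smooth blob inside the inscribed disc: <= 1% mass error at any angle
  blob <- outer(1:65, 1:65, function(i, j) exp(-((i - 33)^2 + (j - 25)^2) / 40))
  for (ang in c(20, 77, 150)) {
    expect_lt(abs(sum(radon_projection(blob, ang)) - sum(blob)) / sum(blob),
              0.01)
  }
  expect_equal(radon_projection(blob, 0), colSums(blob))
  expect_error(radon_projection(matrix(0, 3, 4), 10), "square")
})

test_that("radon-wavelet features are non-negative energies with quadratic scaling", {
  cfg <- feature_config(radon_angles = c(0, 45, 90), radon_scales = 8)
  expect_true(all(radon_wavelet_features(numeric(32), cfg) == 0))
  set.seed(4)
  b <- rnorm(32)
  f1 <- radon_wavelet_features(b, cfg)
  f2 <- radon_wavelet_features(2 * b, cfg)
  expect_true(all(f1 >= 0))
  expect_length(f1, 6)
  expect_lt(max(abs(f2 - 4 * f1) / pmax(f1, 1e-12)), 0.01)
})

test_that("fractional Fourier transform: identity, DFT match, additivity, unitarity", {
  set.seed(5)
  for (N in c(16, 63, 120)) {
    x <- rnorm(N)
    expect_lt(max(Mod(frft(x, 0) - x)), 1e-9)
    W <- exp(-2i * pi * outer(0:(N - 1), 0:(N - 1)) / N) / sqrt(N)
    expect_lt(max(Mod(frft(x, 1) - W %*% x)), 1e-6)
    expect_lt(max(Mod(frft(frft(x, 0.5), 0.5) - frft(x, 1))), 1e-6)
    for (a in c(0.3, 1.7, 2.5))
      expect_lt(abs(sqrt(sum(Mod(frft(x, a))^2)) - sqrt(sum(x^2))), 1e-6)
  }
  expect_error(frft(1:3, 0.5), "length")
  expect_error(frft(rnorm(8), 4), "\\[0, 4\\)")
})

test_that("periodized wavelet decomposition conserves energy (Parseval)", {
  set.seed(6)
  for (wv in c("haar", "db4")) {
    x <- rnorm(128)
    d <- dwt_periodic(x, wv, 3)
    e <- sum(unlist(d$details)^2) + sum(d$approx^2)
    expect_lt(abs(e - sum(x^2)), 1e-6)
  }
  expect_error(dwt_periodic(rnorm(100), "db4", 3), "divisible")
})

test_that("fractional-wavelet features: zero input, order-0 reduction, Parseval", {
  cfg <- feature_config(frwt_fraction = 0.5, wavelet_levels = 3)
  expect_true(all(fractional_wavelet_features(numeric(64), cfg) == 0))
  set.seed(7)
  b <- rnorm(64)
  f0 <- fractional_wavelet_features(b, feature_config(frwt_fraction = 0))
  d <- dwt_periodic(abs(b), "db4", 3)
  expect_lt(abs(f0[["frwt_d1_energy"]] - sum(d$details[[1]]^2)), 1e-9)
  # energy features sum to the transformed signal energy
  f <- fractional_wavelet_features(b, cfg)
  e <- sum(f[grepl("energy", names(f))])
  expect_lt(abs(e - sum(Mod(frft(b, 0.5))^2)), 1e-6)
  expect_length(f, 3 * 4)
  expect_error(fractional_wavelet_features(rnorm(4), cfg), "too deep")
})

test_that("feature matrix assembly: shapes, z-scoring, determinism, reuse", {
  set.seed(8)
  beats <- replicate(5, rnorm(64), simplify = FALSE)
  cfg <- feature_config(fdct_coeffs = 8, radon_angles = c(0, 90),
                        radon_scales = 8, wavelet_levels = 3)
  fm <- extract_feature_matrix(beats, cfg)
  expect_equal(ncol(fm$values), 8 + 2 * 2 + 3 * 4)
  nonconst <- apply(fm$values, 2, sd) > 1e-9
  expect_lt(max(abs(colMeans(fm$values))), 1e-9)
  expect_lt(max(abs(apply(fm$values[, nonconst], 2, sd) - 1)), 1e-9)
  # identical beats map to identical rows
  fm2 <- extract_feature_matrix(rep(list(beats[[1]]), 5), cfg)
  expect_true(all(apply(fm2$values, 2, function(col) max(abs(col - col[1]))) == 0))
  # determinism
  fm3 <- extract_feature_matrix(beats, cfg)
  expect_identical(fm$values, fm3$values)
  # scaling reuse applies training statistics unchanged
  fm4 <- extract_feature_matrix(beats[1:2], cfg, scaling = fm$scaling)
  expect_equal(fm4$values[1, ], fm$values[1, ])
})
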