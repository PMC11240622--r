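# Shared fixtures, all built in code at test time.

# Match detected against true R-peak indices within a time tolerance;
# greedy one-to-one matching in index order.
match_peaks <- function(detected, truth, fs, tol_s = 0.05) {
  tol <- tol_s * fs
  used <- rep(FALSE, length(truth))
  tp <- 0L
  for (d in detected) {
    j <- which(!used & abs(truth - d) <= tol)
    if (length(j)) { used[j[1L]] <- TRUE; tp <- tp + 1L }
  }
  c(sensitivity = tp / max(1L, length(truth)),
    ppv = tp / max(1L, length(detected)))
}

# Two-class Gaussian feature table with 5 informative features among d.
# The informative block carries a total Mahalanobis class separation of
# `separation` standard deviations (per-feature shift separation/sqrt(5)),
# so each informative feature contributes measurably to the surrogate.
make_planted_features <- function(n = 200, d = 20, n_informative = 5,
                                  separation = 3, seed = 1) {
  set.seed(seed)
  y <- rep(c("a", "b"), each = n / 2)
  X <- matrix(rnorm(n * d), n, d)
  X[y == "b", seq_len(n_informative)] <-
    X[y == "b", seq_len(n_informative)] + separation / sqrt(n_informative)
  colnames(X) <- sprintf("f%02d", seq_len(d))
  list(X = X, y = y, informative = seq_len(n_informative))
}

# Linearly separable two-class fixture for training checks (3 sigma shift on
# a few coordinates).
make_separable_features <- function(n = 200, d = 16, seed = 1) {
  set.seed(seed)
  y <- rep(c("neg", "pos"), each = n / 2)
  X <- matrix(rnorm(n * d), n, d)
  X[y == "pos", 1:4] <- X[y == "pos", 1:4] + 3
  colnames(X) <- sprintf("f%02d", seq_len(d))
  list(X = X, y = y)
}

# Independent WFDB fixture writer: emits .hea / .dat (format 16) / .atr
# directly with writeBin, sharing no code with the package reader.
write_wfdb_fixture <- function(dir, name, adc, fs, gain = 200, baseline = 0,
                               ann = NULL) {
  adc <- as.matrix(adc)                       # nsig x nsamp integer ADC units
  nsig <- nrow(adc)
  hea <- file.path(dir, paste0(name, ".hea"))
  lines <- sprintf("%s %d %g %d", name, nsig, fs, ncol(adc))
  for (s in seq_len(nsig))
    lines <- c(lines, sprintf("%s.dat 16 %g(%d)/mV 12 0 0 0 0 lead%d",
                              name, gain, baseline, s))
  writeLines(lines, hea)
  writeBin(as.integer(as.vector(adc)), file.path(dir, paste0(name, ".dat")),
           size = 2L, endian = "little")
  if (!is.null(ann)) {
    stopifnot(all(diff(ann$index) > 0), all(ann$index[1] >= 0))
    words <- integer(0)
    prev <- 0L
    for (r in seq_len(nrow(ann))) {
      dt <- ann$index[r] - prev
      stopifnot(dt <= 1023L)                  # fixtures stay small
      words <- c(words, bitwShiftL(ann$code[r], 10L) + dt)
      prev <- ann$index[r]
    }
    words <- c(words, 0L)                     # EOF marker
    con <- file(file.path(dir, paste0(name, ".atr")), "wb")
    for (w in words) writeBin(c(w %% 256L, w %/% 256L), con, size = 1L)
    close(con)
  }
  invisible(hea)
}

# Literal low-pass recurrence, used as the oracle for the filter equivalence
# tests: f(m) = 2f(m-1) - f(m-2) + g(m) - 2g(m-6) + g(m-12).
lowpass_recurrence_oracle <- function(x) {
  n <- length(x)
  f <- numeric(n)
  g <- function(i) if (i >= 1L) x[i] else 0
  fo <- function(i) if (i >= 1L) f[i] else 0
  for (m in seq_len(n))
    f[m] <- 2 * fo(m - 1L) - fo(m - 2L) + g(m) - 2 * g(m - 6L) + g(m - 12L)
  f
}

# Band-pass cascade impulse response and its peak-response frequency on a
# fixed grid (Hz) at the 200 Hz processing rate.
bandpass_peak_frequency <- function(fs = 200, fmin = 0.1, fmax = 50,
                                    step = 0.01, n_imp = 2048) {
  h <- bandpass_filter(c(1, numeric(n_imp - 1)))
  fgrid <- seq(fmin, fmax, by = step)
  mag <- vapply(fgrid, function(f)
    abs(sum(h * exp(-2i * pi * f * (seq_along(h) - 1) / fs))), numeric(1))
  fgrid[which.max(mag)]
}
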