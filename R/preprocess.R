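# Noise elimination and beat segmentation: integer-coefficient band-pass
# filtering, adaptive dual-threshold QRS detection, 600 ms beat windows.
#
# The integer-coefficient filters are designed for one sampling rate; all
# detection runs at a fixed 200 Hz processing rate and detected indices are
# mapped back to the record's native rate.

#' Detector configuration
#'
#' Constants of the QRS detection chain. All delays/windows are in
#' milliseconds and converted internally at the processing rate.
#'
#' @param fs_proc Processing rate, Hz. The integer-delay band-pass
#'   coefficients realize a ~5-15 Hz passband only at 200 Hz; change with care.
#' @param mwi_ms Moving-window-integration length (default 150 ms, the QRS
#'   duration scale).
#' @param refractory_ms Minimum spacing between accepted QRS detections
#'   (default 200 ms, the physiological refractory period).
#' @param search_back_factor Search-back is triggered when no QRS is found
#'   within this multiple of the median recent RR (default 1.66).
#' @param peak_frac Weight of the signal-noise gap in the first threshold
#'   (default 0.25); the second threshold is half the first.
#' @param refine_ms Half-width of the band-passed local-maximum refinement
#'   window (default 150 ms).
#' @return A list of class `detector_config`.
#' @export
detector_config <- function(fs_proc = 200, mwi_ms = 150, refractory_ms = 200,
                            search_back_factor = 1.66, peak_frac = 0.25,
                            refine_ms = 150) {
  if (fs_proc <= 0) stop("fs_proc must be positive")
  structure(list(fs_proc = fs_proc, mwi_ms = mwi_ms,
                 refractory_ms = refractory_ms,
                 search_back_factor = search_back_factor,
                 peak_frac = peak_frac, refine_ms = refine_ms),
            class = "detector_config")
}

#' Resample a record to the processing rate
#'
#' Linear interpolation onto the new uniform time grid; annotation indices are
#' rescaled by `fs_proc / fs` and rounded. A record already at `fs_proc` is
#' returned unchanged.
#'
#' @param record An [ecg_record].
#' @param fs_proc Target rate in Hz.
#' @return An [ecg_record] at `fs_proc`.
#' @export
resample_to_processing_rate <- function(record, fs_proc = 200) {
  stopifnot(inherits(record, "ecg_record"))
  if (fs_proc <= 0) stop("fs_proc must be positive")
  if (record$fs == fs_proc) return(record)
  n <- length(record$samples)
  t_old <- (seq_len(n) - 1) / record$fs
  t_new <- seq(0, t_old[n], by = 1 / fs_proc)
  y <- stats::approx(t_old, record$samples, xout = t_new, rule = 2)$y
  rp <- if (!is.null(record$r_peaks)) {
    rp <- round(record$r_peaks * fs_proc / record$fs)
    pmin(rp, length(y) - 1L)
  } else NULL
  labs <- record$labels
  if (!is.null(rp)) {           # collapse any duplicates created by rounding
    keep <- !duplicated(rp)
    rp <- rp[keep]
    if (!is.null(labs)) labs <- labs[keep]
  }
  ecg_record(y, fs_proc, r_peaks = rp, labels = labs, meta = record$meta)
}

#' Integer-coefficient low-pass filter
#'
#' The recurrence `f(m) = 2 f(m-1) - f(m-2) + g(m) - 2 g(m-6) + g(m-12)` with
#' zero initial conditions — the cascaded-comb low-pass, transfer function
#' `(1 - z^-6)^2 / (1 - z^-1)^2`, DC gain 36, group delay 5 samples.
#'
#' @param x Numeric vector.
#' @return Filtered vector, same length.
#' @export
lowpass_filter <- function(x) {
  stopifnot_finite(x, "x")
  n <- length(x)
  if (n < 1L) stop("empty input")
  # FIR-equivalent: square of a 6-sample running sum
  h6 <- as.numeric(stats::filter(x, rep(1, 6), method = "convolution", sides = 1))
  h6[seq_len(min(5L, n))] <- cumsum(x[seq_len(min(5L, n))])[seq_len(min(5L, n))]
  y <- as.numeric(stats::filter(h6, rep(1, 6), method = "convolution", sides = 1))
  y[seq_len(min(5L, n))] <- cumsum(h6[seq_len(min(5L, n))])[seq_len(min(5L, n))]
  y
}

#' Integer-coefficient high-pass filter
#'
#' The high-pass companion of [lowpass_filter]: an all-pass 16-sample delay
#' minus a 32-sample running-sum low-pass,
#' `y(m) = 32 g(m-16) - sum_{k=0}^{31} g(m-k)` with zero initial conditions.
#' DC gain 0, gain 32 in the passband, group delay 16 samples.
#'
#' @param x Numeric vector.
#' @return Filtered vector, same length.
#' @export
highpass_filter <- function(x) {
  stopifnot_finite(x, "x")
  n <- length(x)
  if (n < 1L) stop("empty input")
  b <- -rep(1, 32)
  b[17] <- b[17] + 32
  y <- as.numeric(stats::filter(x, b, method = "convolution", sides = 1))
  warm <- which(is.na(y))
  for (m in warm) y[m] <- sum(b[seq_len(m)] * x[m:1])
  y
}

#' Band-pass filter (low-pass then high-pass cascade)
#'
#' At the 200 Hz processing rate the cascade passes roughly 5-15 Hz, the band
#' where QRS energy concentrates.
#'
#' @param x Numeric vector.
#' @return Filtered vector, same length.
#' @export
bandpass_filter <- function(x) highpass_filter(lowpass_filter(x))

#' Five-point derivative filter
#'
#' `y(m) = (1 / 8D) (-x(m-2) - 2 x(m-1) + 2 x(m+1) + x(m+2))` with `D = 1/fs`
#' the sampling period; a centered slope estimate in mV/s. The two samples at
#' each edge are zero.
#'
#' @param x Numeric vector, length >= 5.
#' @param fs Sampling rate in Hz (sets `D`).
#' @return Numeric vector, same length.
#' @export
derivative_filter <- function(x, fs = 200) {
  n <- length(x)
  if (n < 5L) stop("derivative_filter needs at least 5 samples")
  y <- numeric(n)
  i <- 3:(n - 2)
  y[i] <- (fs / 8) * (-x[i - 2] - 2 * x[i - 1] + 2 * x[i + 1] + x[i + 2])
  y
}

#' Pointwise squaring
#'
#' The rectification stage between slope estimation and moving-window
#' integration: `y = x^2`, making all QRS slope energy positive and
#' emphasizing large derivatives.
#'
#' @param x Numeric vector.
#' @return `x^2`.
#' @export
rectify_square <- function(x) x^2

#' Moving-window integration
#'
#' Trailing mean of the last `window` samples,
#' `y(m) = (1/M) * (x(m-M+1) + ... + x(m))`, with zero-padded warm-up.
#'
#' @param x Numeric vector.
#' @param window Window length M in samples (>= 1).
#' @return Numeric vector, same length.
#' @export
moving_window_integrate <- function(x, window) {
  if (window < 1L) stop("window must be >= 1")
  window <- as.integer(window)
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(seq_len(n) - window, 0L)
  (cs[seq_len(n) + 1L] - cs[lo + 1L]) / window
}

# local maxima (strictly greater than the left neighbour, >= right: earliest
# index wins on plateaus/ties)
.local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

#' Detect R-peaks with adaptive dual thresholds
#'
#' Runs the full chain at the processing rate — resample, band-pass,
#' derivative, squaring, moving-window integration — then screens
#' integrated-signal peaks with two adaptive thresholds maintained from
#' running signal-peak and noise-peak estimates (exponential averages with
#' weights 0.125/0.875). A search-back pass with the lower threshold fires
#' when no QRS is seen within `search_back_factor` times the median recent
#' RR. Accepted detections are refined to the local maximum of the
#' band-passed magnitude within `refine_ms`, compensated for the filter group
#' delay, snapped to the raw local maximum, and mapped back to the record's
#' native sampling rate.
#'
#' @param record An [ecg_record] of duration >= 2 s.
#' @param config A [detector_config].
#' @return A list: `r_peaks` (0-based indices at the native rate, strictly
#'   increasing), `state` (final threshold state), `trace` (per-candidate
#'   threshold trace as a data frame).
#' @export
detect_r_peaks <- function(record, config = detector_config()) {
  stopifnot(inherits(record, "ecg_record"))
  if (length(record$samples) / record$fs < 2) stop("record shorter than 2 s")
  fsp <- config$fs_proc
  proc <- resample_to_processing_rate(record, fsp)
  x <- proc$samples
  if (max(x) - min(x) < 1e-12)
    return(list(r_peaks = integer(0),
                state = list(spki = 0, npki = 0, threshold1 = 0, threshold2 = 0),
                trace = data.frame()))
  bp <- bandpass_filter(x)
  d <- derivative_filter(bp, fsp)
  sq <- rectify_square(d)
  M <- max(1L, round(config$mwi_ms / 1000 * fsp))
  mwi <- moving_window_integrate(sq, M)
  refr <- round(config$refractory_ms / 1000 * fsp)
  delay_bp <- 21L                      # low-pass (5) + high-pass (16)
  refine_w <- round(config$refine_ms / 1000 * fsp)

  cand <- .local_maxima(mwi)
  # initialize from the first 2 s
  init <- mwi[seq_len(min(length(mwi), 2L * fsp))]
  spki <- 0.5 * max(init)
  npki <- 0.5 * mean(init)
  thr1 <- npki + config$peak_frac * (spki - npki)
  qrs <- integer(0)
  rr_hist <- numeric(0)
  trace <- vector("list", length(cand))
  last_qrs <- -Inf
  pending <- cand
  k <- 0L
  while (k < length(pending)) {
    k <- k + 1L
    i <- pending[k]
    pk <- mwi[i]
    thr1 <- npki + config$peak_frac * (spki - npki)
    thr2 <- 0.5 * thr1
    accepted <- FALSE
    if (i - last_qrs > refr && pk > thr1) {
      accepted <- TRUE
      spki <- 0.125 * pk + 0.875 * spki
    } else if (i - last_qrs <= refr && pk > thr1) {
      # inside refractory: ignore (late energy of the same QRS)
    } else {
      npki <- 0.125 * pk + 0.875 * npki
      # search-back: have we waited too long since the last QRS?
      if (length(rr_hist) >= 2L) {
        rr_med <- stats::median(utils::tail(rr_hist, 8))
        if (i - last_qrs > config$search_back_factor * rr_med) {
          gap <- pending[pending > last_qrs + refr & pending <= i]
          gap <- gap[mwi[gap] > thr2 & gap != i]
          if (length(gap)) {
            j <- gap[which.max(mwi[gap])]
            if (j - last_qrs > refr) {
              if (length(qrs)) rr_hist <- c(rr_hist, j - qrs[length(qrs)])
              qrs <- c(qrs, j)
              last_qrs <- j
              spki <- 0.25 * mwi[j] + 0.75 * spki
            }
          }
        }
      }
    }
    if (accepted) {
      if (length(qrs)) rr_hist <- c(rr_hist, i - qrs[length(qrs)])
      qrs <- c(qrs, i)
      last_qrs <- i
    }
    trace[[k]] <- c(index = i, peak = pk, spki = spki, npki = npki,
                    threshold1 = thr1, threshold2 = thr2,
                    accepted = as.numeric(accepted))
  }
  qrs <- sort(unique(qrs))
  # refine: local max of |band-passed| near the integrated peak (which lags
  # the QRS by about the MWI half-width), then compensate the filter delay
  # and snap to the raw-signal peak
  refined <- vapply(qrs, function(i) {
    c0 <- i - (M - 1L) %/% 2L
    lo <- max(1L, c0 - refine_w)
    hi <- min(length(bp), c0 + refine_w)
    j <- lo + which.max(abs(bp[lo:hi])) - 1L
    j0 <- j - delay_bp
    lo2 <- max(1L, j0 - round(0.05 * fsp))
    hi2 <- min(length(x), j0 + round(0.05 * fsp))
    lo2 + which.max(x[lo2:hi2]) - 1L
  }, numeric(1))
  refined <- sort(unique(refined))
  if (length(refined) > 1L)   # collapse refinements that landed on one beat
    refined <- refined[c(TRUE, diff(refined) > refr)]
  # map to native rate (1-based proc index -> 0-based native index)
  native <- round((refined - 1L) * record$fs / fsp)
  # final snap on the native signal
  native <- vapply(native, function(i) {
    lo <- max(0L, i - round(0.01 * record$fs))
    hi <- min(length(record$samples) - 1L, i + round(0.01 * record$fs))
    w <- record$samples[(lo:hi) + 1L]
    lo + which.max(w) - 1L
  }, numeric(1))
  native <- sort(unique(native))
  list(r_peaks = as.integer(native),
       state = list(spki = spki, npki = npki,
                    threshold1 = npki + config$peak_frac * (spki - npki),
                    threshold2 = 0.5 * (npki + config$peak_frac * (spki - npki))),
       trace = as.data.frame(do.call(rbind, trace[seq_len(k)])))
}

#' Segment beats around R-peaks
#'
#' Cuts a fixed window of `segment_ms` (default 600 ms) around each peak:
#' length `L = round(segment_ms/1000 * fs)` samples, half-open
#' `[peak - L %/% 2, peak - L %/% 2 + L)`. Windows that exceed the record
#' bounds are dropped and counted. When the record carries ground-truth
#' annotations, each segment is labelled by the nearest annotated beat within
#' 75 ms, else `"unknown"`.
#'
#' @param record An [ecg_record].
#' @param peaks 0-based R-peak indices (sorted, in range).
#' @param segment_ms Window duration in milliseconds.
#' @return A list of class `beat_segments`: `beats` (list of per-beat lists
#'   with `samples`, `r_index`, `source_index`, `label`), `fs`, `length`,
#'   `n_dropped`.
#' @export
segment_beats <- function(record, peaks = record$r_peaks, segment_ms = 600) {
  stopifnot(inherits(record, "ecg_record"))
  if (is.null(peaks)) stop("no peaks supplied and record carries none")
  peaks <- as.integer(peaks)
  if (is.unsorted(peaks, strictly = TRUE)) stop("peaks must be strictly increasing")
  L <- round(segment_ms / 1000 * record$fs)
  n <- length(record$samples)
  half <- L %/% 2L
  tol <- round(0.075 * record$fs)
  beats <- list()
  dropped <- 0L
  for (p in peaks) {
    start <- p - half
    if (start < 0L || start + L > n) { dropped <- dropped + 1L; next }
    label <- "unknown"
    if (!is.null(record$r_peaks) && !is.null(record$labels)) {
      dd <- abs(record$r_peaks - p)
      j <- which.min(dd)
      if (length(j) && dd[j] <= tol) label <- record$labels[j]
    }
    beats[[length(beats) + 1L]] <-
      list(samples = record$samples[(start:(start + L - 1L)) + 1L],
           r_index = half, source_index = p, label = label)
  }
  structure(list(beats = beats, fs = record$fs, length = L, n_dropped = dropped),
            class = "beat_segments")
}

#' @export
print.beat_segments <- function(x, ...) {
  cat(sprintf("<beat_segments> %d beats of %d samples @ %g Hz (%d dropped)\n",
              length(x$beats), x$length, x$fs, x$n_dropped))
  invisible(x)
}
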