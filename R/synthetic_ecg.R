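#' Synthetic ECG configuration
#'
#' Bundles every knob of the synthetic single-lead generator. Defaults
#' describe a resting adult recorded at the MIT-BIH rate: 360 Hz, 70 bpm,
#' 1 mV R-waves. Anomalous beats model premature ventricular-like beats: the
#' preceding RR interval is shortened and the QRS complex is widened and
#' taller.
#'
#' @param fs Sampling frequency, Hz (>= 100).
#' @param duration Record length, seconds.
#' @param heart_rate Mean heart rate, bpm (20-250).
#' @param anomaly_fraction Fraction of beats flagged anomalous, in `[0, 1]`.
#'   The exact count `round(fraction * n_beats)` is drawn without replacement.
#' @param anomaly_spec List: `premature_shortening` (fraction of the
#'   preceding RR removed, default 0.35), `morphology_scale` (QRS amplitude
#'   multiplier, default 1.4), `width_scale` (QRS width multiplier, default 1.5).
#' @param noise_spec List of additive noise sources, see [add_noise]:
#'   `powerline` (`amplitude` mV, `hz` mains frequency),
#'   `baseline_wander` (`amplitude` mV, `hz` < 0.5),
#'   `muscle` (`sd` mV of Gaussian white noise),
#'   `electrode_motion` (`amplitude` mV of step offsets, `rate_per_min`),
#'   plus a `seed`. All amplitudes default to 0 (clean signal).
#' @param rr_jitter_sd Standard deviation of per-beat RR jitter as a fraction
#'   of the mean RR (default 0.03, mild sinus irregularity).
#' @param seed Integer seed; the generator is bit-reproducible given the seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(fs = 360, duration = 30, heart_rate = 70,
                         anomaly_fraction = 0,
                         anomaly_spec = list(),
                         noise_spec = list(),
                         rr_jitter_sd = 0.03,
                         seed = 1L) {
  if (fs < 100) stop("fs must be >= 100 Hz")
  if (heart_rate < 20 || heart_rate > 250) stop("heart_rate must be in [20, 250] bpm")
  if (anomaly_fraction < 0 || anomaly_fraction > 1)
    stop("anomaly_fraction must be in [0, 1]")
  aspec <- utils::modifyList(list(premature_shortening = 0.35,
                                  morphology_scale = 1.4,
                                  width_scale = 1.5), anomaly_spec)
  nspec <- utils::modifyList(list(powerline = list(amplitude = 0, hz = 50),
                                  baseline_wander = list(amplitude = 0, hz = 0.3),
                                  muscle = list(sd = 0),
                                  electrode_motion = list(amplitude = 0, rate_per_min = 0),
                                  seed = derive_seed(seed, 7L)), noise_spec)
  structure(list(fs = fs, duration = duration, heart_rate = heart_rate,
                 anomaly_fraction = anomaly_fraction, anomaly_spec = aspec,
                 noise_spec = nspec, rr_jitter_sd = rr_jitter_sd,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# P-QRS-T template: Gaussian bumps at conventional offsets from the R-peak.
# centers/widths in seconds, amplitudes in mV; the R bump dominates so the
# analytic peak location is the ground truth.
.beat_waves <- function(morph_scale = 1, width_scale = 1) {
  data.frame(
    wave   = c("P", "Q", "R", "S", "T"),
    center = c(-0.20, -0.033, 0, 0.033, 0.28),
    width  = c(0.030, 0.012, 0.013, 0.012, 0.055) *
             c(1, width_scale, width_scale, width_scale, 1),
    amp    = c(0.12, -0.16, 1.00, -0.22, 0.30) *
             c(1, morph_scale, morph_scale, morph_scale, 1)
  )
}

#' Generate a clean synthetic ECG with ground truth
#'
#' Beats are sums of Gaussian bumps for the P, Q, R, S and T waves placed on
#' an RR grid with mild jitter. A seeded subset of beats (exactly
#' `round(anomaly_fraction * n)` of them, chosen without replacement) is made
#' anomalous: the RR interval preceding the beat is shortened by
#' `premature_shortening` and the QRS bumps are scaled in amplitude and
#' width. Ground-truth R-peak indices and labels are recorded on the output.
#' Noise configured in `config$noise_spec` is then added via [add_noise];
#' annotations are unaffected by noise.
#'
#' @param config A [synth_config].
#' @return An [ecg_record] with `r_peaks` and `labels` ground truth.
#' @export
generate_clean_ecg <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  fs <- config$fs
  rr_mean <- 60 / config$heart_rate
  if (config$duration < rr_mean)
    stop("duration shorter than one beat at the requested heart rate")
  # beat grid: draw a generous number of RR intervals, then truncate
  n_max <- ceiling(config$duration / rr_mean * 1.8) + 3L
  rr <- with_seed(config$seed, {
    rr_mean * (1 + stats::rnorm(n_max, 0, config$rr_jitter_sd))
  })
  rr <- pmax(rr, 0.25)
  t_r <- 0.5 + cumsum(c(0, rr))
  keep <- t_r <= config$duration - 0.45      # leave room for the T wave
  t_r <- t_r[keep]
  n <- length(t_r)
  if (n < 1L) stop("duration shorter than one beat at the requested heart rate")
  n_anom <- round(config$anomaly_fraction * n)
  anom <- rep(FALSE, n)
  if (n_anom > 0)
    anom[with_seed(derive_seed(config$seed, 1L), sample.int(n, n_anom))] <- TRUE
  # premature beats steal time from the preceding RR interval
  short <- config$anomaly_spec$premature_shortening
  for (i in which(anom)) if (i > 1L) {
    gap <- t_r[i] - t_r[i - 1L]
    t_r[i] <- t_r[i] - short * gap
  }
  t_r <- sort(t_r)
  nsamp <- round(config$duration * fs)
  tgrid <- (seq_len(nsamp) - 1) / fs
  x <- numeric(nsamp)
  for (i in seq_len(n)) {
    w <- if (anom[i]) .beat_waves(config$anomaly_spec$morphology_scale,
                                  config$anomaly_spec$width_scale)
         else .beat_waves()
    for (k in seq_len(nrow(w))) {
      c0 <- t_r[i] + w$center[k]
      lo <- max(1L, floor((c0 - 5 * w$width[k]) * fs))
      hi <- min(nsamp, ceiling((c0 + 5 * w$width[k]) * fs) + 1L)
      if (lo > hi) next
      seg <- lo:hi
      x[seg] <- x[seg] + w$amp[k] * exp(-0.5 * ((tgrid[seg] - c0) / w$width[k])^2)
    }
  }
  r_peaks <- round(t_r * fs)
  ok <- r_peaks >= 0 & r_peaks < nsamp
  rec <- ecg_record(x, fs, r_peaks = r_peaks[ok],
                    labels = ifelse(anom[ok], "anomalous", "normal"),
                    meta = list(source = "synthetic", config = unclass(config)))
  add_noise(rec, config$noise_spec)
}

#' Add recording noise to an ECG record
#'
#' Four additive, mutually independent noise sources with fixed per-component
#' seed sub-streams (derived from `noise_spec$seed`), so adding components in
#' any order or all at once yields bit-identical output:
#' powerline interference (sinusoid at the mains frequency), baseline wander
#' (low-frequency sinusoid), muscle artifact (Gaussian white noise) and
#' electrode motion (random step offsets at a Poisson rate). Annotations are
#' untouched.
#'
#' @param record An [ecg_record].
#' @param noise_spec See [synth_config]; components with zero amplitude are
#'   skipped, so an all-zero spec returns the input bit-exactly.
#' @return An [ecg_record] with noise added to `samples`.
#' @export
add_noise <- function(record, noise_spec) {
  stopifnot(inherits(record, "ecg_record"))
  spec <- utils::modifyList(list(powerline = list(amplitude = 0, hz = 50),
                                 baseline_wander = list(amplitude = 0, hz = 0.3),
                                 muscle = list(sd = 0),
                                 electrode_motion = list(amplitude = 0, rate_per_min = 0),
                                 seed = 0L), noise_spec)
  amps <- c(spec$powerline$amplitude, spec$baseline_wander$amplitude,
            spec$muscle$sd, spec$electrode_motion$amplitude)
  if (any(amps < 0)) stop("noise amplitudes must be >= 0")
  n <- length(record$samples)
  t <- (seq_len(n) - 1) / record$fs
  x <- record$samples
  if (spec$powerline$amplitude > 0)
    x <- x + spec$powerline$amplitude * sin(2 * pi * spec$powerline$hz * t)
  if (spec$baseline_wander$amplitude > 0)
    x <- x + spec$baseline_wander$amplitude * sin(2 * pi * spec$baseline_wander$hz * t)
  if (spec$muscle$sd > 0)
    x <- x + with_seed(derive_seed(spec$seed, 11L),
                       stats::rnorm(n, 0, spec$muscle$sd))
  if (spec$electrode_motion$amplitude > 0 && spec$electrode_motion$rate_per_min > 0) {
    steps <- with_seed(derive_seed(spec$seed, 13L), {
      n_ev <- stats::rpois(1, spec$electrode_motion$rate_per_min *
                              n / record$fs / 60)
      list(at = sample.int(n, min(n_ev, n)),
           height = stats::rnorm(min(n_ev, n), 0, spec$electrode_motion$amplitude))
    })
    if (length(steps$at)) {
      offs <- numeric(n)
      offs[steps$at] <- steps$height
      x <- x + cumsum(offs)
    }
  }
  out <- record
  out$samples <- x
  out
}
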