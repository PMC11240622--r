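# Multi-transform per-beat feature extraction: fractional DCT magnitudes,
# Radon projections of a Mexican-hat scalogram with Haar sub-band energies,
# and a fractional-Fourier + discrete-wavelet decomposition.

#' Feature-extraction configuration
#'
#' @param fdct_order Fractional order `a` of the cosine transform, in
#'   `[0, 1]`; `a = 1` is the ordinary orthonormal DCT-II.
#' @param fdct_coeffs Number of leading transform magnitudes kept.
#' @param radon_angles Projection angles in degrees, each in `[0, 180)`.
#' @param radon_scales Number of scalogram scales (>= 2), geometrically spaced.
#' @param frwt_fraction Fractional-Fourier order for the fractional-wavelet
#'   features, in `[0, 4)`.
#' @param wavelet_name Mother wavelet for the discrete decomposition
#'   (currently `"db4"` or `"haar"`).
#' @param wavelet_levels Decomposition depth (>= 1).
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(fdct_order = 1, fdct_coeffs = 16,
                           radon_angles = seq(0, 165, by = 15),
                           radon_scales = 24,
                           frwt_fraction = 0.5,
                           wavelet_name = "db4", wavelet_levels = 3) {
  if (fdct_coeffs < 1) stop("fdct_coeffs must be >= 1")
  if (any(radon_angles < 0 | radon_angles >= 180))
    stop("radon_angles must lie in [0, 180)")
  if (radon_scales < 2) stop("radon_scales must be >= 2")
  if (wavelet_levels < 1) stop("wavelet_levels must be >= 1")
  structure(list(fdct_order = fdct_order, fdct_coeffs = fdct_coeffs,
                 radon_angles = radon_angles, radon_scales = radon_scales,
                 frwt_fraction = frwt_fraction, wavelet_name = wavelet_name,
                 wavelet_levels = wavelet_levels),
            class = "feature_config")
}

## ---- fractional DCT ---------------------------------------------------------

# orthonormal DCT-II matrix: C[k+1, n+1] = e_k sqrt(2/N) cos(pi (2n+1) k / 2N)
dct2_matrix <- function(N) {
  k <- 0:(N - 1)
  C <- sqrt(2 / N) * cos(pi * outer(k, 2 * k + 1) / (2 * N))
  C[1, ] <- sqrt(1 / N)
  C
}

.fdct_cache <- new.env(parent = emptyenv())

fdct_matrix <- function(N, a) {
  key <- sprintf("%d_%.10f", N, a)
  if (!is.null(.fdct_cache[[key]])) return(.fdct_cache[[key]])
  C <- dct2_matrix(N)
  M <- if (a == 1) C + 0i else if (a == 0) diag(N) + 0i else {
    e <- eigen(C)
    lam <- e$values / Mod(e$values)          # unit circle, principal branch
    e$vectors %*% (exp(a * log(lam)) * solve(e$vectors))
  }
  .fdct_cache[[key]] <- M
  M
}

#' Fractional discrete cosine transform features
#'
#' The orthonormal DCT-II matrix raised to fractional power `a` via its
#' eigendecomposition (principal branch of the eigenvalue powers); `a = 1`
#' reproduces the standard transform exactly and `a = 0` the identity.
#' Features are the magnitudes of the first `fdct_coeffs` coefficients.
#'
#' @param beat Numeric vector (one beat).
#' @param cfg A [feature_config].
#' @return Named numeric vector `fdct_01 ... fdct_K`.
#' @export
fdct_features <- function(beat, cfg = feature_config()) {
  a <- cfg$fdct_order
  if (a < 0 || a > 1) stop("fdct_order must be in [0, 1]")
  N <- length(beat)
  if (N < cfg$fdct_coeffs) stop("beat shorter than fdct_coeffs")
  y <- Mod(drop(fdct_matrix(N, a) %*% beat))
  out <- y[seq_len(cfg$fdct_coeffs)]
  names(out) <- sprintf("fdct_%02d", seq_len(cfg$fdct_coeffs))
  out
}

## ---- scalogram + Radon ------------------------------------------------------

# Mexican-hat (Ricker) wavelet, unit scale
.ricker <- function(t) (2 / (sqrt(3) * pi^0.25)) * (1 - t^2) * exp(-t^2 / 2)

#' Continuous-wavelet scalogram of a beat
#'
#' Magnitude of the Mexican-hat continuous wavelet transform on
#' geometrically spaced scales, resized to a square grid of side
#' `min(length(beat), 64)` by separable bilinear interpolation.
#'
#' @param beat Numeric vector.
#' @param cfg A [feature_config] (uses `radon_scales`).
#' @return Square numeric matrix (scale x time).
#' @export
beat_scalogram <- function(beat, cfg = feature_config()) {
  N <- length(beat)
  scales <- exp(seq(log(1.5), log(max(3, N / 6)), length.out = cfg$radon_scales))
  rows <- t(vapply(scales, function(s) {
    half <- ceiling(5 * s)
    k <- (-half):half
    ker <- .ricker(k / s) / sqrt(s)
    full <- stats::convolve(c(numeric(half), beat, numeric(half)),
                            rev(ker), type = "open")
    abs(full[(2 * half + 1):(2 * half + N)])
  }, numeric(N)))
  side <- min(N, 64L)
  resize_bilinear(rows, side, side)
}

# separable bilinear resize using stats::approx on each axis
resize_bilinear <- function(m, nr, nc) {
  xs <- seq(1, ncol(m), length.out = nc)
  tmp <- t(apply(m, 1, function(row) stats::approx(seq_along(row), row, xout = xs)$y))
  if (nrow(m) == 1L) tmp <- matrix(tmp, nrow = 1L)
  ys <- seq(1, nrow(m), length.out = nr)
  out <- apply(tmp, 2, function(col) stats::approx(seq_along(col), col, xout = ys)$y)
  matrix(out, nr, nc)
}

# rotate a square image about its center by forward bilinear splatting:
# each input pixel's value is distributed over the four nearest output
# pixels, so total mass is conserved exactly (up to mass leaving the frame).
rotate_splat <- function(img, angle_deg) {
  n <- nrow(img)
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  c0 <- (n + 1) / 2
  ij <- which(img != 0, arr.ind = TRUE)
  out <- matrix(0, n, n)
  if (nrow(ij) == 0L) return(out)
  v <- img[ij]
  u <- ct * (ij[, 1] - c0) - st * (ij[, 2] - c0) + c0
  w <- st * (ij[, 1] - c0) + ct * (ij[, 2] - c0) + c0
  i0 <- floor(u); j0 <- floor(w)
  du <- u - i0; dv <- w - j0
  ii <- c(i0, i0 + 1, i0, i0 + 1)
  jj <- c(j0, j0, j0 + 1, j0 + 1)
  wt <- c((1 - du) * (1 - dv), du * (1 - dv), (1 - du) * dv, du * dv)
  val <- rep(v, 4) * wt
  ok <- ii >= 1 & ii <= n & jj >= 1 & jj <= n & wt != 0
  if (any(ok)) {
    lin <- ii[ok] + (jj[ok] - 1) * n
    s <- rowsum(val[ok], group = lin)
    out[as.integer(rownames(s))] <- s[, 1]
  }
  out
}

#' Radon projection of a square image
#'
#' Line-integral projection: the image is rotated about its center by
#' `angle` degrees (mass-conserving bilinear splatting, zero fill) and its
#' columns are summed. At angle 0 the projection equals the exact column
#' sums.
#'
#' @param image Square numeric matrix.
#' @param angle Angle in degrees.
#' @return Numeric vector of length `nrow(image)`.
#' @export
radon_projection <- function(image, angle) {
  if (nrow(image) != ncol(image)) stop("radon_projection requires a square image")
  if (angle %% 360 == 0) return(colSums(image))
  colSums(rotate_splat(image, angle))
}

# single-level orthonormal Haar split (odd trailing sample ignored)
haar_level1 <- function(x) {
  n2 <- length(x) %/% 2L
  o <- x[2 * seq_len(n2) - 1L]; e <- x[2 * seq_len(n2)]
  list(approx = (o + e) / sqrt(2), detail = (o - e) / sqrt(2))
}

#' Radon-wavelet features of a beat
#'
#' Scalogram of the beat, Radon projection at each configured angle, then a
#' single-level Haar decomposition of each projection; the feature pair per
#' angle is the approximation and detail energy (sum of squared
#' coefficients).
#'
#' @param beat Numeric vector.
#' @param cfg A [feature_config].
#' @return Named numeric vector of length `2 * length(radon_angles)`.
#' @export
radon_wavelet_features <- function(beat, cfg = feature_config()) {
  if (!length(cfg$radon_angles)) stop("radon_angles must be non-empty")
  sg <- beat_scalogram(beat, cfg)
  out <- unlist(lapply(cfg$radon_angles, function(ang) {
    h <- haar_level1(radon_projection(sg, ang))
    c(sum(h$approx^2), sum(h$detail^2))
  }))
  names(out) <- as.vector(rbind(sprintf("rw_a%03d_approx", round(cfg$radon_angles)),
                                sprintf("rw_a%03d_detail", round(cfg$radon_angles))))
  out
}

## ---- fractional Fourier transform ------------------------------------------

.frft_cache <- new.env(parent = emptyenv())

# Orthonormal Hermite-like eigenbasis of the unitary DFT: eigenvectors of the
# Dickinson-Steiglitz commuting matrix, diagonalized separately in the even
# and odd symmetry subspaces (the full matrix has degenerate eigenvalues that
# would otherwise mix DFT eigenspaces), ordered by Hermite index k with the
# standard skip of k = N-1 for even N.
frft_basis <- function(N) {
  key <- as.character(N)
  if (!is.null(.frft_cache[[key]])) return(.frft_cache[[key]])
  S <- matrix(0, N, N)
  diag(S) <- 2 * cos(2 * pi * (0:(N - 1)) / N) - 4
  for (i in 1:N) { j <- (i %% N) + 1L; S[i, j] <- 1; S[j, i] <- 1 }
  half <- (N - 1) %/% 2L
  e <- function(i) { v <- numeric(N); v[i + 1L] <- 1; v }
  Ve <- matrix(e(0), ncol = 1)
  Vo <- matrix(0, N, 0)
  for (k in seq_len(half)) {
    Ve <- cbind(Ve, (e(k) + e(N - k)) / sqrt(2))
    Vo <- cbind(Vo, (e(k) - e(N - k)) / sqrt(2))
  }
  if (N %% 2L == 0L) Ve <- cbind(Ve, e(N %/% 2L))
  ee <- eigen(crossprod(Ve, S %*% Ve), symmetric = TRUE)
  eo <- eigen(crossprod(Vo, S %*% Vo), symmetric = TRUE)
  Ue <- Ve %*% ee$vectors
  Uo <- Vo %*% eo$vectors
  ke <- seq(0, by = 2, length.out = ncol(Ue))
  if (N %% 2L == 0L) ke[length(ke)] <- N
  ko <- seq(1, by = 2, length.out = ncol(Uo))
  o <- order(c(ke, ko))
  b <- list(V = cbind(Ue, Uo)[, o], k = c(ke, ko)[o])
  .frft_cache[[key]] <- b
  b
}

#' Discrete fractional Fourier transform
#'
#' Computed as `V diag(exp(-i pi a k / 2)) V^T x` on the ordered
#' Hermite-like eigenbasis `V` of the unitary DFT. Exactly unitary and
#' additive in `a`: order 0 is the identity, order 1 the unitary DFT, and
#' `frft(frft(x, a), b) == frft(x, a + b)`.
#'
#' @param x Numeric or complex vector, length >= 4.
#' @param a Fractional order in `[0, 4)`.
#' @return Complex vector of the same length.
#' @export
frft <- function(x, a) {
  if (length(x) < 4L) stop("frft needs length >= 4")
  if (a < 0 || a >= 4) stop("a must be in [0, 4)")
  b <- frft_basis(length(x))
  drop(b$V %*% (exp(-1i * pi * a * b$k / 2) * (t(b$V) %*% x)))
}

## ---- discrete wavelet decomposition ----------------------------------------

wavelet_filters <- function(name) {
  h <- switch(name,
    haar = c(1, 1) / sqrt(2),
    db4 = c(0.2303778133088965, 0.7148465705529157, 0.6308807679298589,
            -0.0279837694168599, -0.1870348117190931, 0.0308413818355607,
            0.0328830116668852, -0.0105974017850690),
    stop("unknown wavelet: ", name))
  L <- length(h)
  g <- (-1)^(seq_len(L) - 1) * rev(h)
  list(h = h, g = g)
}

# one periodized analysis step: x (even length) -> list(approx, detail)
dwt_step <- function(x, f) {
  n <- length(x)
  L <- length(f$h)
  idx <- outer(2 * seq_len(n %/% 2L) - 1L, 0:(L - 1L), "+") %% n + 1L
  xm <- matrix(x[idx], ncol = L)
  list(approx = drop(xm %*% f$h), detail = drop(xm %*% f$g))
}

#' Multilevel periodized discrete wavelet decomposition
#'
#' Orthonormal analysis filter bank with periodic extension, so total
#' coefficient energy equals signal energy to machine precision.
#'
#' @param x Numeric vector; its length must be divisible by `2^levels`.
#' @param wavelet `"db4"` or `"haar"`.
#' @param levels Decomposition depth.
#' @return List with `details` (list, finest first) and `approx`.
#' @export
dwt_periodic <- function(x, wavelet = "db4", levels = 3) {
  if (length(x) %% 2^levels != 0)
    stop("length must be divisible by 2^levels for the periodized transform")
  f <- wavelet_filters(wavelet)
  details <- vector("list", levels)
  a <- x
  for (l in seq_len(levels)) {
    s <- dwt_step(a, f)
    details[[l]] <- s$detail
    a <- s$approx
  }
  list(details = details, approx = a)
}

#' Fractional-wavelet features of a beat
#'
#' The beat is carried to the fractional Fourier domain of order
#' `frwt_fraction`, its magnitude is decomposed with a multilevel orthonormal
#' discrete wavelet transform, and each sub-band contributes (energy, mean,
#' standard deviation). Order 0 reduces to wavelet features of `|beat|`.
#'
#' @param beat Numeric vector.
#' @param cfg A [feature_config].
#' @return Named numeric vector of length `3 * (wavelet_levels + 1)`.
#' @export
fractional_wavelet_features <- function(beat, cfg = feature_config()) {
  lv <- cfg$wavelet_levels
  if (2^lv > length(beat)) stop("wavelet_levels too deep for this beat length")
  y <- Mod(frft(beat, cfg$frwt_fraction))
  dec <- dwt_periodic(y, cfg$wavelet_name, lv)
  bands <- c(dec$details, list(dec$approx))
  band_names <- c(sprintf("d%d", seq_len(lv)), sprintf("a%d", lv))
  out <- unlist(lapply(bands, function(b)
    c(sum(b^2), mean(b), stats::sd(b))))
  names(out) <- as.vector(vapply(band_names, function(b)
    sprintf("frwt_%s_%s", b, c("energy", "mean", "sd")), character(3)))
  out
}

## ---- full matrix ------------------------------------------------------------

#' Extract the per-beat feature matrix
#'
#' Concatenates the fractional-DCT, Radon-wavelet and fractional-wavelet
#' vectors for every beat, then z-scores each column. When `scaling` is
#' `NULL` the means and standard deviations are fitted on these beats and
#' stored with the result; passing a previously fitted `scaling` reuses the
#' training statistics (required for leakage-free evaluation). Constant
#' columns are centered but left unscaled.
#'
#' @param beats A `beat_segments` object from [segment_beats], or a list of
#'   numeric vectors.
#' @param cfg A [feature_config].
#' @param scaling Optional scaling list from a previous call.
#' @return A [feature_matrix]; `$scaling` holds the statistics used.
#' @export
extract_feature_matrix <- function(beats, cfg = feature_config(), scaling = NULL) {
  if (inherits(beats, "beat_segments")) {
    labels <- vapply(beats$beats, `[[`, character(1), "label")
    sigs <- lapply(beats$beats, `[[`, "samples")
  } else {
    sigs <- beats
    labels <- rep("unknown", length(beats))
  }
  if (!length(sigs)) stop("need at least one beat")
  rows <- lapply(seq_along(sigs), function(i) {
    v <- c(fdct_features(sigs[[i]], cfg),
           radon_wavelet_features(sigs[[i]], cfg),
           fractional_wavelet_features(sigs[[i]], cfg))
    if (any(!is.finite(v))) {
      bad <- names(v)[which(!is.finite(v))[1L]]
      stop(sprintf("non-finite feature '%s' for beat %d", bad, i))
    }
    v
  })
  vals <- do.call(rbind, rows)
  if (is.null(scaling)) {
    ctr <- colMeans(vals)
    scl <- apply(vals, 2, stats::sd)
    scl[!is.finite(scl) | scl < 1e-12] <- 1
    scaling <- list(center = ctr, scale = scl)
  }
  vals <- sweep(sweep(vals, 2, scaling$center, "-"), 2, scaling$scale, "/")
  feature_matrix(vals, colnames(vals), labels, scaling = scaling)
}
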