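# Morlet continuous wavelet transform, cross-spectrum smoothing, wavelet
# transform coherence (WTC) and the Fisher r-to-z transform.
#
# The CWT follows the standard Fourier-domain formulation: for scale s and
# angular frequencies w_k of the padded series,
#   W(s, t) = ifft( fft(x) * sqrt(2*pi*s/dt) * pi^(-1/4)
#                   * exp(-(s*w_k - omega0)^2 / 2) * [w_k > 0] ).
# Coherence uses the usual smoothing operator: a Gaussian in time with
# standard deviation equal to the scale, then a boxcar across scales 0.6
# octaves wide. With identical non-negative smoothing weights on the cross
# and auto spectra, Cauchy-Schwarz bounds R^2 by 1 up to rounding.

#' Wavelet analysis specification
#'
#' @param omega0 Morlet nondimensional frequency (default 6, the common
#'   compromise between time and frequency localization).
#' @param voices_per_octave Number of scales per octave (>= 8).
#' @param period_range Analyzed Fourier-period range in seconds; the default
#'   spans 1/0.7 Hz to 1/0.01 Hz, excluding cardiac-band noise above 0.7 Hz
#'   and very-low-frequency drift below 0.01 Hz.
#' @param scale_smooth_octaves Width (in octaves) of the boxcar smoothing
#'   across scales used by the coherence estimator.
#' @return A `wavelet_spec` list including the derived Morlet Fourier factor
#'   (`4*pi / (omega0 + sqrt(2 + omega0^2))`) linking scale to period.
#' @export
wavelet_spec <- function(omega0 = 6, voices_per_octave = 12,
                         period_range = c(1 / 0.7, 1 / 0.01),
                         scale_smooth_octaves = 0.6) {
  stopifnot(voices_per_octave >= 8, period_range[1] < period_range[2])
  fourier_factor <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  structure(list(omega0 = omega0, voices_per_octave = voices_per_octave,
                 period_range = period_range,
                 scale_smooth_octaves = scale_smooth_octaves,
                 fourier_factor = fourier_factor),
            class = "wavelet_spec")
}

wavelet_scales <- function(spec) {
  ff <- spec$fourier_factor
  s0 <- spec$period_range[1] / ff
  s1 <- spec$period_range[2] / ff
  n_oct <- log2(s1 / s0)
  j <- seq(0, ceiling(n_oct * spec$voices_per_octave))
  s <- s0 * 2^(j / spec$voices_per_octave)
  s[s <= s1 * 2^(1 / spec$voices_per_octave / 2)]
}

#' Morlet continuous wavelet transform
#'
#' FFT-based CWT on a geometric scale grid. The transform is linear in its
#' input; coefficients inside the cone of influence (within one e-folding
#' time `sqrt(2) * s` of either edge) are retained but flagged in the
#' returned mask.
#'
#' @param x Finite numeric series.
#' @param fs Sampling rate (Hz).
#' @param spec A [wavelet_spec()].
#' @return A `cwt` object: complex coefficient matrix `W` (scales x time),
#'   `scales`, `periods` (s), `freqs` (Hz), `coi` (maximum reliable period
#'   per time point, s), `inside_coi` logical mask, `fs`, `n`.
#' @export
cwt_morlet <- function(x, fs, spec = wavelet_spec()) {
  if (anyNA(x) || any(!is.finite(x))) stop("input series contains NA/Inf")
  n <- length(x)
  dt <- 1 / fs
  scales <- wavelet_scales(spec)
  if (n * dt < 2 * spec$period_range[2])
    warning("series shorter than twice the longest analyzed period; ",
            "long-period estimates are edge-dominated")
  # pad to at least twice the series length so long-scale wavelets never
  # wrap around circularly
  npad <- 2^ceiling(log2(2 * n))
  xpad <- c(x - mean(x), rep(0, npad - n))
  xhat <- stats::fft(xpad)
  k <- seq_len(npad) - 1
  omega <- 2 * pi * k / (npad * dt)
  omega[k > npad / 2] <- -omega[npad - k[k > npad / 2]]
  pos <- omega > 0
  norm_const <- pi^(-1 / 4)
  # one filter column per scale; a single inverse mvfft computes all rows
  filt <- vapply(scales, function(s) {
    psi_hat <- numeric(npad)
    psi_hat[pos] <- norm_const * sqrt(2 * pi * s / dt) *
      exp(-0.5 * (s * omega[pos] - spec$omega0)^2)
    psi_hat
  }, numeric(npad))
  W <- t(stats::mvfft(filt * xhat, inverse = TRUE))[, seq_len(n),
                                                   drop = FALSE] / npad
  periods <- scales * spec$fourier_factor
  t_edge <- pmin(seq_len(n) - 1, n - seq_len(n)) * dt
  coi <- spec$fourier_factor * t_edge / sqrt(2)  # max reliable period per t
  inside <- outer(periods, coi, FUN = ">")       # TRUE = inside the cone
  structure(list(W = W, scales = scales, periods = periods,
                 freqs = 1 / periods, coi = coi, inside_coi = inside,
                 fs = fs, n = n, spec = spec),
            class = "cwt")
}

# Gaussian time smoothing (sd = scale) applied row-wise in the Fourier
# domain, then boxcar smoothing across scales (edge-renormalized averaging
# matrix). Works on real or complex A. The Fourier gain and the scale
# averaging matrix depend only on the grid, so they are cached.
.wtc_cache <- new.env(parent = emptyenv())

wtc_smooth_ops <- function(scales, dt, npad, spec) {
  key <- paste(npad, dt, length(scales), scales[1], scales[length(scales)],
               spec$scale_smooth_octaves, spec$voices_per_octave, sep = "|")
  hit <- .wtc_cache[[key]]
  if (!is.null(hit)) return(hit)
  k <- seq_len(npad) - 1
  omega <- 2 * pi * k / npad                     # radians per sample
  omega <- pmin(omega, 2 * pi - omega)
  gain <- exp(-0.5 * outer(omega, scales / dt)^2)  # npad x ns
  ns <- length(scales)
  half <- max(0L, floor(spec$scale_smooth_octaves * spec$voices_per_octave / 2))
  B <- diag(ns)
  if (half > 0) {
    B <- matrix(0, ns, ns)
    for (i in seq_len(ns)) {
      idx <- max(1L, i - half):min(ns, i + half)
      B[i, idx] <- 1 / length(idx)
    }
  }
  ops <- list(gain = gain, B = B)
  .wtc_cache[[key]] <- ops
  ops
}

wtc_smooth <- function(A, scales, dt, spec) {
  ns <- nrow(A); n <- ncol(A)
  npad <- 2^ceiling(log2(2 * n))
  ops <- wtc_smooth_ops(scales, dt, npad, spec)
  Apad <- matrix(0i, npad, ns)
  Apad[seq_len(n), ] <- t(A)
  sm <- stats::mvfft(stats::mvfft(Apad) * ops$gain, inverse = TRUE) / npad
  out <- ops$B %*% t(sm[seq_len(n), , drop = FALSE])
  if (!is.complex(A)) out <- Re(out)
  out
}

smoothed_power <- function(cw) {
  wtc_smooth(abs(cw$W)^2 / cw$scales, cw$scales, 1 / cw$fs, cw$spec)
}

coherence_from_cwt <- function(cwx, cwy, Px = NULL, Py = NULL) {
  stopifnot(identical(dim(cwx$W), dim(cwy$W)), cwx$fs == cwy$fs)
  dt <- 1 / cwx$fs
  if (is.null(Px)) Px <- smoothed_power(cwx)
  if (is.null(Py)) Py <- smoothed_power(cwy)
  Pxy <- wtc_smooth(cwx$W * Conj(cwy$W) / cwx$scales, cwx$scales, dt, cwx$spec)
  R2 <- Mod(Pxy)^2 / (Px * Py)
  if (max(R2, na.rm = TRUE) > 1 + 1e-9)
    warning("coherence exceeded 1 beyond numerical tolerance before clamping")
  R2 <- pmin(pmax(R2, 0), 1)
  structure(list(R2 = R2, freqs = cwx$freqs, periods = cwx$periods,
                 coi = cwx$coi, inside_coi = cwx$inside_coi, fs = cwx$fs),
            class = "coherence_spectrum")
}

#' Wavelet transform coherence between two series
#'
#' Time- and scale-resolved squared coherence
#' `R2 = |S(W_xy / s)|^2 / (S(|W_x|^2 / s) * S(|W_y|^2 / s))`
#' with smoothing operator `S` (Gaussian in time with sd equal to the
#' scale, boxcar across scales). Symmetric in its arguments.
#'
#' @param x,y Equal-length numeric series sampled at `fs`.
#' @param fs Sampling rate (Hz).
#' @param spec A [wavelet_spec()].
#' @return A `coherence_spectrum`: `R2` in `[0, 1]` (scales x time),
#'   frequency/period axes, and the cone-of-influence mask.
#' @export
wavelet_coherence <- function(x, y, fs, spec = wavelet_spec()) {
  if (length(x) != length(y)) stop("series lengths differ")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant series: coherence undefined")
  coherence_from_cwt(cwt_morlet(x, fs, spec), cwt_morlet(y, fs, spec))
}

#' Fisher r-to-z transform
#'
#' `z = atanh(min(r, 1 - 1e-7))`, applied to coherence values before
#' averaging and clustering; strictly increasing on `[0, 1]`, with `r = 1`
#' mapped to the finite `atanh(1 - 1e-7)`.
#'
#' @param r Coherence value(s) in `[0, 1]`.
#' @return Transformed value(s).
#' @export
fisher_z <- function(r) {
  eps <- 1e-7
  tol <- 1e-9
  if (any(r < -tol, na.rm = TRUE) || any(r > 1 + tol, na.rm = TRUE))
    stop("coherence values outside [0, 1]")
  atanh(pmin(pmax(r, 0), 1 - eps))
}
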