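# Shared small fixtures for fast tests. Heavy synthetic cohorts are built
# inside the tests that need them.

# Small, fast simulation configuration (short sessions, few ROIs).
small_sim_config <- function(seed = 1L, ...) {
  sim_config(
    sampling_rate = 5, n_rois = 4,
    session_plan = data.frame(label = c("rest", "taskA", "taskB", "rest"),
                              duration = c(60, 120, 120, 30)),
    seed = seed, ...)
}

small_wavelet_spec <- function() {
  wavelet_spec(voices_per_octave = 8, period_range = c(2, 30))
}

small_preprocess_config <- function() {
  preprocess_config(trim_head = 10, trim_tail = 10)
}

# A fixed frequency-band object on a given scale grid (for tests that
# exercise windowing/clustering without re-deriving the band).
fixed_foi <- function(freqs, f_lo = 0.10, f_hi = 0.19) {
  idx <- which(freqs >= f_lo & freqs <= f_hi)
  structure(list(f_lo = min(freqs[idx]), f_hi = max(freqs[idx]),
                 scale_idx = idx, p_threshold = NA_real_),
            class = "foi_band")
}

# Planted L1 clusters in feature space (for clustering-level tests that do
# not need the signal chain): k well-separated Laplace-ish clouds.
planted_clusters <- function(n_per, centers, spread = 0.1, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(c_i) {
    matrix(stats::rnorm(n_per * ncol(centers), sd = spread),
           n_per, ncol(centers)) +
      matrix(centers[c_i, ], n_per, ncol(centers), byrow = TRUE)
  }))
  list(X = X, labels = rep(seq_len(nrow(centers)), each = n_per))
}

# Brute-force Floyd-Warshall shortest paths on edge lengths (oracle).
floyd_warshall <- function(len) {
  n <- nrow(len)
  d <- len
  d[d == 0] <- Inf
  diag(d) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# Naive time-domain Morlet CWT (independent oracle for the FFT path):
# direct convolution with the analytic Morlet wavelet, trapezoid-free.
naive_cwt <- function(x, fs, spec, scales) {
  n <- length(x)
  dt <- 1 / fs
  x <- x - mean(x)
  W <- matrix(0i, length(scales), n)
  for (si in seq_along(scales)) {
    s <- scales[si]
    half <- min(n, ceiling(6 * s / dt))
    tt <- seq(-half, half) * dt
    eta <- tt / s
    psi <- pi^(-1 / 4) * exp(1i * spec$omega0 * eta - eta^2 / 2)
    # T&C normalization: wavelet scaled by sqrt(dt/s)
    kern <- Conj(psi) * sqrt(dt / s)
    for (t0 in seq_len(n)) {
      idx <- (t0 - half):(t0 + half)
      ok <- idx >= 1 & idx <= n
      W[si, t0] <- sum(x[idx[ok]] * kern[ok])
    }
  }
  W
}
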