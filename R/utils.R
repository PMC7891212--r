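# Internal numerical helpers shared across modules.

# Real gain profile for a zero-phase FFT filter. `low`/`high` are the -0 dB
# band edges; a raised-cosine ramp of width `trans` Hz sits outside each edge,
# so the filter is unity inside [low, high] and zero beyond the ramps.
fft_gain <- function(n, fs, low = NULL, high = NULL, trans = 1) {
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f) # two-sided spectrum folded to [0, fs/2]
  g <- rep(1, n)
  if (!is.null(low) && low > 0) {
    lo0 <- max(low - trans, 0)
    ramp <- (f - lo0) / max(low - lo0, .Machine$double.eps)
    g <- g * ifelse(f >= low, 1, ifelse(f <= lo0, 0, 0.5 - 0.5 * cos(pi * ramp)))
  }
  if (!is.null(high)) {
    hi1 <- min(high + trans, fs / 2)
    ramp <- (hi1 - f) / max(hi1 - high, .Machine$double.eps)
    g <- g * ifelse(f <= high, 1, ifelse(f >= hi1, 0, 0.5 - 0.5 * cos(pi * ramp)))
  }
  g
}

# Zero-phase band-pass by spectral multiplication with a real gain.
fft_bandpass <- function(x, fs, low, high, trans = 1) {
  n <- length(x)
  Re(stats::fft(stats::fft(x) * fft_gain(n, fs, low, high, trans),
                inverse = TRUE)) / n
}

# Sharp DFT notch: zero all bins within +/- half_bw of f0.
fft_notch <- function(x, fs, f0, half_bw = 1) {
  n <- length(x)
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f)
  g <- as.numeric(abs(f - f0) > half_bw)
  Re(stats::fft(stats::fft(x) * g, inverse = TRUE)) / n
}

# Analytic signal via the frequency-domain Hilbert construction.
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

# Apply a per-vector transform over the node x sample x trial array.
apply_node_trial <- function(arr, f, n_out = dim(arr)[2]) {
  d <- dim(arr)
  out <- array(0, dim = c(d[1], n_out, d[3]))
  for (tr in seq_len(d[3])) {
    for (nd in seq_len(d[1])) {
      out[nd, , tr] <- f(arr[nd, , tr])
    }
  }
  out
}

check_square <- function(m, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop(what, " must be a square matrix, got ",
         paste(dim(m), collapse = " x "), call. = FALSE)
  }
  invisible(m)
}

check_symmetric <- function(m, tol = 1e-8, what = "matrix") {
  check_square(m, what)
  if (max(abs(m - t(m))) > tol * max(1, max(abs(m)))) {
    stop(what, " must be symmetric", call. = FALSE)
  }
  invisible(m)
}

# 1/f^alpha-shaped gaussian noise, unit standard deviation.
pink_noise <- function(n, fs, alpha = 1) {
  w <- stats::rnorm(n)
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f)
  scale <- c(0, 1 / (f[-1]^(alpha / 2)))
  x <- Re(stats::fft(stats::fft(w) * scale, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Slow gaussian process (low-pass noise), unit sd, for amplitude modulators.
slow_noise <- function(n, fs, cutoff = 2) {
  x <- fft_bandpass(stats::rnorm(n), fs, low = 0, high = cutoff, trans = 0.5)
  s <- stats::sd(x)
  if (s < .Machine$double.eps) return(numeric(n))
  x / s
}
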