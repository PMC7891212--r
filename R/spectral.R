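#' Construct a source time-series set
#'
#' Container for multichannel source-space time series: a node x sample x
#' trial array together with its sampling rate and the epoch it covers,
#' expressed in seconds relative to stimulus onset.
#'
#' @param data numeric array, node x sample x trial. A node x sample matrix
#'   is promoted to a single trial.
#' @param fs sampling rate in Hz.
#' @param epoch length-2 numeric, epoch start and end in seconds relative to
#'   stimulus onset. The sample count must equal `(end - start) * fs` within
#'   one sample.
#' @param labels optional character vector of node names.
#' @return An object of class `source_ts`.
#' @export
source_ts <- function(data, fs, epoch, labels = NULL) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1))
  if (!is.array(data) || length(dim(data)) != 3) {
    stop("`data` must be a node x sample x trial array", call. = FALSE)
  }
  if (!all(is.finite(data))) stop("`data` contains non-finite values", call. = FALSE)
  if (fs <= 0) stop("`fs` must be positive", call. = FALSE)
  if (length(epoch) != 2 || epoch[2] <= epoch[1]) {
    stop("`epoch` must be c(start, end) with end > start", call. = FALSE)
  }
  n_expected <- (epoch[2] - epoch[1]) * fs
  if (abs(dim(data)[2] - n_expected) > 1) {
    stop("sample count ", dim(data)[2], " inconsistent with epoch of ",
         n_expected, " samples", call. = FALSE)
  }
  labels <- labels %||% paste0("node", seq_len(dim(data)[1]))
  stopifnot(length(labels) == dim(data)[1])
  structure(list(data = data, fs = fs, epoch = as.numeric(epoch),
                 labels = as.character(labels)),
            class = "source_ts")
}

#' @export
print.source_ts <- function(x, ...) {
  d <- dim(x$data)
  cat("<source_ts> ", d[1], " nodes x ", d[2], " samples x ", d[3],
      " trials @ ", x$fs, " Hz, epoch [", x$epoch[1], ", ", x$epoch[2],
      "] s\n", sep = "")
  invisible(x)
}

# Time axis of one trial.
ts_time <- function(ts) ts$epoch[1] + (seq_len(dim(ts$data)[2]) - 1) / ts$fs

# Sample index range covering [from, to] within the epoch.
window_index <- function(ts, window) {
  if (window[1] < ts$epoch[1] - 1e-9 || window[2] > ts$epoch[2] + 1e-9) {
    stop("window [", window[1], ", ", window[2], "] outside epoch [",
         ts$epoch[1], ", ", ts$epoch[2], "]", call. = FALSE)
  }
  i0 <- round((window[1] - ts$epoch[1]) * ts$fs) + 1
  i1 <- round((window[2] - ts$epoch[1]) * ts$fs)
  i1 <- min(i1, dim(ts$data)[2])
  seq.int(max(i0, 1), i1)
}

# Crop a source_ts to a sub-window of its epoch.
crop_ts <- function(ts, window) {
  idx <- window_index(ts, window)
  source_ts(ts$data[, idx, , drop = FALSE], ts$fs,
            c(window[1], window[1] + length(idx) / ts$fs), ts$labels)
}

#' Broadband preprocessing: band-pass and line-noise notch
#'
#' Applies a zero-phase band-pass filter and a sharp DFT notch at the power
#' line frequency to every node and trial. Both filters are implemented by
#' spectral multiplication with a real gain, so no group delay is introduced.
#'
#' @param ts a [source_ts()].
#' @param band length-2 numeric pass band in Hz (default 0.1--100).
#' @param notch line frequency in Hz to reject (default 60); `NULL` disables.
#' @param notch_halfwidth half-width of the notch in Hz.
#' @return A filtered `source_ts`.
#' @export
preprocess_broadband <- function(ts, band = c(0.1, 100), notch = 60,
                                 notch_halfwidth = 1) {
  stopifnot(inherits(ts, "source_ts"))
  nyq <- ts$fs / 2
  if (any(band >= nyq)) {
    stop("band edges (", paste(band, collapse = ", "),
         " Hz) must lie below the Nyquist frequency ", nyq, " Hz",
         call. = FALSE)
  }
  f <- function(x) {
    y <- fft_bandpass(x, ts$fs, band[1], band[2])
    if (!is.null(notch) && notch < nyq) y <- fft_notch(y, ts$fs, notch, notch_halfwidth)
    y
  }
  out <- apply_node_trial(ts$data, f)
  source_ts(out, ts$fs, ts$epoch, ts$labels)
}

#' Symmetric orthogonalization of source time series
#'
#' Removes zero-lag linear dependence ("signal leakage") among node time
#' courses by replacing them with the closest set of mutually orthogonal
#' signals, treating all nodes symmetrically: the result `Y = O D` (O with
#' orthonormal rows, D diagonal positive) minimizes the Frobenius distance to
#' the input, found by alternating a polar decomposition with a diagonal
#' rescaling step. Trials are concatenated along time before the
#' decomposition so the rank requirement is met, then split back.
#'
#' @param ts a [source_ts()] whose node count does not exceed its total
#'   (trial-concatenated) sample count.
#' @param max_iter,tol iteration cap and relative convergence tolerance for
#'   the alternating scheme.
#' @return A `source_ts` with pairwise-orthogonal node time courses.
#' @export
symmetric_orthogonalize <- function(ts, max_iter = 100, tol = 1e-12) {
  stopifnot(inherits(ts, "source_ts"))
  d <- dim(ts$data)
  n <- d[1]; nt <- d[2] * d[3]
  X <- matrix(aperm(ts$data, c(2, 3, 1)), nrow = nt, ncol = n) # samples x nodes
  if (n > nt) {
    stop("cannot orthogonalize ", n, " nodes with only ", nt,
         " samples (need at least one sample per node)", call. = FALSE)
  }
  r <- qr(X)$rank
  if (r < n) {
    stop("input is rank deficient: rank ", r, " < ", n,
         " nodes; orthogonalization is not defined", call. = FALSE)
  }
  dvec <- sqrt(colSums(X^2))
  last <- Inf
  for (k in seq_len(max_iter)) {
    sv <- svd(X %*% diag(dvec, n))
    O <- sv$u %*% t(sv$v) # orthonormal columns, closest to X D
    dvec <- pmax(colSums(X * O), .Machine$double.eps)
    err <- sum((X - O %*% diag(dvec, n))^2)
    if (abs(last - err) <= tol * max(err, 1)) break
    last <- err
  }
  Y <- O %*% diag(dvec, n)
  out <- aperm(array(Y, dim = c(d[2], d[3], n)), c(3, 1, 2))
  source_ts(out, ts$fs, ts$epoch, ts$labels)
}

#' Equal-width frequency bins
#'
#' Partitions `[low, high]` Hz into contiguous non-overlapping bins of equal
#' width. The defaults give the ten 5 Hz bins from 0.5 to 50.5 Hz used for
#' frequency-binned envelope connectivity.
#'
#' @param low,high range edges in Hz; `high - low` must be an exact multiple
#'   of `width`.
#' @param width bin width in Hz.
#' @return A tibble with columns `bin` (index), `low_hz`, `high_hz`.
#' @export
#' @examples
#' make_bins() # ten 5 Hz bins, 0.5-5.5 ... 45.5-50.5
make_bins <- function(low = 0.5, high = 50.5, width = 5) {
  stopifnot(low >= 0, high > low, width > 0)
  k <- (high - low) / width
  if (abs(k - round(k)) > 1e-9) {
    stop("(high - low) = ", high - low, " is not divisible by width = ",
         width, "; no partial bins are produced", call. = FALSE)
  }
  k <- round(k)
  edges <- low + width * (0:k)
  tibble::tibble(bin = seq_len(k), low_hz = edges[-(k + 1)], high_hz = edges[-1])
}

#' Band-limited Hilbert amplitude envelopes
#'
#' Band-pass filters each node/trial into every frequency bin over the full
#' epoch, takes the modulus of the analytic signal, and only then crops to
#' the analysis window, so filter and Hilbert edge effects stay outside the
#' retained samples.
#'
#' @param ts a [source_ts()].
#' @param bins a bin table from [make_bins()]; all bins must lie below the
#'   Nyquist frequency.
#' @param window length-2 numeric analysis window in seconds, within the
#'   epoch (default `c(0.8, 1.3)`).
#' @return An object of class `envelope_set`: per-bin node x sample x trial
#'   envelope arrays restricted to `window`.
#' @export
band_envelopes <- function(ts, bins, window = c(0.8, 1.3)) {
  stopifnot(inherits(ts, "source_ts"))
  if (max(bins$high_hz) >= ts$fs / 2) {
    stop("bin edge ", max(bins$high_hz), " Hz at or above Nyquist ",
         ts$fs / 2, " Hz", call. = FALSE)
  }
  idx <- window_index(ts, window)
  env <- lapply(seq_len(nrow(bins)), function(b) {
    filt_env <- function(x) {
      Mod(analytic_signal(fft_bandpass(x, ts$fs, bins$low_hz[b], bins$high_hz[b])))
    }
    apply_node_trial(ts$data, filt_env)[, idx, , drop = FALSE]
  })
  structure(list(env = env, bins = bins, window = as.numeric(window),
                 fs = ts$fs, labels = ts$labels),
            class = "envelope_set")
}

#' @export
print.envelope_set <- function(x, ...) {
  d <- dim(x$env[[1]])
  cat("<envelope_set> ", nrow(x$bins), " bins, ", d[1], " nodes x ", d[2],
      " samples x ", d[3], " trials, window [", x$window[1], ", ",
      x$window[2], "] s\n", sep = "")
  invisible(x)
}

#' Amplitude--amplitude coupling between two envelopes
#'
#' The product-moment (Pearson) correlation of two amplitude envelopes.
#'
#' @param env_x,env_y numeric vectors of equal length (at least 3) with
#'   nonzero variance.
#' @return Correlation in `[-1, 1]`.
#' @export
aac <- function(env_x, env_y) {
  if (length(env_x) != length(env_y)) stop("envelopes differ in length", call. = FALSE)
  if (length(env_x) < 3) stop("need at least 3 samples", call. = FALSE)
  if (stats::sd(env_x) == 0 || stats::sd(env_y) == 0) {
    stop("zero-variance envelope: degenerate connection", call. = FALSE)
  }
  stats::cor(env_x, env_y)
}

# Envelope array [N x W x T] -> (W*T) x N matrix, trials concatenated.
env_to_matrix <- function(e) {
  d <- dim(e)
  matrix(aperm(e, c(2, 3, 1)), nrow = d[2] * d[3], ncol = d[1])
}

# Pearson matrix with an explicit degenerate-column check.
cor_checked <- function(A, B = NULL, labels_a, labels_b = labels_a) {
  bad_a <- which(apply(A, 2, stats::sd) == 0)
  if (length(bad_a)) {
    stop("zero-variance envelope for node(s) ",
         paste(labels_a[bad_a], collapse = ", "), call. = FALSE)
  }
  if (is.null(B)) return(stats::cor(A))
  bad_b <- which(apply(B, 2, stats::sd) == 0)
  if (length(bad_b)) {
    stop("zero-variance envelope for node(s) ",
         paste(labels_b[bad_b], collapse = ", "), call. = FALSE)
  }
  stats::cor(A, B)
}

new_conn_block <- function(mat, bin_a, bin_b, labels = NULL) {
  if (!is.null(labels)) dimnames(mat) <- list(labels, labels)
  structure(list(bin_a = bin_a, bin_b = bin_b,
                 kind = if (bin_a == bin_b) "within" else "between",
                 mat = mat),
            class = "conn_block")
}

#' @export
print.conn_block <- function(x, ...) {
  cat("<conn_block> ", x$kind, " bins (", x$bin_a, ", ", x$bin_b, "), ",
      nrow(x$mat), " nodes\n", sep = "")
  invisible(x)
}

#' Within- and between-bin connectivity blocks
#'
#' Computes amplitude--amplitude coupling for every node pair within each
#' frequency bin and between every ordered low-to-high bin pair: `B` within
#' blocks plus `B(B-1)/2` between blocks. Within blocks are symmetric with a
#' zero diagonal; between blocks are returned raw (asymmetric, including the
#' cross-frequency self-coupling diagonal) and are made symmetric later with
#' [symmetrize_max()].
#'
#' @param env an [band_envelopes()] result.
#' @param pool `"concatenate"` (default) correlates envelopes concatenated
#'   across trials; `"average"` correlates per trial and averages the
#'   coefficients.
#' @return A list of `conn_block` objects, within blocks first, then between
#'   blocks in low-to-high order.
#' @export
connectivity_blocks <- function(env, pool = c("concatenate", "average")) {
  stopifnot(inherits(env, "envelope_set"))
  pool <- match.arg(pool)
  B <- nrow(env$bins)
  n <- dim(env$env[[1]])[1]
  if (n < 2) stop("need at least 2 nodes", call. = FALSE)
  n_trials <- dim(env$env[[1]])[3]

  block_cor <- function(a, b) {
    if (pool == "concatenate") {
      A <- env_to_matrix(env$env[[a]])
      Bm <- if (a == b) NULL else env_to_matrix(env$env[[b]])
      cor_checked(A, Bm, env$labels)
    } else {
      mats <- lapply(seq_len(n_trials), function(tr) {
        A <- t(env$env[[a]][, , tr])
        Bm <- if (a == b) NULL else t(env$env[[b]][, , tr])
        cor_checked(A, Bm, env$labels)
      })
      Reduce(`+`, mats) / n_trials
    }
  }

  within <- lapply(seq_len(B), function(b) {
    m <- block_cor(b, b)
    diag(m) <- 0
    new_conn_block(m, b, b, env$labels)
  })
  between <- list()
  if (B > 1) {
    for (a in seq_len(B - 1)) {
      for (b in (a + 1):B) {
        between[[length(between) + 1]] <-
          new_conn_block(block_cor(a, b), a, b, env$labels)
      }
    }
  }
  c(within, between)
}

#' Symmetrize a connectivity block by the elementwise maximum
#'
#' For a directed between-frequency block, keeps the larger of the two
#' directed couplings for every region pair so the block becomes symmetric
#' and undirected; the diagonal is preserved.
#'
#' @param block a `conn_block` or a square numeric matrix.
#' @return Same type as the input, with `out[i,j] = max(in[i,j], in[j,i])`.
#' @export
symmetrize_max <- function(block) {
  if (inherits(block, "conn_block")) {
    block$mat <- symmetrize_max(block$mat)
    return(block)
  }
  check_square(block, "connectivity block")
  pmax(block, t(block))
}
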