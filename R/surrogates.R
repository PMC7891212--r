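#' IAAFT surrogate of a time series
#'
#' Iterative amplitude-adjusted Fourier transform surrogate: preserves the
#' amplitude distribution of the input exactly (the final step is a rank
#' remap onto the original sorted values) and matches its power spectrum to
#' within the convergence tolerance, while destroying any dependence between
#' the series and other signals.
#'
#' @param x numeric vector, length at least 8, non-constant.
#' @param max_iter iteration cap (default 100).
#' @param tol stop when the relative change in spectral amplitude error
#'   falls below `tol` (default 1e-6).
#' @param seed optional integer; when given, the surrogate is reproducible.
#' @return A numeric vector that is a permutation of `x`, with attributes
#'   `iterations` and `spec_err_trace` (relative spectral amplitude error
#'   after each iteration).
#' @export
iaaft <- function(x, max_iter = 100, tol = 1e-6, seed = NULL) {
  if (length(x) < 8) stop("need at least 8 samples", call. = FALSE)
  if (!all(is.finite(x))) stop("input must be finite", call. = FALSE)
  if (stats::sd(x) == 0) {
    stop("constant input: phase randomization is undefined", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  amp_sorted <- sort(x)
  target <- Mod(stats::fft(x))
  target_norm <- sqrt(sum(target^2))
  s <- sample(x)
  trace <- numeric(0)
  last <- Inf
  iters <- 0
  for (k in seq_len(max_iter)) {
    iters <- k
    S <- stats::fft(s)
    mag <- Mod(S)
    phase <- ifelse(mag > 0, S / mag, 1 + 0i)
    s2 <- Re(stats::fft(target * phase, inverse = TRUE)) / n
    s <- amp_sorted[rank(s2, ties.method = "first")]
    err <- sqrt(sum((Mod(stats::fft(s)) - target)^2)) / target_norm
    trace <- c(trace, err)
    if (is.finite(last) && abs(last - err) < tol * max(err, .Machine$double.eps)) break
    last <- err
  }
  attr(s, "iterations") <- iters
  attr(s, "spec_err_trace") <- trace
  s
}

#' Surrogate-based null connectivity statistics
#'
#' Builds `n_surrogates` null datasets by replacing every node and trial
#' with its s-th IAAFT surrogate simultaneously (destroying all genuine
#' coupling while preserving each node's spectrum and amplitude
#' distribution), re-runs the band-envelope connectivity pipeline on each,
#' and returns the per-connection mean and sample standard deviation of the
#' null coupling values.
#'
#' Surrogates are generated on `surrogate_window` (by default the
#' post-stimulus part of the epoch, 0 s to epoch end), then connectivity is
#' computed on the usual analysis `window` inside it.
#'
#' @param ts a [source_ts()] (already orthogonalized, in the standard
#'   pipeline order).
#' @param bins bin table from [make_bins()].
#' @param window analysis window in seconds.
#' @param n_surrogates number of null datasets (default 100).
#' @param seed integer seed for reproducibility.
#' @param surrogate_window window on which surrogates are generated;
#'   defaults to `c(max(0, epoch start), epoch end)`.
#' @param pool trial pooling, as in [connectivity_blocks()].
#' @param max_iter,tol IAAFT controls, see [iaaft()].
#' @return An object of class `null_stats`: per block, matrices `mean` and
#'   `sd` of the null coupling.
#' @export
null_connectivity <- function(ts, bins, window = c(0.8, 1.3),
                              n_surrogates = 100, seed = NULL,
                              surrogate_window = NULL,
                              pool = "concatenate",
                              max_iter = 100, tol = 1e-6) {
  stopifnot(inherits(ts, "source_ts"))
  if (n_surrogates < 2) stop("need at least 2 surrogates", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  surrogate_window <- surrogate_window %||% c(max(0, ts$epoch[1]), ts$epoch[2])
  base <- crop_ts(ts, surrogate_window)
  d <- dim(base$data)
  sums <- NULL
  sqs <- NULL
  meta <- NULL
  for (s in seq_len(n_surrogates)) {
    surr <- apply_node_trial(base$data, function(x) {
      as.numeric(iaaft(x, max_iter = max_iter, tol = tol))
    })
    sts <- source_ts(surr, base$fs, base$epoch, base$labels)
    blocks <- connectivity_blocks(band_envelopes(sts, bins, window), pool = pool)
    if (is.null(sums)) {
      sums <- lapply(blocks, function(b) b$mat * 0)
      sqs <- sums
      meta <- lapply(blocks, function(b) b[c("bin_a", "bin_b", "kind")])
    }
    for (i in seq_along(blocks)) {
      sums[[i]] <- sums[[i]] + blocks[[i]]$mat
      sqs[[i]] <- sqs[[i]] + blocks[[i]]$mat^2
    }
  }
  stats_list <- lapply(seq_along(sums), function(i) {
    m <- sums[[i]] / n_surrogates
    v <- pmax(sqs[[i]] - n_surrogates * m^2, 0) / (n_surrogates - 1)
    c(meta[[i]], list(mean = m, sd = sqrt(v)))
  })
  structure(list(blocks = stats_list, n_surrogates = n_surrogates,
                 bins = bins, window = window,
                 surrogate_window = surrogate_window),
            class = "null_stats")
}

#' @export
print.null_stats <- function(x, ...) {
  cat("<null_stats> ", length(x$blocks), " blocks, ", x$n_surrogates,
      " surrogates\n", sep = "")
  invisible(x)
}

#' Z-score empirical connectivity against the surrogate null
#'
#' `z[i,j] = (emp[i,j] - mean_null[i,j]) / sd_null[i,j]`. Connections with a
#' degenerate null (`sd_null = 0`) are set to 0 rather than infinity, so they
#' can never become edges, and their count is reported via a message.
#'
#' @param empirical list of `conn_block`s from [connectivity_blocks()].
#' @param null a `null_stats` object matching the empirical blocks.
#' @return A list of `conn_block`s holding z-scores.
#' @export
zscore_blocks <- function(empirical, null) {
  stopifnot(inherits(null, "null_stats"))
  if (length(empirical) != length(null$blocks)) {
    stop("block count mismatch: ", length(empirical), " empirical vs ",
         length(null$blocks), " null", call. = FALSE)
  }
  n_degenerate <- 0L
  out <- lapply(seq_along(empirical), function(i) {
    b <- empirical[[i]]
    nb <- null$blocks[[i]]
    if (b$bin_a != nb$bin_a || b$bin_b != nb$bin_b ||
        !identical(dim(b$mat), dim(nb$mean))) {
      stop("shape/bin mismatch at block ", i, " (bins ", b$bin_a, ",",
           b$bin_b, ")", call. = FALSE)
    }
    z <- (b$mat - nb$mean) / nb$sd
    bad <- nb$sd == 0
    count <- bad
    if (b$kind == "within") diag(count) <- FALSE # diagonal is structurally zero
    n_degenerate <<- n_degenerate + sum(count)
    z[bad] <- 0
    b$mat <- z
    b
  })
  if (n_degenerate > 0) {
    message(n_degenerate, " connection(s) had a degenerate null (sd = 0); z set to 0")
  }
  out
}
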