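test_that("broadband preprocessing rejects line noise and preserves the passband", {
  fs <- 500
  epoch <- c(0, 2)
  tt <- seq(0, 2 - 1 / fs, by = 1 / fs)
  x60 <- sin(2 * pi * 60 * tt)
  x10 <- sin(2 * pi * 10 * tt)
  ts <- source_ts(rbind(x60, x10), fs, epoch)
  out <- preprocess_broadband(ts)
  rms <- function(v) sqrt(mean(v^2))
  expect_lt(rms(out$data[1, , 1]), 0.1 * rms(x60))
  expect_lt(abs(rms(out$data[2, , 1]) - rms(x10)) / rms(x10), 0.05)
})

test_that("frequencies above the broadband edge are attenuated by >= 20 dB", {
  fs <- 500
  ts <- white_ts(1, fs, c(0, 4), seed = 42)
  out <- preprocess_broadband(ts)
  spec <- Mod(fft(out$data[1, , 1]))^2
  f <- (seq_along(spec) - 1) / length(spec) * fs
  pass <- mean(spec[f > 10 & f < 50])
  stopband <- mean(spec[f > 105 & f < 200])
  expect_lt(stopband, pass / 100) # >= 20 dB down
})

test_that("band edges at or above Nyquist are rejected", {
  ts <- white_ts(2, 100, c(0, 1))
  expect_error(preprocess_broadband(ts, band = c(0.1, 60)), "Nyquist")
})

test_that("symmetric orthogonalization yields a diagonal Gram matrix and fixes orthogonal input", {
  set.seed(7)
  n <- 4; nt <- 200
  X <- matrix(rnorm(n * nt), n, nt)
  ts <- source_ts(X, fs = nt, epoch = c(0, 1))
  out <- symmetric_orthogonalize(ts)
  Y <- out$data[, , 1]
  G <- Y %*% t(Y)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8 * max(diag(G)))
  # orthogonal input is a fixed point
  Q <- qr.Q(qr(t(X)))[, 1:n] # orthonormal columns
  Xo <- t(Q) * c(1, 2, 3, 4) # orthogonal rows, distinct norms
  tso <- source_ts(Xo, fs = nt, epoch = c(0, 1))
  outo <- symmetric_orthogonalize(tso)
  expect_lt(max(abs(outo$data[, , 1] - Xo)), 1e-8)
})

test_that("rank-deficient input is rejected with the deficient dimension named", {
  X <- matrix(rnorm(2 * 3), 3, 2) # 3 nodes, 2 samples
  X <- rbind(X[1, ], X[2, ], X[1, ] + X[2, ])
  ts <- source_ts(array(X, dim = c(3, 2, 1)), fs = 2, epoch = c(0, 1))
  expect_error(symmetric_orthogonalize(ts), "3 nodes")
  # more nodes than samples, independent rows
  set.seed(1)
  ts2 <- source_ts(matrix(rnorm(8), 4, 2), fs = 2, epoch = c(0, 1))
  expect_error(symmetric_orthogonalize(ts2), "orthogonalize")
})

test_that("make_bins produces the canonical ten 5 Hz bins and rejects indivisible ranges", {
  b <- make_bins()
  expect_equal(nrow(b), 10)
  expect_equal(c(b$low_hz[1], b$high_hz[1]), c(0.5, 5.5))
  expect_equal(c(b$low_hz[10], b$high_hz[10]), c(45.5, 50.5))
  expect_true(all(b$high_hz[-10] == b$low_hz[-1])) # contiguous
  b2 <- make_bins(0, 10, 5)
  expect_equal(b2$low_hz, c(0, 5))
  expect_equal(b2$high_hz, c(5, 10))
  expect_error(make_bins(0, 7, 5), "divisible")
})

test_that("the Hilbert envelope recovers constant and slowly varying amplitudes", {
  fs <- 100
  epoch <- c(0, 3)
  tt <- seq(0, 3 - 1 / fs, by = 1 / fs)
  carrier <- sin(2 * pi * 8 * tt)
  am <- (1 + 0.5 * sin(2 * pi * 1 * tt))
  ts <- source_ts(rbind(carrier, am * carrier, 0 * tt), fs, epoch)
  env <- band_envelopes(ts, bins2(), window = c(0.8, 1.3))
  e <- env$env[[2]] # bin (5.5, 10.5) holds the 8 Hz carrier
  idx <- round(0.8 * fs) + seq_len(dim(e)[2])
  expect_lt(max(abs(e[1, , 1] - 1)), 0.05)
  a_true <- am[idx]
  expect_lt(sqrt(mean((e[2, , 1] - a_true)^2)) / sqrt(mean(a_true^2)), 0.05)
  expect_equal(max(e[3, , 1]), 0)
})

test_that("analysis windows outside the epoch and bins above Nyquist error", {
  ts <- white_ts(2, 100, c(0, 1))
  expect_error(band_envelopes(ts, bins2(), window = c(0.8, 1.3)), "outside epoch")
  ts2 <- white_ts(2, 20, c(0, 2))
  expect_error(band_envelopes(ts2, bins2(), window = c(0.8, 1.3)), "Nyquist")
})

test_that("aac matches the textbook product-moment correlation", {
  expect_equal(aac(c(1, 5, 3, 2, 8), c(1, 5, 3, 2, 8)), 1.0)
  expect_equal(aac(c(1, 5, 3, 2, 8), 10 - 2 * c(1, 5, 3, 2, 8)), -1.0)
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 6)
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(aac(x, y), num / den)
  expect_error(aac(c(1, 1, 1), c(1, 2, 3)), "zero-variance")
  expect_error(aac(1:4, 1:3), "length")
})

test_that("connectivity block counts follow B + B(B-1)/2", {
  fs <- 210
  ts <- white_ts(3, fs, c(0, 1.5), seed = 3)
  blocks10 <- connectivity_blocks(
    band_envelopes(ts, make_bins(0.5, 50.5, 5), window = c(0.5, 1)))
  expect_length(blocks10, 55)
  blocks4 <- connectivity_blocks(
    band_envelopes(ts, make_bins(0.5, 20.5, 5), window = c(0.5, 1)))
  expect_length(blocks4, 10)
  expect_equal(sum(vapply(blocks4, function(b) b$kind == "within", logical(1))), 4)
  blocks1 <- connectivity_blocks(
    band_envelopes(ts, make_bins(0.5, 5.5, 5), window = c(0.5, 1)))
  expect_length(blocks1, 1)
  expect_equal(blocks1[[1]]$kind, "within")
  # within blocks are exactly symmetric with zero diagonal
  w <- blocks4[[1]]$mat
  expect_equal(w, t(w))
  expect_equal(diag(w), rep(0, 3), ignore_attr = TRUE)
})

test_that("permuting node order permutes all blocks consistently", {
  fs <- 80
  ts <- white_ts(4, fs, c(0, 2), n_trials = 2, seed = 9)
  perm <- c(3, 1, 4, 2)
  tsp <- source_ts(ts$data[perm, , , drop = FALSE], fs, ts$epoch,
                   ts$labels[perm])
  b1 <- connectivity_blocks(band_envelopes(ts, bins2(), window = c(0.8, 1.3)))
  b2 <- connectivity_blocks(band_envelopes(tsp, bins2(), window = c(0.8, 1.3)))
  for (k in seq_along(b1)) {
    expect_equal(b2[[k]]$mat, b1[[k]]$mat[perm, perm], tolerance = 1e-12)
  }
})

test_that("symmetrize_max keeps the larger directed coupling and fixes symmetric input", {
  m <- matrix(c(0, 0.3, 0.7, 0), 2, 2, byrow = TRUE)
  expect_equal(symmetrize_max(m), matrix(c(0, 0.7, 0.7, 0), 2, 2))
  s <- matrix(c(0, 0.4, 0.4, 0), 2, 2)
  expect_equal(symmetrize_max(s), s)
  z <- matrix(0, 3, 3)
  expect_equal(symmetrize_max(z), z)
  expect_error(symmetrize_max(matrix(0, 2, 3)), "square")
})

test_that("a single planted pair dominates its between block across seeds", {
  hits <- 0
  n_seeds <- 20
  for (s in seq_len(n_seeds)) {
    cfg <- synth_config(n_nodes = 6, n_trials = 12, fs = 80,
                        epoch = c(-0.2, 2), bins = bins2(),
                        planted_pairs = data.frame(node_i = 1, node_j = 2,
                                                   bin_a = 1, bin_b = 2,
                                                   strength = 0.9),
                        seed = 1000 + s)
    ts <- generate_coupled_timeseries(cfg)
    blocks <- connectivity_blocks(band_envelopes(ts, bins2(),
                                                 window = c(0.8, 1.3)))
    bet <- blocks[[3]]$mat # the single between block (1,2)
    off <- bet
    diag(off) <- -Inf
    hits <- hits + (which.max(off) == which(row(off) == 1 & col(off) == 2))
  }
  expect_gte(hits / n_seeds, 0.95)
})
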