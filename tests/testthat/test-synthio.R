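test_that("structural generator: density 1 gives the complete graph", {
  sc <- generate_structural_matrix(4, 1.0, n_modules = 1, seed = 1)
  expect_equal(sum(sc$mat[upper.tri(sc$mat)]), 6)
  expect_equal(sc$mat, t(sc$mat))
  expect_equal(diag(sc$mat), rep(0, 4), ignore_attr = TRUE)
})

test_that("structural generator is seed-deterministic and density-accurate", {
  a <- generate_structural_matrix(10, 0.3, n_modules = 2, seed = 7)
  b <- generate_structural_matrix(10, 0.3, n_modules = 2, seed = 7)
  expect_identical(a$mat, b$mat)
  sc <- generate_structural_matrix(50, 0.2, n_modules = 2, seed = 3)
  realized <- sum(sc$mat[upper.tri(sc$mat)]) / (50 * 49 / 2)
  expect_lt(abs(realized - 0.2), 0.05)
  g <- igraph::graph_from_adjacency_matrix(sc$mat, mode = "undirected")
  expect_true(igraph::is_connected(g))
  # within-module edges denser than between-module edges
  same <- outer(sc$modules, sc$modules, "==") & upper.tri(sc$mat)
  diff <- (!outer(sc$modules, sc$modules, "==")) & upper.tri(sc$mat)
  expect_gt(mean(sc$mat[same]), mean(sc$mat[diff]))
})

test_that("structural generator respects requested density within binomial error", {
  set.seed(11)
  for (dens in c(0.15, 0.4)) {
    sc <- generate_structural_matrix(40, dens, n_modules = 2,
                                     seed = sample.int(1e6, 1))
    pairs <- 40 * 39 / 2
    realized <- sum(sc$mat[upper.tri(sc$mat)]) / pairs
    expect_lt(abs(realized - dens), 4 * sqrt(dens * (1 - dens) / pairs))
  }
})

test_that("too-low density for connectivity errors explicitly", {
  expect_error(generate_structural_matrix(10, 0.01, seed = 1), "too low")
})

test_that("uncoupled nodes have near-zero envelope correlations", {
  cfg <- synth_config(n_nodes = 4, n_trials = 12, fs = 80,
                      epoch = c(-0.2, 2.2), bins = bins2(),
                      planted_pairs = data.frame(
                        node_i = c(1, 3), node_j = c(2, 4),
                        bin_a = c(1, 1), bin_b = c(2, 2),
                        strength = c(0, 0)),
                      seed = 5)
  ts <- generate_coupled_timeseries(cfg)
  env <- band_envelopes(ts, bins2(), window = c(0.3, 1.9))
  # decimate envelopes past their autocorrelation time before correlating,
  # so the iid bound 3/sqrt(T) applies to the retained sample count
  keep <- seq(1, dim(env$env[[1]])[2], by = round(0.25 * 80))
  rs <- c()
  for (b in 1:2) {
    e <- env$env[[b]][, keep, , drop = FALSE]
    m <- matrix(aperm(e, c(2, 3, 1)), ncol = 4)
    cc <- cor(m)
    rs <- c(rs, cc[upper.tri(cc)])
  }
  t_eff <- 12 * length(keep)
  expect_gte(mean(abs(rs) < 3 / sqrt(t_eff)), 0.95)
})

test_that("a strongly coupled pair stands out from the unplanted background", {
  cfg <- synth_config(n_nodes = 6, n_trials = 12, fs = 80,
                      epoch = c(-0.2, 2), bins = bins2(),
                      planted_pairs = data.frame(node_i = 1, node_j = 2,
                                                 bin_a = 1, bin_b = 2,
                                                 strength = 0.9),
                      seed = 21)
  ts <- generate_coupled_timeseries(cfg)
  blocks <- connectivity_blocks(band_envelopes(ts, bins2(),
                                               window = c(0.8, 1.3)))
  bet <- blocks[[3]]$mat
  planted <- bet[1, 2]
  others <- bet[-(which(row(bet) == 1 & col(bet) == 2))]
  expect_gt(planted, quantile(others, 0.95))
})

test_that("time-series generation is bit-identical under a fixed seed", {
  cfg <- synth_config(n_nodes = 3, n_trials = 2, fs = 80,
                      epoch = c(-0.2, 2), bins = bins2(),
                      hub_node = NULL, seed = 99)
  a <- generate_coupled_timeseries(cfg)
  b <- generate_coupled_timeseries(cfg)
  expect_identical(a$data, b$data)
})

test_that("planted coupling strengthens mean AAC monotonically", {
  mean_aac <- function(strength) {
    vals <- vapply(1:10, function(s) {
      cfg <- synth_config(n_nodes = 4, n_trials = 3, fs = 80,
                          epoch = c(-0.2, 2), bins = bins2(),
                          planted_pairs = data.frame(node_i = 1, node_j = 2,
                                                     bin_a = 1, bin_b = 2,
                                                     strength = strength),
                          seed = 400 + s)
      ts <- generate_coupled_timeseries(cfg)
      blocks <- connectivity_blocks(band_envelopes(ts, bins2(),
                                                   window = c(0.8, 1.3)))
      blocks[[3]]$mat[1, 2]
    }, numeric(1))
    mean(vals)
  }
  m <- vapply(c(0.2, 0.5, 0.9), mean_aac, numeric(1))
  expect_true(all(diff(m) > 0))
})

test_that("synth_config validates strengths, nodes, bins and Nyquist", {
  expect_error(synth_config(4, fs = 80, bins = bins2(),
                            planted_pairs = data.frame(node_i = 1, node_j = 2,
                                                       bin_a = 1, bin_b = 2,
                                                       strength = 1.5)),
               "strength")
  expect_error(synth_config(4, fs = 80, bins = bins2(),
                            planted_pairs = data.frame(node_i = 1, node_j = 9,
                                                       bin_a = 1, bin_b = 2,
                                                       strength = 0.5)),
               "node")
  expect_error(synth_config(4, fs = 80, bins = bins2(), hub_node = 9), "hub_node")
  expect_error(synth_config(4, fs = 15, bins = bins2()), "Nyquist|twice")
})

test_that("multilayer fixture plants a dominant connector hub", {
  sup <- generate_multilayer_fixture(8, 3, intralayer_density = 0.4,
                                     interlayer_density = 0.06,
                                     planted_hub = 2, seed = 12)
  B <- sup$n_layers
  cnt <- integer(8)
  for (a in 1:(B - 1)) for (b in (a + 1):B) {
    nz <- which(supra_block(sup, a, b) != 0, arr.ind = TRUE)
    for (r in seq_len(nrow(nz))) {
      cnt[nz[r, 1]] <- cnt[nz[r, 1]] + 1L
      if (nz[r, 2] != nz[r, 1]) cnt[nz[r, 2]] <- cnt[nz[r, 2]] + 1L
    }
  }
  expect_gte(cnt[2], 2 * max(cnt[-2]))
  expect_equal(sup$mat, t(sup$mat))
  expect_equal(diag(sup$mat), rep(0, 24), ignore_attr = TRUE)
})

test_that("fixture respects degenerate and deterministic cases", {
  sup0 <- generate_multilayer_fixture(6, 2, interlayer_density = 0, seed = 4)
  expect_equal(interconnectedness(sup0), 0L)
  a <- generate_multilayer_fixture(6, 2, seed = 8)
  b <- generate_multilayer_fixture(6, 2, seed = 8)
  expect_identical(a$mat, b$mat)
  expect_error(generate_multilayer_fixture(6, 1), "at least 2 layers")
})

test_that("fixture's planted hub attains DCI rank 1", {
  sup <- generate_multilayer_fixture(10, 3, interlayer_density = 0.05,
                                     planted_hub = 1, seed = 31)
  prof <- dci_profile(sup, seq_len(10))
  expect_equal(which.max(prof$dci_scaled), 1L)
})

test_that("time series and structural matrices round-trip through disk", {
  dir <- withr::local_tempdir()
  cfg <- synth_config(n_nodes = 3, n_trials = 2, fs = 80,
                      epoch = c(-0.2, 2), bins = bins2(), seed = 14)
  ts <- generate_coupled_timeseries(cfg)
  write_timeseries(ts, file.path(dir, "ts"))
  ts2 <- read_timeseries(file.path(dir, "ts"))
  expect_equal(ts2$data, ts$data, tolerance = 1e-12)
  expect_equal(ts2$fs, ts$fs)
  expect_equal(ts2$labels, ts$labels)
  sc <- generate_structural_matrix(5, 0.6, seed = 2)
  write_structural(sc, file.path(dir, "sc.tsv"))
  sc2 <- read_structural(file.path(dir, "sc.tsv"))
  expect_equal(sc2$mat, sc$mat)
})
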