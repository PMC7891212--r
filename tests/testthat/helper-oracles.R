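# Independent oracles and small fixture builders shared across tests.
# Each oracle re-derives the quantity from first principles, by a different
# route than the package implementation.

# Count interlayer edges directly from a list of between-layer blocks
# (every nonzero entry of each (a<b) block is one interlayer edge).
oracle_count_interlayer <- function(between_mats, drop_node = NULL) {
  total <- 0
  for (m in between_mats) {
    if (!is.null(drop_node)) m <- m[-drop_node, -drop_node, drop = FALSE]
    total <- total + sum(m != 0)
  }
  total
}

# Rebuild-from-scratch DCI oracle: extract the between blocks of a supra
# matrix, drop the node from every block, and recount.
oracle_dci <- function(supra, node) {
  B <- supra$n_layers
  between <- list()
  for (a in seq_len(B - 1)) {
    for (b in (a + 1):B) {
      between[[length(between) + 1]] <- supra_block(supra, a, b)
    }
  }
  i_full <- oracle_count_interlayer(between)
  i_rm <- oracle_count_interlayer(between, drop_node = node)
  100 * (i_full - i_rm) / i_full
}

# Exhaustive orthogonal-MST prefix oracle. Uses igraph::mst (independent of
# the package's Kruskal) and its own efficiency computation from shortest
# path distances. Requires tie-free weights.
oracle_efficiency <- function(mat) {
  n <- nrow(mat)
  ut <- which(upper.tri(mat) & mat > 0, arr.ind = TRUE)
  if (nrow(ut) == 0) return(0)
  g <- igraph::graph_from_data_frame(
    data.frame(from = ut[, 1], to = ut[, 2]), directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  d <- igraph::distances(g, weights = 1 / mat[ut])
  inv <- 1 / d[upper.tri(d)]
  inv[!is.finite(inv)] <- 0
  mean(inv)
}

oracle_omst <- function(weights) {
  n <- nrow(weights)
  total_w <- sum(weights[upper.tri(weights)])
  ge_full <- oracle_efficiency(weights)
  remaining <- weights
  retained <- weights * 0
  js <- numeric(0)
  unions <- list()
  repeat {
    ut <- which(upper.tri(remaining) & remaining > 0, arr.ind = TRUE)
    if (nrow(ut) == 0) break
    g <- igraph::graph_from_data_frame(
      data.frame(from = ut[, 1], to = ut[, 2]), directed = FALSE,
      vertices = data.frame(name = seq_len(n)))
    if (igraph::components(g)$no > 1) break
    mt <- igraph::mst(g, weights = 1 / remaining[ut])
    el <- igraph::as_edgelist(mt)
    for (r in seq_len(nrow(el))) {
      i <- as.integer(el[r, 1]); j <- as.integer(el[r, 2])
      retained[i, j] <- weights[i, j]
      retained[j, i] <- weights[j, i]
      remaining[i, j] <- 0
      remaining[j, i] <- 0
    }
    ge <- oracle_efficiency(retained)
    cost <- sum(retained[upper.tri(retained)]) / total_w
    js <- c(js, ge / ge_full - cost)
    unions[[length(unions) + 1]] <- retained
  }
  best <- which.max(js)
  list(retained = unions[[best]], n_rounds = best, gce_curve = js)
}

# Random symmetric nonnegative weight matrix with distinct entries.
random_weights <- function(n, density = 1, seed = 1) {
  set.seed(seed)
  m <- matrix(0, n, n)
  ut <- upper.tri(m)
  w <- stats::runif(sum(ut))
  w[stats::runif(sum(ut)) > density] <- 0
  m[ut] <- w
  m + t(m)
}

# Exhaustive one-sample sign-flip p-value by direct enumeration.
oracle_signflip_p <- function(values) {
  n <- length(values)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  obs <- mean(values)
  null <- as.numeric(signs %*% values) / n
  sum(null >= obs - 1e-12) / nrow(signs)
}

# Small white-noise source set.
white_ts <- function(n_nodes, fs, epoch, n_trials = 1, seed = 1) {
  set.seed(seed)
  n_samp <- round((epoch[2] - epoch[1]) * fs)
  source_ts(array(stats::rnorm(n_nodes * n_samp * n_trials),
                  dim = c(n_nodes, n_samp, n_trials)),
            fs, epoch)
}

# Two-bin table usable at low sampling rates.
bins2 <- function() make_bins(0.5, 10.5, 5)
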