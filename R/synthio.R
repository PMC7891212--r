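#' Generate a modular binary structural connectivity matrix
#'
#' Stochastic block model stand-in for a binarized tractography matrix:
#' within-module edges are more probable than between-module edges, the
#' requested overall edge density is matched in expectation, and sampling is
#' rejected until the graph is connected.
#'
#' @param n_nodes number of nodes (at least 2).
#' @param edge_density target overall edge density in (0, 1].
#' @param n_modules number of equally sized modules (default 1).
#' @param seed integer seed.
#' @param within_between_ratio ratio of within- to between-module edge
#'   probability (default 4; ignored when `n_modules = 1`).
#' @param ensure_connected reject samples until connected (default TRUE).
#' @param max_tries rejection cap before failing.
#' @param labels optional node names.
#' @return An object of class `structural_matrix`: binary symmetric `mat`
#'   with zero diagonal, `labels`, and `modules` (module assignment).
#' @export
generate_structural_matrix <- function(n_nodes, edge_density, n_modules = 1,
                                       seed = NULL, within_between_ratio = 4,
                                       ensure_connected = TRUE,
                                       max_tries = 500, labels = NULL) {
  if (n_nodes < 2) stop("need at least 2 nodes", call. = FALSE)
  if (edge_density <= 0 || edge_density > 1) {
    stop("edge_density must be in (0, 1]", call. = FALSE)
  }
  if (n_modules < 1) stop("n_modules must be >= 1", call. = FALSE)
  total_pairs <- n_nodes * (n_nodes - 1) / 2
  if (ensure_connected && edge_density * total_pairs < n_nodes - 1) {
    stop("edge_density ", edge_density, " too low to permit a connected ",
         "graph on ", n_nodes, " nodes", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  modules <- rep(seq_len(n_modules), length.out = n_nodes)
  modules <- sort(modules)
  same <- outer(modules, modules, "==")
  n_within <- sum(same[upper.tri(same)])
  n_between <- total_pairs - n_within
  r <- if (n_modules == 1) 1 else within_between_ratio
  p_between <- edge_density * total_pairs / (n_within * r + n_between)
  p_within <- min(r * p_between, 1)
  p_between <- min(p_between, 1)
  pmat <- ifelse(same, p_within, p_between)

  for (try in seq_len(max_tries)) {
    m <- matrix(0, n_nodes, n_nodes)
    ut <- upper.tri(m)
    m[ut] <- as.numeric(stats::runif(total_pairs) < pmat[ut])
    m <- m + t(m)
    if (!ensure_connected) break
    g <- igraph::graph_from_adjacency_matrix(m, mode = "undirected")
    if (igraph::is_connected(g)) break
    if (try == max_tries) {
      stop("failed to sample a connected graph at density ", edge_density,
           " in ", max_tries, " tries", call. = FALSE)
    }
  }
  labels <- labels %||% paste0("node", seq_len(n_nodes))
  dimnames(m) <- list(labels, labels)
  structure(list(mat = m, labels = labels, modules = modules),
            class = "structural_matrix")
}

#' @export
print.structural_matrix <- function(x, ...) {
  cat("<structural_matrix> ", nrow(x$mat), " nodes, ",
      sum(x$mat[upper.tri(x$mat)]), " edges, ",
      length(unique(x$modules)), " module(s)\n", sep = "")
  invisible(x)
}

#' Configuration for the coupled oscillatory time-series generator
#'
#' Describes a synthetic source dataset: band-limited oscillations riding on
#' 1/f-plus-white background noise, with planted amplitude-envelope coupling
#' within or across frequency bins. Each planted pair shares a common slow
#' amplitude modulator between node i's envelope in bin `bin_a` and node j's
#' envelope in bin `bin_b`, mixed in with weight `strength`. An optional
#' `hub_node` is coupled to several partners across at least three distinct
#' bin pairs, making it a planted connector.
#'
#' Defaults mirror the study conditions: 1200 Hz sampling, an epoch from
#' -0.4 to 2.0 s around stimulus onset, and ten 5 Hz bins from 0.5 to
#' 50.5 Hz.
#'
#' @param n_nodes number of sources.
#' @param n_trials trials per dataset (default 1).
#' @param fs sampling rate in Hz (default 1200); must exceed twice the
#'   highest bin edge.
#' @param epoch epoch window in seconds (default `c(-0.4, 2)`).
#' @param bins bin table from [make_bins()].
#' @param planted_pairs data frame with columns `node_i`, `node_j`, `bin_a`,
#'   `bin_b`, `strength` (each strength in `[0, 1]`), or NULL.
#' @param hub_node optional node index to make a planted connector hub.
#' @param hub_strength coupling strength of the hub's pairs (default 0.8).
#' @param noise length-2 numeric `c(one_over_f_exponent, white_sd)`
#'   (default `c(1, 0.5)`).
#' @param osc_amplitude amplitude of planted oscillations relative to the
#'   unit-sd background (default 2).
#' @param seed integer seed.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_nodes, n_trials = 1, fs = 1200,
                         epoch = c(-0.4, 2), bins = make_bins(),
                         planted_pairs = NULL, hub_node = NULL,
                         hub_strength = 0.8, noise = c(1, 0.5),
                         osc_amplitude = 2, seed = NULL) {
  stopifnot(n_nodes >= 2, n_trials >= 1)
  if (fs <= 2 * max(bins$high_hz)) {
    stop("fs = ", fs, " must exceed twice the highest bin edge ",
         max(bins$high_hz), " Hz", call. = FALSE)
  }
  B <- nrow(bins)
  if (!is.null(hub_node)) {
    if (hub_node < 1 || hub_node > n_nodes) {
      stop("hub_node ", hub_node, " out of range 1..", n_nodes, call. = FALSE)
    }
    if (B < 3) stop("need at least 3 bins to plant a connector hub", call. = FALSE)
    # couple the hub across every low/high bin pair and within the first
    # bins, so it is both a strong centrality hub and an interfrequency
    # connector (its couplings span >= 3 bin pairs)
    bp <- utils::combn(min(B, 4L), 2L)
    bin_a <- c(bp[1, ], seq_len(min(B, 2L)))
    bin_b <- c(bp[2, ], seq_len(min(B, 2L)))
    partners <- setdiff(seq_len(n_nodes), hub_node)
    partners <- rep(partners, length.out = length(bin_a))
    hub_pairs <- tibble::tibble(
      node_i = hub_node,
      node_j = partners,
      bin_a = as.integer(bin_a),
      bin_b = as.integer(bin_b),
      strength = hub_strength
    )
    planted_pairs <- if (is.null(planted_pairs)) hub_pairs else
      dplyr::bind_rows(tibble::as_tibble(planted_pairs), hub_pairs)
  }
  if (!is.null(planted_pairs)) {
    planted_pairs <- tibble::as_tibble(planted_pairs)
    with(planted_pairs, {
      if (any(strength < 0 | strength > 1)) {
        stop("coupling strength must be in [0, 1]", call. = FALSE)
      }
      if (any(c(node_i, node_j) < 1) || any(c(node_i, node_j) > n_nodes)) {
        stop("planted pair references node outside 1..", n_nodes, call. = FALSE)
      }
      if (any(c(bin_a, bin_b) < 1) || any(c(bin_a, bin_b) > B)) {
        stop("planted pair references bin outside 1..", B, call. = FALSE)
      }
    })
  }
  structure(list(n_nodes = n_nodes, n_trials = n_trials, fs = fs,
                 epoch = as.numeric(epoch), bins = bins,
                 planted_pairs = planted_pairs, hub_node = hub_node,
                 noise = noise, osc_amplitude = osc_amplitude, seed = seed),
            class = "synth_config")
}

#' Generate coupled oscillatory source time series
#'
#' Each node receives 1/f^alpha background noise plus white noise. Every
#' planted pair adds a band-limited oscillation at the two bin centers whose
#' amplitude envelopes share a common slow modulator with mixing weight
#' equal to the coupling strength; at strength 0 the modulators are fully
#' independent. The generated set is reproducible under the config seed.
#'
#' @param cfg a [synth_config()].
#' @return A [source_ts()].
#' @export
generate_coupled_timeseries <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n_samp <- round((cfg$epoch[2] - cfg$epoch[1]) * cfg$fs)
  tt <- cfg$epoch[1] + (seq_len(n_samp) - 1) / cfg$fs
  alpha <- cfg$noise[1]; white_sd <- cfg$noise[2]
  dat <- array(0, dim = c(cfg$n_nodes, n_samp, cfg$n_trials))
  for (tr in seq_len(cfg$n_trials)) {
    for (nd in seq_len(cfg$n_nodes)) {
      dat[nd, , tr] <- pink_noise(n_samp, cfg$fs, alpha) +
        stats::rnorm(n_samp, sd = white_sd)
    }
  }
  pp <- cfg$planted_pairs
  if (!is.null(pp) && nrow(pp) > 0) {
    centers <- (cfg$bins$low_hz + cfg$bins$high_hz) / 2
    depth <- 0.5 # modulation depth around the unit carrier amplitude
    for (k in seq_len(nrow(pp))) {
      ci <- pp$strength[k]
      fa <- centers[pp$bin_a[k]]
      fb <- centers[pp$bin_b[k]]
      for (tr in seq_len(cfg$n_trials)) {
        shared <- slow_noise(n_samp, cfg$fs)
        ui <- slow_noise(n_samp, cfg$fs)
        uj <- slow_noise(n_samp, cfg$fs)
        env_i <- pmax(1 + depth * ((1 - ci) * ui + ci * shared), 0.05)
        env_j <- pmax(1 + depth * ((1 - ci) * uj + ci * shared), 0.05)
        ph_i <- stats::runif(1, 0, 2 * pi)
        ph_j <- stats::runif(1, 0, 2 * pi)
        dat[pp$node_i[k], , tr] <- dat[pp$node_i[k], , tr] +
          cfg$osc_amplitude * env_i * sin(2 * pi * fa * tt + ph_i)
        dat[pp$node_j[k], , tr] <- dat[pp$node_j[k], , tr] +
          cfg$osc_amplitude * env_j * sin(2 * pi * fb * tt + ph_j)
      }
    }
  }
  source_ts(dat, cfg$fs, cfg$epoch, paste0("node", seq_len(cfg$n_nodes)))
}

#' Make a structural matrix support a set of planted couplings
#'
#' Sets the structural connection of every planted node pair to 1. Coupled
#' sources communicate along anatomical connections, so a synthetic cohort
#' should not mask out its own planted coupling structure.
#'
#' @param sc a `structural_matrix`.
#' @param planted_pairs data frame with `node_i`, `node_j` columns (e.g.
#'   from a [synth_config()]).
#' @return The updated `structural_matrix`.
#' @export
ensure_structural_support <- function(sc, planted_pairs) {
  stopifnot(inherits(sc, "structural_matrix"))
  if (is.null(planted_pairs) || nrow(planted_pairs) == 0) return(sc)
  for (k in seq_len(nrow(planted_pairs))) {
    i <- planted_pairs$node_i[k]; j <- planted_pairs$node_j[k]
    if (i != j) {
      sc$mat[i, j] <- 1
      sc$mat[j, i] <- 1
    }
  }
  sc
}

#' Generate a supra-adjacency fixture with a planted connector hub
#'
#' Direct network-level fixture: random weighted intralayer graphs, sparse
#' random interlayer blocks, and one planted hub whose interlayer edge count
#' is boosted to at least twice that of any other node (skipped when
#' `interlayer_density = 0`, which yields no interlayer structure at all).
#'
#' @param n_nodes nodes per layer.
#' @param n_bins number of layers (at least 2).
#' @param intralayer_density edge density of each within-layer graph.
#' @param interlayer_density density of entries in each between-layer block.
#' @param planted_hub node index to boost (default 1).
#' @param seed integer seed.
#' @return A `supra_adjacency`.
#' @export
generate_multilayer_fixture <- function(n_nodes, n_bins,
                                        intralayer_density = 0.3,
                                        interlayer_density = 0.05,
                                        planted_hub = 1, seed = NULL) {
  if (n_bins < 2) stop("need at least 2 layers for interlayer structure", call. = FALSE)
  if (intralayer_density < 0 || intralayer_density > 1 ||
      interlayer_density < 0 || interlayer_density > 1) {
    stop("densities must be in [0, 1]", call. = FALSE)
  }
  if (planted_hub < 1 || planted_hub > n_nodes) {
    stop("planted_hub out of range 1..", n_nodes, call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  N <- n_nodes; B <- n_bins
  blocks <- list()
  for (b in seq_len(B)) {
    m <- matrix(0, N, N)
    ut <- upper.tri(m)
    on <- stats::runif(sum(ut)) < intralayer_density
    w <- stats::runif(sum(ut), 0.5, 1.5) * on
    m[ut] <- w
    m <- m + t(m)
    blocks[[b]] <- m
  }
  between <- list()
  pair_idx <- list()
  for (a in seq_len(B - 1)) {
    for (b in (a + 1):B) {
      m <- matrix(stats::runif(N * N, 0.5, 1.5) *
                    (stats::runif(N * N) < interlayer_density), N, N)
      # background edges avoid the hub so its count is fully controlled
      m[planted_hub, ] <- 0
      m[, planted_hub] <- 0
      # symmetric from the start so the supra matrix is symmetric
      between[[length(between) + 1]] <- symmetrize_max(m)
      pair_idx[[length(pair_idx) + 1]] <- c(a, b)
    }
  }
  if (interlayer_density > 0) {
    # give the hub >= 2x the interlayer edge count of any other node, plus 1
    incidence <- function() {
      cnt <- integer(N)
      for (m in between) {
        nz <- which(m != 0, arr.ind = TRUE)
        for (r in seq_len(nrow(nz))) {
          i <- nz[r, 1]; j <- nz[r, 2]
          cnt[i] <- cnt[i] + 1L
          if (j != i) cnt[j] <- cnt[j] + 1L
        }
      }
      cnt
    }
    others <- setdiff(seq_len(N), planted_hub)
    # replica self-pairs (hub to its own copy in another layer) raise only
    # the hub's count; use them first
    for (bi in seq_along(between)) {
      cnt <- incidence()
      if (cnt[planted_hub] >= 2 * max(cnt[others]) + 1) break
      between[[bi]][planted_hub, planted_hub] <- stats::runif(1, 0.5, 1.5)
    }
    # then add symmetric hub-partner pairs, always to the least-loaded partner
    open <- expand.grid(bi = seq_along(between), j = others)
    repeat {
      cnt <- incidence()
      if (cnt[planted_hub] >= 2 * max(cnt[others]) + 1) break
      if (nrow(open) > 0) {
        pick <- which.min(cnt[open$j])
        bi <- open$bi[pick]; j <- open$j[pick]
        wnew <- stats::runif(1, 0.5, 1.5)
        between[[bi]][planted_hub, j] <- wnew
        between[[bi]][j, planted_hub] <- wnew
        open <- open[-pick, , drop = FALSE]
        next
      }
      # hub capacity exhausted: thin background edges at the busiest node
      busiest <- others[which.max(cnt[others])]
      removed <- FALSE
      for (bi in seq_along(between)) {
        nz <- which(between[[bi]] != 0, arr.ind = TRUE)
        for (r in seq_len(nrow(nz))) {
          i <- nz[r, 1]; j <- nz[r, 2]
          if (planted_hub %in% c(i, j)) next
          if (busiest %in% c(i, j)) {
            between[[bi]][i, j] <- 0
            between[[bi]][j, i] <- 0
            removed <- TRUE
            break
          }
        }
        if (removed) break
      }
      if (!removed) {
        stop("failed to plant hub: interlayer blocks saturated", call. = FALSE)
      }
    }
  }
  all_blocks <- c(
    lapply(seq_len(B), function(b) new_conn_block(blocks[[b]], b, b)),
    lapply(seq_along(between), function(i) {
      new_conn_block(between[[i]], pair_idx[[i]][1], pair_idx[[i]][2])
    })
  )
  assemble_supra(all_blocks, N, B)
}
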