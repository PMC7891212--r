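#' Pipeline run configuration
#'
#' Collects every tunable of the subject-level pipeline. Defaults are the
#' study conditions wherever one exists: ten 5 Hz bins from 0.5 to 50.5 Hz,
#' a 0.8--1.3 s analysis window, 100 IAAFT surrogates, a hub threshold of
#' z > 2, 5000 permutations, and PageRank damping 0.85.
#'
#' @param bins bin table from [make_bins()].
#' @param window analysis window in seconds.
#' @param preprocess apply [preprocess_broadband()] first (default TRUE).
#' @param band,notch broadband filter settings.
#' @param n_surrogates surrogate count for the null (default 100).
#' @param hub_threshold hub z threshold (default 2).
#' @param n_permutations group-test permutations (default 5000).
#' @param damping PageRank damping (default 0.85).
#' @param mask_order `"omst_first"` (study order: threshold, then mask) or
#'   `"mask_first"` for sensitivity analysis.
#' @param count_replica_pairs count i-to-i cross-layer entries in
#'   interconnectedness (default TRUE).
#' @param pool trial pooling for coupling, see [connectivity_blocks()].
#' @param min_hub_subjects group candidate rule: a node enters the group
#'   test when it is a hub in at least this many subjects (default 1).
#' @param seed integer seed controlling every stochastic stage.
#' @return A list of class `run_config`.
#' @export
run_config <- function(bins = make_bins(), window = c(0.8, 1.3),
                       preprocess = TRUE, band = c(0.1, 100), notch = 60,
                       n_surrogates = 100, hub_threshold = 2,
                       n_permutations = 5000, damping = 0.85,
                       mask_order = c("omst_first", "mask_first"),
                       count_replica_pairs = TRUE,
                       pool = c("concatenate", "average"),
                       min_hub_subjects = 1, seed = NULL) {
  stopifnot(n_surrogates >= 2, n_permutations >= 1,
            damping > 0, damping < 1)
  structure(list(bins = bins, window = as.numeric(window),
                 preprocess = preprocess, band = band, notch = notch,
                 n_surrogates = n_surrogates, hub_threshold = hub_threshold,
                 n_permutations = n_permutations, damping = damping,
                 mask_order = match.arg(mask_order),
                 count_replica_pairs = count_replica_pairs,
                 pool = match.arg(pool),
                 min_hub_subjects = min_hub_subjects, seed = seed),
            class = "run_config")
}

#' Run the full subject-level pipeline
#'
#' Orthogonalizes the source time series, computes within- and between-bin
#' envelope coupling, z-scores it against IAAFT surrogate nulls, thresholds
#' each block with orthogonal minimum spanning trees, applies the binary
#' structural constraint, assembles the supra-adjacency matrix, computes
#' multilayer versatility, flags hubs, and profiles DCI over them. Negative
#' z-scores are clipped to 0 before thresholding (only connections stronger
#' than the null can form edges).
#'
#' @param ts a [source_ts()] or a directory path readable by
#'   [read_timeseries()].
#' @param sc a `structural_matrix` or a file path readable by
#'   [read_structural()].
#' @param config a [run_config()].
#' @param out_dir optional directory: when given, every stage's output is
#'   persisted (blocks, z-blocks, supra triplets, tables, provenance YAML).
#' @param verbose log stage-level progress with edge counts (default TRUE).
#' @return An object of class `ml_subject`: `supra`, `hub_table` (tibble:
#'   node, label, versatility, z_versatility, is_hub), `dci` (a
#'   [dci_profile()] tibble, empty when no hubs), `sparsity` (per-block
#'   tibble), `interconnectedness`, `zblocks`, `config`.
#' @export
run_subject <- function(ts, sc, config = run_config(), out_dir = NULL,
                        verbose = TRUE) {
  # validate inputs before any computation
  if (is.character(ts)) {
    if (!dir.exists(ts)) stop("time-series directory not found: ", ts, call. = FALSE)
  }
  if (is.character(sc)) {
    if (!file.exists(sc)) stop("structural matrix file not found: ", sc, call. = FALSE)
    sc <- read_structural(sc)
  }
  if (is.character(ts)) ts <- read_timeseries(ts)
  stopifnot(inherits(ts, "source_ts"), inherits(sc, "structural_matrix"),
            inherits(config, "run_config"))
  if (nrow(sc$mat) != dim(ts$data)[1]) {
    stop("structural matrix has ", nrow(sc$mat), " nodes but time series has ",
         dim(ts$data)[1], call. = FALSE)
  }
  say <- function(...) if (verbose) message("[multihub] ", ...)
  if (!is.null(config$seed)) set.seed(config$seed)

  if (config$preprocess) {
    say("broadband filter ", config$band[1], "-", config$band[2],
        " Hz, notch ", config$notch, " Hz")
    ts <- preprocess_broadband(ts, config$band, config$notch)
  }
  say("symmetric orthogonalization of ", dim(ts$data)[1], " nodes")
  ts <- symmetric_orthogonalize(ts)

  B <- nrow(config$bins)
  say("envelopes for ", B, " bins, window [", config$window[1], ", ",
      config$window[2], "] s")
  env <- band_envelopes(ts, config$bins, config$window)
  empirical <- connectivity_blocks(env, pool = config$pool)
  say(length(empirical), " connectivity blocks (", B, " within, ",
      B * (B - 1) / 2, " between)")

  say("null connectivity from ", config$n_surrogates, " IAAFT surrogates")
  null <- null_connectivity(ts, config$bins, config$window,
                            n_surrogates = config$n_surrogates,
                            pool = config$pool)
  zblocks <- zscore_blocks(empirical, null)

  say("OMST thresholding + structural mask (order: ", config$mask_order, ")")
  thresholded <- lapply(zblocks, function(b) {
    m <- pmax(b$mat, 0) # only above-null connections may form edges
    if (b$kind == "between") {
      m <- symmetrize_max(m)
      diag(m) <- 0 # spanning-tree thresholding is defined on simple graphs
    }
    if (config$mask_order == "mask_first") m <- apply_structural_mask(m, sc)
    res <- if (any(m[upper.tri(m)] > 0)) omst(m)$retained else m
    if (config$mask_order == "omst_first") res <- apply_structural_mask(res, sc)
    b$mat <- res
    b
  })
  spars <- tibble::tibble(
    bin_a = vapply(thresholded, function(b) b$bin_a, integer(1)),
    bin_b = vapply(thresholded, function(b) b$bin_b, integer(1)),
    kind = vapply(thresholded, function(b) b$kind, character(1)),
    n_edges = vapply(thresholded, function(b) {
      sum(b$mat[upper.tri(b$mat)] != 0)
    }, numeric(1)),
    sparsity = vapply(thresholded, sparsity, numeric(1))
  )
  for (i in seq_len(nrow(spars))) {
    say("  block (", spars$bin_a[i], ",", spars$bin_b[i], "): ",
        spars$n_edges[i], " edges, sparsity ",
        sprintf("%.3f", spars$sparsity[i]))
  }

  N <- dim(ts$data)[1]
  supra <- assemble_supra(thresholded, N, B, labels = ts$labels)
  icc <- interconnectedness(supra, config$count_replica_pairs)
  say("supra-adjacency ", N * B, " node-layers, interconnectedness ", icc)

  vers <- versatility(supra, damping = config$damping)
  zv <- zscore_nodes(vers)
  hubs <- detect_hubs(zv, config$hub_threshold)
  hub_table <- tibble::tibble(node = seq_len(N), label = ts$labels,
                              versatility = as.numeric(vers),
                              z_versatility = as.numeric(zv),
                              is_hub = as.logical(hubs))
  say(sum(hubs), " hub(s) at z > ", config$hub_threshold)

  if (sum(hubs) > 0 && icc > 0) {
    dci_tab <- dci_profile(supra, which(hubs), config$count_replica_pairs)
  } else {
    if (sum(hubs) == 0) say("no hubs detected; DCI profile skipped")
    if (icc == 0) say("no interlayer edges; DCI profile skipped")
    dci_tab <- tibble::tibble(node = integer(), label = character(),
                              dci_raw = numeric(), dci_scaled = numeric())
    class(dci_tab) <- c("dci_result", class(dci_tab))
  }

  result <- structure(list(supra = supra, hub_table = hub_table,
                           dci = dci_tab, sparsity = spars,
                           interconnectedness = icc, zblocks = zblocks,
                           labels = ts$labels, config = config),
                      class = "ml_subject")
  if (!is.null(out_dir)) persist_subject(result, out_dir)
  result
}

# Persist every stage output plus a provenance record.
persist_subject <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_blocks(result$zblocks, out_dir, prefix = "z",
               bins = result$config$bins, window = result$config$window)
  write_supra(result$supra, file.path(out_dir, "supra.tsv"))
  utils::write.table(result$hub_table, file.path(out_dir, "hub_table.tsv"),
                     sep = "\t", row.names = FALSE)
  utils::write.table(as.data.frame(result$dci),
                     file.path(out_dir, "dci.tsv"),
                     sep = "\t", row.names = FALSE)
  utils::write.table(result$sparsity, file.path(out_dir, "sparsity.tsv"),
                     sep = "\t", row.names = FALSE)
  cfg <- result$config
  prov <- list(
    package = "multihub",
    version = as.character(utils::packageVersion("multihub")),
    r_version = R.version.string,
    interconnectedness = result$interconnectedness,
    config = list(
      bins = as.data.frame(cfg$bins), window = cfg$window,
      preprocess = cfg$preprocess, band = cfg$band, notch = cfg$notch,
      n_surrogates = cfg$n_surrogates, hub_threshold = cfg$hub_threshold,
      n_permutations = cfg$n_permutations, damping = cfg$damping,
      mask_order = cfg$mask_order,
      count_replica_pairs = cfg$count_replica_pairs, pool = cfg$pool,
      min_hub_subjects = cfg$min_hub_subjects, seed = cfg$seed
    )
  )
  yaml::write_yaml(prov, file.path(out_dir, "provenance.yaml"))
  invisible(out_dir)
}

#' @export
print.ml_subject <- function(x, ...) {
  cat("<ml_subject> ", length(x$labels), " nodes x ",
      x$supra$n_layers, " layers, interconnectedness ",
      x$interconnectedness, ", ", sum(x$hub_table$is_hub), " hub(s)\n",
      sep = "")
  invisible(x)
}

#' Group-level connector hub inference across subjects
#'
#' Collects per-subject scaled DCI (0 where a node is not a hub for that
#' subject), restricts to candidate nodes that are hubs in at least
#' `min_hub_subjects` subjects, and runs the one-sample, one-tailed
#' sign-flip permutation test per candidate.
#'
#' @param subjects list of `ml_subject` results with identical node labels.
#' @param config a [run_config()]; `n_permutations`, `min_hub_subjects` and
#'   `seed` are used.
#' @return A [group_test()] tibble restricted to candidates, with the
#'   candidate rule recorded in `attr(, "candidate_rule")`. Empty (with a
#'   warning) when no node is a hub anywhere.
#' @export
run_group <- function(subjects, config = run_config()) {
  if (length(subjects) < 2) stop("need at least 2 subjects", call. = FALSE)
  labels <- subjects[[1]]$labels
  for (i in seq_along(subjects)) {
    if (!identical(subjects[[i]]$labels, labels)) {
      mism <- which(subjects[[i]]$labels != labels)
      stop("subject ", i, " node labels differ at position(s) ",
           paste(utils::head(mism, 5), collapse = ", "), call. = FALSE)
    }
  }
  n <- length(labels)
  hub_counts <- integer(n)
  vals <- matrix(0, nrow = length(subjects), ncol = n,
                 dimnames = list(NULL, labels))
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    hub_counts <- hub_counts + as.integer(s$hub_table$is_hub)
    if (nrow(s$dci) > 0) vals[i, s$dci$node] <- s$dci$dci_scaled
  }
  candidates <- which(hub_counts >= config$min_hub_subjects)
  if (length(candidates) == 0) {
    warning("no node is a hub in >= ", config$min_hub_subjects,
            " subject(s); empty group result", call. = FALSE)
    out <- tibble::tibble(node = integer(), label = character(),
                          effect = numeric(), p_value = numeric(),
                          p_bh = numeric(), n_subjects = integer(),
                          method = character(), all_zero = logical())
    class(out) <- c("group_result", class(out))
    return(out)
  }
  res <- group_test(vals[, candidates, drop = FALSE],
                    n_permutations = config$n_permutations,
                    seed = config$seed)
  res$node <- as.integer(candidates)
  attr(res, "candidate_rule") <-
    paste0("hub in >= ", config$min_hub_subjects, " subject(s)")
  res
}
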