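#' Multilayer versatility (multilayer PageRank centrality)
#'
#' The stationary distribution of a random walk with teleportation on the
#' (N*B)-node supra graph: transition probabilities are column-normalized
#' supra weights, dangling node-layers teleport uniformly, and with
#' probability `1 - damping` the walker teleports uniformly. Node-layer
#' scores are aggregated by summing a node's score over its B layer
#' replicas, so the aggregate sums to 1.
#'
#' @param supra a `supra_adjacency` with at least one edge.
#' @param damping teleportation damping factor (default 0.85).
#' @param tol power-iteration convergence tolerance (default 1e-10).
#' @param max_iter iteration cap.
#' @return Named numeric vector of per-node versatility scores summing to 1.
#' @export
versatility <- function(supra, damping = 0.85, tol = 1e-10, max_iter = 10000) {
  stopifnot(inherits(supra, "supra_adjacency"))
  if (damping <= 0 || damping >= 1) stop("damping must be in (0,1)", call. = FALSE)
  S <- supra$mat
  nb <- nrow(S)
  colsums <- colSums(S)
  if (all(colsums == 0)) stop("supra matrix has no edges", call. = FALSE)
  nonzero <- colsums > 0
  P <- S
  P[, nonzero] <- sweep(S[, nonzero, drop = FALSE], 2, colsums[nonzero], "/")
  P[, !nonzero] <- 0
  dangling <- !nonzero
  v <- rep(1 / nb, nb)
  for (k in seq_len(max_iter)) {
    v_new <- as.numeric(damping * (P %*% v + sum(v[dangling]) / nb) +
                          (1 - damping) / nb)
    if (max(abs(v_new - v)) < tol) {
      v <- v_new
      break
    }
    v <- v_new
  }
  node_id <- rep(seq_len(supra$n_nodes), times = supra$n_layers)
  agg <- as.numeric(rowsum(v, node_id))
  stats::setNames(agg, supra$labels)
}

#' Z-score a vector of node values
#'
#' Standardizes to mean 0, sd 1. The default uses the population standard
#' deviation (denominator n); set `sd_type = "sample"` for the n-1
#' convention.
#'
#' @param values numeric vector, length at least 2, nonconstant.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return Standardized vector (names preserved).
#' @export
zscore_nodes <- function(values, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  if (!all(is.finite(values))) stop("values must be finite", call. = FALSE)
  s <- stats::sd(values)
  if (s == 0) stop("zero variance: z-scores undefined", call. = FALSE)
  if (sd_type == "population") {
    n <- length(values)
    s <- s * sqrt((n - 1) / n)
  }
  (values - mean(values)) / s
}

#' Detect hubs by thresholding z-scored versatility
#'
#' A node is a hub when its z-scored multilayer versatility strictly exceeds
#' the threshold (default 2).
#'
#' @param z numeric vector of z-scores.
#' @param threshold hub threshold in z units (default 2, strict inequality).
#' @return Logical vector (names preserved).
#' @export
detect_hubs <- function(z, threshold = 2) {
  if (!all(is.finite(z))) stop("z must be finite", call. = FALSE)
  z > threshold
}

#' Interconnectedness of a multilayer network
#'
#' The number of interlayer connections: nonzero entries in the off-diagonal
#' (between-layer) blocks of the supra-adjacency matrix, counting each
#' undirected interlayer edge once. Replica self-pairs (node i in layer a to
#' node i in layer b) count by default; set `count_replica_pairs = FALSE` to
#' exclude them.
#'
#' @param supra a `supra_adjacency`.
#' @param count_replica_pairs include i-to-i cross-layer entries (default
#'   TRUE).
#' @return Integer count of interlayer edges.
#' @export
interconnectedness <- function(supra, count_replica_pairs = TRUE) {
  stopifnot(inherits(supra, "supra_adjacency"))
  B <- supra$n_layers
  total <- 0L
  for (a in seq_len(B - 1)) {
    for (b in (a + 1):B) {
      blk <- supra_block(supra, a, b) != 0
      if (!count_replica_pairs) diag(blk) <- FALSE
      total <- total + sum(blk)
    }
  }
  as.integer(total)
}

#' Delta centrality on interconnectedness (DCI) of one node
#'
#' The percent change in interconnectedness when a node is removed: all B
#' layer replicas of the node have their supra rows and columns zeroed, and
#' `DCI = 100 * (I_full - I_removed) / I_full`. Positive DCI means removal
#' reduces interlayer connectivity.
#'
#' @param supra a `supra_adjacency` with at least one interlayer edge.
#' @param node node index (1-based).
#' @param count_replica_pairs passed to [interconnectedness()].
#' @return DCI in percent.
#' @export
dci <- function(supra, node, count_replica_pairs = TRUE) {
  stopifnot(inherits(supra, "supra_adjacency"))
  N <- supra$n_nodes
  if (node < 1 || node > N) stop("node ", node, " out of range 1..", N, call. = FALSE)
  i_full <- interconnectedness(supra, count_replica_pairs)
  if (i_full == 0) stop("interconnectedness is 0: DCI undefined", call. = FALSE)
  idx <- node + (seq_len(supra$n_layers) - 1) * N
  cut <- supra
  cut$mat[idx, ] <- 0
  cut$mat[, idx] <- 0
  i_rm <- interconnectedness(cut, count_replica_pairs)
  100 * (i_full - i_rm) / i_full
}

#' DCI profile over candidate nodes
#'
#' Computes raw DCI for each candidate and a scaled version,
#' `dci_scaled = dci_raw / sd(dci_raw)` (sample sd over candidates) with the
#' zero point preserved: no mean is subtracted, because a zero DCI (a node
#' with no interlayer edges) is meaningful and most values are zero. If the
#' sd is zero or undefined, the raw values are returned unscaled.
#'
#' @param supra a `supra_adjacency`.
#' @param candidates integer vector of node indices (nonempty), typically
#'   the hubs from [detect_hubs()].
#' @param count_replica_pairs passed to [dci()].
#' @return A tibble of class `dci_result` with columns `node`, `label`,
#'   `dci_raw`, `dci_scaled`; the full-network interconnectedness is in
#'   `attr(, "interconnectedness_full")`.
#' @export
dci_profile <- function(supra, candidates, count_replica_pairs = TRUE) {
  stopifnot(inherits(supra, "supra_adjacency"))
  if (length(candidates) == 0) stop("candidates must be nonempty", call. = FALSE)
  raw <- vapply(candidates, function(v) dci(supra, v, count_replica_pairs),
                numeric(1))
  s <- if (length(raw) > 1) stats::sd(raw) else 0
  scaled <- if (is.na(s) || s == 0) raw else raw / s
  out <- tibble::tibble(
    node = as.integer(candidates),
    label = supra$labels[candidates],
    dci_raw = raw,
    dci_scaled = scaled
  )
  attr(out, "interconnectedness_full") <-
    interconnectedness(supra, count_replica_pairs)
  class(out) <- c("dci_result", class(out))
  out
}

# All 2^n sign patterns as a (2^n x n) matrix of +/-1.
sign_patterns <- function(n) {
  m <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  dimnames(m) <- NULL
  m
}

#' One-sample, one-tailed sign-flip permutation test across subjects
#'
#' Tests, per node, whether the mean scaled DCI across subjects is greater
#' than 0. The null is built by randomly negating each subject's value
#' (valid under symmetry of the null distribution); the one-tailed p-value
#' counts null means at least as large as the observed mean. When
#' `2^n_subjects <= exact_limit` all sign patterns are enumerated and the
#' p-value is exact (`#{null >= obs} / 2^n`, the identity pattern included);
#' otherwise `n_permutations` random sign vectors are drawn and
#' `p = (1 + #{null >= obs}) / (1 + n_permutations)`.
#'
#' @param dci_by_subject numeric matrix, subjects x nodes (column names are
#'   node labels). Nodes where a subject is not a hub carry 0.
#' @param n_permutations random draws when not enumerating (default 5000).
#' @param seed integer seed for the random branch.
#' @param exact_limit enumerate exhaustively when `2^n <= exact_limit`
#'   (default 4096, i.e. up to 12 subjects).
#' @return A tibble of class `group_result` with columns `node`, `label`,
#'   `effect` (mean across subjects), `p_value`, `p_bh`
#'   (Benjamini-Hochberg adjusted), `n_subjects`, `method`, `all_zero`.
#' @export
group_test <- function(dci_by_subject, n_permutations = 5000, seed = NULL,
                       exact_limit = 4096) {
  if (!is.matrix(dci_by_subject)) dci_by_subject <- as.matrix(dci_by_subject)
  n_subj <- nrow(dci_by_subject)
  if (n_subj < 2) stop("need at least 2 subjects", call. = FALSE)
  n_nodes <- ncol(dci_by_subject)
  if (n_nodes == 0) stop("no candidate nodes", call. = FALSE)
  labels <- colnames(dci_by_subject) %||% paste0("node", seq_len(n_nodes))
  exact <- 2^n_subj <= exact_limit
  if (exact) {
    signs <- sign_patterns(n_subj)
  } else {
    if (!is.null(seed)) set.seed(seed)
    signs <- matrix(sample(c(-1, 1), n_permutations * n_subj, replace = TRUE),
                    nrow = n_permutations)
  }
  eps <- 1e-12
  obs <- colMeans(dci_by_subject)
  null_means <- (signs %*% dci_by_subject) / n_subj
  count_ge <- colSums(sweep(null_means, 2, obs - eps, ">="))
  p <- if (exact) count_ge / nrow(signs) else (1 + count_ge) / (1 + n_permutations)
  all_zero <- apply(dci_by_subject, 2, function(x) all(x == 0))
  p[all_zero] <- 1
  out <- tibble::tibble(
    node = seq_len(n_nodes),
    label = labels,
    effect = unname(obs),
    p_value = unname(p),
    p_bh = stats::p.adjust(p, method = "BH"),
    n_subjects = n_subj,
    method = if (exact) "exact" else "random",
    all_zero = all_zero
  )
  class(out) <- c("group_result", class(out))
  out
}
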