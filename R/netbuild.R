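# Kruskal maximum-weight spanning tree/forest with deterministic
# lexicographic tie-breaking on (weight desc, i, j). Returns the edge index
# subset forming the tree and the number of components it leaves.
kruskal_max_tree <- function(ei, ej, w, n) {
  ord <- order(-w, ei, ej)
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  keep <- integer(0)
  for (k in ord) {
    ra <- find(ei[k]); rb <- find(ej[k])
    if (ra != rb) {
      parent[ra] <- rb
      keep <- c(keep, k)
      if (length(keep) == n - 1) break
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  list(keep = keep, n_components = length(unique(roots)))
}

# Weighted global efficiency on distances 1/w, via igraph.
global_efficiency_w <- function(mat) {
  ut <- upper.tri(mat) & mat > 0
  if (!any(ut)) return(0)
  idx <- which(ut, arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = idx[, 1], to = idx[, 2]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(mat)))
  )
  igraph::global_efficiency(g, weights = 1 / mat[ut], directed = FALSE)
}

#' Orthogonal minimum spanning tree (OMST) thresholding
#'
#' Data-driven thresholding of a weighted connectivity matrix: successive
#' maximum-weight spanning trees over edges not yet retained (each round
#' edge-disjoint, i.e. "orthogonal", to the previous ones) are unioned, and
#' after each round the global cost-efficiency objective
#' `J = GE(retained)/GE(input) - Cost(retained)` is evaluated, where `GE` is
#' weighted global efficiency on distances `1/w` and `Cost` is the retained
#' weight sum divided by the total input weight. The retained network is the
#' union over the prefix of rounds maximizing `J`.
#'
#' @param weights symmetric nonnegative matrix with zero diagonal.
#' @param max_rounds optional cap on the number of spanning-tree rounds.
#' @return An object of class `omst_result`: `retained` (weighted matrix),
#'   `n_rounds` (rounds kept), `gce_curve` (J per round), `rounds_total`
#'   (rounds evaluated), `forest_fallback` (TRUE when the input graph is
#'   disconnected and round 1 is a maximum spanning forest).
#' @export
omst <- function(weights, max_rounds = Inf) {
  check_symmetric(weights, what = "weights")
  if (any(weights < 0)) stop("weights must be nonnegative", call. = FALSE)
  if (any(diag(weights) != 0)) stop("diagonal must be zero", call. = FALSE)
  n <- nrow(weights)
  ut <- which(upper.tri(weights) & weights > 0, arr.ind = TRUE)
  if (nrow(ut) == 0) stop("input has no edges", call. = FALSE)
  ei <- ut[, 1]; ej <- ut[, 2]
  w <- weights[cbind(ei, ej)]
  total_w <- sum(w)
  ge_full <- global_efficiency_w(weights)

  used <- rep(FALSE, length(w))
  retained <- weights * 0
  gce <- numeric(0)
  round_edge_sets <- list()
  forest_fallback <- FALSE
  m <- 0
  while (m < max_rounds) {
    avail <- which(!used)
    if (length(avail) == 0) break
    kt <- kruskal_max_tree(ei[avail], ej[avail], w[avail], n)
    if (kt$n_components > 1) {
      if (m == 0) {
        forest_fallback <- TRUE # disconnected input: keep the spanning forest
      } else {
        break # no spanning tree among unused edges
      }
    }
    if (length(kt$keep) == 0) break
    sel <- avail[kt$keep]
    used[sel] <- TRUE
    m <- m + 1
    round_edge_sets[[m]] <- sel
    retained[cbind(ei[sel], ej[sel])] <- w[sel]
    retained[cbind(ej[sel], ei[sel])] <- w[sel]
    ge <- global_efficiency_w(retained)
    cost <- sum(retained[upper.tri(retained)]) / total_w
    gce <- c(gce, (if (ge_full > 0) ge / ge_full else 0) - cost)
  }
  best <- which.max(gce)
  final <- weights * 0
  for (r in seq_len(best)) {
    sel <- round_edge_sets[[r]]
    final[cbind(ei[sel], ej[sel])] <- w[sel]
    final[cbind(ej[sel], ei[sel])] <- w[sel]
  }
  structure(list(retained = final, n_rounds = best, gce_curve = gce,
                 rounds_total = m, forest_fallback = forest_fallback),
            class = "omst_result")
}

#' @export
print.omst_result <- function(x, ...) {
  cat("<omst_result> ", x$n_rounds, "/", x$rounds_total,
      " rounds kept, density ", signif(sparsity(x$retained), 3),
      if (x$forest_fallback) ", forest fallback" else "", "\n", sep = "")
  invisible(x)
}

#' Apply the binary structural connectivity constraint
#'
#' Entry-wise multiplication of a functional connectivity block by a binary
#' structural matrix, so only anatomically plausible connections survive.
#'
#' @param block a `conn_block`, `omst_result`, or square numeric matrix.
#' @param sc a `structural_matrix` (see [generate_structural_matrix()]) or a
#'   binary matrix of matching dimension.
#' @return Same type as `block`, masked.
#' @export
apply_structural_mask <- function(block, sc) {
  scm <- if (inherits(sc, "structural_matrix")) sc$mat else sc
  if (inherits(block, "conn_block")) {
    block$mat <- apply_structural_mask(block$mat, scm)
    return(block)
  }
  if (inherits(block, "omst_result")) {
    block$retained <- apply_structural_mask(block$retained, scm)
    return(block)
  }
  if (!all(dim(block) == dim(scm))) {
    stop("dimension mismatch: block ", paste(dim(block), collapse = "x"),
         " vs structural ", paste(dim(scm), collapse = "x"), call. = FALSE)
  }
  block * scm
}

#' Assemble the supra-adjacency matrix of the full multilayer network
#'
#' Places the `B` within-frequency matrices on the block diagonal and each
#' between-frequency matrix (low bin a, high bin b, a < b) at off-diagonal
#' block (a, b), with its transpose at (b, a). Between blocks must already be
#' symmetric (see [symmetrize_max()]), making the supra matrix symmetric.
#'
#' @param blocks list of `conn_block`s (or bare matrices in canonical order:
#'   within 1..B, then between pairs (1,2), (1,3), ..., (B-1,B)); exactly
#'   `B + B(B-1)/2` of them.
#' @param n_nodes node count N.
#' @param n_layers layer (bin) count B.
#' @param labels optional node labels.
#' @return An object of class `supra_adjacency` with fields `mat`
#'   ((N*B) x (N*B)), `n_nodes`, `n_layers`, `labels`.
#' @export
assemble_supra <- function(blocks, n_nodes, n_layers, labels = NULL) {
  B <- n_layers; N <- n_nodes
  expected <- B + B * (B - 1) / 2
  if (length(blocks) != expected) {
    stop("expected ", expected, " blocks for ", B, " layers, got ",
         length(blocks), call. = FALSE)
  }
  if (!inherits(blocks[[1]], "conn_block")) {
    # bare matrices: assume canonical order (within 1..B, then (a,b) a<b)
    pair_list <- rbind(
      cbind(seq_len(B), seq_len(B)),
      if (B > 1) do.call(rbind, lapply(seq_len(B - 1), function(a) {
        cbind(a, (a + 1):B)
      }))
    )
    blocks <- lapply(seq_along(blocks), function(i) {
      new_conn_block(blocks[[i]], pair_list[i, 1], pair_list[i, 2])
    })
  }
  seen <- matrix(FALSE, B, B)
  S <- matrix(0, N * B, N * B)
  for (b in blocks) {
    if (!all(dim(b$mat) == c(N, N))) {
      stop("block (", b$bin_a, ",", b$bin_b, ") has shape ",
           paste(dim(b$mat), collapse = "x"), ", expected ", N, "x", N,
           call. = FALSE)
    }
    if (b$bin_a != b$bin_b) check_symmetric(b$mat, what = paste0(
      "between block (", b$bin_a, ",", b$bin_b, ")"))
    ia <- (b$bin_a - 1) * N + seq_len(N)
    ib <- (b$bin_b - 1) * N + seq_len(N)
    S[ia, ib] <- b$mat
    S[ib, ia] <- t(b$mat)
    seen[b$bin_a, b$bin_b] <- TRUE
  }
  need <- which(upper.tri(seen, diag = TRUE) & !seen, arr.ind = TRUE)
  need <- need[need[, 1] <= need[, 2], , drop = FALSE]
  if (nrow(need) > 0) {
    stop("missing block(s): ",
         paste(sprintf("(%d,%d)", need[, 1], need[, 2]), collapse = ", "),
         call. = FALSE)
  }
  labels <- labels %||% rownames(blocks[[1]]$mat) %||% paste0("node", seq_len(N))
  structure(list(mat = S, n_nodes = N, n_layers = B, labels = labels),
            class = "supra_adjacency")
}

#' @export
print.supra_adjacency <- function(x, ...) {
  cat("<supra_adjacency> ", x$n_nodes, " nodes x ", x$n_layers,
      " layers (", nrow(x$mat), " node-layers), ",
      interconnectedness(x), " interlayer edges\n", sep = "")
  invisible(x)
}

#' Extract one layer-pair block from a supra-adjacency matrix
#'
#' @param supra a `supra_adjacency`.
#' @param a,b layer indices.
#' @return The N x N block for layer pair (a, b).
#' @export
supra_block <- function(supra, a, b) {
  stopifnot(inherits(supra, "supra_adjacency"))
  N <- supra$n_nodes
  supra$mat[(a - 1) * N + seq_len(N), (b - 1) * N + seq_len(N)]
}

#' Edge density (sparsity) of a zero-diagonal square matrix
#'
#' The number of nonzero upper-triangle entries divided by `N(N-1)/2`. A
#' single spanning tree on 246 nodes gives 245/30135, i.e. 0.008 at three
#' decimals.
#'
#' @param mat square matrix with zero diagonal, or an `omst_result`.
#' @return Fraction of possible undirected edges present.
#' @export
sparsity <- function(mat) {
  if (inherits(mat, "omst_result")) mat <- mat$retained
  if (inherits(mat, "conn_block")) mat <- mat$mat
  check_square(mat, "sparsity input")
  n <- nrow(mat)
  if (n < 2) return(0)
  sum(mat[upper.tri(mat)] != 0) / (n * (n - 1) / 2)
}
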