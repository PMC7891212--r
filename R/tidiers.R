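#' Tidy a subject-level pipeline result
#'
#' One row per node: versatility, z-scored versatility, hub flag, and (for
#' hubs) raw and scaled DCI.
#'
#' @param x an `ml_subject` from [run_subject()].
#' @param ... unused.
#' @return A tibble with columns `node`, `label`, `versatility`,
#'   `z_versatility`, `is_hub`, `dci_raw`, `dci_scaled`.
#' @method tidy ml_subject
#' @export
tidy.ml_subject <- function(x, ...) {
  dplyr::left_join(x$hub_table,
                   dplyr::select(tibble::as_tibble(x$dci), -"label"),
                   by = "node")
}

#' Glance at a subject-level pipeline result
#'
#' @param x an `ml_subject`.
#' @param ... unused.
#' @return A one-row tibble: node/layer counts, interconnectedness, hub
#'   count, and mean within-/between-layer sparsity.
#' @method glance ml_subject
#' @export
glance.ml_subject <- function(x, ...) {
  tibble::tibble(
    n_nodes = length(x$labels),
    n_layers = x$supra$n_layers,
    interconnectedness = x$interconnectedness,
    n_hubs = sum(x$hub_table$is_hub),
    mean_sparsity_within = mean(x$sparsity$sparsity[x$sparsity$kind == "within"]),
    mean_sparsity_between = mean(x$sparsity$sparsity[x$sparsity$kind == "between"])
  )
}

#' @method tidy group_result
#' @export
tidy.group_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "group_result")
  out
}

#' @method glance group_result
#' @export
glance.group_result <- function(x, ...) {
  tibble::tibble(
    n_candidates = nrow(x),
    n_significant = sum(x$p_value < 0.05),
    n_significant_bh = sum(x$p_bh < 0.05),
    min_p = if (nrow(x)) min(x$p_value) else NA_real_,
    method = if (nrow(x)) x$method[1] else NA_character_
  )
}

#' @method tidy omst_result
#' @export
tidy.omst_result <- function(x, ...) {
  idx <- which(upper.tri(x$retained) & x$retained != 0, arr.ind = TRUE)
  tibble::tibble(from = idx[, 1], to = idx[, 2], weight = x$retained[idx])
}

#' @method glance omst_result
#' @export
glance.omst_result <- function(x, ...) {
  tibble::tibble(
    n_rounds = x$n_rounds,
    rounds_evaluated = x$rounds_total,
    n_edges = sum(x$retained[upper.tri(x$retained)] != 0),
    sparsity = sparsity(x$retained),
    gce = max(x$gce_curve),
    forest_fallback = x$forest_fallback
  )
}
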