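# Delimited-text persistence for every pipeline artifact. One file per
# trial for time series (rows = nodes, columns = samples) plus a YAML
# manifest; matrices as TSV; the supra matrix as sparse triplets.

#' Write a source time-series set to a directory
#'
#' One whitespace-delimited file per trial (rows = nodes, columns =
#' samples) plus a `manifest.yaml` recording sampling rate, epoch, labels
#' and the trial file names.
#'
#' @param ts a [source_ts()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_timeseries <- function(ts, dir) {
  stopifnot(inherits(ts, "source_ts"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n_trials <- dim(ts$data)[3]
  files <- sprintf("trial_%03d.tsv", seq_len(n_trials))
  for (tr in seq_len(n_trials)) {
    utils::write.table(ts$data[, , tr], file.path(dir, files[tr]),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  manifest <- list(fs = ts$fs, epoch = as.list(ts$epoch),
                   labels = as.list(ts$labels), n_trials = n_trials,
                   trial_files = as.list(files))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a source time-series set written by [write_timeseries()]
#'
#' @param dir directory containing `manifest.yaml` and trial files.
#' @return A [source_ts()].
#' @export
read_timeseries <- function(dir) {
  mf <- file.path(dir, "manifest.yaml")
  if (!file.exists(mf)) stop("no manifest.yaml in ", dir, call. = FALSE)
  manifest <- yaml::read_yaml(mf)
  trials <- lapply(manifest$trial_files, function(f) {
    as.matrix(utils::read.table(file.path(dir, f), sep = "\t"))
  })
  n <- nrow(trials[[1]]); s <- ncol(trials[[1]])
  dat <- array(0, dim = c(n, s, length(trials)))
  for (tr in seq_along(trials)) dat[, , tr] <- trials[[tr]]
  source_ts(dat, manifest$fs, unlist(manifest$epoch),
            unlist(manifest$labels))
}

#' Write / read a structural connectivity matrix as delimited text
#'
#' @param sc a `structural_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structural <- function(sc, path) {
  stopifnot(inherits(sc, "structural_matrix"))
  utils::write.table(sc$mat, path, sep = "\t", row.names = FALSE,
                     col.names = sc$labels)
  invisible(path)
}

#' @rdname write_structural
#' @param labels optional node labels overriding the file header.
#' @export
read_structural <- function(path, labels = NULL) {
  if (!file.exists(path)) stop("structural matrix file not found: ", path,
                               call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df)
  labels <- labels %||% colnames(df)
  dimnames(m) <- list(labels, labels)
  check_symmetric(m, what = "structural matrix")
  if (!all(m %in% c(0, 1))) stop("structural matrix must be binary", call. = FALSE)
  structure(list(mat = m, labels = labels,
                 modules = rep(1L, nrow(m))),
            class = "structural_matrix")
}

#' Write connectivity blocks as delimited matrices
#'
#' Each block goes to `"<prefix>_b<A>_b<B>.tsv"`; a JSON sidecar records the
#' bin table and analysis window.
#'
#' @param blocks list of `conn_block`s.
#' @param dir output directory.
#' @param prefix file-name prefix (default `"conn"`).
#' @param bins,window optional metadata for the sidecar.
#' @return `dir`, invisibly.
#' @export
write_blocks <- function(blocks, dir, prefix = "conn", bins = NULL,
                         window = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (b in blocks) {
    f <- sprintf("%s_b%d_b%d.tsv", prefix, b$bin_a, b$bin_b)
    utils::write.table(b$mat, file.path(dir, f), sep = "\t",
                       row.names = FALSE, col.names = FALSE)
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    side <- list(prefix = prefix,
                 n_blocks = length(blocks),
                 bins = if (!is.null(bins)) as.data.frame(bins),
                 window = window)
    jsonlite::write_json(side, file.path(dir, paste0(prefix, "_meta.json")),
                         auto_unbox = TRUE, null = "null")
  }
  invisible(dir)
}

#' Write / read a supra-adjacency matrix as sparse triplet text
#'
#' Upper-triangle nonzero entries as `row col weight` lines, after a header
#' comment recording the node and layer counts.
#'
#' @param supra a `supra_adjacency`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_supra <- function(supra, path) {
  stopifnot(inherits(supra, "supra_adjacency"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_nodes=%d n_layers=%d", supra$n_nodes,
                     supra$n_layers), con)
  idx <- which(upper.tri(supra$mat) & supra$mat != 0, arr.ind = TRUE)
  utils::write.table(data.frame(row = idx[, 1], col = idx[, 2],
                                weight = supra$mat[idx]),
                     con, sep = "\t", row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_supra
#' @param labels optional node labels.
#' @export
read_supra <- function(path, labels = NULL) {
  header <- readLines(path, n = 1)
  m <- regmatches(header, regexec("n_nodes=(\\d+) n_layers=(\\d+)", header))[[1]]
  if (length(m) != 3) stop("malformed supra header: ", header, call. = FALSE)
  N <- as.integer(m[2]); B <- as.integer(m[3])
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#")
  S <- matrix(0, N * B, N * B)
  S[cbind(df$row, df$col)] <- df$weight
  S[cbind(df$col, df$row)] <- df$weight
  structure(list(mat = S, n_nodes = N, n_layers = B,
                 labels = labels %||% paste0("node", seq_len(N))),
            class = "supra_adjacency")
}
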