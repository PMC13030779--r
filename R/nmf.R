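# Rank-2 segment factorization and block-level feature assembly.
#
# Each 20 ms segment X (C x 20, entrywise >= 0) is approximated as W H with
# W (C x r) the spatial loadings and H (r x 20) the temporal activations,
# by minimizing ||X - WH||_F^2 with multiplicative updates. W is the feature
# carried forward; five consecutive W's concatenated column-wise give the
# C x 10 block feature.

#' NMF configuration
#'
#' @param r factorization rank (2 for the spatial feature pipeline).
#' @param max_iter maximum multiplicative-update iterations.
#' @param tol stop when the relative decrease of the squared Frobenius error
#'   falls below this.
#' @param eps additive guard in the update denominators.
#' @param seed master seed from which per-segment initializations are derived.
#' @return list of class `nmf_config`.
#' @export
nmf_config <- function(r = 2, max_iter = 200, tol = 1e-5, eps = 1e-9,
                       seed = 1) {
  if (!is_scalar_number(r) || r < 1) abort_argument("r must be >= 1")
  if (!is_scalar_number(max_iter) || max_iter < 1)
    abort_argument("max_iter must be >= 1")
  structure(list(r = as.integer(r), max_iter = as.integer(max_iter),
                 tol = tol, eps = eps, seed = as.integer(seed)),
            class = "nmf_config")
}

#' Factorize one non-negative segment
#'
#' Multiplicative updates for `min ||X - WH||_F^2` over entrywise
#' non-negative `W` (C x r) and `H` (r x ncol(X)), with an additive guard
#' `eps` in each denominator so all-zero inputs degrade gracefully instead of
#' dividing by zero. Factors are initialized Uniform(0.1, 1) from `seed`
#' unless `init` supplies them. On return the columns of `W` (and rows of
#' `H`) are ordered by descending Euclidean norm of the matching `H` row,
#' fixing the permutation ambiguity so feature columns are comparable across
#' segments.
#'
#' @param X non-negative numeric matrix (channels x time points).
#' @param r rank.
#' @param max_iter,tol,eps see [nmf_config()].
#' @param seed integer seed for the random initialization.
#' @param init optional list with matrices `W` and `H` to start from.
#' @return object of class `nmf_result`: `W`, `H`, `err_trace` (squared
#'   Frobenius error, starting at the initial factors), `n_iter`.
#' @export
nmf_factorize <- function(X, r = 2, max_iter = 200, tol = 1e-5, eps = 1e-9,
                          seed = 1, init = NULL) {
  if (!is.matrix(X) || !is.numeric(X))
    abort_argument("X must be a numeric matrix")
  if (any(X < 0)) abort_argument("X must be entrywise non-negative")
  if (!is_scalar_number(r) || r < 1 || max_iter < 1)
    abort_argument("need r >= 1 and max_iter >= 1")
  C <- nrow(X); J <- ncol(X); r <- as.integer(r)
  if (all(X == 0)) {
    warning("all-zero segment: returning zero factors", call. = FALSE)
    return(structure(list(W = matrix(0, C, r), H = matrix(0, r, J),
                          err_trace = 0, n_iter = 0L),
                     class = "nmf_result"))
  }
  if (is.null(init)) {
    init <- with_seed(seed, list(W = matrix(runif(C * r, 0.1, 1), C, r),
                                 H = matrix(runif(r * J, 0.1, 1), r, J)))
  }
  if (!all(dim(init$W) == c(C, r)) || !all(dim(init$H) == c(r, J)))
    abort_argument("init factors have wrong dimensions")
  if (any(init$W < 0) || any(init$H < 0))
    abort_argument("init factors must be non-negative")
  res <- nmf_mu_cpp(X, init$W, init$H, as.integer(max_iter), tol, eps)
  W <- res$W; H <- res$H
  ord <- order(sqrt(rowSums(H^2)), decreasing = TRUE)
  structure(list(W = W[, ord, drop = FALSE], H = H[ord, , drop = FALSE],
                 err_trace = res$err_trace, n_iter = res$n_iter),
            class = "nmf_result")
}

#' @export
print.nmf_result <- function(x, ...) {
  cat(sprintf("<nmf_result: W %dx%d, %d iterations, final error %.4g>\n",
              nrow(x$W), ncol(x$W), x$n_iter, tail(x$err_trace, 1)))
  invisible(x)
}

#' Spatial feature matrix of one decoding block
#'
#' Factorizes each of the block's five segments at rank `config$r` and
#' concatenates the spatial factors column-wise in temporal order, yielding
#' the C x 10 feature matrix (for rank 2). The initialization seed is
#' derived from `config$seed` and the block id and shared by the block's
#' segments, so identical segments factorize identically while distinct
#' blocks stay decoupled.
#'
#' @param block a `segment_block` from [make_blocks()].
#' @param config an [nmf_config()].
#' @return numeric matrix with `nrow(block$segments[[1]])` rows and
#'   `5 * config$r` columns, with the block label as attribute `label`.
#' @export
extract_block_features <- function(block, config = nmf_config()) {
  stopifnot(inherits(block, "segment_block"))
  if (length(block$segments) < 1) abort_argument("block has no segments")
  block_id <- block$id %||% 0L
  Ws <- lapply(seq_along(block$segments), function(s) {
    res <- tryCatch(
      nmf_factorize(block$segments[[s]], r = config$r,
                    max_iter = config$max_iter, tol = config$tol,
                    eps = config$eps,
                    seed = derive_seed(config$seed, block_id)),
      error = function(e)
        abort_argument(sprintf("segment %d: %s", s, conditionMessage(e))))
    res$W
  })
  F <- do.call(cbind, Ws)
  attr(F, "label") <- block$label
  F
}

#' Feature dataset for a list of blocks
#'
#' @param blocks list of `segment_block`s ([blocks_from_trials()]).
#' @param config an [nmf_config()].
#' @return a `feature_dataset`: `features` (list of C x 10 matrices),
#'   `labels`, `trial` (source trial index per block), `t0`.
#' @export
extract_features <- function(blocks, config = nmf_config()) {
  if (!length(blocks)) abort_argument("no blocks to extract features from")
  feats <- lapply(blocks, extract_block_features, config = config)
  structure(list(
    features = lapply(feats, function(f) { attr(f, "label") <- NULL; f }),
    labels = vapply(blocks, function(b) as.character(b$label), ""),
    trial = vapply(blocks, function(b) b$trial %||% NA_integer_, 0L),
    t0 = vapply(blocks, function(b) b$t0, 0)),
    class = "feature_dataset")
}

#' Raw-block features (factorization bypass)
#'
#' For the ablation that omits the NMF branch: the absolute-valued raw block
#' (segments re-concatenated to C x 100) is used directly as the feature
#' matrix, keeping the rest of the pipeline unchanged.
#'
#' @inheritParams extract_features
#' @return a `feature_dataset` whose features are C x 100 matrices.
#' @export
extract_raw_features <- function(blocks) {
  if (!length(blocks)) abort_argument("no blocks to extract features from")
  structure(list(
    features = lapply(blocks, function(b) do.call(cbind, b$segments)),
    labels = vapply(blocks, function(b) as.character(b$label), ""),
    trial = vapply(blocks, function(b) b$trial %||% NA_integer_, 0L),
    t0 = vapply(blocks, function(b) b$t0, 0)),
    class = "feature_dataset")
}

#' @export
print.feature_dataset <- function(x, ...) {
  d <- dim(x$features[[1]])
  cat(sprintf("<feature_dataset: %d features of %d x %d (%s)>\n",
              length(x$features), d[1], d[2],
              paste(sprintf("%s:%d", names(table(x$labels)), table(x$labels)),
                    collapse = " ")))
  invisible(x)
}

features_as_array <- function(fd) {
  d <- dim(fd$features[[1]])
  array(unlist(fd$features, use.names = FALSE),
        dim = c(d[1], d[2], length(fd$features)))
}

#' Fit per-entry standardization statistics
#'
#' Subject-specific z-scoring: for every (channel, column) entry of the
#' feature matrix, the mean and standard deviation across the supplied
#' (training) features. Entries with zero spread get a unit divisor so
#' constant entries standardize to 0.
#'
#' @param fd a `feature_dataset` of training features (>= 2 features).
#' @return a `norm_stats` list with matrices `mean` and `sd`.
#' @export
fit_normalizer <- function(fd) {
  stopifnot(inherits(fd, "feature_dataset"))
  if (length(fd$features) < 2)
    abort_argument("need at least 2 features to fit the normalizer")
  A <- features_as_array(fd)
  m <- apply(A, c(1, 2), mean)
  s <- apply(A, c(1, 2), sd)
  degenerate <- s <= 0
  if (any(degenerate)) {
    message(sprintf("%d constant feature entries: unit divisor applied",
                    sum(degenerate)))
    s[degenerate] <- 1
  }
  structure(list(mean = m, sd = s), class = "norm_stats")
}

#' Apply (or invert) fitted standardization
#'
#' Test features are always transformed with the training statistics.
#'
#' @param fd a `feature_dataset`.
#' @param stats a `norm_stats` from [fit_normalizer()].
#' @return a `feature_dataset` with standardized features.
#' @export
apply_normalizer <- function(fd, stats) {
  stopifnot(inherits(fd, "feature_dataset"), inherits(stats, "norm_stats"))
  fd$features <- lapply(fd$features, function(f) (f - stats$mean) / stats$sd)
  fd$norm_stats <- stats
  fd
}

#' @rdname apply_normalizer
#' @export
invert_normalizer <- function(fd, stats) {
  stopifnot(inherits(fd, "feature_dataset"), inherits(stats, "norm_stats"))
  fd$features <- lapply(fd$features, function(f) f * stats$sd + stats$mean)
  fd$norm_stats <- NULL
  fd
}

#' Export spatial weights keyed by channel label
#'
#' Writes one row per channel and one column per feature column (the five
#' concatenated rank-2 spatial factors), suitable for topographic plotting
#' downstream.
#'
#' @param feature a single C x 10 feature matrix.
#' @param channel_labels electrode names, one per row.
#' @param path output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
export_spatial_weights <- function(feature, channel_labels, path) {
  if (nrow(feature) != length(channel_labels))
    abort_argument("one channel label per feature row required")
  dt <- data.table::data.table(channel = channel_labels)
  cols <- as.data.frame(feature)
  names(cols) <- sprintf("W%d", seq_len(ncol(feature)))
  data.table::fwrite(cbind(dt, cols), path, sep = "\t")
  invisible(path)
}
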