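# Contrastive and classification objectives.
#
# Similarity between embeddings is the negative squared Euclidean distance
# psi(z, z') = -||z - z'||^2. Per anchor z with positive z+ and M negatives
# z_j^-, the contrastive term is
#   -psi(z, z+) + log sum_j exp psi(z, z_j^-),
# i.e. an alignment term pulling the positive close plus a log-sum-exp
# uniformity term pushing negatives apart; the loss is the mean over anchors.

#' Embedding similarity
#'
#' Negative squared Euclidean distance: non-positive, symmetric, and zero
#' exactly when the embeddings coincide.
#'
#' @param z,zp numeric vectors of equal length.
#' @return a scalar `-sum((z - zp)^2)`.
#' @export
similarity <- function(z, zp) {
  if (length(z) != length(zp))
    abort_argument("embeddings must have equal dimensionality")
  -sum((z - zp)^2)
}

#' Assemble a contrastive batch
#'
#' @param anchors d x A matrix of anchor embeddings (columns are anchors).
#' @param positives d x A matrix, one positive per anchor (same class).
#' @param negatives d x M x A array, M negatives per anchor (other classes).
#' @return a `contrastive_batch` list.
#' @export
contrastive_batch <- function(anchors, positives, negatives) {
  anchors <- as.matrix(anchors); positives <- as.matrix(positives)
  if (length(dim(negatives)) == 2L)
    negatives <- array(negatives, c(nrow(negatives), ncol(negatives), 1L))
  if (!all(dim(anchors) == dim(positives)))
    abort_argument("anchors and positives must share dimensions")
  if (dim(negatives)[1] != nrow(anchors) ||
      dim(negatives)[3] != ncol(anchors))
    abort_argument("negatives must be d x M x A for d x A anchors")
  if (dim(negatives)[2] < 1) abort_argument("need M >= 1 negatives per anchor")
  structure(list(anchors = anchors, positives = positives,
                 negatives = negatives), class = "contrastive_batch")
}

# Squared distances from each anchor to its negatives: M x A matrix.
neg_sqdist <- function(anchors, negatives) {
  M <- dim(negatives)[2]; A <- dim(negatives)[3]
  diff <- negatives - array(rep(anchors, each = 1),
                            c(nrow(anchors), 1, A))[, rep(1, M), , drop = FALSE]
  matrix(colSums(diff^2, dims = 1), M, A)
}

#' Contrastive loss of a batch
#'
#' Mean over anchors of `-psi(z, z+) + log sum_j exp psi(z, z_j^-)` with the
#' log-sum-exp evaluated stably. By default the positive is excluded from
#' the denominator sum; `include_positive = TRUE` switches to the InfoNCE
#' convention that includes it.
#'
#' @param batch a [contrastive_batch()].
#' @param include_positive include the positive in the log-sum-exp.
#' @return scalar loss.
#' @export
contrastive_loss <- function(batch, include_positive = FALSE) {
  stopifnot(inherits(batch, "contrastive_batch"))
  if (ncol(batch$anchors) < 1) abort_argument("empty contrastive batch")
  contrastive_loss_impl(batch, include_positive, grad = FALSE)$loss
}

contrastive_loss_impl <- function(batch, include_positive = FALSE,
                                  grad = TRUE) {
  A <- ncol(batch$anchors); M <- dim(batch$negatives)[2]
  d2p <- colSums((batch$anchors - batch$positives)^2)        # A
  d2n <- neg_sqdist(batch$anchors, batch$negatives)          # M x A
  sims <- -d2n
  if (include_positive) sims <- rbind(sims, -d2p)
  mx <- apply(sims, 2, max)
  w_un <- exp(sweep(sims, 2, mx))                            # (M[+1]) x A
  lse <- mx + log(colSums(w_un))
  loss <- mean(d2p + lse)
  if (!grad) return(list(loss = loss))
  w <- sweep(w_un, 2, colSums(w_un), "/")                    # softmax weights
  wn <- w[seq_len(M), , drop = FALSE]
  wp <- if (include_positive) w[M + 1L, ] else numeric(A)
  # d/dz_a: 2(z_a - z_p)(1 - wp) - 2 sum_j wn_j (z_a - z_j)
  diffp <- batch$anchors - batch$positives                   # d x A
  danch <- 2 * sweep(diffp, 2, 1 - wp, "*")
  dpos <- -2 * sweep(diffp, 2, 1 - wp, "*")
  dneg <- array(0, dim(batch$negatives))
  for (j in seq_len(M)) {
    diffn <- batch$anchors - batch$negatives[, j, ]
    if (is.null(dim(diffn))) diffn <- matrix(diffn, ncol = A)
    contrib <- 2 * sweep(diffn, 2, wn[j, ], "*")
    danch <- danch - contrib
    dneg[, j, ] <- contrib
  }
  list(loss = loss, danchors = danch / A, dpositives = dpos / A,
       dnegatives = dneg / A)
}

#' Cross-entropy loss from probabilities
#'
#' `-log p(true class)`, averaged over samples. Zero probabilities on the
#' true class are clipped at 1e-12 with a warning.
#'
#' @param probabilities numeric vector (one sample) or N x n_classes matrix
#'   with rows summing to one.
#' @param true_label class index (1-based) or class name matching the
#'   probability names/colnames; vector of length N for matrix input.
#' @return scalar mean cross-entropy (natural log).
#' @export
cross_entropy_loss <- function(probabilities, true_label) {
  if (is.null(dim(probabilities)))
    probabilities <- matrix(probabilities, nrow = 1,
                            dimnames = list(NULL, names(probabilities)))
  if (any(probabilities < -1e-9) ||
      any(abs(rowSums(probabilities) - 1) > 1e-6))
    abort_argument("probabilities must be non-negative and sum to 1 per sample")
  n <- nrow(probabilities)
  if (length(true_label) != n)
    abort_argument("one true label per probability row required")
  if (is.character(true_label)) {
    idx <- match(true_label, colnames(probabilities))
    if (anyNA(idx)) abort_argument("true label not among the class names")
  } else {
    idx <- as.integer(true_label)
    if (any(idx < 1 | idx > ncol(probabilities)))
      abort_argument("true label index out of range")
  }
  p <- probabilities[cbind(seq_len(n), idx)]
  if (any(p <= 0)) {
    warning("zero probability on the true class clipped at 1e-12",
            call. = FALSE)
    p <- pmax(p, 1e-12)
  }
  mean(-log(p))
}

#' Composite training objective
#'
#' `ce + lambda * contrastive`; with `lambda = 0` (the default) the joint
#' phase optimizes plain cross-entropy.
#'
#' @param ce scalar cross-entropy loss.
#' @param contrastive scalar contrastive loss.
#' @param lambda_contrastive non-negative weight.
#' @return scalar total loss.
#' @export
total_loss <- function(ce, contrastive, lambda_contrastive = 0) {
  if (!is_scalar_number(lambda_contrastive) || lambda_contrastive < 0)
    abort_argument("lambda_contrastive must be >= 0")
  ce + lambda_contrastive * contrastive
}
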