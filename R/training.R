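# Two-stage optimization: contrastive pre-training of the encoder, then
# joint refinement of encoder + classifier with the composite objective.

#' Training configuration
#'
#' @param lr Adam learning rate.
#' @param pretrain_epochs,joint_epochs epochs of the two stages.
#' @param batch_size minibatch size.
#' @param M negatives sampled per anchor.
#' @param lambda_contrastive weight of the contrastive term during joint
#'   refinement (0 = plain cross-entropy).
#' @param master_seed seed governing shuffling and pair sampling.
#' @return a `train_config` list.
#' @export
train_config <- function(lr = 1e-3, pretrain_epochs = 50, joint_epochs = 50,
                         batch_size = 64, M = 8, lambda_contrastive = 0,
                         master_seed = 1) {
  if (!is_scalar_number(lr) || lr <= 0) abort_argument("lr must be > 0")
  if (pretrain_epochs < 0 || joint_epochs < 0)
    abort_argument("epoch counts must be >= 0")
  if (M < 1) abort_argument("M must be >= 1")
  structure(list(lr = lr, pretrain_epochs = as.integer(pretrain_epochs),
                 joint_epochs = as.integer(joint_epochs),
                 batch_size = as.integer(batch_size), M = as.integer(M),
                 lambda_contrastive = lambda_contrastive,
                 master_seed = as.integer(master_seed)),
            class = "train_config")
}

#' Sample anchor/positive/negative index triples
#'
#' For every usable sample in the batch: a positive drawn uniformly from the
#' other samples of the same class and `M` negatives drawn (with
#' replacement) from samples of different classes. Anchors whose class has
#' no second member, or no negatives, are skipped.
#'
#' @param labels batch labels.
#' @param M negatives per anchor.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return list with integer `anchor`, `positive` and M x A `negatives`.
#' @export
sample_pairs <- function(labels, M = 8, seed = NULL) {
  n <- length(labels)
  draw <- function() {
    anchor <- integer(); positive <- integer(); negs <- NULL
    for (i in seq_len(n)) {
      same <- setdiff(which(labels == labels[i]), i)
      other <- which(labels != labels[i])
      if (!length(same) || !length(other)) next
      anchor <- c(anchor, i)
      positive <- c(positive, if (length(same) == 1L) same else sample(same, 1))
      nd <- if (length(other) == 1L) rep(other, M) else
        sample(other, M, replace = TRUE)
      negs <- cbind(negs, nd)
    }
    if (!length(anchor)) {
      warning("batch has no usable anchors (single class?)", call. = FALSE)
      return(list(anchor = integer(), positive = integer(),
                  negatives = matrix(integer(), M, 0)))
    }
    dimnames(negs) <- NULL
    list(anchor = anchor, positive = positive, negatives = negs)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, which = names(params),
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in which) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

encoder_param_names <- function(model) {
  setdiff(names(model$params), c("head_W", "head_b"))
}

batch_indices <- function(n, batch_size) {
  split(seq_len(n), ceiling(seq_len(n) / batch_size))
}

#' Contrastive pre-training of the encoder
#'
#' Minimizes the contrastive loss over minibatches with Adam; only encoder
#' parameters are updated (the classifier head is untouched). The model
#' environment is modified in place.
#'
#' @param model an `nmf_encoder` from [build_encoder()].
#' @param fd a standardized `feature_dataset` with >= 2 classes.
#' @param cfg a [train_config()].
#' @return invisibly, a history data.frame (epoch, contrastive loss).
#' @export
pretrain_contrastive <- function(model, fd, cfg = train_config()) {
  stopifnot(inherits(model, "nmf_encoder"), inherits(fd, "feature_dataset"))
  labels <- fd$labels
  if (length(unique(labels)) < 2)
    abort_argument("contrastive pre-training needs >= 2 classes")
  X_all <- features_to_tensor(fd)
  n <- length(labels)
  history <- data.frame(epoch = integer(), loss = numeric())
  if (cfg$pretrain_epochs == 0) return(invisible(history))
  opt <- adam_init(model$params)
  enc_names <- encoder_param_names(model)
  for (epoch in seq_len(cfg$pretrain_epochs)) {
    losses <- c()
    with_seed(derive_seed(cfg$master_seed, epoch), {
      ord <- sample.int(n)
      for (bi in batch_indices(n, cfg$batch_size)) {
        idx <- ord[bi]
        pairs <- suppressWarnings(sample_pairs(labels[idx], cfg$M))
        if (!length(pairs$anchor)) next
        fw <- enc_forward(model, X_all[, , idx, drop = FALSE],
                          train = TRUE, keep_cache = TRUE)
        z <- fw$z
        batch <- contrastive_batch(
          z[, pairs$anchor, drop = FALSE],
          z[, pairs$positive, drop = FALSE],
          array(z[, as.vector(pairs$negatives)],
                c(nrow(z), nrow(pairs$negatives), length(pairs$anchor))))
        cl <- contrastive_loss_impl(batch)
        if (!is.finite(cl$loss))
          stop(sprintf("contrastive loss diverged (epoch %d): %g",
                       epoch, cl$loss))
        # scatter pair gradients back onto batch embeddings
        dz <- z * 0
        for (a in seq_along(pairs$anchor)) {
          dz[, pairs$anchor[a]] <- dz[, pairs$anchor[a]] + cl$danchors[, a]
          dz[, pairs$positive[a]] <- dz[, pairs$positive[a]] + cl$dpositives[, a]
          for (j in seq_len(nrow(pairs$negatives)))
            dz[, pairs$negatives[j, a]] <-
              dz[, pairs$negatives[j, a]] + cl$dnegatives[, j, a]
        }
        grads <- enc_backward(model, fw$cache, dz = dz)
        st <- adam_step(model$params, grads, opt, cfg$lr, which = enc_names)
        model$params <- st$params; opt <- st$state
        losses <- c(losses, cl$loss)
      }
    })
    history <- rbind(history,
                     data.frame(epoch = epoch, loss = mean(losses)))
  }
  invisible(history)
}

#' Joint refinement of encoder and classifier
#'
#' Minimizes cross-entropy (plus `lambda_contrastive` times the contrastive
#' loss when positive) over minibatches with Adam, updating all parameters.
#' Stores the class vocabulary on the model.
#'
#' @inheritParams pretrain_contrastive
#' @param classes optional fixed class ordering; defaults to sorted unique
#'   labels.
#' @return invisibly, a history data.frame (epoch, ce, contrastive, total,
#'   train_acc).
#' @export
joint_train <- function(model, fd, cfg = train_config(), classes = NULL) {
  stopifnot(inherits(model, "nmf_encoder"), inherits(fd, "feature_dataset"))
  classes <- classes %||% sort(unique(fd$labels))
  if (length(classes) != model$config$n_classes)
    abort_argument(sprintf("model expects %d classes; data has %d",
                           model$config$n_classes, length(classes)))
  model$classes <- classes
  y <- match(fd$labels, classes)
  X_all <- features_to_tensor(fd)
  n <- length(y)
  history <- data.frame(epoch = integer(), ce = numeric(),
                        contrastive = numeric(), total = numeric(),
                        train_acc = numeric())
  if (cfg$joint_epochs == 0) return(invisible(history))
  opt <- adam_init(model$params)
  lam <- cfg$lambda_contrastive
  for (epoch in seq_len(cfg$joint_epochs)) {
    ce_l <- c(); co_l <- c(); acc <- c()
    with_seed(derive_seed(cfg$master_seed, 100000L + epoch), {
      ord <- sample.int(n)
      for (bi in batch_indices(n, cfg$batch_size)) {
        idx <- ord[bi]
        nb <- length(idx)
        fw <- enc_forward(model, X_all[, , idx, drop = FALSE],
                          train = TRUE, keep_cache = TRUE)
        probs <- softmax_cols(fw$logits)
        yb <- y[idx]
        ce <- mean(-log(pmax(probs[cbind(yb, seq_len(nb))], 1e-12)))
        dlogits <- probs
        dlogits[cbind(yb, seq_len(nb))] <-
          dlogits[cbind(yb, seq_len(nb))] - 1
        dlogits <- dlogits / nb
        co <- 0; dz <- NULL
        if (lam > 0) {
          pairs <- suppressWarnings(sample_pairs(fd$labels[idx], cfg$M))
          if (length(pairs$anchor)) {
            z <- fw$z
            batch <- contrastive_batch(
              z[, pairs$anchor, drop = FALSE],
              z[, pairs$positive, drop = FALSE],
              array(z[, as.vector(pairs$negatives)],
                    c(nrow(z), nrow(pairs$negatives), length(pairs$anchor))))
            cl <- contrastive_loss_impl(batch)
            co <- cl$loss
            dz <- z * 0
            for (a in seq_along(pairs$anchor)) {
              dz[, pairs$anchor[a]] <- dz[, pairs$anchor[a]] +
                lam * cl$danchors[, a]
              dz[, pairs$positive[a]] <- dz[, pairs$positive[a]] +
                lam * cl$dpositives[, a]
              for (j in seq_len(nrow(pairs$negatives)))
                dz[, pairs$negatives[j, a]] <-
                  dz[, pairs$negatives[j, a]] + lam * cl$dnegatives[, j, a]
            }
          }
        }
        tot <- total_loss(ce, co, lam)
        if (!is.finite(tot))
          stop(sprintf("training loss diverged (epoch %d): %g", epoch, tot))
        grads <- enc_backward(model, fw$cache, dz = dz, dlogits = dlogits)
        st <- adam_step(model$params, grads, opt, cfg$lr)
        model$params <- st$params; opt <- st$state
        ce_l <- c(ce_l, ce); co_l <- c(co_l, co)
        acc <- c(acc, mean(max.col(t(probs), ties.method = "first") == yb))
      }
    })
    history <- rbind(history, data.frame(
      epoch = epoch, ce = mean(ce_l), contrastive = mean(co_l),
      total = mean(ce_l) + lam * mean(co_l), train_acc = mean(acc)))
  }
  invisible(history)
}

#' Classifier fit on a frozen encoder
#'
#' The ablation that skips joint refinement: embeddings are computed in
#' evaluation mode with the pre-trained encoder frozen, and only the linear
#' head is trained with cross-entropy.
#'
#' @inheritParams joint_train
#' @return invisibly, a history data.frame (epoch, ce, train_acc).
#' @export
train_head_only <- function(model, fd, cfg = train_config(), classes = NULL) {
  stopifnot(inherits(model, "nmf_encoder"), inherits(fd, "feature_dataset"))
  classes <- classes %||% sort(unique(fd$labels))
  model$classes <- classes
  y <- match(fd$labels, classes)
  Z <- enc_forward(model, features_to_tensor(fd), train = FALSE)$z
  n <- length(y)
  opt <- adam_init(model$params[c("head_W", "head_b")])
  history <- data.frame(epoch = integer(), ce = numeric(),
                        train_acc = numeric())
  for (epoch in seq_len(cfg$joint_epochs)) {
    ce_l <- c(); acc <- c()
    with_seed(derive_seed(cfg$master_seed, 200000L + epoch), {
      ord <- sample.int(n)
      for (bi in batch_indices(n, cfg$batch_size)) {
        idx <- ord[bi]
        zb <- Z[, idx, drop = FALSE]
        logits <- model$params$head_W %*% zb + model$params$head_b
        probs <- softmax_cols(logits)
        yb <- y[idx]
        nb <- length(idx)
        ce <- mean(-log(pmax(probs[cbind(yb, seq_len(nb))], 1e-12)))
        dlogits <- probs
        dlogits[cbind(yb, seq_len(nb))] <- dlogits[cbind(yb, seq_len(nb))] - 1
        dlogits <- dlogits / nb
        grads <- list(head_W = dlogits %*% t(zb), head_b = rowSums(dlogits))
        hp <- model$params[c("head_W", "head_b")]
        st <- adam_step(hp, grads, opt, cfg$lr)
        model$params$head_W <- st$params$head_W
        model$params$head_b <- st$params$head_b
        opt <- st$state
        ce_l <- c(ce_l, ce)
        acc <- c(acc, mean(max.col(t(probs), ties.method = "first") == yb))
      }
    })
    history <- rbind(history, data.frame(epoch = epoch, ce = mean(ce_l),
                                         train_acc = mean(acc)))
  }
  invisible(history)
}
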