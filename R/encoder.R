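# Residual 1-D convolutional encoder with latent projection and linear
# classifier head.
#
# Architecture: stem conv (k=3, s=1, p=1, 32 channels) + BatchNorm + GELU;
# three residual stages with channel widths (32, 64, 128) and strides
# (1, 2, 2), each stage holding N residual blocks of two conv layers
# (BatchNorm + GELU inside, GELU after the skip addition); downsampling
# blocks project the shortcut with a strided 1x1 convolution; adaptive
# average pooling to length 1; FC1 (128 -> 128, GELU) and FC2 (128 -> 32)
# into the latent space; a linear head maps latents to class logits.

#' Encoder configuration
#'
#' @param in_channels number of input channels C (feature-matrix rows).
#' @param n_classes number of movement classes.
#' @param stage_channels channel widths of the three residual stages.
#' @param stage_strides first-block stride per stage.
#' @param blocks_per_stage residual blocks per stage (N1, N2, N3).
#' @param kernel convolution kernel size (odd).
#' @param padding symmetric zero padding.
#' @param latent_dim embedding dimensionality.
#' @param input_length expected feature-matrix columns (10 for rank-2 NMF
#'   features, 100 for the raw-block ablation).
#' @param bn_momentum,bn_eps BatchNorm running-average momentum and variance
#'   guard.
#' @return an `encoder_config` list.
#' @export
encoder_config <- function(in_channels, n_classes = 4,
                           stage_channels = c(32, 64, 128),
                           stage_strides = c(1, 2, 2),
                           blocks_per_stage = c(1, 1, 1),
                           kernel = 3, padding = 1, latent_dim = 32,
                           input_length = 10,
                           bn_momentum = 0.1, bn_eps = 1e-5) {
  if (!is_scalar_number(in_channels) || in_channels < 1)
    abort_argument("in_channels must be a positive integer")
  if (kernel %% 2 != 1) abort_argument("kernel size must be odd")
  if (latent_dim < 1) abort_argument("latent_dim must be positive")
  if (length(stage_channels) != length(stage_strides) ||
      length(stage_channels) != length(blocks_per_stage))
    abort_argument("stage_channels, stage_strides, blocks_per_stage must have equal length")
  structure(list(in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes),
                 stage_channels = as.integer(stage_channels),
                 stage_strides = as.integer(stage_strides),
                 blocks_per_stage = as.integer(blocks_per_stage),
                 kernel = as.integer(kernel), padding = as.integer(padding),
                 latent_dim = as.integer(latent_dim),
                 input_length = as.integer(input_length),
                 bn_momentum = bn_momentum, bn_eps = bn_eps),
            class = "encoder_config")
}

conv_out_len <- function(L, k, s, p) (L + 2L * p - k) %/% s + 1L

#' Per-stage output shapes by pure convolution arithmetic
#'
#' Computes `floor((L + 2p - k)/s) + 1` through the network without
#' instantiating parameters: stem, each residual stage, pooled vector, FC1,
#' latent.
#'
#' @param config an [encoder_config()].
#' @param input_length input sequence length.
#' @return list of integer vectors `(channels, length)` for convolutional
#'   outputs and `(width)` for vector outputs.
#' @export
shape_trace <- function(config, input_length = 10) {
  stopifnot(inherits(config, "encoder_config"))
  if (!is_scalar_number(input_length) || input_length < 1)
    abort_argument("input_length must be >= 1")
  k <- config$kernel; p <- config$padding
  L <- conv_out_len(as.integer(input_length), k, 1L, p)
  if (L < 1) abort_argument("stem output length collapsed to zero")
  trace <- list(c(config$stage_channels[1], L))
  for (s in seq_along(config$stage_channels)) {
    L <- conv_out_len(L, k, config$stage_strides[s], p)
    if (L < 1) abort_argument(sprintf("stage %d output length collapsed to zero", s))
    # remaining convs in the stage are stride 1 with "same" padding
    trace[[length(trace) + 1L]] <- c(config$stage_channels[s], L)
  }
  ch <- tail(config$stage_channels, 1)
  c(trace, list(c(ch, 1L), ch, config$latent_dim))
}

# Stage/block table the forward and backward passes iterate over.
encoder_arch <- function(config) {
  arch <- list()
  in_ch <- config$stage_channels[1]
  for (s in seq_along(config$stage_channels)) {
    out_ch <- config$stage_channels[s]
    for (j in seq_len(config$blocks_per_stage[s])) {
      stride <- if (j == 1L) config$stage_strides[s] else 1L
      proj <- stride != 1L || in_ch != out_ch
      arch[[length(arch) + 1L]] <-
        list(name = sprintf("s%d_b%d", s, j), in_ch = in_ch,
             out_ch = out_ch, stride = stride, proj = proj)
      in_ch <- out_ch
    }
  }
  arch
}

init_conv <- function(C_out, C_in, k) {
  list(W = matrix(rnorm(C_out * C_in * k, 0, sqrt(2 / (C_in * k))),
                  C_out, C_in * k),
       b = numeric(C_out))
}
init_fc <- function(n_out, n_in) {
  list(W = matrix(rnorm(n_out * n_in, 0, sqrt(2 / n_in)), n_out, n_in),
       b = numeric(n_out))
}

#' Build a seeded encoder + classifier model
#'
#' Parameters use He fan-in initialization drawn from `seed`; BatchNorm
#' scales start at 1 with zero shift and unit running variance. The returned
#' handle is an environment mutated in place by the training routines.
#'
#' @param config an [encoder_config()].
#' @param seed integer seed for the parameter initialization.
#' @return an object of class `nmf_encoder`.
#' @export
build_encoder <- function(config, seed = 1) {
  stopifnot(inherits(config, "encoder_config"))
  # validate the geometry up front
  shape_trace(config, config$input_length)
  k <- config$kernel
  params <- list(); buffers <- list()
  add_bn <- function(prefix, C) {
    params[[paste0(prefix, "_g")]] <<- rep(1, C)
    params[[paste0(prefix, "_b")]] <<- numeric(C)
    buffers[[paste0(prefix, "_rm")]] <<- numeric(C)
    buffers[[paste0(prefix, "_rv")]] <<- rep(1, C)
  }
  with_seed(seed, {
    cv <- init_conv(config$stage_channels[1], config$in_channels, k)
    params$stem_conv_W <- cv$W; params$stem_conv_b <- cv$b
    add_bn("stem_bn", config$stage_channels[1])
    for (blk in encoder_arch(config)) {
      p <- blk$name
      c1 <- init_conv(blk$out_ch, blk$in_ch, k)
      c2 <- init_conv(blk$out_ch, blk$out_ch, k)
      params[[paste0(p, "_conv1_W")]] <- c1$W
      params[[paste0(p, "_conv1_b")]] <- c1$b
      params[[paste0(p, "_conv2_W")]] <- c2$W
      params[[paste0(p, "_conv2_b")]] <- c2$b
      add_bn(paste0(p, "_bn1"), blk$out_ch)
      add_bn(paste0(p, "_bn2"), blk$out_ch)
      if (blk$proj) {
        pj <- init_conv(blk$out_ch, blk$in_ch, 1)
        params[[paste0(p, "_proj_W")]] <- pj$W
        params[[paste0(p, "_proj_b")]] <- pj$b
        add_bn(paste0(p, "_projbn"), blk$out_ch)
      }
    }
    ch <- tail(config$stage_channels, 1)
    f1 <- init_fc(ch, ch)
    params$fc1_W <- f1$W; params$fc1_b <- f1$b
    f2 <- init_fc(config$latent_dim, ch)
    params$fc2_W <- f2$W; params$fc2_b <- f2$b
    hd <- init_fc(config$n_classes, config$latent_dim)
    params$head_W <- hd$W; params$head_b <- hd$b
  })
  model <- new.env(parent = emptyenv())
  model$params <- params
  model$buffers <- buffers
  model$config <- config
  model$classes <- NULL
  class(model) <- "nmf_encoder"
  model
}

#' @export
print.nmf_encoder <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, 0L))
  cat(sprintf("<nmf_encoder: C=%d L=%d -> latent %d -> %d classes, %d parameters>\n",
              x$config$in_channels, x$config$input_length,
              x$config$latent_dim, x$config$n_classes, n_par))
  invisible(x)
}

# Forward pass. Returns pooled vector, latent z, logits, and (if keep_cache)
# everything the backward pass needs. In training mode BatchNorm buffers in
# the model environment are updated in place.
enc_forward <- function(model, X, train = FALSE, keep_cache = FALSE) {
  P <- model$params; cfg <- model$config
  run_bn <- function(prefix, Y) {
    r <- bn_fwd(Y, P[[paste0(prefix, "_g")]], P[[paste0(prefix, "_b")]],
                model$buffers[[paste0(prefix, "_rm")]],
                model$buffers[[paste0(prefix, "_rv")]],
                train, cfg$bn_momentum, cfg$bn_eps)
    if (train) {
      model$buffers[[paste0(prefix, "_rm")]] <- r$rm
      model$buffers[[paste0(prefix, "_rv")]] <- r$rv
    }
    r
  }
  caches <- list()
  cv <- conv_fwd(X, P$stem_conv_W, P$stem_conv_b, 1L, cfg$padding)
  bn <- run_bn("stem_bn", cv$Y)
  h <- bn$Y * pnorm(bn$Y)
  if (keep_cache) caches$stem <- list(conv = cv$cache, bn = bn$cache, pre = bn$Y)
  for (blk in encoder_arch(cfg)) {
    p <- blk$name
    c1 <- conv_fwd(h, P[[paste0(p, "_conv1_W")]], P[[paste0(p, "_conv1_b")]],
                   blk$stride, cfg$padding)
    b1 <- run_bn(paste0(p, "_bn1"), c1$Y)
    g1 <- b1$Y * pnorm(b1$Y)
    c2 <- conv_fwd(g1, P[[paste0(p, "_conv2_W")]], P[[paste0(p, "_conv2_b")]],
                   1L, cfg$padding)
    b2 <- run_bn(paste0(p, "_bn2"), c2$Y)
    if (blk$proj) {
      pc <- conv_fwd(h, P[[paste0(p, "_proj_W")]], P[[paste0(p, "_proj_b")]],
                     blk$stride, 0L)
      pb <- run_bn(paste0(p, "_projbn"), pc$Y)
      sc <- pb$Y
    } else {
      pc <- NULL; pb <- NULL; sc <- h
    }
    pre <- b2$Y + sc
    out <- pre * pnorm(pre)
    if (keep_cache)
      caches[[p]] <- list(conv1 = c1$cache, bn1 = b1$cache, pre1 = b1$Y,
                          conv2 = c2$cache, bn2 = b2$cache,
                          proj = if (blk$proj) pc$cache,
                          projbn = if (blk$proj) pb$cache,
                          pre = pre)
    h <- out
  }
  Lh <- dim(h)[2]
  pooled <- colSums(aperm(h, c(2, 1, 3)), dims = 1) / Lh  # (channels, batch)
  a1 <- P$fc1_W %*% pooled + P$fc1_b
  g1 <- a1 * pnorm(a1)
  z <- P$fc2_W %*% g1 + P$fc2_b
  logits <- P$head_W %*% z + P$head_b
  if (keep_cache) {
    caches$pool_len <- dim(h)[2]
    caches$pooled <- pooled
    caches$a1 <- a1; caches$g1 <- g1; caches$z <- z
  }
  list(z = z, logits = logits, pooled = pooled,
       cache = if (keep_cache) caches)
}

# Backward pass from gradients at the latent (`dz`) and/or the logits
# (`dlogits`). Returns a named gradient list parallel to model$params.
enc_backward <- function(model, caches, dz = NULL, dlogits = NULL) {
  P <- model$params; cfg <- model$config
  grads <- list()
  if (!is.null(dlogits)) {
    grads$head_W <- dlogits %*% t(caches$z)
    grads$head_b <- rowSums(dlogits)
    dz_total <- crossprod(P$head_W, dlogits)
    if (!is.null(dz)) dz_total <- dz_total + dz
  } else {
    grads$head_W <- P$head_W * 0
    grads$head_b <- P$head_b * 0
    dz_total <- dz
  }
  grads$fc2_W <- dz_total %*% t(caches$g1)
  grads$fc2_b <- rowSums(dz_total)
  dg1 <- crossprod(P$fc2_W, dz_total)
  da1 <- dg1 * (pnorm(caches$a1) + caches$a1 * dnorm(caches$a1))
  grads$fc1_W <- da1 %*% t(caches$pooled)
  grads$fc1_b <- rowSums(da1)
  dpool <- crossprod(P$fc1_W, da1)             # (channels, batch)
  Lp <- caches$pool_len
  dh <- array(rep(dpool / Lp, each = 1), c(nrow(dpool), 1, ncol(dpool)))
  dh <- dh[, rep(1, Lp), , drop = FALSE]       # broadcast mean gradient
  arch <- rev(encoder_arch(cfg))
  for (blk in arch) {
    p <- blk$name; cc <- caches[[p]]
    dpre <- dh * (pnorm(cc$pre) + cc$pre * dnorm(cc$pre))
    # main branch: bn2 <- conv2 <- gelu(bn1) <- conv1
    b2 <- bn_bwd(dpre, cc$bn2)
    grads[[paste0(p, "_bn2_g")]] <- b2$dg
    grads[[paste0(p, "_bn2_b")]] <- b2$db
    c2 <- conv_bwd(b2$dX, cc$conv2, P[[paste0(p, "_conv2_W")]])
    grads[[paste0(p, "_conv2_W")]] <- c2$dW
    grads[[paste0(p, "_conv2_b")]] <- c2$db
    dg1b <- c2$dX * (pnorm(cc$pre1) + cc$pre1 * dnorm(cc$pre1))
    b1 <- bn_bwd(dg1b, cc$bn1)
    grads[[paste0(p, "_bn1_g")]] <- b1$dg
    grads[[paste0(p, "_bn1_b")]] <- b1$db
    c1 <- conv_bwd(b1$dX, cc$conv1, P[[paste0(p, "_conv1_W")]])
    grads[[paste0(p, "_conv1_W")]] <- c1$dW
    grads[[paste0(p, "_conv1_b")]] <- c1$db
    dh_in <- c1$dX
    # shortcut branch
    if (blk$proj) {
      pb <- bn_bwd(dpre, cc$projbn)
      grads[[paste0(p, "_projbn_g")]] <- pb$dg
      grads[[paste0(p, "_projbn_b")]] <- pb$db
      pj <- conv_bwd(pb$dX, cc$proj, P[[paste0(p, "_proj_W")]])
      grads[[paste0(p, "_proj_W")]] <- pj$dW
      grads[[paste0(p, "_proj_b")]] <- pj$db
      dh_in <- dh_in + pj$dX
    } else {
      dh_in <- dh_in + dpre
    }
    dh <- dh_in
  }
  dg0 <- dh * (pnorm(caches$stem$pre) + caches$stem$pre * dnorm(caches$stem$pre))
  b0 <- bn_bwd(dg0, caches$stem$bn)
  grads$stem_bn_g <- b0$dg
  grads$stem_bn_b <- b0$db
  c0 <- conv_bwd(b0$dX, caches$stem$conv, P$stem_conv_W)
  grads$stem_conv_W <- c0$dW
  grads$stem_conv_b <- c0$db
  grads
}

features_to_tensor <- function(features) {
  if (inherits(features, "feature_dataset")) features <- features$features
  if (is.matrix(features)) features <- list(features)
  d <- dim(features[[1]])
  array(unlist(features, use.names = FALSE), c(d[1], d[2], length(features)))
}

#' Embed feature matrices in the latent space
#'
#' Evaluation-mode forward pass (BatchNorm running statistics, no
#' stochastic layers), hence deterministic.
#'
#' @param model an `nmf_encoder`.
#' @param F a C x L feature matrix, a list of them, or a `feature_dataset`.
#' @return numeric vector of length `latent_dim` for a single matrix,
#'   otherwise a latent_dim x N matrix.
#' @export
encode <- function(model, F) {
  stopifnot(inherits(model, "nmf_encoder"))
  single <- is.matrix(F)
  X <- features_to_tensor(F)
  if (dim(X)[1] != model$config$in_channels ||
      dim(X)[2] != model$config$input_length)
    abort_argument(sprintf("feature shape %dx%d does not match model (%dx%d)",
                           dim(X)[1], dim(X)[2], model$config$in_channels,
                           model$config$input_length))
  z <- enc_forward(model, X, train = FALSE)$z
  if (single) drop(z) else z
}

#' Class probabilities for feature matrices
#'
#' Softmax over the classifier logits; entries are non-negative and sum
#' to one per sample.
#'
#' @inheritParams encode
#' @return probability vector (single matrix) or N x n_classes matrix.
#' @export
classify <- function(model, F) {
  stopifnot(inherits(model, "nmf_encoder"))
  single <- is.matrix(F)
  X <- features_to_tensor(F)
  if (dim(X)[1] != model$config$in_channels ||
      dim(X)[2] != model$config$input_length)
    abort_argument("feature shape does not match the model configuration")
  pr <- softmax_cols(enc_forward(model, X, train = FALSE)$logits)
  cls <- model$classes %||% paste0("class", seq_len(model$config$n_classes))
  if (single) stats::setNames(drop(pr), cls) else {
    out <- t(pr); colnames(out) <- cls; out
  }
}

#' Predicted class labels for a feature dataset
#' @inheritParams encode
#' @return character vector of predicted labels.
#' @export
predict_labels <- function(model, F) {
  pr <- classify(model, F)
  if (is.null(dim(pr))) pr <- matrix(pr, 1, dimnames = list(NULL, names(pr)))
  colnames(pr)[max.col(pr, ties.method = "first")]
}

#' Save / load an encoder checkpoint
#'
#' The checkpoint embeds the configuration, parameters, BatchNorm buffers
#' and class labels; reloading reproduces evaluation output bit-for-bit.
#'
#' @param model an `nmf_encoder`.
#' @param path file path.
#' @return `path` invisibly; `load_encoder` returns the model.
#' @export
save_encoder <- function(model, path) {
  stopifnot(inherits(model, "nmf_encoder"))
  saveRDS(list(params = model$params, buffers = model$buffers,
               config = model$config, classes = model$classes), path)
  invisible(path)
}

#' @rdname save_encoder
#' @export
load_encoder <- function(path) {
  st <- readRDS(path)
  model <- new.env(parent = emptyenv())
  model$params <- st$params; model$buffers <- st$buffers
  model$config <- st$config; model$classes <- st$classes
  class(model) <- "nmf_encoder"
  model
}

# Checksum used by determinism tests.
param_checksum <- function(model) {
  sum(vapply(model$params, function(p) sum(p^2), 0))
}
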