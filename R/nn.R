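# Differentiable layer primitives for the 1-D residual encoder.
#
# Tensors are arrays (channels, length, batch); R's column-major layout makes
# channel-wise broadcasting (vector op array) exact. Convolutions are im2col
# matrix products so BLAS does the work; every forward returns the cache its
# analytic backward needs.

conv_fwd <- function(X, Wm, b, stride, pad) {
  d <- dim(X); C <- d[1]; L <- d[2]; N <- d[3]
  k <- ncol(Wm) %/% C
  Lp <- L + 2L * pad
  Lout <- (Lp - k) %/% stride + 1L
  if (Lp < k || Lout < 1L)
    abort_argument("sequence length collapsed below one output sample")
  if (pad > 0) {
    Xp <- array(0, c(C, Lp, N))
    Xp[, (pad + 1L):(pad + L), ] <- X
  } else Xp <- X
  pos <- outer(seq_len(k), (seq_len(Lout) - 1L) * stride, "+")  # k x Lout
  idx0 <- (rep(as.vector(pos), each = C) - 1L) * C + rep(seq_len(C), k * Lout)
  idx <- rep(idx0, times = N) +
    rep((seq_len(N) - 1L) * (C * Lp), each = C * k * Lout)
  Xc <- matrix(Xp[idx], nrow = C * k)
  Y <- Wm %*% Xc + b
  list(Y = array(Y, c(nrow(Wm), Lout, N)),
       cache = list(Xc = Xc, C = C, L = L, N = N, Lp = Lp,
                    Lout = Lout, k = k, stride = stride, pad = pad))
}

conv_bwd <- function(dY, cache, Wm) {
  dYm <- matrix(dY, nrow = dim(dY)[1])
  dW <- dYm %*% t(cache$Xc)
  db <- rowSums(dYm)
  dXc <- crossprod(Wm, dYm)                  # (C*k) x (Lout*N)
  C <- cache$C; k <- cache$k; Lout <- cache$Lout
  dXp <- array(0, c(C, cache$Lp, cache$N))
  # Within one kernel offset the target positions are distinct, so the
  # scatter-add is k plain vectorized additions.
  for (kk in seq_len(k)) {
    block <- array(dXc[((kk - 1L) * C + 1L):(kk * C), ],
                   c(C, Lout, cache$N))
    pos <- (seq_len(Lout) - 1L) * cache$stride + kk
    dXp[, pos, ] <- dXp[, pos, ] + block
  }
  dX <- if (cache$pad > 0) {
    dXp[, (cache$pad + 1L):(cache$pad + cache$L), , drop = FALSE]
  } else dXp
  list(dX = dX, dW = dW, db = db)
}

# Batch normalization over the channel dimension (statistics across length
# and batch). Training mode uses batch statistics and returns updated running
# averages (unbiased variance, momentum `mom`); evaluation mode uses the
# stored running statistics.
bn_fwd <- function(X, g, b, rm, rv, train, mom = 0.1, eps = 1e-5) {
  n <- prod(dim(X)[-1])
  if (train) {
    m <- rowMeans(X, dims = 1)
    v <- pmax(rowMeans(X * X, dims = 1) - m * m, 0)
    istd <- 1 / sqrt(v + eps)
    xhat <- (X - m) * istd
    unb <- if (n > 1) n / (n - 1) else 1
    rm <- (1 - mom) * rm + mom * m
    rv <- (1 - mom) * rv + mom * v * unb
  } else {
    istd <- 1 / sqrt(rv + eps)
    xhat <- (X - rm) * istd
  }
  list(Y = g * xhat + b,
       cache = list(xhat = xhat, istd = istd, g = g, n = n),
       rm = rm, rv = rv)
}

bn_bwd <- function(dY, cache) {
  dg <- rowSums(dY * cache$xhat, dims = 1)
  db <- rowSums(dY, dims = 1)
  dxhat <- dY * cache$g
  s1 <- rowSums(dxhat, dims = 1)
  s2 <- rowSums(dxhat * cache$xhat, dims = 1)
  dX <- (cache$istd / cache$n) * (cache$n * dxhat - s1 - cache$xhat * s2)
  list(dX = dX, dg = dg, db = db)
}

# Exact (erf-based) GELU: x * Phi(x).
gelu_fwd <- function(X) list(Y = X * pnorm(X), cache = X)
gelu_bwd <- function(dY, X) dY * (pnorm(X) + X * dnorm(X))

fc_fwd <- function(X, W, b) list(Y = W %*% X + b, cache = X)
fc_bwd <- function(dY, X, W) {
  list(dX = crossprod(W, dY), dW = dY %*% t(X), db = rowSums(dY))
}

softmax_cols <- function(L) {
  Z <- exp(sweep(L, 2, apply(L, 2, max)))
  sweep(Z, 2, colSums(Z), "/")
}
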