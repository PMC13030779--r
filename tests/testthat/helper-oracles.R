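# Independent oracles shared across test files.

# Box-constrained random-restart minimizer of ||X - WH||_F^2 (L-BFGS-B,
# lower bound 0): the reference optimum for small NMF instances.
restart_minimizer <- function(X, r, restarts = 30, seed = 1) {
  C <- nrow(X); J <- ncol(X)
  obj <- function(par) {
    W <- matrix(par[1:(C * r)], C, r)
    H <- matrix(par[-(1:(C * r))], r, J)
    sum((X - W %*% H)^2)
  }
  gr <- function(par) {
    W <- matrix(par[1:(C * r)], C, r)
    H <- matrix(par[-(1:(C * r))], r, J)
    E <- W %*% H - X
    c(2 * E %*% t(H), 2 * t(W) %*% E)
  }
  best <- Inf
  with_seed_local(seed, {
    for (i in seq_len(restarts)) {
      par0 <- runif(C * r + r * J, 0.05, 1)
      fit <- optim(par0, obj, gr, method = "L-BFGS-B", lower = 0,
                   control = list(maxit = 500))
      best <- min(best, fit$value)
    }
  })
  best
}

# Per-anchor double loop straight from the contrastive-loss definition.
naive_contrastive <- function(batch, include_positive = FALSE) {
  A <- ncol(batch$anchors)
  total <- 0
  for (a in seq_len(A)) {
    z <- batch$anchors[, a]
    psis <- vapply(seq_len(dim(batch$negatives)[2]),
                   function(j) similarity(z, batch$negatives[, j, a]), 0)
    if (include_positive)
      psis <- c(psis, similarity(z, batch$positives[, a]))
    total <- total - similarity(z, batch$positives[, a]) + log(sum(exp(psis)))
  }
  total / A
}
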