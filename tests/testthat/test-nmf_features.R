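test_that("exact low-rank inputs are recovered to small relative error", {
  errs <- vapply(1:20, function(s) {
    with_seed_local(s, {
      w <- abs(rnorm(9)) + 0.05
      h <- abs(rnorm(20)) + 0.05
      X <- w %o% h
      res <- nmf_factorize(X, r = 2, max_iter = 500, tol = 0, seed = s)
      sqrt(tail(res$err_trace, 1)) / sqrt(sum(X^2))
    })
  }, 0)
  expect_lt(median(errs), 1e-3)
})

test_that("the error trace never increases and stops at tolerance", {
  for (s in 1:40) {
    X <- random_segment(10, 20, seed = s)
    res <- nmf_factorize(X, seed = s)
    expect_true(all(diff(res$err_trace) <= 1e-10))
  }
  # tol = 0 runs to max_iter
  res <- nmf_factorize(random_segment(seed = 5), max_iter = 17, tol = 0)
  expect_identical(res$n_iter, 17L)
})

test_that("factors stay non-negative and column order follows H row energy", {
  res <- nmf_factorize(random_segment(15, 20, seed = 3), seed = 3)
  expect_true(all(res$W >= 0))
  expect_true(all(res$H >= 0))
  expect_gte(sqrt(sum(res$H[1, ]^2)), sqrt(sum(res$H[2, ]^2)))
})

test_that("degenerate and invalid segments are handled", {
  expect_warning(res <- nmf_factorize(matrix(0, 5, 20)), "all-zero")
  expect_true(all(res$W == 0) && all(res$H == 0))
  expect_identical(tail(res$err_trace, 1), 0)
  expect_error(nmf_factorize(matrix(c(-1, rep(1, 19)), 4, 5)),
               class = "nmfdecode_argument_error")
})

test_that("scaling the input scales the error trace quadratically", {
  X <- random_segment(6, 12, seed = 9)
  cs <- 3.7
  init <- with_seed_local(2, list(W = matrix(runif(12, 0.1, 1), 6, 2),
                                  H = matrix(runif(24, 0.1, 1), 2, 12)))
  init_sc <- list(W = sqrt(cs) * init$W, H = sqrt(cs) * init$H)
  r1 <- nmf_factorize(X, max_iter = 50, tol = 0, init = init)
  r2 <- nmf_factorize(cs * X, max_iter = 50, tol = 0, init = init_sc)
  expect_equal(r2$err_trace, cs^2 * r1$err_trace, tolerance = 1e-6)
})

test_that("multiplicative updates come within 5% of a restart minimizer", {
  for (s in 1:5) {
    X <- random_segment(3, 4, seed = 100 + s)
    res <- nmf_factorize(X, r = 2, max_iter = 1000, tol = 0, seed = s)
    best <- restart_minimizer(X, 2, restarts = 30, seed = s)
    expect_lte(tail(res$err_trace, 1), best * 1.05 + 1e-12)
  }
})

test_that("block features concatenate five spatial factors to 10 columns", {
  for (C in c(7L, 22L)) {
    segs <- lapply(1:5, function(i) random_segment(C, 20, seed = i))
    F <- extract_block_features(make_block(segs), nmf_config(seed = 1))
    expect_identical(dim(F), c(C, 10L))
    expect_identical(attr(F, "label"), "KG")
  }
  # identical segments yield five identical W sub-blocks under a fixed seed
  seg <- random_segment(9, 20, seed = 4)
  F <- extract_block_features(make_block(rep(list(seg), 5)),
                              nmf_config(seed = 11))
  for (k in 2:5)
    expect_identical(F[, (2 * k - 1):(2 * k)], F[, 1:2])
  # determinism across calls
  F2 <- extract_block_features(make_block(rep(list(seg), 5)),
                               nmf_config(seed = 11))
  expect_identical(F, F2)
})

test_that("nmf errors propagate with the segment index attached", {
  segs <- lapply(1:5, function(i) random_segment(4, 20, seed = i))
  segs[[3]][1, 1] <- -1
  expect_error(extract_block_features(make_block(segs)), "segment 3")
})

test_that("z-scoring standardizes training entries and round-trips", {
  fd <- toy_features(n_per_class = 10, C = 8, seed = 2)
  ns <- fit_normalizer(fd)
  z <- apply_normalizer(fd, ns)
  A <- array(unlist(z$features), c(8, 10, length(z$features)))
  expect_lt(max(abs(apply(A, c(1, 2), mean))), 1e-8)
  expect_lt(max(abs(apply(A, c(1, 2), var) - 1)), 1e-6)
  # held-out transform + inverse recovers the originals
  held <- toy_features(n_per_class = 4, C = 8, seed = 3)
  back <- invert_normalizer(apply_normalizer(held, ns), ns)
  expect_equal(back$features, held$features, tolerance = 1e-8)
})

test_that("constant feature entries standardize to zero via the std guard", {
  fd <- toy_features(n_per_class = 5, C = 8, seed = 4)
  fd$features <- lapply(fd$features, function(f) { f[2, 3] <- 42; f })
  expect_message(ns <- fit_normalizer(fd), "constant")
  z <- apply_normalizer(fd, ns)
  expect_true(all(vapply(z$features, function(f) f[2, 3] == 0, TRUE)))
  expect_error(fit_normalizer(structure(list(features = list(),
                                             labels = character()),
                                        class = "feature_dataset")),
               class = "nmfdecode_argument_error")
})
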