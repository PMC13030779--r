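test_that("shape trace reproduces the architecture contract on length-10 input", {
  tr <- shape_trace(encoder_config(60), 10)
  expect_equal(tr, list(c(32L, 10L), c(32L, 10L), c(64L, 5L), c(128L, 3L),
                        c(128L, 1L), 128L, 32L))
})

test_that("shape trace follows convolution arithmetic at boundaries", {
  cfg <- encoder_config(4, stage_channels = c(8, 16), stage_strides = c(2, 2),
                        blocks_per_stage = c(1, 1))
  tr <- shape_trace(cfg, 5)
  expect_identical(tr[[2]], c(8L, 3L))      # floor((5+2-3)/2)+1
  # length-1 input through a stride-2 stage: floor((1+2-3)/2)+1 = 1
  tr1 <- shape_trace(encoder_config(4), 1)
  expect_identical(tr1[[3]], c(64L, 1L))
  expect_error(shape_trace(encoder_config(4), 0),
               class = "nmfdecode_argument_error")
  expect_error(encoder_config(4, kernel = 4),
               class = "nmfdecode_argument_error")
})

test_that("shape trace matches shapes observed on real tensors", {
  ns <- asNamespace("nmfdecode")
  with_seed_local(21, {
    for (i in 1:5) {
      chans <- sort(sample(4:32, 3))
      L <- sample(6:16, 1)
      cfg <- encoder_config(sample(3:10, 1), stage_channels = chans,
                            stage_strides = c(1, 2, 2),
                            blocks_per_stage = sample(1:2, 3, replace = TRUE),
                            latent_dim = sample(c(8, 16, 32), 1),
                            input_length = L)
      tr <- shape_trace(cfg, L)
      m <- build_encoder(cfg, seed = i)
      X <- array(rnorm(cfg$in_channels * L * 3), c(cfg$in_channels, L, 3))
      fw <- ns$enc_forward(m, X, train = FALSE, keep_cache = TRUE)
      arch <- ns$encoder_arch(cfg)
      # last block of each stage carries that stage's output shape
      stage_last <- vapply(1:3, function(s)
        max(which(vapply(arch, function(b)
          as.integer(substr(b$name, 2, 2)), 0L) == s)), 0L)
      for (s in 1:3) {
        d <- dim(fw$cache[[arch[[stage_last[s]]]$name]]$pre)
        expect_identical(d[1:2], as.integer(tr[[s + 1]]))
      }
      expect_identical(nrow(fw$z), as.integer(tail(tr, 1)[[1]]))
    }
  })
})

test_that("building is deterministic in the seed", {
  cfg <- encoder_config(7)
  m1 <- build_encoder(cfg, seed = 5)
  m2 <- build_encoder(cfg, seed = 5)
  m3 <- build_encoder(cfg, seed = 6)
  cs <- nmfdecode:::param_checksum
  expect_identical(cs(m1), cs(m2))
  expect_false(isTRUE(all.equal(cs(m1), cs(m3))))
})

test_that("stride-1 blocks reduce to the skip path when the main branch is zeroed", {
  ns <- asNamespace("nmfdecode")
  cfg <- encoder_config(6)
  m <- build_encoder(cfg, seed = 2)
  m$params$s1_b1_conv2_W[] <- 0
  m$params$s1_b1_conv2_b[] <- 0
  m$params$s1_b1_bn2_b[] <- 0
  X <- array(rnorm(6 * 10 * 2), c(6, 10, 2))
  fw <- ns$enc_forward(m, X, train = FALSE, keep_cache = TRUE)
  stem_out <- fw$cache$stem$pre * pnorm(fw$cache$stem$pre)  # GELU(stem BN)
  # pre-activation of the block equals its input: the residual is dead
  expect_equal(fw$cache$s1_b1$pre, stem_out, tolerance = 1e-12)
})

test_that("classification produces a probability simplex and encode is deterministic", {
  cfg <- encoder_config(9, n_classes = 4)
  m <- build_encoder(cfg, seed = 3)
  F <- matrix(rnorm(90), 9, 10)
  p <- classify(m, F)
  expect_length(p, 4)
  expect_true(all(p >= 0))
  expect_equal(sum(p), 1, tolerance = 1e-6)
  batch <- with_seed_local(12, lapply(1:40, function(i)
    matrix(rnorm(90), 9, 10)))
  P <- classify(m, batch)
  expect_false(anyNA(P))
  expect_equal(rowSums(P), rep(1, 40), tolerance = 1e-6)
  # untrained: above chance-floor confidence but not degenerate one-hot
  expect_gt(mean(apply(P, 1, max)), 0.25 - 1e-9)
  expect_lt(mean(apply(P, 1, max)), 0.95)
  expect_identical(encode(m, F), encode(m, F))
  expect_error(encode(m, matrix(0, 9, 7)), class = "nmfdecode_argument_error")
  expect_error(encode(m, matrix(0, 5, 10)), class = "nmfdecode_argument_error")
})

test_that("checkpoints reload bit-stably", {
  cfg <- encoder_config(5, n_classes = 4)
  m <- build_encoder(cfg, seed = 8)
  m$classes <- c("KG", "PG", "WE", "WF")
  F <- matrix(rnorm(50), 5, 10)
  path <- file.path(withr::local_tempdir(), "enc.rds")
  save_encoder(m, path)
  m2 <- load_encoder(path)
  expect_identical(encode(m2, F), encode(m, F))
  expect_identical(classify(m2, F), classify(m, F))
})

test_that("analytic gradients match finite differences on a tiny model", {
  ns <- asNamespace("nmfdecode")
  cfg <- encoder_config(3, n_classes = 3, stage_channels = c(4, 5, 6),
                        input_length = 6)
  m <- build_encoder(cfg, seed = 5)
  with_seed_local(9, {
    X <- array(rnorm(3 * 6 * 4), c(3, 6, 4))
  })
  y <- c(1L, 2L, 3L, 1L)
  loss_of <- function(model) {
    buf <- model$buffers
    fw <- ns$enc_forward(model, X, train = TRUE, keep_cache = TRUE)
    model$buffers <- buf
    probs <- ns$softmax_cols(fw$logits)
    list(loss = mean(-log(probs[cbind(y, 1:4)])), fw = fw, probs = probs)
  }
  r <- loss_of(m)
  dl <- r$probs
  dl[cbind(y, 1:4)] <- dl[cbind(y, 1:4)] - 1
  dl <- dl / 4
  grads <- ns$enc_backward(m, r$fw$cache, dlogits = dl)
  eps <- 1e-6
  with_seed_local(31, {
    for (nm in c("stem_conv_W", "s1_b1_conv1_W", "s2_b1_proj_W",
                 "s2_b1_bn1_g", "s3_b1_conv2_W", "fc1_W", "fc2_b",
                 "head_W")) {
      for (k in sample(length(m$params[[nm]]), 3)) {
        mc <- new.env()
        mc$params <- m$params; mc$buffers <- m$buffers; mc$config <- m$config
        class(mc) <- "nmf_encoder"
        mc$params[[nm]][k] <- mc$params[[nm]][k] + eps
        lp <- loss_of(mc)$loss
        mc$params[[nm]][k] <- mc$params[[nm]][k] - 2 * eps
        lm <- loss_of(mc)$loss
        expect_equal(grads[[nm]][k], (lp - lm) / (2 * eps),
                     tolerance = 1e-4,
                     info = sprintf("%s[%d]", nm, k))
      }
    }
  })
})
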