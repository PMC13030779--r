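test_that("pair sampling respects class structure and the seed", {
  labels <- c("A", "A", "B", "B")
  p <- sample_pairs(labels, M = 2, seed = 3)
  expect_length(p$anchor, 4)
  for (i in seq_along(p$anchor)) {
    expect_identical(labels[p$positive[i]], labels[p$anchor[i]])
    expect_false(p$positive[i] == p$anchor[i])
    expect_true(all(labels[p$negatives[, i]] != labels[p$anchor[i]]))
  }
  expect_identical(sample_pairs(labels, M = 2, seed = 3), p)
  expect_warning(empty <- sample_pairs(rep("A", 4), M = 2, seed = 1),
                 "single class")
  expect_length(empty$anchor, 0)
  # a lone-member class is skipped but others are kept
  p2 <- suppressWarnings(sample_pairs(c("A", "B", "B"), M = 1, seed = 1))
  expect_false(1 %in% p2$anchor)
})

test_that("contrastive pre-training reduces the loss and organizes the space", {
  fd <- toy_features(n_per_class = 20, seed = 6)
  m <- build_encoder(encoder_config(8, 4), seed = 1)
  hist <- pretrain_contrastive(m, fd, train_config(pretrain_epochs = 6,
                                                   joint_epochs = 0,
                                                   batch_size = 32,
                                                   master_seed = 2))
  expect_identical(nrow(hist), 6L)
  expect_lt(hist$loss[6], hist$loss[1])
  # same-class embeddings end closer than different-class embeddings
  Z <- encode(m, fd)
  D <- as.matrix(dist(t(Z)))
  same <- outer(fd$labels, fd$labels, "==") & upper.tri(D)
  diff <- outer(fd$labels, fd$labels, "!=") & upper.tri(D)
  expect_lt(mean(D[same]), mean(D[diff]))
})

test_that("zero pre-training epochs leave parameters untouched", {
  fd <- toy_features(n_per_class = 4, seed = 2)
  m <- build_encoder(encoder_config(8, 4), seed = 9)
  before <- nmfdecode:::param_checksum(m)
  pretrain_contrastive(m, fd, train_config(pretrain_epochs = 0))
  expect_identical(nmfdecode:::param_checksum(m), before)
})

test_that("joint training fits separable data and is seed-reproducible", {
  fd <- toy_features(n_per_class = 25, seed = 3)
  run <- function() {
    m <- build_encoder(encoder_config(8, 4), seed = 4)
    h <- joint_train(m, fd, train_config(pretrain_epochs = 0,
                                         joint_epochs = 8, batch_size = 32,
                                         master_seed = 5))
    list(m = m, h = h)
  }
  r1 <- run()
  expect_gt(tail(r1$h$train_acc, 1), 0.9)
  held <- toy_features(n_per_class = 8, seed = 31)
  expect_gt(mean(predict_labels(r1$m, held) == held$labels), 0.9)
  r2 <- run()
  expect_identical(r1$h, r2$h)
  expect_identical(nmfdecode:::param_checksum(r1$m),
                   nmfdecode:::param_checksum(r2$m))
})

test_that("label-shuffled training stays at chance on held-out data", {
  fd <- toy_features(n_per_class = 25, seed = 8)
  with_seed_local(42, fd$labels <- sample(fd$labels))
  m <- build_encoder(encoder_config(8, 4), seed = 2)
  joint_train(m, fd, train_config(pretrain_epochs = 0, joint_epochs = 4,
                                  batch_size = 32, master_seed = 3))
  held <- toy_features(n_per_class = 25, seed = 77)
  acc <- mean(predict_labels(m, held) == held$labels)
  expect_gt(acc, 0.25 - 0.08)
  expect_lt(acc, 0.25 + 0.08)
})

test_that("head-only refinement freezes the encoder", {
  fd <- toy_features(n_per_class = 15, seed = 5)
  m <- build_encoder(encoder_config(8, 4), seed = 6)
  pretrain_contrastive(m, fd, train_config(pretrain_epochs = 3,
                                           batch_size = 32, master_seed = 1))
  enc_before <- m$params[nmfdecode:::encoder_param_names(m)]
  head_before <- m$params$head_W
  train_head_only(m, fd, train_config(joint_epochs = 5, batch_size = 32,
                                      master_seed = 1))
  expect_identical(m$params[nmfdecode:::encoder_param_names(m)], enc_before)
  expect_false(isTRUE(all.equal(m$params$head_W, head_before)))
})

test_that("training configuration is validated", {
  expect_error(train_config(lr = 0), class = "nmfdecode_argument_error")
  expect_error(train_config(M = 0), class = "nmfdecode_argument_error")
  expect_error(train_config(pretrain_epochs = -1),
               class = "nmfdecode_argument_error")
})
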