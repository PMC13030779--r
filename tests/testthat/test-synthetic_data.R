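test_that("generated recordings have the promised bookkeeping", {
  spec <- small_spec(seed = 2, trials_per_class = 3)
  rec <- generate_dataset(spec)
  expect_s3_class(rec, "raw_recording")
  expect_identical(nrow(rec$data), 13L)
  expect_identical(nrow(rec$annotations), 12L)
  expect_identical(as.integer(table(rec$annotations$label)), rep(3L, 4))
  expect_identical(ncol(rec$data),
                   as.integer(12 * (spec$trial_s + spec$rest_s) * spec$fs))
  expect_true(all(rec$annotations$duration == spec$trial_s * spec$fs))
})

test_that("generation is bit-identical for a fixed seed", {
  r1 <- generate_dataset(small_spec(seed = 9, trials_per_class = 2))
  r2 <- generate_dataset(small_spec(seed = 9, trials_per_class = 2))
  expect_identical(r1$data, r2$data)
  expect_identical(r1$annotations, r2$annotations)
  r3 <- generate_dataset(small_spec(seed = 10, trials_per_class = 2))
  expect_false(identical(r1$data, r3$data))
})

test_that("zero snr removes all class information from channel power", {
  rec <- generate_dataset(small_spec(seed = 5, snr = 0,
                                     trials_per_class = 20))
  ts <- epoch_trials(rec)
  power <- vapply(ts$trials, function(m) mean(m^2), 0)
  fit <- aov(power ~ factor(ts$labels))
  p <- summary(fit)[[1]]$`Pr(>F)`[1]
  expect_gt(p, 0.05)
})

test_that("class topographies are recoverable from the NMF features", {
  spec <- small_spec(seed = 3, snr = 8, trials_per_class = 4)
  rec <- generate_dataset(spec)
  ts <- epoch_trials(bandpass_filter(rec))
  blocks <- blocks_from_trials(ts)
  fd <- extract_features(blocks, nmf_config(seed = 1))
  loadings <- nmfdecode:::class_loadings(spec)
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  # best-matching W column against each class's first loading vector,
  # averaged over that class's blocks
  sim <- matrix(0, 4, 4)  # true class x loading class
  for (k in seq_along(spec$classes)) {
    idx <- which(fd$labels == spec$classes[k])
    for (l in seq_along(spec$classes)) {
      a <- loadings[[l]][, 1]
      sim[k, l] <- mean(vapply(fd$features[idx], function(F)
        max(apply(F, 2, cosine, a = a)), 0))
    }
  }
  for (k in 1:4)
    expect_identical(which.max(sim[k, ]), as.integer(k))
})

test_that("channel perturbations follow their contracts", {
  rec <- generate_dataset(small_spec(seed = 4, trials_per_class = 2))
  expect_identical(perturb_channels(rec, "drop", 0), rec)
  dropped <- perturb_channels(rec, "drop", 3, seed = 1)
  expect_identical(sum(rowSums(abs(dropped$data)) == 0), 3L)
  shifted <- perturb_channels(rec, "shift", 4, seed = 2)
  changed <- vapply(seq_len(13), function(i)
    !identical(shifted$data[i, ], rec$data[i, ]), TRUE)
  expect_identical(sum(changed), 8L)
  expect_identical(shifted$annotations, rec$annotations)
  expect_error(perturb_channels(rec, "drop", 14),
               class = "nmfdecode_argument_error")
  expect_error(perturb_channels(rec, "shift", 7),
               class = "nmfdecode_argument_error")
})

test_that("decoding degrades as channels are dropped", {
  cfg <- default_config(seed = 21)
  cfg$synth <- utils::modifyList(cfg$synth, list(
    n_channels = 13, channels = get_channel_set("set5")$labels,
    trials_per_class = 6, trial_s = 1, rest_s = 0.25, snr = 6))
  cfg$montage$set <- "set5"
  cfg$preprocess$n_train <- 4
  cfg$preprocess$n_test <- 2
  cfg$training <- utils::modifyList(cfg$training, list(
    pretrain_epochs = 2, joint_epochs = 4, batch_size = 32))
  accs <- vapply(c(0L, 10L), function(mag) {
    mean(vapply(1:3, function(s) {
      c2 <- cfg; c2$seed <- cfg$seed + s
      rec <- generate_dataset(synthetic_spec(
        n_channels = 13, channels = get_channel_set("set5")$labels,
        trials_per_class = 6, trial_s = 1, rest_s = 0.25, snr = 6,
        seed = c2$seed))
      rec <- perturb_channels(rec, "drop", mag, seed = c2$seed)
      run_pipeline(c2, rec = rec)$metrics$accuracy
    }, 0))
  }, 0)
  expect_gte(accs[1], accs[2])
})

test_that("invalid focus electrodes and snr are rejected", {
  expect_error(small_spec(pattern_focus = c("C1", "QQ7")),
               class = "nmfdecode_argument_error")
  expect_error(small_spec(snr = -1), class = "nmfdecode_argument_error")
})
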