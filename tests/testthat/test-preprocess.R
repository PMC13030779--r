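sine_recording <- function(freqs, fs = 1000, secs = 2) {
  t <- seq_len(fs * secs) / fs
  data <- do.call(rbind, lapply(freqs, function(f) sin(2 * pi * f * t)))
  raw_recording(data, fs, get_channel_set("set6")$labels[seq_along(freqs)])
}

test_that("band-pass response passes 10 Hz and rejects 50 Hz as designed", {
  rec <- sine_recording(c(10, 50))
  out <- bandpass_filter(rec, 1, 40, 4)
  # discard filter edges before measuring amplitude
  core <- 501:1500
  gain <- function(ch) sqrt(mean(out$data[ch, core]^2) /
                              mean(rec$data[ch, core]^2))
  expect_lt(abs(gain(1) - 1), 0.05)
  # frequency-response oracle: forward-backward filtering applies the
  # squared magnitude of the designed Butterworth response
  bf <- signal::butter(4, c(1, 40) / 500, type = "pass")
  w <- 2 * pi * 50 / 1000
  ew <- exp(-1i * w * (seq_along(bf$b) - 1))
  H50 <- Mod(sum(bf$b * ew) / sum(bf$a * ew))^2
  att_db <- 20 * log10(gain(2))
  expect_equal(att_db, 20 * log10(H50), tolerance = 0.05)
  expect_lt(att_db, -12)
  expect_identical(dim(out$data), dim(rec$data))
})

test_that("band-pass is linear at zero and validates its band", {
  rec <- raw_recording(matrix(0, 3, 500), 1000, c("C1", "C2", "C3"))
  out <- bandpass_filter(rec)
  expect_true(all(out$data == 0))
  expect_error(bandpass_filter(rec, 1, 600),
               class = "nmfdecode_argument_error")
  expect_error(bandpass_filter(rec, 0, 40),
               class = "nmfdecode_argument_error")
})

make_trialset <- function(n_per_class, classes = c("KG", "PG", "WE", "WF"),
                          C = 3, T = 400, fs = 1000) {
  labels <- rep(classes, each = n_per_class)
  structure(list(trials = lapply(seq_along(labels),
                                 function(i) matrix(i, C, T)),
                 labels = labels, fs = fs,
                 channel_labels = c("C1", "C2", "C3")),
            class = "trial_set")
}

test_that("splitting is balanced, disjoint and seed-reproducible", {
  ts <- make_trialset(20)
  sp <- split_trials(ts, 16, 4, seed = 7)
  expect_length(sp$train$trials, 64)
  expect_length(sp$test$trials, 16)
  expect_identical(as.integer(table(sp$train$labels)), rep(16L, 4))
  expect_identical(as.integer(table(sp$test$labels)), rep(4L, 4))
  # disjoint: trial matrices are constant = original index
  tr_ids <- vapply(sp$train$trials, function(m) m[1, 1], 0)
  te_ids <- vapply(sp$test$trials, function(m) m[1, 1], 0)
  expect_length(intersect(tr_ids, te_ids), 0)
  sp2 <- split_trials(ts, 16, 4, seed = 7)
  expect_identical(vapply(sp2$test$trials, function(m) m[1, 1], 0), te_ids)
  expect_error(split_trials(make_trialset(10), 16, 4, seed = 1),
               class = "nmfdecode_argument_error")
})

test_that("block cutting yields the sliding-window count and geometry", {
  trial <- matrix(rnorm(2 * 5000), 2, 5000)
  blocks <- make_blocks(trial, "KG", 1000)
  expect_length(blocks, 99)   # floor((5000 - 100)/50) + 1
  expect_identical(vapply(blocks, function(b) b$t0, 0), seq(0, 4900, by = 50))
  b1 <- blocks[[1]]
  expect_length(b1$segments, 5)
  expect_true(all(vapply(b1$segments, ncol, 0L) == 20))
  expect_true(all(vapply(b1$segments, function(s) all(s >= 0), TRUE)))
  expect_identical(b1$label, "KG")
  # boundary: exactly one block
  one <- make_blocks(trial[, 1:100, drop = FALSE], "PG", 1000)
  expect_length(one, 1)
  # short trial: empty with a warning
  expect_warning(none <- make_blocks(trial[, 1:80, drop = FALSE], "PG", 1000),
                 "shorter")
  expect_length(none, 0)
})

test_that("block count matches a brute-force window enumerator", {
  brute_count <- function(T, blk, hop) {
    n <- 0; t0 <- 0
    while (t0 + blk <= T) { n <- n + 1; t0 <- t0 + hop }
    n
  }
  with_seed_local(11, {
    for (i in 1:25) {
      T <- sample(100:3000, 1)
      trial <- matrix(1, 1, T)
      expect_length(make_blocks(trial, "x", 1000), brute_count(T, 100, 50))
    }
  })
})

test_that("segments tile the block and carry absolute values", {
  trial <- matrix(seq(-300, 299), 3, 200)
  blocks <- make_blocks(trial, "WE", 1000)
  for (b in blocks) {
    span <- (b$t0 + 1):(b$t0 + 100)
    expect_identical(do.call(cbind, b$segments), abs(trial[, span]))
  }
  # explicit sign flip example
  trial2 <- matrix(-3, 1, 100)
  expect_true(all(make_blocks(trial2, "x", 1000)[[1]]$segments[[1]] == 3))
})

test_that("non-kilohertz sampling rates scale the segment width", {
  trial <- matrix(rnorm(2 * 250), 2, 250)
  blocks <- make_blocks(trial, "KG", 500)  # 20 ms -> 10 samples
  expect_true(all(vapply(blocks[[1]]$segments, ncol, 0L) == 10))
  expect_length(blocks, (250 - 50) %/% 25 + 1)
})

test_that("epoching recovers annotated trials", {
  labs <- c("C1", "C2")
  data <- matrix(rnorm(2 * 1000), 2, 1000)
  ann <- data.frame(onset = c(100, 600), duration = c(200, 200),
                    label = c("KG", "WF"))
  ts <- epoch_trials(raw_recording(data, 1000, labs, ann))
  expect_length(ts$trials, 2)
  expect_identical(ts$trials[[1]], data[, 101:300])
  expect_identical(ts$labels, c("KG", "WF"))
})
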