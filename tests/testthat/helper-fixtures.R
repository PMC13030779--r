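# Shared in-code fixtures.

# Small synthetic spec: 13 central/centro-parietal electrodes, short trials.
# Keeps unit tests fast; the full default spec is exercised by the
# parameter-recovery acceptance test.
small_spec <- function(seed = 1, snr = 6, trials_per_class = 6,
                       trial_s = 1, rest_s = 0.25, ...) {
  labs <- get_channel_set("set5")$labels
  synthetic_spec(n_channels = length(labs), channels = labs,
                 trials_per_class = trials_per_class, trial_s = trial_s,
                 rest_s = rest_s, snr = snr, seed = seed, ...)
}

# Gaussian class-template features: class k boosts row 2k-1. Linearly
# separable, so optimization sanity checks converge quickly.
toy_features <- function(n_per_class = 25, C = 8, L = 10, sep = 2,
                         classes = c("KG", "PG", "WE", "WF"), seed = 1) {
  stopifnot(C >= 2 * length(classes) - 1)
  feats <- list(); labels <- character()
  with_seed_local(seed, {
    for (k in seq_along(classes)) {
      for (i in seq_len(n_per_class)) {
        f <- matrix(rnorm(C * L, 0, 0.5), C, L)
        f[2 * k - 1, ] <- f[2 * k - 1, ] + sep
        feats[[length(feats) + 1L]] <- f
        labels <- c(labels, classes[k])
      }
    }
  })
  structure(list(features = feats, labels = labels,
                 trial = rep(seq_along(classes), each = n_per_class),
                 t0 = rep(0, length(labels))),
            class = "feature_dataset")
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

random_segment <- function(C = 12, J = 20, seed = 1) {
  with_seed_local(seed, matrix(abs(rnorm(C * J)), C, J))
}

make_block <- function(segments, label = "KG", t0 = 0, id = 1L) {
  structure(list(segments = segments, label = label, t0 = t0, id = id,
                 trial = 1L),
            class = "segment_block")
}

# Brute-force metrics from first principles, used as the independent oracle
# for kappa and macro-F1.
brute_metrics <- function(truth, pred, classes) {
  n <- length(truth)
  acc <- sum(truth == pred) / n
  f1 <- numeric(length(classes))
  for (i in seq_along(classes)) {
    cl <- classes[i]
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    f1[i] <- if (tp == 0) 0 else {
      p <- tp / (tp + fp); r <- tp / (tp + fn)
      2 * p * r / (p + r)
    }
  }
  pe <- 0
  for (cl in classes) pe <- pe + (sum(truth == cl) / n) * (sum(pred == cl) / n)
  kappa <- if (abs(1 - pe) < 1e-12) {
    if (acc >= 1 - 1e-12) 1 else 0
  } else (acc - pe) / (1 - pe)
  list(accuracy = acc, macro_f1 = mean(f1), kappa = kappa)
}
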