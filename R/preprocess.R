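# Band-pass filtering, epoching, train/test splitting, and cutting 100 ms
# decoding blocks of five 20 ms non-negative segments.

#' Band-pass filter a recording
#'
#' Fourth-order Butterworth band-pass (1-40 Hz by default), applied to each
#' channel independently. The default is zero-phase (forward-backward), which
#' doubles the effective order and removes group delay; `zero_phase = FALSE`
#' gives the causal single pass a streaming decoder would use.
#'
#' @param rec a [raw_recording()].
#' @param low,high band edges in Hz; must satisfy `0 < low < high < fs/2`.
#' @param order Butterworth design order.
#' @param zero_phase forward-backward filtering if `TRUE` (default).
#' @return a filtered `raw_recording` of identical shape.
#' @export
bandpass_filter <- function(rec, low = 1, high = 40, order = 4,
                            zero_phase = TRUE) {
  stopifnot(inherits(rec, "raw_recording"))
  nyq <- rec$fs / 2
  if (!is_scalar_number(low) || !is_scalar_number(high) ||
      low <= 0 || high <= low || high >= nyq)
    abort_argument(sprintf("band [%g, %g] Hz outside (0, Nyquist=%g)",
                           low, high, nyq))
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  run <- if (zero_phase) {
    function(x) signal::filtfilt(bf, x)
  } else {
    function(x) as.numeric(signal::filter(bf, x))
  }
  out <- t(apply(rec$data, 1, run))
  raw_recording(out, rec$fs, rec$channel_labels, rec$annotations)
}

#' Cut a recording into labelled trials
#'
#' Extracts one channels x samples matrix per annotation (half-open sample
#' intervals, 0-based onsets).
#'
#' @param rec a [raw_recording()] with annotations.
#' @return a `trial_set`: list with `trials` (list of matrices), `labels`,
#'   `fs`, `channel_labels`.
#' @export
epoch_trials <- function(rec) {
  stopifnot(inherits(rec, "raw_recording"))
  ann <- rec$annotations
  if (!nrow(ann)) abort_argument("recording has no annotations to epoch")
  if (any(ann$onset + ann$duration > ncol(rec$data)))
    abort_format("annotation extends past the end of the recording")
  trials <- lapply(seq_len(nrow(ann)), function(i) {
    idx <- (ann$onset[i] + 1):(ann$onset[i] + ann$duration[i])
    rec$data[, idx, drop = FALSE]
  })
  structure(list(trials = trials, labels = ann$label, fs = rec$fs,
                 channel_labels = rec$channel_labels),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set: %d trials (%s), %d channels @ %g Hz>\n",
              length(x$trials),
              paste(sprintf("%s:%d", names(table(x$labels)), table(x$labels)),
                    collapse = " "),
              length(x$channel_labels), x$fs))
  invisible(x)
}

#' Class-balanced train/test split of trials
#'
#' Randomly assigns `n_train` trials per class to the training set and
#' `n_test` to the test set (the subject-wise 16/4 protocol by default),
#' reproducibly for a given seed.
#'
#' @param ts a `trial_set` from [epoch_trials()].
#' @param n_train,n_test trials per class in each partition.
#' @param seed integer RNG seed for the assignment.
#' @return list with `train` and `test` trial sets.
#' @export
split_trials <- function(ts, n_train = 16, n_test = 4, seed = 1) {
  stopifnot(inherits(ts, "trial_set"))
  counts <- table(ts$labels)
  if (any(counts < n_train + n_test))
    abort_argument(sprintf(
      "need %d trials per class; got min %d", n_train + n_test, min(counts)))
  take <- function(ts, idx) {
    structure(list(trials = ts$trials[idx], labels = ts$labels[idx],
                   fs = ts$fs, channel_labels = ts$channel_labels),
              class = "trial_set")
  }
  with_seed(seed, {
    tr_idx <- integer(); te_idx <- integer()
    for (cl in names(counts)) {
      pool <- which(ts$labels == cl)
      picked <- sample(pool, n_train + n_test)
      tr_idx <- c(tr_idx, picked[seq_len(n_train)])
      te_idx <- c(te_idx, picked[n_train + seq_len(n_test)])
    }
    list(train = take(ts, sort(tr_idx)), test = take(ts, sort(te_idx)))
  })
}

#' Cut one trial into sliding decoding blocks
#'
#' Slides a `block_ms` window (default 100 ms) with a `hop_ms` hop (default
#' 50 ms, i.e. 50% block overlap) over a trial and splits each window into
#' contiguous non-overlapping `segment_ms` segments (default 20 ms, so five
#' per block). Entrywise absolute value enforces the non-negativity the
#' factorization requires. Each block inherits the trial label.
#'
#' @param trial channels x samples numeric matrix.
#' @param label class label attached to every block.
#' @param fs sampling rate in Hz.
#' @param block_ms,hop_ms,segment_ms window geometry in milliseconds;
#'   `block_ms` must be an integer multiple of `segment_ms`.
#' @return list of `segment_block` objects (possibly empty, with a warning,
#'   if the trial is shorter than one block). Each has `segments` (list of
#'   C x w non-negative matrices), `label`, `t0` (0-based onset sample).
#' @export
make_blocks <- function(trial, label, fs, block_ms = 100, hop_ms = 50,
                        segment_ms = 20) {
  if (!is.matrix(trial) || !is.numeric(trial))
    abort_argument("trial must be a numeric channels x samples matrix")
  blk <- round(block_ms * fs / 1000)
  hop <- round(hop_ms * fs / 1000)
  seg <- round(segment_ms * fs / 1000)
  if (seg < 1 || hop < 1 || blk < 1)
    abort_argument("window parameters collapse to zero samples at this fs")
  if (blk %% seg != 0)
    abort_argument("block_ms must be an integer multiple of segment_ms")
  n_seg <- blk %/% seg
  T <- ncol(trial)
  if (T < blk) {
    warning(sprintf("trial of %d samples shorter than one %d-sample block",
                    T, blk), call. = FALSE)
    return(list())
  }
  n_blocks <- (T - blk) %/% hop + 1L
  a <- abs(trial)
  lapply(seq_len(n_blocks), function(b) {
    t0 <- (b - 1L) * hop
    segments <- lapply(seq_len(n_seg), function(s) {
      a[, (t0 + (s - 1L) * seg + 1L):(t0 + s * seg), drop = FALSE]
    })
    structure(list(segments = segments, label = label, t0 = t0),
              class = "segment_block")
  })
}

#' Blocks for a whole trial set
#'
#' Applies [make_blocks()] to every trial, tagging each block with its trial
#' index (used later for per-trial majority voting and per-segment seeding).
#'
#' @inheritParams make_blocks
#' @param ts a `trial_set`.
#' @return flat list of `segment_block`s with `$trial` and `$id` fields.
#' @export
blocks_from_trials <- function(ts, block_ms = 100, hop_ms = 50,
                               segment_ms = 20) {
  stopifnot(inherits(ts, "trial_set"))
  out <- list()
  id <- 0L
  for (i in seq_along(ts$trials)) {
    bl <- make_blocks(ts$trials[[i]], ts$labels[i], ts$fs,
                      block_ms, hop_ms, segment_ms)
    for (b in bl) {
      id <- id + 1L
      b$trial <- i
      b$id <- id
      out[[id]] <- b
    }
  }
  out
}
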