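# Synthetic 4-class motor-EEG surrogate generator.
#
# Each active trial is a sum of two class-specific sources: a fixed
# non-negative spatial loading vector (a focal topography over the central
# and centro-parietal rows) times an amplitude-modulated band-limited
# oscillation in the 8-30 Hz sensorimotor range. Background activity is
# 1/f-shaped noise, spatially correlated across neighbouring electrodes, and
# scaled so that the signal-to-noise power ratio over the active windows
# equals the requested snr. Trials alternate with noise-only rest gaps.

#' Specification of a synthetic motor-EEG dataset
#'
#' @param n_channels number of electrodes (60 = the full montage).
#' @param fs sampling rate (Hz).
#' @param classes movement class names.
#' @param trials_per_class trials generated per class.
#' @param trial_s active-trial duration (seconds).
#' @param rest_s rest gap between trials (seconds).
#' @param snr linear signal-to-noise power ratio over active windows; 0
#'   means no class signal at all (pure noise).
#' @param pattern_focus electrode labels carrying the class topographies;
#'   default the C and CP rows.
#' @param channels electrode labels to simulate; defaults to the full
#'   60-channel montage (required when `n_channels != 60`).
#' @param erd if `TRUE`, class sources suppress (rather than add) rhythmic
#'   power: a class-independent baseline rhythm is generated on the focus
#'   electrodes and attenuated by the class topography during trials,
#'   mimicking event-related desynchronization.
#' @param drift amplitude of a slow multiplicative drift (0 disables).
#' @param shift number of electrode pairs swapped with a montage neighbour
#'   after generation (0 disables).
#' @param seed master RNG seed; everything downstream is deterministic in it.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_channels = 60, fs = 1000,
                           classes = c("KG", "PG", "WE", "WF"),
                           trials_per_class = 20, trial_s = 5, rest_s = 5,
                           snr = 4, pattern_focus = NULL, channels = NULL,
                           erd = FALSE, drift = 0, shift = 0, seed = 1) {
  if (is.null(channels)) {
    if (n_channels != 60)
      abort_argument("supply `channels` explicitly when n_channels != 60")
    channels <- montage_labels()
  }
  if (length(channels) != n_channels)
    abort_argument("length(channels) must equal n_channels")
  pattern_focus <- pattern_focus %||%
    intersect(get_channel_set("set5")$labels, channels)
  if (!all(pattern_focus %in% channels))
    abort_argument(sprintf("pattern_focus labels absent from montage: %s",
                           paste(setdiff(pattern_focus, channels),
                                 collapse = ", ")))
  if (!is_scalar_number(snr) || snr < 0) abort_argument("snr must be >= 0")
  structure(list(n_channels = as.integer(n_channels), fs = fs,
                 classes = classes,
                 trials_per_class = as.integer(trials_per_class),
                 trial_s = trial_s, rest_s = rest_s, snr = snr,
                 pattern_focus = pattern_focus, channels = channels,
                 erd = isTRUE(erd), drift = drift, shift = as.integer(shift),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Two fixed non-negative spatial loading vectors per class, each a focal bump
# centred on a class-specific electrode of the focus region with small
# spillover to row neighbours and the homologous electrode of the other row.
class_loadings <- function(spec) {
  focus <- spec$pattern_focus
  # distinct centre electrodes per class, falling back to spread positions
  # when the canonical sites are not simulated
  canonical <- list(KG = c("C5", "CP3"), PG = c("C6", "CP4"),
                    WE = c("C1", "CP5"), WF = c("C2", "CP6"))
  used <- character()
  centers <- lapply(seq_along(spec$classes), function(k) {
    cl <- spec$classes[k]
    cand <- canonical[[cl]] %||% character()
    cand <- cand[cand %in% focus]
    while (length(cand) < 2) {
      free <- setdiff(focus, c(used, cand))
      pick <- free[((k - 1) * 2 + length(cand)) %% length(free) + 1]
      cand <- c(cand, pick)
    }
    used <<- c(used, cand)
    cand
  })
  lapply(centers, function(ctr) {
    vapply(ctr, function(cen) {
      a <- numeric(length(spec$channels))
      names(a) <- spec$channels
      a[focus] <- 0.05
      i <- match(cen, focus)
      a[cen] <- 1
      row_mates <- focus[abs(seq_along(focus) - i) == 1]
      a[row_mates] <- pmax(a[row_mates], 0.4)
      homolog <- sub("^C(?=[0-9z])", "CP", cen, perl = TRUE)
      if (homolog == cen) homolog <- sub("^CP", "C", cen)
      if (homolog %in% focus) a[homolog] <- pmax(a[homolog], 0.3)
      unname(a)
    }, numeric(length(spec$channels)))
  })
}

# Carrier frequencies (Hz) for the two sources of each class, all in 8-30 Hz.
class_freqs <- function(n_classes) {
  base <- list(c(10, 22), c(12, 25), c(9, 18), c(14, 28))
  lapply(seq_len(n_classes), function(k) base[[(k - 1) %% 4 + 1]])
}

# 1/f-amplitude noise, spatially correlated by mixing neighbouring channels.
pink_noise <- function(n_ch, n_samp, fs) {
  freqs <- c(1, seq_len(n_samp - 1)) * fs / n_samp
  shape <- 1 / sqrt(pmax(freqs, 1))
  out <- matrix(0, n_ch, n_samp)
  for (ch in seq_len(n_ch)) {
    spec <- fft(rnorm(n_samp)) * shape
    out[ch, ] <- Re(fft(spec, inverse = TRUE)) / n_samp
  }
  # mix across the channel ordering (montage neighbours share noise)
  kernel <- c(0.15, 0.25, 0.6, 0.25, 0.15)
  K <- matrix(0, n_ch, n_ch)
  for (i in seq_len(n_ch)) {
    js <- (i - 2):(i + 2)
    ok <- js >= 1 & js <= n_ch
    K[i, js[ok]] <- kernel[ok] / sum(kernel[ok])
  }
  K %*% out
}

#' Generate a synthetic labelled motor-EEG recording
#'
#' Deterministic in `spec$seed` (bit-identical across calls). Trials are laid
#' out as active/rest alternations; annotations mark the active windows with
#' their class labels in a seeded random order.
#'
#' @param spec a [synthetic_spec()].
#' @return a [raw_recording()] with `trials_per_class * length(classes)`
#'   annotations.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  fs <- spec$fs
  n_cl <- length(spec$classes)
  n_trials <- n_cl * spec$trials_per_class
  trial_n <- round(spec$trial_s * fs)
  rest_n <- round(spec$rest_s * fs)
  total <- n_trials * (trial_n + rest_n)
  loadings <- class_loadings(spec)
  freqs <- class_freqs(n_cl)
  with_seed(spec$seed, {
    order_cl <- sample(rep(seq_len(n_cl), spec$trials_per_class))
    noise <- pink_noise(spec$n_channels, total, fs)
    signal <- matrix(0, spec$n_channels, total)
    onsets <- (seq_len(n_trials) - 1L) * (trial_n + rest_n)
    tt <- seq_len(trial_n) / fs
    for (i in seq_len(n_trials)) {
      k <- order_cl[i]
      cols <- onsets[i] + seq_len(trial_n)
      tri <- matrix(0, spec$n_channels, trial_n)
      for (comp in 1:2) {
        f <- freqs[[k]][comp]
        fe <- runif(1, 0.3, 1.2)
        env <- 0.6 + 0.4 * sin(2 * pi * fe * tt + runif(1, 0, 2 * pi))
        carrier <- sin(2 * pi * f * tt + runif(1, 0, 2 * pi))
        tri <- tri + loadings[[k]][, comp] %o% (env * carrier)
      }
      signal[, cols] <- tri
    }
    active <- as.vector(vapply(seq_len(n_trials),
                               function(i) onsets[i] + seq_len(trial_n),
                               numeric(trial_n)))
    if (spec$snr > 0) {
      p_sig <- mean(signal[, active]^2)
      p_noi <- mean(noise[, active]^2)
      noise <- noise * sqrt(p_sig / (spec$snr * p_noi))
    } else {
      signal[] <- 0
    }
    if (spec$erd && spec$snr > 0) {
      # rhythmic baseline on the focus electrodes, attenuated where (and
      # when) the class topography is active: power decrease instead of
      # power increase
      fmask <- as.numeric(spec$channels %in% spec$pattern_focus)
      base_rhythm <- fmask %o%
        sin(2 * pi * 11 * seq_len(total) / fs + runif(1, 0, 2 * pi))
      base_rhythm <- base_rhythm * sqrt(mean(signal[, active]^2) /
                                          max(mean(base_rhythm^2), 1e-12))
      atten <- matrix(0, spec$n_channels, total)
      for (i in seq_len(n_trials)) {
        k <- order_cl[i]
        cols <- onsets[i] + seq_len(trial_n)
        prof <- pmin(rowSums(loadings[[k]]), 1)
        atten[, cols] <- prof
      }
      data <- base_rhythm * (1 - 0.9 * atten) + noise
    } else {
      data <- 10 * signal + if (spec$snr > 0) 10 * noise else noise
    }
    if (spec$drift > 0) {
      ph <- runif(spec$n_channels, 0, 2 * pi)
      tall <- seq_len(total) / fs
      for (ch in seq_len(spec$n_channels))
        data[ch, ] <- data[ch, ] *
          (1 + spec$drift * sin(2 * pi * 0.02 * tall + ph[ch]))
    }
    ann <- data.frame(onset = onsets, duration = trial_n,
                      label = spec$classes[order_cl],
                      stringsAsFactors = FALSE)
    rec <- raw_recording(data, fs, spec$channels, ann,
                         task_set = spec$classes)
    if (spec$shift > 0)
      rec <- perturb_channels(rec, "shift", spec$shift,
                              seed = derive_seed(spec$seed, 999L))
    rec
  })
}

#' Perturb a recording's channels
#'
#' Robustness scenarios: `"drop"` zeroes out `magnitude` randomly chosen
#' channels (electrode loss); `"shift"` swaps `magnitude` randomly chosen
#' channels with their montage neighbour (electrode displacement), changing
#' exactly `2 * magnitude` rows. Annotations are untouched.
#'
#' @param rec a [raw_recording()].
#' @param mode `"drop"` or `"shift"`.
#' @param magnitude number of channels (drop) or swap pairs (shift).
#' @param seed RNG seed for the channel choice.
#' @return the perturbed `raw_recording`.
#' @export
perturb_channels <- function(rec, mode = c("drop", "shift"), magnitude,
                             seed = 1) {
  stopifnot(inherits(rec, "raw_recording"))
  mode <- match.arg(mode)
  n_ch <- nrow(rec$data)
  if (!is_scalar_number(magnitude) || magnitude < 0)
    abort_argument("magnitude must be a non-negative count")
  magnitude <- as.integer(magnitude)
  if (magnitude == 0) return(rec)
  if (mode == "drop") {
    if (magnitude > n_ch)
      abort_argument("cannot drop more channels than the recording has")
    with_seed(seed, {
      sel <- sample.int(n_ch, magnitude)
      rec$data[sel, ] <- 0
    })
  } else {
    if (2L * magnitude > n_ch)
      abort_argument("too many swap pairs for the channel count")
    with_seed(seed, {
      avail <- seq_len(n_ch)
      for (s in seq_len(magnitude)) {
        i <- if (length(avail) == 1L) avail else sample(avail, 1)
        j <- if (i < n_ch && (i + 1L) %in% avail) i + 1L else i - 1L
        if (!(j %in% avail)) {
          cand <- avail[abs(avail - i) == min(abs(setdiff(avail, i) - i))]
          j <- cand[1]
        }
        tmp <- rec$data[i, ]
        rec$data[i, ] <- rec$data[j, ]
        rec$data[j, ] <- tmp
        avail <- setdiff(avail, c(i, j))
      }
    })
  }
  rec
}
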