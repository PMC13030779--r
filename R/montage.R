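# 10-10 montage model and the six nested channel-reduction sets.
#
# The cap is organised in left-to-right, front-to-back order: within a row,
# odd (left) electrodes come first in descending number, then the midline "z"
# site, then even (right) electrodes in ascending number. CPz is the recording
# reference and AFz the ground, so neither carries data.

row_order <- function(prefix, odd, z = TRUE, even = odd + 1) {
  c(paste0(prefix, rev(seq(1, odd, by = 2))),
    if (z) paste0(prefix, "z"),
    paste0(prefix, seq(2, even, by = 2)))
}

# Rows used by the reduction sets (the unique memberships consistent with the
# printed set sizes 36/29/22/13/7; CPz excluded as the reference electrode).
.montage_rows <- list(
  F  = row_order("F", 5),                       # F5 F3 F1 Fz F2 F4 F6
  FC = row_order("FC", 5),                      # FC5 ... FCz ... FC6
  C  = row_order("C", 5),                       # C5 C3 C1 Cz C2 C4 C6
  CP = c("CP5", "CP3", "CP1", "CP2", "CP4", "CP6"),
  P  = row_order("P", 7)                        # P7 P5 P3 P1 Pz P2 P4 P6 P8
)

# Default identity of the 24 channels that complete the 60-channel full cap
# beyond the F/FC/C/CP/P rows. The full montage records 60 EEG channels after
# excluding the reference; the exact outlying membership is configurable via
# options(nmfdecode.set1_extra = <character(24)>).
.set1_extra_default <- c(
  "Fp1", "Fp2",
  "AF7", "AF3", "AF4", "AF8",
  "F7", "F8", "FT7", "FT8", "T7", "T8",
  "TP9", "TP7", "TP8", "TP10",
  "PO7", "PO3", "POz", "PO4", "PO8",
  "O1", "Oz", "O2"
)

#' Full 10-10 electrode vocabulary used by the package
#'
#' Returns the ordered labels of the 60-channel recording montage: the
#' frontal through parietal rows used by the channel-reduction sets plus the
#' outlying prefrontal, temporal, parieto-occipital and occipital sites.
#'
#' @param set1_extra optional character vector of the 24 outlying labels; by
#'   default taken from `options(nmfdecode.set1_extra)` or the built-in list.
#' @return character vector of 60 electrode labels, front-to-back,
#'   left-to-right.
#' @export
montage_labels <- function(set1_extra = NULL) {
  extra <- set1_extra %||% getOption("nmfdecode.set1_extra", .set1_extra_default)
  if (length(extra) != 24L || anyDuplicated(extra))
    abort_argument("set1_extra must be 24 unique electrode labels")
  core <- unlist(.montage_rows, use.names = FALSE)
  if (any(extra %in% core))
    abort_argument("set1_extra labels overlap the F/FC/C/CP/P rows")
  # Interleave rows front-to-back.
  front  <- extra[1:6]                    # Fp + AF
  f_out  <- extra[7:8]                    # F7/F8
  ft     <- extra[9:10]
  t_row  <- extra[11:12]
  tp     <- extra[13:16]                  # TP9 TP7 TP8 TP10
  po     <- extra[17:21]
  o_row  <- extra[22:24]
  c(front,
    f_out[1], .montage_rows$F, f_out[2],
    ft[1], .montage_rows$FC, ft[2],
    t_row[1], .montage_rows$C, t_row[2],
    tp[1], tp[2], .montage_rows$CP, tp[3], tp[4],
    .montage_rows$P,
    po, o_row)
}

.channel_set_names <- paste0("set", 1:6)

#' Channel-reduction sets of the progressive electrode-removal protocol
#'
#' Six nested electrode subsets narrowing from the full 60-channel cap to the
#' 7 core central electrodes over the motor cortex:
#' set1 (60) full cap; set2 (36) F+FC+C+CP+P rows; set3 (29) drops F;
#' set4 (22) C+CP+P; set5 (13) C+CP; set6 (7) the C row alone.
#'
#' @param name one of `"set1"`..`"set6"`.
#' @param set1_extra see [montage_labels()].
#' @return an object of class `channel_set` with fields `name` and `labels`.
#' @export
get_channel_set <- function(name, set1_extra = NULL) {
  if (!is.character(name) || length(name) != 1L || !name %in% .channel_set_names)
    abort_argument(sprintf("unknown channel set '%s' (expected set1..set6)",
                           as.character(name)[1]))
  r <- .montage_rows
  labels <- switch(name,
    set6 = r$C,
    set5 = c(r$C, r$CP),
    set4 = c(r$C, r$CP, r$P),
    set3 = c(r$FC, r$C, r$CP, r$P),
    set2 = c(r$F, r$FC, r$C, r$CP, r$P),
    set1 = montage_labels(set1_extra))
  structure(list(name = name, labels = labels), class = "channel_set")
}

#' @export
print.channel_set <- function(x, ...) {
  cat(sprintf("<channel_set %s: %d electrodes>\n", x$name, length(x$labels)))
  cat(" ", paste(x$labels, collapse = " "), "\n")
  invisible(x)
}

#' All six channel sets
#' @return named list of `channel_set` objects, set1 through set6.
#' @export
channel_sets <- function() {
  stats::setNames(lapply(.channel_set_names, get_channel_set),
                  .channel_set_names)
}

# Neighbour map used by the electrode-shift perturbation: adjacency along the
# montage ordering (nearest listed electrode).
montage_neighbor <- function(label, labels = montage_labels()) {
  i <- match(label, labels)
  if (is.na(i)) abort_lookup(sprintf("electrode '%s' not in montage", label))
  if (i == length(labels)) labels[i - 1L] else labels[i + 1L]
}
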