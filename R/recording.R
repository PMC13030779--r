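# RawRecording container and recording I/O (delimited array fixtures with a
# JSON sidecar, and a minimal 16-bit EDF reader/writer).

#' Construct a raw multichannel recording
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector, one 10-10 label per row of `data`.
#' @param annotations data.frame with columns `onset` (0-based sample index),
#'   `duration` (samples) and `label` (class name); intervals are half-open
#'   `[onset, onset + duration)` and must not overlap.
#' @param task_set labels the annotations may use; `NULL` skips the check.
#' @return object of class `raw_recording`.
#' @export
raw_recording <- function(data, fs, channel_labels,
                          annotations = empty_annotations(),
                          task_set = NULL) {
  if (!is.matrix(data) || !is.numeric(data))
    abort_format("data must be a numeric channels x samples matrix")
  if (length(channel_labels) != nrow(data))
    abort_format(sprintf("%d channel labels for %d data rows",
                         length(channel_labels), nrow(data)))
  if (!is_scalar_number(fs) || fs <= 0)
    abort_argument("fs must be a positive number")
  annotations <- as.data.frame(annotations)
  if (!all(c("onset", "duration", "label") %in% names(annotations)))
    abort_format("annotations need columns onset, duration, label")
  if (nrow(annotations)) {
    o <- order(annotations$onset)
    annotations <- annotations[o, , drop = FALSE]
    ends <- annotations$onset + annotations$duration
    if (any(annotations$onset < 0) || any(annotations$duration <= 0))
      abort_format("annotation onsets must be >= 0 with positive durations")
    if (any(annotations$onset[-1] < head(ends, -1)))
      abort_format("annotations overlap")
    if (!is.null(task_set) && !all(annotations$label %in% task_set))
      abort_format("annotation labels outside the configured task set")
  }
  rownames(annotations) <- NULL
  known <- channel_labels %in% montage_labels()
  rec <- structure(list(data = data, fs = fs,
                        channel_labels = as.character(channel_labels),
                        annotations = annotations),
                   class = "raw_recording")
  if (!all(known)) {
    attr(rec, "unknown_labels") <- channel_labels[!known]
    warning(sprintf("labels not in the 10-10 vocabulary (retained): %s",
                    paste(channel_labels[!known], collapse = ", ")),
            call. = FALSE)
  }
  rec
}

empty_annotations <- function() {
  data.frame(onset = integer(), duration = integer(),
             label = character(), stringsAsFactors = FALSE)
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording: %d channels x %d samples @ %g Hz, %d annotations>\n",
              nrow(x$data), ncol(x$data), x$fs, nrow(x$annotations)))
  invisible(x)
}

#' Restrict a recording to a channel set
#'
#' Rows are restricted and reordered to the set's order; annotations are
#' untouched.
#'
#' @param rec a [raw_recording()].
#' @param cs a `channel_set` (see [get_channel_set()]) or a set name.
#' @return a `raw_recording` with `length(cs$labels)` channels.
#' @export
subset_channels <- function(rec, cs) {
  stopifnot(inherits(rec, "raw_recording"))
  if (is.character(cs)) cs <- get_channel_set(cs)
  idx <- match(cs$labels, rec$channel_labels)
  if (anyNA(idx))
    abort_lookup(sprintf("recording lacks electrodes: %s",
                         paste(cs$labels[is.na(idx)], collapse = ", ")))
  raw_recording(rec$data[idx, , drop = FALSE], rec$fs, cs$labels,
                rec$annotations)
}

annotations_to_sidecar <- function(ann) {
  lapply(seq_len(nrow(ann)), function(i)
    list(onset = ann$onset[i], duration = ann$duration[i],
         label = ann$label[i]))
}

sidecar_to_annotations <- function(lst) {
  if (!length(lst)) return(empty_annotations())
  data.frame(onset = vapply(lst, function(a) as.numeric(a$onset), 0),
             duration = vapply(lst, function(a) as.numeric(a$duration), 0),
             label = vapply(lst, function(a) as.character(a$label), ""),
             stringsAsFactors = FALSE)
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Read a recording from disk
#'
#' Two on-disk forms are supported: a delimited numeric matrix (channels in
#' rows) with a JSON sidecar `{fs, channel_labels, annotations}` sharing the
#' file stem, or a 16-bit EDF file (sidecar optional, carrying annotations).
#'
#' @param path path to the data file (`.tsv`/`.csv` fixture or `.edf`).
#' @param format `"auto"` (by extension), `"fixture"` or `"edf"`.
#' @return a [raw_recording()].
#' @export
load_recording <- function(path, format = c("auto", "fixture", "edf")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort_io(sprintf("no such file: %s", path))
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "fixture"
  if (format == "edf") return(read_edf_recording(path))
  side <- sidecar_path(path)
  if (!file.exists(side)) abort_io(sprintf("missing sidecar: %s", side))
  meta <- jsonlite::read_json(side)
  dt <- tryCatch(data.table::fread(path, header = FALSE),
                 error = function(e) abort_io(conditionMessage(e)))
  data <- as.matrix(dt)
  dimnames(data) <- NULL
  labels <- vapply(meta$channel_labels, as.character, "")
  if (length(labels) != nrow(data))
    abort_format(sprintf("sidecar lists %d labels but data has %d rows",
                         length(labels), nrow(data)))
  raw_recording(data, as.numeric(meta$fs), labels,
                sidecar_to_annotations(meta$annotations))
}

#' Write a recording to disk
#'
#' Inverse of [load_recording()]. The fixture form round-trips values at full
#' floating precision; EDF quantizes to 16 bits over each channel's range.
#'
#' @param rec a [raw_recording()].
#' @param path output path (`.tsv` or `.edf`).
#' @param format `"auto"`, `"fixture"` or `"edf"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "fixture", "edf")) {
  stopifnot(inherits(rec, "raw_recording"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "fixture"
  meta <- list(fs = rec$fs, n_samples = ncol(rec$data),
               channel_labels = as.list(rec$channel_labels),
               annotations = annotations_to_sidecar(rec$annotations))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  if (format == "edf") {
    write_edf_recording(rec, path)
  } else {
    data.table::fwrite(data.table::as.data.table(rec$data), path, sep = "\t",
                       col.names = FALSE)
  }
  invisible(path)
}

# ---- minimal EDF (European Data Format) support -----------------------------
# 16-bit integer records; one data record per second. Annotations are not
# embedded (no EDF+ annotation stream): they travel in the JSON sidecar.

pad_field <- function(x, width) {
  s <- substr(formatC(as.character(x), width = -1), 1, width)
  formatC(s, width = -width, flag = "-")
}

write_edf_recording <- function(rec, path) {
  ns <- nrow(rec$data)
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9)
    abort_argument("EDF writer requires an integer sampling rate")
  spr <- as.integer(round(fs))            # samples per 1 s record
  n_rec <- ceiling(ncol(rec$data) / spr)
  total <- n_rec * spr
  pmin <- apply(rec$data, 1, min); pmax <- apply(rec$data, 1, max)
  flat <- pmax - pmin < 1e-12
  pmin[flat] <- pmin[flat] - 1; pmax[flat] <- pmax[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb"); on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8), pad_field("", 80), pad_field("", 80),
    pad_field("01.01.26", 8), pad_field("00.00.00", 8),
    pad_field(256 * (ns + 1), 8), pad_field("", 44),
    pad_field(n_rec, 8), pad_field(1, 8), pad_field(ns, 4),
    paste(pad_field(rec$channel_labels, 16), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(rep(pad_field("uV", 8), ns), collapse = ""),
    paste(pad_field(signif(pmin, 7), 8), collapse = ""),
    paste(pad_field(signif(pmax, 7), 8), collapse = ""),
    paste(rep(pad_field(dmin, 8), ns), collapse = ""),
    paste(rep(pad_field(dmax, 8), ns), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(rep(pad_field(spr, 8), ns), collapse = ""),
    paste(rep(pad_field("", 32), ns), collapse = ""))
  writeChar(hdr, con, eos = NULL)
  x <- cbind(rec$data, matrix(0, ns, total - ncol(rec$data)))
  scale <- (dmax - dmin) / (pmax - pmin)
  dig <- round((x - pmin) * scale + dmin)   # per-channel affine, recycled by row
  dig[dig < dmin] <- dmin; dig[dig > dmax] <- dmax
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * spr + 1):(r * spr)
    block <- t(dig[, cols, drop = FALSE])   # per signal contiguous
    writeBin(as.integer(block), con, size = 2, endian = "little")
  }
  invisible(path)
}

read_edf_recording <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  rd_str <- function(n) readChar(con, n, useBytes = TRUE)
  rd_num <- function(n) as.numeric(trimws(rd_str(n)))
  rd_str(8); rd_str(80); rd_str(80); rd_str(8); rd_str(8)
  hdr_bytes <- rd_num(8); rd_str(44)
  n_rec <- rd_num(8); rec_dur <- rd_num(8); ns <- as.integer(rd_num(4))
  if (!is.finite(ns) || ns < 1) abort_format("unreadable EDF header")
  labels <- trimws(vapply(seq_len(ns), function(i) rd_str(16), ""))
  for (i in seq_len(ns)) rd_str(80)                   # transducer
  for (i in seq_len(ns)) rd_str(8)                    # physical dim
  pmin <- vapply(seq_len(ns), function(i) rd_num(8), 0)
  pmax <- vapply(seq_len(ns), function(i) rd_num(8), 0)
  dmin <- vapply(seq_len(ns), function(i) rd_num(8), 0)
  dmax <- vapply(seq_len(ns), function(i) rd_num(8), 0)
  for (i in seq_len(ns)) rd_str(80)                   # prefilter
  spr <- vapply(seq_len(ns), function(i) as.integer(rd_num(8)), 0L)
  for (i in seq_len(ns)) rd_str(32)
  if (length(unique(spr)) != 1L)
    abort_format("EDF with per-signal sampling rates is not supported")
  fs <- spr[1] / rec_dur
  total <- n_rec * spr[1]
  data <- matrix(0, ns, total)
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = ns * spr[1], size = 2,
                   endian = "little")
    if (length(raw) < ns * spr[1]) abort_format("truncated EDF data record")
    data[, ((r - 1) * spr[1] + 1):(r * spr[1])] <-
      t(matrix(raw, nrow = spr[1]))
  }
  gain <- (pmax - pmin) / (dmax - dmin)
  data <- (data - dmin) * gain + pmin
  side <- sidecar_path(path)
  ann <- empty_annotations(); n_samples <- total
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side)
    ann <- sidecar_to_annotations(meta$annotations)
    if (!is.null(meta$n_samples)) n_samples <- as.integer(meta$n_samples)
    if (!is.null(meta$channel_labels)) {
      side_labels <- vapply(meta$channel_labels, as.character, "")
      if (length(side_labels) == ns) labels <- side_labels
    }
  }
  raw_recording(data[, seq_len(min(n_samples, total)), drop = FALSE],
                fs, labels, ann)
}
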