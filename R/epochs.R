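#' Construct an epoch set
#'
#' Per-subject EEG epochs organized by condition. Every epoch is a
#' channels x samples matrix with identical channel order and sample count.
#'
#' @param epochs Named list: condition label -> list of channels x samples
#'   matrices.
#' @param channel_labels,sample_rate As in [eeg_recording()].
#' @param subject_id,group Subject metadata.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(epochs, channel_labels, sample_rate,
                      subject_id = NA_character_, group = NA_character_) {
  stopifnot(is.list(epochs))
  lens <- unlist(lapply(epochs, function(e) vapply(e, ncol, 0L)))
  if (length(lens) > 0 && length(unique(lens)) != 1) {
    stop("all epochs must have the same sample count")
  }
  chs <- unlist(lapply(epochs, function(e) vapply(e, nrow, 0L)))
  if (length(chs) > 0 && any(chs != length(channel_labels))) {
    stop("all epochs must have one row per channel label")
  }
  structure(
    list(epochs = epochs, channel_labels = as.character(channel_labels),
         sample_rate = sample_rate, subject_id = subject_id, group = group),
    class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  counts <- vapply(x$epochs, length, 0L)
  cat(sprintf("<epoch_set> %s (%s): %s\n", x$subject_id, x$group,
              paste(names(counts), counts, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Number of epochs per condition
#' @param x An `epoch_set`.
#' @return Named integer vector.
#' @export
epoch_counts <- function(x) vapply(x$epochs, length, 0L)

#' Cut a recording into condition epochs
#'
#' Cuts each annotated interval into consecutive non-overlapping epochs of
#' exactly `epoch_length_s`. Windows are half-open in samples,
#' `[onset, onset + L)` at 0-based indices, with the onset rounded to the
#' nearest sample; a partial trailing segment is dropped, so a 9.9-s
#' annotation yields no 10-s epoch and a 430-s rest block yields 43.
#'
#' @param rec An [eeg_recording()] with annotations.
#' @param epoch_length_s Epoch length in seconds (default 10, the duration
#'   of one stimulus presentation).
#' @param rest_selection How to pick rest fragments when `n_rest` is given:
#'   `"contiguous"` takes the first `n_rest` fragments from the start of the
#'   rest block, `"sampled"` draws them at random without replacement.
#' @param n_rest Optional cap on the number of rest fragments.
#' @param amplitude_threshold Optional artifact guard: epochs whose absolute
#'   amplitude exceeds this value (microvolts) are dropped. Off by default;
#'   epochs are assumed artifact-free.
#' @return An [epoch_set()].
#' @export
extract_epochs <- function(rec, epoch_length_s = 10,
                           rest_selection = c("contiguous", "sampled"),
                           n_rest = NULL, amplitude_threshold = NULL) {
  rest_selection <- match.arg(rest_selection)
  stopifnot(epoch_length_s > 0)
  ann <- rec$annotations
  if (nrow(ann) == 0) {
    stop("recording has no annotations: supply an events file")
  }
  known <- eeg_conditions()
  unknown <- setdiff(unique(ann$label), known)
  if (length(unknown) > 0) {
    warning("dropping annotations with unknown condition label(s): ",
            paste(unknown, collapse = ", "))
    ann <- ann[ann$label %in% known, , drop = FALSE]
  }
  if (!"rest" %in% ann$label) stop("no rest annotation present")

  fs <- rec$sample_rate
  L <- round(epoch_length_s * fs)
  out <- list()
  for (cond in intersect(known, unique(ann$label))) {
    rows <- ann[ann$label == cond, , drop = FALSE]
    eps <- list()
    for (i in seq_len(nrow(rows))) {
      onset <- round(rows$onset_s[i] * fs)          # 0-based sample index
      n_avail <- floor(rows$duration_s[i] * fs)
      k <- n_avail %/% L
      for (j in seq_len(k)) {
        lo <- onset + (j - 1L) * L
        eps[[length(eps) + 1L]] <- rec$data[, (lo + 1L):(lo + L), drop = FALSE]
      }
    }
    if (!is.null(amplitude_threshold)) {
      keep <- vapply(eps, function(e) max(abs(e)) <= amplitude_threshold, TRUE)
      eps <- eps[keep]
    }
    if (cond == "rest" && !is.null(n_rest) && length(eps) > n_rest) {
      idx <- if (rest_selection == "contiguous") seq_len(n_rest)
             else sort(sample.int(length(eps), n_rest))
      eps <- eps[idx]
    }
    if (length(eps) == 0) {
      warning("condition '", cond, "' has no complete epochs; omitted")
    } else {
      out[[cond]] <- eps
    }
  }
  epoch_set(out, rec$channel_labels, fs, rec$subject_id, rec$group)
}
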