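#' Condition labels used by the stimulation protocol
#'
#' The protocol has one resting-state condition and four tactile stimulus
#' types: slow (2-3 cm/s) or fast (12-15 cm/s) stroking with a soft or hard
#' brush. Each stimulus is presented 10 times for 10 s.
#'
#' @return Character vector of the five condition labels.
#' @export
eeg_conditions <- function() {
  c("rest", "slow_soft", "fast_soft", "slow_hard", "fast_hard")
}

#' @rdname eeg_conditions
#' @export
stimulation_conditions <- function() setdiff(eeg_conditions(), "rest")

#' Construct a continuous EEG recording
#'
#' @param data Numeric channels x samples matrix, microvolts.
#' @param channel_labels Electrode labels, one per row of `data`; must be the
#'   19 labels of the 10-20 montage (any order).
#' @param sample_rate Sampling rate in Hz.
#' @param annotations Data frame with columns `onset_s`, `duration_s`,
#'   `label` marking condition intervals.
#' @param subject_id,group Optional subject metadata (`group` is `"patient"`
#'   or `"control"`).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, channel_labels, sample_rate,
                          annotations = NULL,
                          subject_id = NA_character_, group = NA_character_) {
  data <- as.matrix(data)
  if (is.null(annotations)) {
    annotations <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                              label = character(0))
  }
  rec <- structure(
    list(data = data, channel_labels = as.character(channel_labels),
         sample_rate = sample_rate,
         annotations = as.data.frame(annotations),
         subject_id = subject_id, group = group),
    class = "eeg_recording")
  validate_recording(rec)
  rec
}

validate_recording <- function(rec) {
  known <- montage_electrodes()
  unknown <- setdiff(rec$channel_labels, known)
  if (length(unknown) > 0) {
    stop("unknown channel label(s): ", paste(unknown, collapse = ", "))
  }
  if (length(rec$channel_labels) != length(known)) {
    stop("expected ", length(known), " channels of the 10-20 montage, got ",
         length(rec$channel_labels))
  }
  if (anyDuplicated(rec$channel_labels)) stop("duplicated channel labels")
  if (nrow(rec$data) != length(rec$channel_labels)) {
    stop("data has ", nrow(rec$data), " rows but ",
         length(rec$channel_labels), " channel labels")
  }
  if (!is.numeric(rec$sample_rate) || rec$sample_rate <= 0) {
    stop("sample_rate must be a positive number")
  }
  ann <- rec$annotations
  if (nrow(ann) > 0) {
    dur_s <- ncol(rec$data) / rec$sample_rate
    if (any(ann$onset_s < 0)) stop("annotation onsets must be non-negative")
    if (any(ann$onset_s + ann$duration_s > dur_s + 1e-9)) {
      stop("annotation extends beyond the end of the recording (",
           dur_s, " s)")
    }
  }
  invisible(rec)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s (%s): %d channels x %d samples @ %g Hz, %d annotations\n",
              x$subject_id, x$group, nrow(x$data), ncol(x$data),
              x$sample_rate, nrow(x$annotations)))
  invisible(x)
}

#' Read an EEG recording
#'
#' Reads a recording in one of two dialects: 16-bit `edf` (European Data
#' Format, one data record per second, annotations supplied through a
#' sidecar events file `<path>.events.tsv` with columns onset_s, duration_s,
#' label) or the package's plain-text `epoch_archive` dialect, which stores
#' metadata, annotations and the channels x samples matrix in a single
#' tab-separated file.
#'
#' @param path Path to the recording file.
#' @param dialect `"edf"` or `"epoch_archive"`.
#' @param events_path Events sidecar for the EDF dialect; defaults to
#'   `<path>.events.tsv`.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, dialect = c("edf", "epoch_archive"),
                           events_path = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(dialect,
         edf = read_recording_edf(path, events_path),
         epoch_archive = read_recording_archive(path))
}

#' Write an EEG recording
#'
#' Counterpart of [read_recording()]. The EDF dialect quantizes samples to
#' 16 bits over a symmetric physical range; the range used at write time is
#' remembered on objects read back from EDF so that write-read-write
#' round-trips are byte-identical.
#'
#' @param rec An [eeg_recording()].
#' @param path Output path.
#' @param dialect `"edf"` or `"epoch_archive"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, dialect = c("edf", "epoch_archive")) {
  dialect <- match.arg(dialect)
  validate_recording(rec)
  switch(dialect,
         edf = write_recording_edf(rec, path),
         epoch_archive = write_recording_archive(rec, path))
  invisible(path)
}

## ---- EDF dialect -----------------------------------------------------------

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF header field too wide: '", x, "'")
  formatC(x, width = -width)
}

edf_num <- function(x) formatC(x, format = "g", digits = 7)

write_recording_edf <- function(rec, path) {
  fs <- rec$sample_rate
  if (abs(fs - round(fs)) > 1e-9) stop("EDF dialect requires an integer sample rate")
  fs <- as.integer(round(fs))
  n_samp <- ncol(rec$data)
  if (n_samp %% fs != 0) {
    stop("EDF dialect requires a whole number of 1-s data records; ",
         "got ", n_samp, " samples at ", fs, " Hz")
  }
  n_rec <- n_samp %/% fs
  ns <- nrow(rec$data)

  phys_range <- attr(rec, "edf_phys_range")
  if (is.null(phys_range)) {
    pm <- max(1, ceiling(max(abs(rec$data))))
    phys_range <- c(-pm, pm)
  }
  dig_min <- -32767L; dig_max <- 32767L
  scale <- (phys_range[2] - phys_range[1]) / (dig_max - dig_min)
  digital <- round((rec$data - phys_range[1]) / scale) + dig_min
  digital[digital > dig_max] <- dig_max
  digital[digital < dig_min] <- dig_min
  storage.mode(digital) <- "integer"

  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  header_bytes <- 256L + 256L * ns
  put(edf_pad("0", 8))
  put(edf_pad(paste(rec$subject_id, rec$group), 80))
  put(edf_pad("tactileEEG export", 80))
  put(edf_pad("01.01.20", 8))
  put(edf_pad("00.00.00", 8))
  put(edf_pad(header_bytes, 8))
  put(edf_pad("", 44))
  put(edf_pad(n_rec, 8))
  put(edf_pad("1", 8))
  put(edf_pad(ns, 4))
  for (lab in rec$channel_labels) put(edf_pad(paste("EEG", lab), 16))
  for (i in seq_len(ns)) put(edf_pad("AgCl electrode", 80))
  for (i in seq_len(ns)) put(edf_pad("uV", 8))
  for (i in seq_len(ns)) put(edf_pad(edf_num(phys_range[1]), 8))
  for (i in seq_len(ns)) put(edf_pad(edf_num(phys_range[2]), 8))
  for (i in seq_len(ns)) put(edf_pad(dig_min, 8))
  for (i in seq_len(ns)) put(edf_pad(dig_max, 8))
  for (i in seq_len(ns)) put(edf_pad("HP:0.05Hz LP:70Hz", 80))
  for (i in seq_len(ns)) put(edf_pad(fs, 8))
  for (i in seq_len(ns)) put(edf_pad("", 32))
  # data records: per second, all channels consecutively
  idx <- matrix(seq_len(n_samp), nrow = fs)
  for (r in seq_len(n_rec)) {
    block <- t(digital[, idx[, r], drop = FALSE])  # fs x ns, column per channel
    writeBin(as.integer(block), con, size = 2L, endian = "little")
  }

  events_path <- paste0(path, ".events.tsv")
  utils::write.table(rec$annotations, events_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_recording_edf <- function(path, events_path = NULL) {
  if (is.null(events_path)) events_path <- paste0(path, ".events.tsv")
  con <- file(path, "rb")
  on.exit(close(con))
  get <- function(n) {
    raw <- readBin(con, "raw", n = n)
    trimws(rawToChar(raw))
  }
  get(8)                              # version
  patient <- get(80)
  get(80); get(8); get(8); get(8); get(44)
  n_rec <- as.integer(get(8))
  rec_dur <- as.numeric(get(8))
  ns <- as.integer(get(4))
  labels <- vapply(seq_len(ns), function(i) get(16), "")
  labels <- sub("^EEG ", "", labels)
  for (i in seq_len(ns)) get(80)      # transducer
  for (i in seq_len(ns)) get(8)       # physical dimension
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) get(8), ""))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) get(8), ""))
  dig_min <- as.integer(vapply(seq_len(ns), function(i) get(8), ""))
  dig_max <- as.integer(vapply(seq_len(ns), function(i) get(8), ""))
  for (i in seq_len(ns)) get(80)      # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) get(8), ""))
  for (i in seq_len(ns)) get(32)      # reserved
  if (length(unique(spr)) != 1) stop("mixed per-channel sampling rates are not supported")
  fs <- spr[1] / rec_dur

  n_total <- n_rec * spr[1]
  data <- matrix(0, nrow = ns, ncol = n_total)
  for (r in seq_len(n_rec)) {
    block <- readBin(con, "integer", n = spr[1] * ns, size = 2L,
                     signed = TRUE, endian = "little")
    block <- matrix(block, nrow = spr[1], ncol = ns)
    cols <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    data[, cols] <- t(block)
  }
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  data <- (data - dig_min) * scale + phys_min

  if (!file.exists(events_path)) {
    stop("no annotations found for ", path,
         ": supply an events file at ", events_path,
         " (columns onset_s, duration_s, label)")
  }
  ann <- utils::read.delim(events_path, stringsAsFactors = FALSE)

  meta <- strsplit(patient, " +")[[1]]
  subject_id <- if (length(meta) >= 1) meta[1] else NA_character_
  group <- if (length(meta) >= 2) meta[2] else NA_character_
  rec <- eeg_recording(data, labels, fs, ann, subject_id, group)
  attr(rec, "edf_phys_range") <- c(phys_min[1], phys_max[1])
  rec
}

## ---- plain-text epoch-archive dialect --------------------------------------

write_recording_archive <- function(rec, path) {
  meta <- c(
    "#eeg_recording\tv1",
    paste0("#subject_id\t", rec$subject_id),
    paste0("#group\t", rec$group),
    paste0("#sample_rate\t", format(rec$sample_rate, digits = 12)),
    if (nrow(rec$annotations) > 0) {
      sprintf("#annotation\t%.6f\t%.6f\t%s",
              rec$annotations$onset_s, rec$annotations$duration_s,
              rec$annotations$label)
    }
  )
  body <- vapply(seq_len(nrow(rec$data)), function(i) {
    paste(rec$channel_labels[i],
          paste(sprintf("%.6f", rec$data[i, ]), collapse = "\t"),
          sep = "\t")
  }, "")
  writeLines(c(meta, body), path)
  invisible(path)
}

read_recording_archive <- function(path) {
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  meta <- strsplit(lines[is_meta], "\t", fixed = TRUE)
  keys <- vapply(meta, `[[`, "", 1)
  if (!identical(keys[1], "#eeg_recording")) {
    stop("not an epoch-archive recording: ", path)
  }
  grab <- function(key) {
    hit <- which(keys == key)
    if (length(hit) == 0) return(NA_character_)
    meta[[hit[1]]][2]
  }
  ann_rows <- meta[keys == "#annotation"]
  ann <- if (length(ann_rows) > 0) {
    data.frame(onset_s = as.numeric(vapply(ann_rows, `[[`, "", 2)),
               duration_s = as.numeric(vapply(ann_rows, `[[`, "", 3)),
               label = vapply(ann_rows, `[[`, "", 4))
  } else NULL
  body <- strsplit(lines[!is_meta], "\t", fixed = TRUE)
  labels <- vapply(body, `[[`, "", 1)
  data <- do.call(rbind, lapply(body, function(row) as.numeric(row[-1])))
  eeg_recording(data, labels, as.numeric(grab("#sample_rate")), ann,
                grab("#subject_id"), grab("#group"))
}
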