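#' Spectral estimation window specification
#'
#' The default estimator is Welch's method: the 10-s epoch is split into
#' 2-s Hann-tapered segments with 50% overlap and the segment periodograms
#' are averaged, trading frequency resolution (0.5 Hz) for variance
#' reduction. `mode = "rectangular"` instead computes the plain single-window
#' periodogram of the whole epoch (no taper, no averaging); this mode is the
#' reference against which the estimator is checked, since it equals the
#' direct DFT periodogram exactly.
#'
#' @param mode `"welch"` or `"rectangular"`.
#' @param window_s Segment length in seconds (Welch mode).
#' @param overlap Fractional segment overlap in `[0, 1)` (Welch mode).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(mode = c("welch", "rectangular"),
                        window_s = 2, overlap = 0.5) {
  mode <- match.arg(mode)
  stopifnot(window_s > 0, overlap >= 0, overlap < 1)
  structure(list(mode = mode, window_s = window_s, overlap = overlap),
            class = "window_spec")
}

#' Power spectral density of one epoch
#'
#' One-sided PSD per electrode on the FFT frequency grid, in signal
#' units^2/Hz. Each segment is demeaned before tapering, so the integral of
#' the PSD over frequency equals the time-domain variance (Parseval) up to
#' the taper's leakage.
#'
#' @param epoch Channels x samples numeric matrix (a vector is treated as a
#'   single channel).
#' @param rate Sampling rate in Hz.
#' @param spec A [window_spec()].
#' @return An object of class `eeg_spectrum`: list with `freq` (Hz) and
#'   `psd` (channels x frequencies).
#' @export
compute_psd <- function(epoch, rate, spec = window_spec()) {
  if (is.vector(epoch)) epoch <- matrix(epoch, nrow = 1)
  if (anyNA(epoch)) stop("epoch contains NA/NaN samples")
  n <- ncol(epoch)
  if (n < 2 * rate) stop("epoch must be at least 2 s long")
  if (spec$mode == "rectangular") {
    nwin <- n
    starts <- 1L
    w <- rep(1, nwin)
  } else {
    nwin <- round(spec$window_s * rate)
    if (nwin > n) stop("epoch shorter than the analysis window")
    step <- max(1L, round(nwin * (1 - spec$overlap)))
    starts <- seq(1L, n - nwin + 1L, by = step)
    w <- hann_window(nwin)
  }
  u <- sum(w^2)
  nch <- nrow(epoch)
  nfreq <- nwin %/% 2 + 1L
  nseg <- length(starts)
  # stack all segments of all channels as columns of one matrix so the
  # whole epoch needs a single FFT call
  idx <- outer(seq_len(nwin), starts - 1L, `+`)      # nwin x nseg
  segs <- epoch[, as.vector(idx), drop = FALSE]      # nch x (nwin*nseg)
  dim(segs) <- c(nch, nwin, nseg)
  segs <- aperm(segs, c(2, 1, 3))
  dim(segs) <- c(nwin, nch * nseg)
  segs <- sweep(segs, 2, colMeans(segs))
  ft <- stats::mvfft(segs * w)
  p <- Mod(ft[seq_len(nfreq), , drop = FALSE])^2
  dim(p) <- c(nfreq * nch, nseg)
  acc <- matrix(rowMeans(p), nfreq, nch)
  psd <- t(acc) / (rate * u)
  # one-sided: double everything except DC and (for even nwin) Nyquist
  dbl <- rep(2, nfreq)
  dbl[1] <- 1
  if (nwin %% 2 == 0) dbl[nfreq] <- 1
  psd <- psd * rep(dbl, each = nch)
  rownames(psd) <- rownames(epoch)
  structure(list(freq = (seq_len(nfreq) - 1) * rate / nwin, psd = psd),
            class = "eeg_spectrum")
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))

#' Normalize a spectrum to relative power over 2-20 Hz
#'
#' Divides each electrode's PSD by that electrode's total power in the
#' [2, 20) Hz analysis range, so the 18 unit-width bins of a subsequent
#' [integrate_bins()] sum to 1 (relative power). `mode = "none"` passes the
#' spectrum through unchanged (absolute power).
#'
#' @param spectrum An `eeg_spectrum`.
#' @param mode `"relative"` or `"none"`.
#' @return An `eeg_spectrum`.
#' @export
normalize_spectrum <- function(spectrum, mode = c("relative", "none")) {
  mode <- match.arg(mode)
  if (mode == "none") return(spectrum)
  total <- integrate_range(spectrum, 2, 20)
  if (any(total <= 0)) {
    stop("zero total power in [2, 20) Hz; cannot normalize a flat-zero signal")
  }
  spectrum$psd <- spectrum$psd / total
  spectrum
}

# trapezoidal integral of the piecewise-linear PSD over [lo, hi), per channel
integrate_range <- function(spectrum, lo, hi) {
  w <- trapezoid_weights(spectrum$freq, lo, hi)
  as.numeric(spectrum$psd %*% w)
}

# weights w such that sum(w * p) = integral over [lo, hi] of the linear
# interpolant of p on grid f
trapezoid_weights <- function(f, lo, hi) {
  if (lo < f[1] - 1e-9 || hi > f[length(f)] + 1e-9) {
    stop("frequency grid does not cover [", lo, ", ", hi, "] Hz")
  }
  w <- numeric(length(f))
  for (i in seq_len(length(f) - 1L)) {
    a <- f[i]; b <- f[i + 1L]
    x1 <- max(a, lo); x2 <- min(b, hi)
    if (x2 <= x1) next
    h <- b - a
    t1 <- (x1 - a) / h; t2 <- (x2 - a) / h
    len <- x2 - x1
    w[i] <- w[i] + len * (2 - t1 - t2) / 2
    w[i + 1L] <- w[i + 1L] + len * (t1 + t2) / 2
  }
  w
}

#' Integrate a spectrum over unit-width frequency bins
#'
#' Integrates the PSD over the 18 half-open unit bins [2,3), [3,4), ...,
#' [19,20) Hz by trapezoidal quadrature of the piecewise-linear spectrum.
#' The bins partition [2, 20) without overlap, so their sum equals the
#' direct integral over the whole range.
#'
#' @param spectrum An `eeg_spectrum` (normalized or not).
#' @return A `bin_spectrum`: channels x 18 matrix with bin labels
#'   `"2-3"`, ..., `"19-20"` and attribute `edges`.
#' @export
integrate_bins <- function(spectrum) {
  edges <- 2:20
  if (max(diff(spectrum$freq)) > 1 + 1e-9) {
    stop("frequency grid coarser than 1 Hz; use longer epochs or windows")
  }
  wmat <- vapply(seq_len(length(edges) - 1L),
                 function(i) trapezoid_weights(spectrum$freq, edges[i], edges[i + 1L]),
                 numeric(length(spectrum$freq)))
  bins <- spectrum$psd %*% wmat
  colnames(bins) <- paste(edges[-length(edges)], edges[-1], sep = "-")
  structure(bins, edges = edges, class = c("bin_spectrum", class(bins)))
}

#' Band definitions
#'
#' Two band sets are in use: the `"contrast"` scheme applied to
#' stimulation-vs-rest differences (theta 4-6, alpha 11-13, beta 17-20 Hz,
#' plus slow 2-6) and the `"resting"` scheme used for resting-state group
#' comparisons (slow 2-6, alpha 8-12, beta 16-20 Hz). Band edges must align
#' with the integer bin edges.
#'
#' @param name `"contrast"`, `"resting"`, or a named list of `c(low, high)`
#'   pairs for a custom scheme.
#' @return Named list of frequency ranges.
#' @export
band_scheme <- function(name = c("contrast", "resting")) {
  if (is.list(name)) {
    bands <- name
  } else {
    name <- match.arg(name)
    bands <- switch(name,
      contrast = list(slow = c(2, 6), theta = c(4, 6),
                      alpha = c(11, 13), beta = c(17, 20)),
      resting  = list(slow = c(2, 6), alpha = c(8, 12), beta = c(16, 20)))
  }
  for (nm in names(bands)) {
    b <- bands[[nm]]
    if (b[1] >= b[2] || b[1] < 2 || b[2] > 20 ||
        any(abs(b - round(b)) > 1e-9)) {
      stop("band '", nm, "' must lie within [2, 20] Hz with integer edges")
    }
  }
  bands
}

#' Mean band power from a bin spectrum
#'
#' Mean of the unit-bin powers whose bins lie within `[low, high)`; e.g.
#' theta 4-6 Hz is the mean of bins [4,5) and [5,6).
#'
#' @param bins A `bin_spectrum`.
#' @param band Numeric `c(low, high)` aligned to bin edges.
#' @return Numeric vector, one value per channel.
#' @export
band_power <- function(bins, band) {
  edges <- attr(bins, "edges")
  if (band[1] < edges[1] || band[2] > edges[length(edges)]) {
    stop("band outside the [2, 20) Hz analysis range")
  }
  if (any(abs(band - round(band)) > 1e-9)) {
    stop("band edges must align with integer bin edges")
  }
  lo <- edges[-length(edges)]
  keep <- lo >= band[1] & lo < band[2]
  rowMeans(bins[, keep, drop = FALSE])
}

# per-epoch bin spectra of one condition: array [epoch, channel, bin].
# Batched implementation of the compute_psd -> normalize_spectrum ->
# integrate_bins chain: all epochs' tapered segments share one FFT call.
# Equivalent to mapping the per-epoch chain over the list (the unit tests
# assert this), just fast enough for resampling studies.
epoch_bin_array <- function(epochs, rate, spec, normalize) {
  nep <- length(epochs)
  nch <- nrow(epochs[[1]])
  n <- ncol(epochs[[1]])
  if (any(vapply(epochs, anyNA, TRUE))) stop("epoch contains NA/NaN samples")
  if (n < 2 * rate) stop("epoch must be at least 2 s long")
  if (spec$mode == "rectangular") {
    nwin <- n; starts <- 1L; w <- rep(1, nwin)
  } else {
    nwin <- round(spec$window_s * rate)
    if (nwin > n) stop("epoch shorter than the analysis window")
    step <- max(1L, round(nwin * (1 - spec$overlap)))
    starts <- seq(1L, n - nwin + 1L, by = step)
    w <- hann_window(nwin)
  }
  nseg <- length(starts)
  nfreq <- nwin %/% 2 + 1L
  freq <- (seq_len(nfreq) - 1) * rate / nwin
  idx <- as.vector(outer(seq_len(nwin), starts - 1L, `+`))

  big <- matrix(0, nwin, nch * nseg * nep)
  for (i in seq_len(nep)) {
    segs <- epochs[[i]][, idx, drop = FALSE]
    dim(segs) <- c(nch, nwin, nseg)
    big[, ((i - 1L) * nch * nseg + 1L):(i * nch * nseg)] <-
      matrix(aperm(segs, c(2, 1, 3)), nwin)
  }
  big <- sweep(big, 2, colMeans(big))
  ft <- stats::mvfft(big * w)
  p <- Mod(ft[seq_len(nfreq), , drop = FALSE])^2
  # average the segment periodograms: reorder so the segment axis is first,
  # then one colSums call
  dim(p) <- c(nfreq * nch, nseg, nep)
  p <- aperm(p, c(2, 1, 3))
  dim(p) <- c(nseg, nfreq * nch * nep)
  psd <- colSums(p) / (nseg * rate * sum(w^2))
  dim(psd) <- c(nfreq, nch * nep)
  dbl <- rep(2, nfreq); dbl[1] <- 1; if (nwin %% 2 == 0) dbl[nfreq] <- 1
  psd <- psd * dbl

  edges <- 2:20
  if (max(diff(freq)) > 1 + 1e-9) {
    stop("frequency grid coarser than 1 Hz; use longer epochs or windows")
  }
  wmat <- vapply(seq_len(length(edges) - 1L),
                 function(i) trapezoid_weights(freq, edges[i], edges[i + 1L]),
                 numeric(nfreq))
  dim(psd) <- c(nfreq, nch * nep)
  bins <- crossprod(psd, wmat)                  # (nch*nep) x 18
  if (normalize == "relative") {
    total <- as.numeric(crossprod(psd, trapezoid_weights(freq, 2, 20)))
    if (any(total <= 0)) {
      stop("zero total power in [2, 20) Hz; cannot normalize a flat-zero signal")
    }
    bins <- bins / total
  }
  dim(bins) <- c(nch, nep, length(edges) - 1L)
  arr <- aperm(bins, c(2, 1, 3))
  dimnames(arr) <- list(NULL, rownames(epochs[[1]]),
                        paste(edges[-length(edges)], edges[-1], sep = "-"))
  arr
}

merge_condition_map <- function(conditions, merge_rule) {
  stim <- stimulation_conditions()
  switch(merge_rule,
    per_stimulus = stats::setNames(conditions, conditions),
    valence_pairs = stats::setNames(
      ifelse(conditions == "rest", "rest",
             ifelse(conditions %in% c("slow_soft", "fast_soft"),
                    "pleasant", "unpleasant")),
      conditions),
    all_stimulation = stats::setNames(
      ifelse(conditions == "rest", "rest", "stimulation"), conditions))
}

#' Condition-level band-power table
#'
#' For each subject and (merged) condition, averages the per-epoch bin
#' spectra over all epochs of the condition -- the expectation-equivalent of
#' concatenating the 10-s epochs into one long segment -- and then averages
#' bins into bands. `merge_rule` controls pooling of the four stimulus
#' types: `"per_stimulus"` keeps them separate, `"valence_pairs"` merges
#' soft-brush (pleasant) and hard-brush (unpleasant) pairs (2 x 10 trials
#' x 10 s = 200 s per pair), `"all_stimulation"` pools all 40 trials.
#'
#' @param epoch_sets List of [epoch_set()] objects (one per subject).
#' @param scheme A [band_scheme()].
#' @param merge_rule One of `"per_stimulus"`, `"valence_pairs"`,
#'   `"all_stimulation"`.
#' @param spec A [window_spec()].
#' @param normalize `"relative"` or `"none"`, see [normalize_spectrum()].
#' @return A `band_power_table`: tibble with columns subject, group,
#'   condition, electrode, band, power.
#' @export
condition_table <- function(epoch_sets, scheme = band_scheme("contrast"),
                            merge_rule = c("per_stimulus", "valence_pairs",
                                           "all_stimulation"),
                            spec = window_spec(),
                            normalize = c("relative", "none")) {
  merge_rule <- match.arg(merge_rule)
  normalize <- match.arg(normalize)
  if (inherits(epoch_sets, "epoch_set")) epoch_sets <- list(epoch_sets)
  montage <- epoch_sets[[1]]$channel_labels
  for (es in epoch_sets) {
    if (!identical(es$channel_labels, montage)) {
      stop("all subjects must share the same montage/channel order")
    }
  }
  rows <- list()
  for (es in epoch_sets) {
    cmap <- merge_condition_map(names(es$epochs), merge_rule)
    for (merged in unique(cmap)) {
      eps <- unlist(es$epochs[names(cmap)[cmap == merged]], recursive = FALSE)
      arr <- epoch_bin_array(eps, es$sample_rate, spec, normalize)
      mean_bins <- apply(arr, c(2, 3), mean)
      attr(mean_bins, "edges") <- 2:20
      for (bnd in names(scheme)) {
        bp <- band_power(mean_bins, scheme[[bnd]])
        rows[[length(rows) + 1L]] <- tibble::tibble(
          subject = es$subject_id, group = es$group, condition = merged,
          electrode = montage, band = bnd, power = as.numeric(bp))
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("band_power_table", class(out))
  out
}

#' Stimulation-minus-rest contrast map
#'
#' Per subject and electrode, the band-power difference
#' Delta = mean over stimulation conditions - rest, for one named band.
#' Negative values at theta frequencies indicate theta suppression under
#' stimulation. Subjects lacking a rest or stimulation entry are dropped
#' with a warning.
#'
#' @param table A `band_power_table` from [condition_table()].
#' @param band Band name present in the table (e.g. `"theta"`).
#' @param stim_rule Which non-rest conditions enter the stimulation mean;
#'   default all of them.
#' @return A `contrast_map`: subjects x electrodes matrix with attributes
#'   `band` and `groups` (named by subject).
#' @export
band_contrast <- function(table, band, stim_rule = NULL) {
  tab <- table[table$band == band, , drop = FALSE]
  if (nrow(tab) == 0) stop("band '", band, "' not present in the table")
  conds <- unique(tab$condition)
  stim <- setdiff(conds, "rest")
  if (!is.null(stim_rule)) stim <- intersect(stim, stim_rule)
  if (length(stim) == 0 || !"rest" %in% conds) {
    stop("table must contain rest and at least one stimulation condition")
  }
  electrodes <- unique(tab$electrode)
  subjects <- unique(tab$subject)
  keep <- vapply(subjects, function(s) {
    have <- unique(tab$condition[tab$subject == s])
    "rest" %in% have && any(stim %in% have)
  }, TRUE)
  if (!all(keep)) {
    warning("dropping subject(s) without both rest and stimulation: ",
            paste(subjects[!keep], collapse = ", "))
    subjects <- subjects[keep]
  }
  if (length(subjects) == 0) stop("no subjects with complete condition data")
  delta <- matrix(NA_real_, length(subjects), length(electrodes),
                  dimnames = list(subjects, electrodes))
  groups <- character(length(subjects))
  for (i in seq_along(subjects)) {
    sub <- tab[tab$subject == subjects[i], ]
    groups[i] <- sub$group[1]
    rest <- sub[sub$condition == "rest", ]
    stim_mean <- tapply(sub$power[sub$condition %in% stim],
                        sub$electrode[sub$condition %in% stim], mean)
    delta[i, ] <- as.numeric(stim_mean[electrodes]) -
      rest$power[match(electrodes, rest$electrode)]
  }
  structure(delta, band = band,
            groups = stats::setNames(groups, subjects),
            class = c("contrast_map", class(delta)))
}
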