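## Cortical-thickness reference distributions (mm, mean and SD per group)
## for the regions examined in the study; used as sampling distributions by
## the morphometry generator.
thickness_reference <- function() {
  rbind(
    data.frame(hemi = "rh",
               region = c("anteriorcingulate", "posteriorcingulate",
                          "middlefrontal", "parahippocampal",
                          "inferiorparietal", "superiorparietal",
                          "paracentral", "postcentral", "precentral",
                          "precuneus", "supramarginal", "insula"),
               control_mean = c(2.7, 2.5, 2.6, 2.8, 2.5, 2.2, 2.5, 2.0, 2.6, 2.4, 2.6, 3.1),
               control_sd   = c(0.3, 0.2, 0.1, 0.3, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1),
               patient_mean = c(2.5, 2.5, 2.6, 2.8, 2.4, 2.2, 2.3, 2.0, 2.3, 2.4, 2.4, 2.9),
               patient_sd   = c(0.2, 0.2, 0.2, 0.3, 0.1, 0.1, 0.1, 0.1, 0.2, 0.1, 0.2, 0.2)),
    data.frame(hemi = "lh",
               region = c("anteriorcingulate", "posteriorcingulate",
                          "middlefrontal", "parahippocampal",
                          "inferiorparietal", "superiorparietal",
                          "paracentral", "postcentral", "precentral",
                          "precuneus", "supramarginal", "insula"),
               control_mean = c(2.8, 2.6, 2.5, 2.8, 2.5, 2.2, 2.4, 2.0, 2.6, 2.4, 2.6, 3.1),
               control_sd   = c(0.2, 0.1, 0.1, 0.3, 0.1, 0.1, 0.2, 0.1, 0.1, 0.1, 0.1, 0.1),
               patient_mean = c(2.7, 2.4, 2.4, 2.9, 2.4, 2.1, 2.3, 2.0, 2.3, 2.4, 2.4, 2.8),
               patient_sd   = c(0.4, 0.2, 0.2, 0.2, 0.1, 0.1, 0.1, 0.1, 0.2, 0.1, 0.2, 0.2))
  )
}

## Subcortical / global volume sampling distributions (voxel counts).
volume_reference <- function() {
  data.frame(
    structure = c("right_putamen", "left_putamen", "right_insula",
                  "left_insula"),
    control_mean = c(5200, 5200, 7600, 7600),
    control_sd   = c(450, 450, 600, 600),
    patient_mean = c(4300, 4350, 6500, 6550),
    patient_sd   = c(500, 500, 650, 650))
}

global_reference <- function() {
  list(total_gray_volume = list(control = c(680000, 45000),
                                patient = c(560000, 55000)),
       surface_holes = list(control = c(30, 12), patient = c(85, 35)))
}

#' Spectral profile of generated EEG
#'
#' The one-sided PSD (uV^2/Hz) targeted by the generator for a subject in a
#' given condition: 1/f background plus flat-topped band components. Used
#' both to synthesize epochs (frequency-domain shaping of white Gaussian
#' noise) and as the analytic reference in spectral-fidelity checks.
#'
#' @param spec A [cohort_spec()].
#' @param subject List with `group` (`"patient"`/`"control"`), latent
#'   suppression `d`, latent beta gain `b`, and optional per-component
#'   multiplicative `factors`.
#' @param condition Condition label (`"rest"` or a stimulation condition).
#' @param freq Frequencies (Hz) at which to evaluate.
#' @return Numeric vector of PSD values at `freq`.
#' @export
generator_psd_profile <- function(spec, subject, condition, freq) {
  bg <- spec$background
  p <- ifelse(freq >= 0.5 & freq <= 45,
              bg$amplitude / pmax(freq, 0.5)^bg$exponent, 0)
  stim <- condition != "rest"
  factors <- subject$factors
  for (nm in names(spec$components)) {
    comp <- spec$components[[nm]]
    pw <- comp$power[[subject$group]]
    if (!is.null(factors) && nm %in% names(factors)) pw <- pw * factors[[nm]]
    if (stim) {
      if (nm == "theta") pw <- pw * (1 - subject$d)
      if (nm == "alpha") pw <- pw * spec$stim_gain[["alpha"]]
      if (nm == "beta")  pw <- pw * spec$stim_gain[["beta"]] * (1 + subject$b)
    }
    inband <- freq >= comp$range[1] & freq < comp$range[2]
    p[inband] <- p[inband] + pw / diff(comp$range)
  }
  p
}

#' Generate synthetic EEG epochs for one subject and condition
#'
#' Each epoch is a realization of a Gaussian process whose one-sided PSD is
#' [generator_psd_profile()]: white Gaussian noise per channel is shaped in
#' the frequency domain (zero-phase band-limited filtering), which makes the
#' oscillatory components narrowband noise rather than pure tones. Channels
#' are independent; the between-subject structure lives in `subject`.
#'
#' @inheritParams generator_psd_profile
#' @param n_epochs Number of epochs to generate.
#' @param epoch_s Epoch length, seconds.
#' @return List of channels x samples matrices (19 x `epoch_s * rate`).
#' @export
generate_eeg <- function(spec, subject, condition, n_epochs,
                         epoch_s = spec$trial_s) {
  validate_cohort_spec(spec)
  fs <- spec$sample_rate
  L <- round(epoch_s * fs)
  nch <- length(montage_electrodes())
  freq <- (seq_len(L) - 1) * fs / L
  # fold to the one-sided grid for profile lookup
  fold <- pmin(freq, fs - freq)
  prof <- generator_psd_profile(spec, subject, condition, fold)
  g <- sqrt(prof * fs / 2)
  g[1] <- 0
  # synthesize directly in the frequency domain: hermitian complex Gaussian
  # coefficients scaled by g; all epochs and channels share one inverse FFT
  half <- if (L %% 2 == 0) L %/% 2 - 1L else (L - 1L) %/% 2
  hi <- seq(2L, 1L + half)           # 1 .. half (0-based k)
  lo <- L + 2L - hi                  # conjugate partners
  ncol_all <- nch * n_epochs
  X <- matrix(0 + 0i, L, ncol_all)
  re <- matrix(stats::rnorm(half * ncol_all), half, ncol_all)
  im <- matrix(stats::rnorm(half * ncol_all), half, ncol_all)
  X[hi, ] <- complex(real = re, imaginary = im) * (g[hi] * sqrt(L / 2))
  X[lo, ] <- Conj(X[hi, ])
  if (L %% 2 == 0) {
    X[L %/% 2 + 1L, ] <- stats::rnorm(ncol_all) * (g[L %/% 2 + 1L] * sqrt(L))
  }
  x <- Re(stats::mvfft(X, inverse = TRUE)) / L    # L x (nch * n_epochs)
  lapply(seq_len(n_epochs), function(i) {
    m <- t(x[, ((i - 1L) * nch + 1L):(i * nch), drop = FALSE])
    rownames(m) <- montage_electrodes()
    m
  })
}

draw_truncnorm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  pmin(pmax(x, lo), hi)
}

# covariate = mean + sd * (r z + sqrt(1-r^2) eps): normal marginal whose
# rank correlation with any monotone transform of z is the copula target
couple_covariate <- function(z, rho_s, mean, sd) {
  r <- copula_pearson(rho_s)
  w <- r * z + sqrt(1 - r^2) * stats::rnorm(length(z))
  mean + sd * w
}

#' Generate morphometry records for a cohort
#'
#' Thickness values are drawn from group-specific normal distributions
#' matching the study's reference means/SDs (truncated to the plausible
#' (0, 6) mm range). Patient volume covariates are monotone (linear-normal)
#' transforms of the latent theta-suppression normal via a Gaussian copula,
#' calibrated so the Spearman correlation with the latent suppression hits
#' the `couplings` target in expectation; surface holes use the negative
#' target. Paracentral/precentral thickness couples to the latent beta
#' enhancement the same way.
#'
#' @param spec A [cohort_spec()].
#' @param ground_truth Data frame from the latent-draw stage of
#'   [simulate_cohort()] (columns subject_id, group, z_d, z_b).
#' @return A `morphometry_set`.
#' @export
generate_morphometry <- function(spec, ground_truth) {
  gt <- ground_truth
  n <- nrow(gt)
  is_pat <- gt$group == "patient"
  th_ref <- thickness_reference()
  coupled_regions <- names(spec$beta_couplings)

  th <- list()
  for (i in seq_len(nrow(th_ref))) {
    row <- th_ref[i, ]
    v <- numeric(n)
    for (grp in c("control", "patient")) {
      sel <- gt$group == grp
      m <- row[[paste0(grp, "_mean")]]; s <- row[[paste0(grp, "_sd")]]
      if (grp == "patient" && row$region %in% coupled_regions) {
        v[sel] <- couple_covariate(gt$z_b[sel],
                                   spec$beta_couplings[[row$region]], m, s)
      } else {
        v[sel] <- stats::rnorm(sum(sel), m, s)
      }
    }
    th[[i]] <- tibble::tibble(subject_id = gt$subject_id, hemi = row$hemi,
                              region = row$region,
                              thickness_mm = pmin(pmax(v, 0.51), 5.9))
  }
  thickness <- do.call(rbind, th)

  vol_ref <- volume_reference()
  vols <- list()
  for (i in seq_len(nrow(vol_ref))) {
    row <- vol_ref[i, ]
    v <- numeric(n)
    v[!is_pat] <- stats::rnorm(sum(!is_pat), row$control_mean, row$control_sd)
    if (row$structure %in% names(spec$couplings)) {
      v[is_pat] <- couple_covariate(gt$z_d[is_pat],
                                    spec$couplings[[row$structure]],
                                    row$patient_mean, row$patient_sd)
    } else {
      v[is_pat] <- stats::rnorm(sum(is_pat), row$patient_mean, row$patient_sd)
    }
    vols[[i]] <- tibble::tibble(subject_id = gt$subject_id,
                                structure = row$structure,
                                volume = pmax(round(v), 0))
  }
  volumes <- do.call(rbind, vols)

  gl <- global_reference()
  tgv <- numeric(n); holes <- numeric(n)
  tgv[!is_pat] <- stats::rnorm(sum(!is_pat), gl$total_gray_volume$control[1],
                               gl$total_gray_volume$control[2])
  tgv[is_pat] <- couple_covariate(gt$z_d[is_pat],
                                  spec$couplings[["total_gray_volume"]],
                                  gl$total_gray_volume$patient[1],
                                  gl$total_gray_volume$patient[2])
  holes[!is_pat] <- stats::rnorm(sum(!is_pat), gl$surface_holes$control[1],
                                 gl$surface_holes$control[2])
  holes[is_pat] <- couple_covariate(gt$z_d[is_pat],
                                    spec$couplings[["surface_holes"]],
                                    gl$surface_holes$patient[1],
                                    gl$surface_holes$patient[2])
  globals <- tibble::tibble(subject_id = gt$subject_id,
                            total_gray_volume = pmax(round(tgv), 0),
                            surface_holes = pmax(round(holes), 0))

  structure(list(thickness = sort_by_cols(thickness, c("subject_id", "hemi", "region")),
                 volumes = sort_by_cols(volumes, c("subject_id", "structure")),
                 globals = sort_by_cols(globals, "subject_id"),
                 raw = tibble::tibble(subject_id = character(0), table = character(0),
                                      column = character(0), value = numeric(0))),
            class = "morphometry_set")
}

#' Generate clinical outcomes for a cohort
#'
#' Patient GOSe values are integers in the observed 3-7 range, rank-coupled
#' to the latent theta suppression through the Gaussian copula at the
#' `gose` coupling target (at |rho| = 0.99, the maximum allowed, GOSe is an
#' essentially deterministic monotone function of the suppression rank);
#' GCS is drawn uniformly from `gcs_range`. Controls get GCS 15 / GOSe 8.
#'
#' @inheritParams generate_morphometry
#' @return Tibble with columns subject_id, group, gcs, gose.
#' @export
generate_outcomes <- function(spec, ground_truth) {
  gt <- ground_truth
  is_pat <- gt$group == "patient"
  gcs <- ifelse(is_pat,
                sample(seq(spec$gcs_range[1], spec$gcs_range[2]),
                       nrow(gt), replace = TRUE),
                15L)
  gose <- integer(nrow(gt))
  gose[!is_pat] <- 8L
  if (any(is_pat)) {
    r <- copula_pearson(spec$couplings[["gose"]])
    w <- r * gt$z_d[is_pat] + sqrt(1 - r^2) * stats::rnorm(sum(is_pat))
    u <- stats::pnorm(w)
    cuts <- cumsum(spec$gose_probs)
    gose[is_pat] <- 3L + findInterval(u, cuts[-length(cuts)],
                                      left.open = TRUE)
  }
  tibble::tibble(subject_id = gt$subject_id, group = gt$group,
                 gcs = as.integer(gcs), gose = as.integer(gose))
}

#' Simulate a complete synthetic study
#'
#' Draws per-subject latents (theta suppression d, beta enhancement b,
#' per-component band-power factors), then generates EEG epoch sets for all
#' five conditions, morphometry tables and clinical outcomes with the
#' coupling structure of [cohort_spec()]. Fully deterministic under the
#' spec's seed: the caller's RNG state is saved and restored.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `synthetic_cohort`: list with `spec`,
#'   `epoch_sets` (named by subject), `morphometry`, `clinical` and
#'   `ground_truth` (subject_id, group, z_d, z_b, d, b).
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  validate_cohort_spec(spec)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  ids <- c(sprintf("P%02d", seq_len(spec$n_patients)),
           sprintf("C%02d", seq_len(spec$n_controls)))
  groups <- rep(c("patient", "control"), c(spec$n_patients, spec$n_controls))
  n <- length(ids)
  z_d <- stats::rnorm(n); z_b <- stats::rnorm(n)
  s_rng <- spec$suppression$range
  b_rng <- spec$beta_enhancement$range
  d <- ifelse(groups == "patient",
              s_rng[1] + diff(s_rng) * stats::pnorm(z_d),
              spec$suppression$control)
  b <- ifelse(groups == "patient",
              b_rng[1] + diff(b_rng) * stats::pnorm(z_b),
              spec$beta_enhancement$control)
  ground_truth <- tibble::tibble(subject_id = ids, group = groups,
                                 z_d = z_d, z_b = z_b, d = d, b = b,
                                 seed = spec$seed)

  epoch_sets <- list()
  comp_names <- names(spec$components)
  for (i in seq_len(n)) {
    factors <- stats::setNames(
      exp(stats::rnorm(length(comp_names), 0, spec$subject_sd)), comp_names)
    subject <- list(group = groups[i], d = d[i], b = b[i], factors = factors)
    eps <- list(rest = generate_eeg(spec, subject, "rest", spec$n_rest,
                                    spec$rest_s))
    for (cond in stimulation_conditions()) {
      eps[[cond]] <- generate_eeg(spec, subject, cond, spec$n_trials,
                                  spec$trial_s)
    }
    epoch_sets[[ids[i]]] <- epoch_set(eps, montage_electrodes(),
                                      spec$sample_rate, ids[i], groups[i])
  }

  morphometry <- generate_morphometry(spec, ground_truth)
  clinical <- generate_outcomes(spec, ground_truth)
  structure(list(spec = spec, epoch_sets = epoch_sets,
                 morphometry = morphometry, clinical = clinical,
                 ground_truth = ground_truth),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects (%d patients / %d controls), seed %d\n",
              length(x$epoch_sets), x$spec$n_patients, x$spec$n_controls,
              x$spec$seed))
  invisible(x)
}

#' Write / read a synthetic cohort on disk
#'
#' Serializes the cohort through the pipeline's own I/O dialects: one
#' recording per subject (epochs concatenated back into a continuous signal
#' with condition annotations), FreeSurfer-style morphometry tables, the
#' clinical table, `cohort.yaml` (the generating spec) and
#' `ground_truth.tsv`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory.
#' @param dialect Recording dialect, see [write_recording()].
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, dialect = "epoch_archive") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  eeg_dir <- file.path(dir, "eeg")
  dir.create(eeg_dir, showWarnings = FALSE)
  ext <- if (dialect == "edf") ".edf" else ".tsv"
  for (es in cohort$epoch_sets) {
    fs <- es$sample_rate
    pieces <- list(); ann <- list(); t0 <- 0
    for (cond in names(es$epochs)) {
      for (ep in es$epochs[[cond]]) {
        pieces[[length(pieces) + 1L]] <- ep
        ann[[length(ann) + 1L]] <- data.frame(
          onset_s = t0, duration_s = ncol(ep) / fs, label = cond)
        t0 <- t0 + ncol(ep) / fs
      }
    }
    rec <- eeg_recording(do.call(cbind, pieces), es$channel_labels, fs,
                         do.call(rbind, ann), es$subject_id, es$group)
    write_recording(rec, file.path(eeg_dir, paste0(es$subject_id, ext)),
                    dialect)
  }
  write_morphometry(cohort$morphometry, file.path(dir, "morphometry"))
  write_clinical(cohort$clinical, file.path(dir, "clinical.tsv"))
  write_cohort_spec(cohort$spec, file.path(dir, "cohort.yaml"))
  utils::write.table(cohort$ground_truth, file.path(dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @param dir Directory written by [write_cohort()].
#' @export
read_cohort <- function(dir, dialect = "epoch_archive") {
  # fail fast on missing tables before any EEG is read
  required <- c("cohort.yaml", "clinical.tsv",
                file.path("morphometry", c("lh.aparc.thickness.tsv",
                                           "rh.aparc.thickness.tsv",
                                           "aseg.volume.tsv")))
  missing <- required[!file.exists(file.path(dir, required))]
  if (length(missing) > 0) {
    stop("cohort directory ", dir, " is missing: ",
         paste(missing, collapse = ", "))
  }
  spec <- read_cohort_spec(file.path(dir, "cohort.yaml"))
  ext <- if (dialect == "edf") ".edf" else ".tsv"
  files <- sort(list.files(file.path(dir, "eeg"),
                           pattern = paste0("\\", ext, "$"), full.names = TRUE))
  epoch_sets <- list()
  for (f in files) {
    rec <- read_recording(f, dialect)
    es <- extract_epochs(rec, epoch_length_s = spec$trial_s)
    epoch_sets[[es$subject_id]] <- es
  }
  gt_path <- file.path(dir, "ground_truth.tsv")
  ground_truth <- if (file.exists(gt_path)) {
    tibble::as_tibble(utils::read.delim(gt_path, stringsAsFactors = FALSE))
  } else NULL
  structure(list(spec = spec, epoch_sets = epoch_sets,
                 morphometry = read_morphometry(
                   list(lh = file.path(dir, "morphometry", "lh.aparc.thickness.tsv"),
                        rh = file.path(dir, "morphometry", "rh.aparc.thickness.tsv")),
                   file.path(dir, "morphometry", "aseg.volume.tsv")),
                 clinical = read_clinical(file.path(dir, "clinical.tsv")),
                 ground_truth = ground_truth),
            class = "synthetic_cohort")
}
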