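#' Synthetic cohort specification
#'
#' Parameters of the synthetic study generator. The defaults reproduce the
#' study conditions: 10 patients vs 15 controls, 250 Hz, 19-channel 10-20
#' montage, 4 stimulus types x 10 trials x 10 s and 40 rest fragments x
#' 10 s per subject. Spectra are 1/f background noise plus band-limited
#' Gaussian components whose power depends on group and condition; patients
#' at rest have elevated slow-wave (2-6 Hz) and reduced alpha/beta power,
#' stimulation raises alpha/beta power in both groups and multiplies the
#' theta component by (1 - d) where d is the subject's latent theta
#' suppression. Morphometry covariates and the GOSe outcome are rank-coupled
#' to d through a Gaussian copula at the target Spearman correlations in
#' `couplings`; `beta_couplings` couples paracentral/precentral thickness to
#' the latent beta enhancement.
#'
#' @param n_patients,n_controls Group sizes.
#' @param sample_rate Sampling rate, Hz.
#' @param n_trials Trials per stimulus type.
#' @param trial_s Trial (epoch) length, seconds.
#' @param n_rest Number of 10-s rest fragments.
#' @param rest_s Rest fragment length, seconds.
#' @param background `list(amplitude, exponent)` of the 1/f background:
#'   PSD amplitude/f^exponent (uV^2/Hz) over 0.5-45 Hz. The default
#'   amplitude puts the control resting alpha signal-to-background ratio
#'   near 2.
#' @param components Named list of oscillatory components, each
#'   `list(range = c(lo, hi), power = c(control, patient))` with power in
#'   uV^2 at rest.
#' @param stim_gain Multipliers applied to alpha and beta component power
#'   under stimulation (both groups).
#' @param suppression `list(range = c(lo, hi), control)`: patient theta
#'   suppression d is a monotone transform of a standard-normal latent into
#'   `range`; controls get the fixed value `control`.
#' @param beta_enhancement Same structure for the latent beta gain b
#'   (stimulation beta power is further multiplied by 1 + b).
#' @param subject_sd Log-scale SD of per-subject band-power factors
#'   (between-subject dispersion).
#' @param couplings Named target Spearman correlations between latent theta
#'   suppression d and each patient covariate; negative for surface holes.
#' @param beta_couplings Target Spearman correlations between latent beta
#'   gain and coupled thickness regions.
#' @param gose_probs Probabilities of GOSe values 3..7 in the patient group.
#' @param gcs_range Patient GCS values sampled uniformly from this range.
#' @param seed Integer seed; the whole cohort regenerates bit-identically
#'   from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 10, n_controls = 15,
                        sample_rate = 250,
                        n_trials = 10, trial_s = 10,
                        n_rest = 40, rest_s = 10,
                        background = list(amplitude = 37, exponent = 1),
                        components = list(
                          delta = list(range = c(2, 4), power = c(control = 15, patient = 45)),
                          theta = list(range = c(4, 6), power = c(control = 12, patient = 40)),
                          alpha = list(range = c(9, 13), power = c(control = 30, patient = 8)),
                          beta  = list(range = c(16, 20), power = c(control = 10, patient = 3))),
                        stim_gain = c(alpha = 1.3, beta = 1.4),
                        suppression = list(range = c(0, 0.6), control = 0),
                        beta_enhancement = list(range = c(0, 0.4), control = 0),
                        subject_sd = 0.25,
                        couplings = c(total_gray_volume = 0.85,
                                      right_putamen = 0.85,
                                      right_insula = 0.85,
                                      surface_holes = -0.85,
                                      gose = 0.85),
                        beta_couplings = c(paracentral = 0.8, precentral = 0.8),
                        gose_probs = c(`3` = 0.4, `4` = 0, `5` = 0.3,
                                       `6` = 0.2, `7` = 0.1),
                        gcs_range = c(5, 7),
                        seed = 1012L) {
  spec <- structure(
    list(n_patients = n_patients, n_controls = n_controls,
         sample_rate = sample_rate, n_trials = n_trials, trial_s = trial_s,
         n_rest = n_rest, rest_s = rest_s, background = background,
         components = components, stim_gain = stim_gain,
         suppression = suppression, beta_enhancement = beta_enhancement,
         subject_sd = subject_sd, couplings = couplings,
         beta_couplings = beta_couplings, gose_probs = gose_probs,
         gcs_range = gcs_range, seed = as.integer(seed)),
    class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  if (spec$n_patients < 1 || spec$n_controls < 1) stop("group sizes must be positive")
  if (spec$sample_rate <= 0) stop("sample_rate must be positive")
  if (spec$n_trials < 1 || spec$n_rest < 1) stop("trial and rest counts must be positive")
  if (spec$subject_sd <= 0) stop("subject_sd (dispersion) must be > 0")
  if (spec$background$amplitude <= 0 || spec$background$exponent < 0) {
    stop("background amplitude must be > 0 and exponent >= 0")
  }
  for (nm in names(spec$components)) {
    comp <- spec$components[[nm]]
    if (comp$range[1] >= comp$range[2]) stop("component '", nm, "' has an empty band")
    if (any(comp$power < 0)) stop("component '", nm, "' has negative power")
  }
  rhos <- c(spec$couplings, spec$beta_couplings)
  if (any(abs(rhos) > 0.99)) {
    stop("unreachable target correlation (|rho| > 0.99): ",
         paste(names(rhos)[abs(rhos) > 0.99], collapse = ", "))
  }
  if (any(abs(rhos) > 1)) stop("target correlations must lie in [-1, 1]")
  if (abs(sum(spec$gose_probs) - 1) > 1e-9) stop("gose_probs must sum to 1")
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %d patients / %d controls, %g Hz, %d trials x %g s per stimulus, %d rest x %g s, seed %d\n",
              x$n_patients, x$n_controls, x$sample_rate, x$n_trials,
              x$trial_s, x$n_rest, x$rest_s, x$seed))
  invisible(x)
}

#' Save / load a cohort spec as YAML
#'
#' `cohort.yaml` documents every generator default alongside the data it
#' produced; loading it back reconstructs an identical spec.
#'
#' @param spec A [cohort_spec()].
#' @param path YAML file path.
#' @return `write_cohort_spec` returns `path`; `read_cohort_spec` the spec.
#' @export
write_cohort_spec <- function(spec, path) {
  # yaml serializes named atomic vectors as plain sequences; convert them
  # to lists so the names survive the round trip
  friendly <- function(x) {
    if (is.list(x)) lapply(x, friendly)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(friendly(unclass(spec)), path)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$stim_gain <- unlist(raw$stim_gain)
  raw$couplings <- unlist(raw$couplings)
  raw$beta_couplings <- unlist(raw$beta_couplings)
  raw$gose_probs <- unlist(raw$gose_probs)
  raw$gcs_range <- unlist(raw$gcs_range)
  raw$suppression$range <- unlist(raw$suppression$range)
  raw$beta_enhancement$range <- unlist(raw$beta_enhancement$range)
  raw$components <- lapply(raw$components, function(c_) {
    list(range = unlist(c_$range), power = unlist(c_$power))
  })
  do.call(cohort_spec, raw)
}

# latent Pearson correlation that yields Spearman rho_s under a Gaussian copula
copula_pearson <- function(rho_s) 2 * sin(pi * rho_s / 6)
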