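test_that("the cohort regenerates bit-identically from its seed", {
  spec <- cohort_spec(n_patients = 2, n_controls = 2, n_trials = 2,
                      n_rest = 3, seed = 123)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_identical(a$epoch_sets, b$epoch_sets)
  expect_identical(a$morphometry, b$morphometry)
  expect_identical(a$clinical, b$clinical)
})

test_that("generated spectra match the generator's analytic band targets", {
  spec <- cohort_spec(seed = 7)
  subject <- list(group = "control", d = 0, b = 0)
  set.seed(7)
  eps <- generate_eeg(spec, subject, "rest", 120)
  # independent estimate: rectangular periodogram averaged over epochs
  acc <- 0
  for (ep in eps) {
    ps <- compute_psd(ep, 250, window_spec("rectangular"))
    acc <- acc + ps$psd
  }
  psd_hat <- acc / length(eps)
  freq <- compute_psd(eps[[1]], 250, window_spec("rectangular"))$freq
  prof <- generator_psd_profile(spec, subject, "rest", freq)
  for (band in list(c(2, 4), c(4, 6), c(9, 13), c(16, 20))) {
    sel <- freq >= band[1] & freq < band[2]
    df <- freq[2] - freq[1]
    got <- mean(rowSums(psd_hat[, sel]) * df)        # mean over channels
    want <- sum(prof[sel]) * df
    expect_lt(abs(got - want) / want, 0.10)
  }
})

test_that("patients at rest have more slow-wave and less alpha/beta power", {
  spec <- cohort_spec(seed = 21)
  set.seed(21)
  pat <- generate_eeg(spec, list(group = "patient", d = 0, b = 0), "rest", 100)
  ctl <- generate_eeg(spec, list(group = "control", d = 0, b = 0), "rest", 100)
  bp <- function(eps, band) {
    vapply(eps, function(ep) {
      mean(band_power(integrate_bins(compute_psd(ep[1:3, , drop = FALSE], 250)),
                      band))
    }, 0)
  }
  expect_gt(mean(bp(pat, c(2, 6))), mean(bp(ctl, c(2, 6))))
  expect_lt(mean(bp(pat, c(8, 12))), mean(bp(ctl, c(8, 12))))
  expect_lt(mean(bp(pat, c(16, 20))), mean(bp(ctl, c(16, 20))))
})

test_that("zero suppression leaves stimulation theta power at rest level", {
  spec <- cohort_spec(seed = 33)
  subject <- list(group = "patient", d = 0, b = 0)
  set.seed(33)
  rest <- generate_eeg(spec, subject, "rest", 40)
  stim <- generate_eeg(spec, subject, "slow_soft", 40)
  # absolute theta power per epoch (channel-averaged); gains touch alpha/beta
  theta <- function(eps) vapply(eps, function(ep) {
    mean(band_power(integrate_bins(compute_psd(ep, 250)), c(4, 6)))
  }, 0)
  p <- wilcox.test(theta(stim), theta(rest))$p.value
  expect_gt(p, 0.01)
})

test_that("suppression shows up as a negative theta contrast for patients", {
  spec <- cohort_spec(seed = 13)
  subject <- list(group = "patient", d = 0.5, b = 0)
  set.seed(13)
  rest <- generate_eeg(spec, subject, "rest", 30)
  stim <- generate_eeg(spec, subject, "fast_hard", 30)
  theta <- function(eps) mean(vapply(eps, function(ep) {
    mean(band_power(integrate_bins(compute_psd(ep, 250)), c(4, 6)))
  }, 0))
  expect_lt(theta(stim), theta(rest))
})

test_that("morphometry distributions and copula couplings are calibrated", {
  spec <- cohort_spec(n_patients = 100, n_controls = 2, seed = 55)
  set.seed(55)
  n <- 102
  gt <- tibble::tibble(
    subject_id = sprintf("S%03d", 1:n),
    group = rep(c("patient", "control"), c(100, 2)),
    z_d = rnorm(n), z_b = rnorm(n),
    d = pnorm(z_d) * 0.6, b = pnorm(z_b) * 0.4)
  ms <- generate_morphometry(spec, gt)
  # patient right precentral thickness matches its reference distribution
  th <- ms$thickness
  pre <- th$thickness_mm[th$hemi == "rh" & th$region == "precentral" &
                           th$subject_id %in% gt$subject_id[gt$group == "patient"]]
  expect_gt(mean(pre), 2.3 - 0.2)
  expect_lt(mean(pre), 2.3 + 0.2)
  expect_true(all(th$thickness_mm > 0 & th$thickness_mm < 6))
  # coupling at rho 0.85: empirical Spearman vs latent suppression
  pat <- gt$group == "patient"
  put <- ms$volumes[ms$volumes$structure == "right_putamen", ]
  rho <- cor(gt$d[pat], put$volume[match(gt$subject_id[pat], put$subject_id)],
             method = "spearman")
  expect_gt(rho, 0.75); expect_lt(rho, 0.92)
  holes <- ms$globals$surface_holes[match(gt$subject_id[pat], ms$globals$subject_id)]
  expect_lt(cor(gt$d[pat], holes, method = "spearman"), -0.7)
})

test_that("zero coupling decouples covariates from suppression", {
  spec <- cohort_spec(n_patients = 100, n_controls = 2,
                      couplings = c(total_gray_volume = 0, right_putamen = 0,
                                    right_insula = 0, surface_holes = 0,
                                    gose = 0),
                      seed = 56)
  set.seed(56)
  n <- 102
  gt <- tibble::tibble(
    subject_id = sprintf("S%03d", 1:n),
    group = rep(c("patient", "control"), c(100, 2)),
    z_d = rnorm(n), z_b = rnorm(n),
    d = pnorm(z_d) * 0.6, b = pnorm(z_b) * 0.4)
  ms <- generate_morphometry(spec, gt)
  cl <- generate_outcomes(spec, gt)
  pat <- gt$group == "patient"
  put <- ms$volumes[ms$volumes$structure == "right_putamen", ]
  rho <- cor(gt$d[pat], put$volume[match(gt$subject_id[pat], put$subject_id)],
             method = "spearman")
  expect_lt(abs(rho), 0.3)
  rho_g <- cor(gt$d[pat], cl$gose[match(gt$subject_id[pat], cl$subject_id)],
               method = "spearman")
  expect_gt(cor.test(gt$d[pat], cl$gose[match(gt$subject_id[pat], cl$subject_id)],
                     method = "spearman", exact = FALSE)$p.value, 0.05)
})

test_that("outcomes stay in the observed GOSe range and saturate at maximal coupling", {
  spec <- cohort_spec(seed = 77)
  coh <- small_cohort()
  pat <- coh$clinical[coh$clinical$group == "patient", ]
  expect_true(all(pat$gose %in% 3:7))
  expect_true(all(pat$gcs >= 5 & pat$gcs <= 7))
  ctl <- coh$clinical[coh$clinical$group == "control", ]
  expect_true(all(ctl$gose == 8L))
  # near-maximal coupling: GOSe is a monotone step function of suppression rank
  spec_max <- cohort_spec(n_patients = 50, n_controls = 1,
                          couplings = c(total_gray_volume = 0.85,
                                        right_putamen = 0.85,
                                        right_insula = 0.85,
                                        surface_holes = -0.85, gose = 0.99),
                          seed = 78)
  set.seed(78)
  gt <- tibble::tibble(subject_id = sprintf("S%02d", 1:51),
                       group = rep(c("patient", "control"), c(50, 1)),
                       z_d = rnorm(51), z_b = rnorm(51),
                       d = pnorm(z_d) * 0.6, b = pnorm(z_b) * 0.4)
  cl <- generate_outcomes(spec_max, gt)
  pat <- gt$group == "patient"
  expect_gt(cor(gt$d[pat], cl$gose[pat], method = "spearman"), 0.9)
})

test_that("unreachable coupling targets are rejected", {
  expect_error(cohort_spec(couplings = c(total_gray_volume = 0.999,
                                         right_putamen = 0.85,
                                         right_insula = 0.85,
                                         surface_holes = -0.85, gose = 0.85)),
               "unreachable")
})

test_that("cohort spec round-trips through YAML", {
  spec <- reduced_spec(seed = 4242)
  p <- file.path(withr::local_tempdir(), "cohort.yaml")
  write_cohort_spec(spec, p)
  back <- read_cohort_spec(p)
  expect_equal(back, spec)
})
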