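# direct DFT periodogram oracle (independent of compute_psd internals)
periodogram_oracle <- function(x, rate) {
  x <- x - mean(x)
  n <- length(x)
  X <- fft(x)
  nf <- n %/% 2 + 1
  p <- Mod(X[1:nf])^2 / (n * rate)
  dbl <- rep(2, nf); dbl[1] <- 1; if (n %% 2 == 0) dbl[nf] <- 1
  list(freq = (0:(nf - 1)) * rate / n, psd = p * dbl)
}

test_that("PSD equals the direct DFT periodogram in rectangular mode", {
  set.seed(10)
  x <- rnorm(2500)
  ps <- compute_psd(x, 250, window_spec("rectangular"))
  or <- periodogram_oracle(x, 250)
  expect_equal(ps$freq, or$freq)
  expect_equal(as.numeric(ps$psd), or$psd, tolerance = 1e-12)
})

test_that("total PSD power matches time-domain variance (Parseval)", {
  set.seed(11)
  x <- rnorm(5000)
  ps <- compute_psd(x, 250, window_spec("rectangular"))
  df <- ps$freq[2] - ps$freq[1]
  expect_equal(sum(ps$psd) * df, mean((x - mean(x))^2), tolerance = 1e-10)
})

test_that("PSD handles degenerate and invalid epochs", {
  z <- matrix(0, 19, 2500, dimnames = list(montage_electrodes(), NULL))
  ps <- compute_psd(z, 250)
  expect_true(all(ps$psd == 0))
  expect_error(compute_psd(matrix(1, 19, 100), 250), "at least 2 s")
  bad <- z; bad[1, 1] <- NA
  expect_error(compute_psd(bad, 250), "NA")
})

test_that("a pure tone concentrates its power in the containing unit bin", {
  t <- (0:2499) / 250
  for (f0 in c(4.5, 10.5, 17.5)) {
    x <- sin(2 * pi * f0 * t)
    bins <- integrate_bins(compute_psd(x, 250, window_spec("rectangular")))
    target <- paste(floor(f0), floor(f0) + 1, sep = "-")
    expect_gt(bins[1, target] / sum(bins), 0.90)
  }
})

test_that("normalization makes bins sum to one and is scale invariant", {
  ep <- toy_signal(2500)
  ps <- compute_psd(ep, 250)
  bins <- integrate_bins(normalize_spectrum(ps))
  expect_equal(unname(rowSums(bins)), rep(1, 19), tolerance = 1e-12)
  ps10 <- compute_psd(ep * 10, 250)
  expect_equal(normalize_spectrum(ps10)$psd, normalize_spectrum(ps)$psd,
               tolerance = 1e-12)
  # pass-through mode leaves the spectrum untouched
  expect_identical(normalize_spectrum(ps, "none"), ps)
  z <- compute_psd(matrix(0, 19, 2500), 250)
  expect_error(normalize_spectrum(z), "zero total power")
})

test_that("bin integration is exact quadrature of the piecewise-linear PSD", {
  set.seed(12)
  ps <- compute_psd(rnorm(2500), 250, window_spec("rectangular"))
  bins <- integrate_bins(ps)
  # sum over the 18 bins equals the direct integral over [2, 20)
  direct <- sum(vapply(seq_along(ps$freq)[-1], function(i) {
    a <- ps$freq[i - 1]; b <- ps$freq[i]
    x1 <- max(a, 2); x2 <- min(b, 20)
    if (x2 <= x1) return(0)
    pa <- ps$psd[1, i - 1]; pb <- ps$psd[1, i]
    f <- function(x) pa + (pb - pa) * (x - a) / (b - a)
    (x2 - x1) * (f(x1) + f(x2)) / 2
  }, 0))
  expect_equal(sum(bins), direct, tolerance = 1e-9)
  # constant spectral density -> equal bins
  flat <- structure(list(freq = seq(0, 125, by = 0.5),
                         psd = matrix(3, 1, 251)), class = "eeg_spectrum")
  fb <- integrate_bins(flat)
  expect_equal(as.numeric(fb), rep(3, 18))
  # grid coarser than 1 Hz is rejected
  coarse <- structure(list(freq = seq(0, 125, by = 2), psd = matrix(1, 1, 63)),
                      class = "eeg_spectrum")
  expect_error(integrate_bins(coarse), "coarser")
})

test_that("band_power averages the member bins", {
  bins <- matrix(seq_len(18), 1, dimnames = list("Cz", NULL))
  attr(bins, "edges") <- 2:20
  # theta 4-6 = mean of bins [4,5) and [5,6) (positions 3 and 4)
  expect_equal(band_power(bins, c(4, 6)), c(Cz = mean(c(3, 4))))
  expect_equal(band_power(bins, c(5, 6)), c(Cz = 4))
  expect_equal(band_power(bins, c(17, 20)), c(Cz = mean(c(16, 17, 18))))
  expect_error(band_power(bins, c(19, 21)), "outside")
  expect_error(band_scheme(list(bad = c(3.5, 6))), "integer edges")
})

test_that("condition_table matches a brute-force loop and merges valences", {
  es <- small_cohort()$epoch_sets[[1]]
  tab <- condition_table(list(es), band_scheme("contrast"),
                         merge_rule = "per_stimulus")
  # brute force: average per-epoch normalized bin spectra, then band mean
  brute <- function(cond, band) {
    mats <- lapply(es$epochs[[cond]], function(ep) {
      integrate_bins(normalize_spectrum(compute_psd(ep, es$sample_rate)))
    })
    mean_bins <- Reduce(`+`, mats) / length(mats)
    attr(mean_bins, "edges") <- 2:20
    band_power(mean_bins, band)
  }
  for (cond in c("rest", "slow_soft")) {
    got <- tab$power[tab$condition == cond & tab$band == "theta"]
    expect_equal(got, unname(brute(cond, c(4, 6))), tolerance = 1e-12)
  }
  # identical epochs -> merge is idempotent
  es2 <- epoch_set(list(rest = rep(es$epochs$rest[1], 5),
                        slow_soft = es$epochs$slow_soft[1]),
                   es$channel_labels, es$sample_rate, "X", "control")
  t2 <- condition_table(list(es2), band_scheme("contrast"))
  one <- band_power(integrate_bins(normalize_spectrum(
    compute_psd(es$epochs$rest[[1]], es$sample_rate))), c(4, 6))
  expect_equal(t2$power[t2$condition == "rest" & t2$band == "theta"],
               unname(one), tolerance = 1e-12)
  # valence merge pools soft-brush conditions: 2 x 10 trials x 10 s = 200 s
  tv <- condition_table(list(es), band_scheme("contrast"),
                        merge_rule = "valence_pairs")
  expect_setequal(unique(tv$condition), c("rest", "pleasant", "unpleasant"))
})

test_that("band_contrast is stimulation minus rest with toy arithmetic", {
  tab <- tibble::tibble(
    subject = rep("S1", 6), group = "patient",
    condition = rep(c("rest", "stim_a", "stim_b"), each = 2),
    electrode = rep(c("Cz", "Pz"), 3),
    band = "theta",
    power = c(10, 20, 6, 14, 8, 18))
  tab$condition <- sub("stim_a", "slow_soft", tab$condition)
  tab$condition <- sub("stim_b", "fast_hard", tab$condition)
  cm <- band_contrast(tab, "theta")
  expect_equal(unname(cm["S1", "Cz"]), mean(c(6, 8)) - 10)
  expect_equal(unname(cm["S1", "Pz"]), mean(c(14, 18)) - 20)
  # identical stim and rest -> zero
  tab0 <- tab; tab0$power <- rep(c(10, 20), 3)
  expect_equal(unname(band_contrast(tab0, "theta")["S1", ]), c(0, 0))
  expect_error(band_contrast(tab, "gamma"), "not present")
})
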