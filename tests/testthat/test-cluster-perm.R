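test_that("Spearman rho is the midrank Pearson correlation", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  y <- c(2, 7, 1, 8, 2, 8, 1, 8)   # heavy ties
  got <- spearman_rho(x, y)
  # direct formula oracle on midranks
  rx <- rank(x); ry <- rank(y)
  want <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(got, cor(x, y, method = "spearman"), tolerance = 1e-12)
  expect_equal(spearman_rho(1:8, (1:8)^3), 1)
  expect_equal(spearman_rho(1:8, rev(1:8)), -1)
  expect_warning(z <- spearman_rho(rep(1, 5), 1:5), "zero variance")
  expect_true(is.na(z))
  expect_error(spearman_rho(1:3, 1:3), "at least 4")
})

test_that("rho-to-t uses the standard transform and is monotone", {
  expect_equal(rho_to_t(0, 10), 0)
  expect_equal(rho_to_t(0.8, 10), 0.8 * sqrt(8 / 0.36))
  rhos <- seq(-0.95, 0.95, by = 0.05)
  expect_true(all(diff(rho_to_t(rhos, 12)) > 0))
  expect_identical(rho_to_t(1, 10), Inf)
  expect_identical(rho_to_t(-1, 10), -Inf)
  expect_error(rho_to_t(0.5, 3), "n >= 4")
})

test_that("threshold_map matches a sorted-array quantile oracle", {
  set.seed(20)
  null_t <- rnorm(5000)
  tmap <- setNames(c(-4, 0.1, 3.5, rep(0, 16)), montage_electrodes())
  res <- threshold_map(tmap, null_t)
  s <- sort(null_t)
  # type-7 quantile oracle
  q_oracle <- function(p) {
    h <- (length(s) - 1) * p + 1
    s[floor(h)] + (h - floor(h)) * (s[floor(h) + 1] - s[floor(h)])
  }
  expect_equal(res$thresholds, c(q_oracle(0.025), q_oracle(0.975)),
               tolerance = 1e-12)
  expect_equal(which(res$positive), 3L, ignore_attr = TRUE)
  expect_equal(which(res$negative), 1L, ignore_attr = TRUE)
  # all-zero map with symmetric null: nothing supra-threshold
  zero <- setNames(rep(0, 19), montage_electrodes())
  res0 <- threshold_map(zero, null_t)
  expect_false(any(res0$positive | res0$negative))
  expect_error(threshold_map(tmap, rep(1, 100)), "degenerate")
})

test_that("clusters follow montage adjacency with sign separation", {
  adj <- montage_adjacency()
  tmap <- setNames(rep(0, 19), montage_electrodes())
  pos <- neg <- setNames(rep(FALSE, 19), montage_electrodes())
  # singleton survives at min size 1
  tmap["Fz"] <- 3.1; pos["Fz"] <- TRUE
  cl <- form_clusters(pos, neg, tmap, adj)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$mass, 3.1)
  expect_equal(cl$electrodes, "Fz")
  # two adjacent electrodes merge (C3 ~ Cz on the montage)
  tmap[c("C3", "Cz")] <- c(2, 2.5); pos[c("C3", "Cz")] <- TRUE; pos["Fz"] <- FALSE
  tmap["Fz"] <- 0
  cl <- form_clusters(pos, neg, tmap, adj)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$mass, 4.5)
  expect_equal(cl$size, 2)
  # two non-adjacent electrodes stay separate singletons (Fp1 vs O2)
  pos[] <- FALSE; pos[c("Fp1", "O2")] <- TRUE
  tmap[] <- 0; tmap[c("Fp1", "O2")] <- c(2.2, 2.8)
  cl <- form_clusters(pos, neg, tmap, adj)
  expect_equal(nrow(cl), 2)
  expect_setequal(cl$electrodes, c("Fp1", "O2"))
  # opposite signs never merge even when adjacent
  neg["Fp2"] <- TRUE; tmap["Fp2"] <- -2.5
  cl <- form_clusters(pos, neg, tmap, adj)
  expect_equal(nrow(cl), 3)
  # min size discards small components
  cl2 <- form_clusters(pos, neg, tmap, adj, min_size = 2)
  expect_equal(nrow(cl2), 0)
})

test_that("the permutation test is deterministic and hits the p floor", {
  set.seed(30)
  n <- 12
  d <- sort(runif(n))
  cm <- flat_contrast(-d) + matrix(rnorm(n * 19, 0, 0.02), n, 19)
  covv <- setNames(d * 1000 + rnorm(n, 0, 20), rownames(cm))
  res <- permutation_test(cm, covv, config = perm_config(seed = 44),
                          covariate_name = "volume")
  res2 <- permutation_test(cm, covv, config = perm_config(seed = 44),
                           covariate_name = "volume")
  expect_identical(res$clusters, res2$clusters)
  expect_equal(res$n_permutations, 500L)
  # strong negative association: the dominant cluster is negative and at
  # the add-one floor 1/501, displayed as 0.002
  main <- res$clusters[which.max(abs(res$clusters$mass)), ]
  expect_equal(main$sign, -1)
  expect_equal(main$p, 1 / 501)
  expect_equal(round(main$p, 3), 0.002)
  # p is invariant under strictly monotone transforms of the covariate
  res3 <- permutation_test(cm, exp(covv / 500),
                           config = perm_config(seed = 44))
  expect_equal(res3$clusters$p, res$clusters$p)
})

# all permutations of 1..n (small n), recursive; avoids any dependency
all_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

test_that("random permutation p agrees with exhaustive enumeration at n = 5", {
  set.seed(33)
  n <- 5
  cm <- flat_contrast(c(-1, -0.5, 0, 0.5, 1)) +
    matrix(rnorm(n * 19, 0, 0.25), n, 19)
  covv <- c(5, 4, 3, 1, 2)
  adj <- montage_adjacency()
  cfg <- perm_config(n_permutations = 500, seed = 8)
  res <- permutation_test(cm, covv, adj, cfg)
  expect_gt(nrow(res$clusters), 0)

  # exhaustive oracle over all 120 permutations, using the same thresholds
  perms <- all_permutations(n)
  rx <- apply(cm, 2, rank)
  null_max <- apply(perms, 1, function(p) {
    t_vals <- rho_to_t(as.numeric(cor(rx, rank(covv)[p])), n)
    m <- 0
    pos <- t_vals > res$thresholds[2]; neg <- t_vals < res$thresholds[1]
    for (comp in connected_components(which(pos), adj)) {
      m <- max(m, abs(sum(t_vals[comp])))
    }
    for (comp in connected_components(which(neg), adj)) {
      m <- max(m, abs(sum(t_vals[comp])))
    }
    m
  })
  for (i in seq_len(nrow(res$clusters))) {
    p_exact <- mean(null_max >= abs(res$clusters$mass[i]))
    se <- sqrt(p_exact * (1 - p_exact) / 500)
    expect_lt(abs(res$clusters$p[i] - p_exact), 3 * se + 2 / 500)
  }
})

test_that("constant or missing covariates are handled explicitly", {
  cm <- flat_contrast(rnorm(8))
  expect_error(permutation_test(cm, rep(1, 8)), "constant")
  covv <- c(1:7, NA)
  expect_warning(res <- permutation_test(cm, covv,
                                         config = perm_config(seed = 2)),
                 "missing")
  expect_equal(res$n, 7)
  expect_error(permutation_test(cm[1:4, ], 1:4), "at least 5")
})

test_that("the covariate battery recovers the generator's coupling signs", {
  coh <- cached("battery_cohort", function() {
    simulate_cohort(cohort_spec(n_controls = 2, seed = 7003))
  })
  cm <- theta_contrast_of(coh)
  batt <- run_covariate_battery(cm, coh$morphometry, coh$clinical,
                                perm_config(seed = 11))
  expect_named(batt, c("total_gray_volume", "right_putamen", "right_insula",
                       "surface_holes", "gose", "paracentral_thickness",
                       "precentral_thickness"))
  # contrast is stim - rest: suppression-coupled volumes associate
  # negatively, surface holes positively
  dominant_sign <- function(nm) {
    cl <- batt[[nm]]$clusters
    cl$sign[which.max(abs(cl$mass))]
  }
  for (nm in c("total_gray_volume", "right_putamen", "right_insula", "gose")) {
    expect_equal(dominant_sign(nm), -1, label = nm)
  }
  expect_equal(dominant_sign("surface_holes"), 1)
  # strong coupling reaches corrected significance for coupled covariates
  n_sig <- sum(vapply(batt, function(r) any(r$clusters$significant), TRUE))
  expect_gte(n_sig, 2)
  sig <- function(nm) {
    cl <- batt[[nm]]$clusters
    cl[cl$significant, , drop = FALSE]
  }
  expect_true(all(sig("total_gray_volume")$sign == -1))
  expect_true(all(sig("surface_holes")$sign == 1))
  expect_true(all(sig("gose")$sign == -1))
  # determinism under the same seed
  batt2 <- run_covariate_battery(cm, coh$morphometry, coh$clinical,
                                 perm_config(seed = 11))
  expect_identical(lapply(batt, `[[`, "clusters"),
                   lapply(batt2, `[[`, "clusters"))
  expect_error(run_covariate_battery(cm, coh$morphometry, coh$clinical,
                                     covariates = "nope"),
               "available")
})
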