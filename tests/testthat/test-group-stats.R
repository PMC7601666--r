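# exhaustive permutation oracle for the rank-sum test (no ties)
rank_sum_perm_oracle <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - na * (na + 1) / 2
  }
  u_obs <- u_of(seq_len(na))
  splits <- combn(n, na)
  us <- apply(splits, 2, u_of)
  mu <- na * (n - na) / 2
  # two-sided: as-or-more extreme distance from the null mean
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

test_that("Mann-Whitney U agrees with the exhaustive permutation oracle", {
  # all untied integer samples with n_a + n_b <= 10
  set.seed(1)
  for (na in 2:5) for (nb in 2:5) {
    x <- sample(1:50, na + nb)
    a <- x[seq_len(na)]; b <- x[-seq_len(na)]
    res <- mann_whitney_u(a, b)
    expect_true(res$exact)
    expect_equal(res$p, rank_sum_perm_oracle(a, b), tolerance = 1e-12,
                 label = sprintf("p for n_a=%d n_b=%d", na, nb))
  }
  # canonical cases
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(res$statistic), 0)
  expect_equal(res$p, 0.1)   # 2 of C(6,3)=20 arrangements as extreme
  big <- mann_whitney_u(rep(c(1, 2), 10), rep(c(1, 2), 10))
  expect_false(big$exact)
  expect_equal(unname(big$statistic), 20 * 20 / 2)  # n_a n_b / 2
  expect_gt(big$p, 0.99)
})

test_that("identical samples give the null U and a z near zero", {
  a <- c(1.5, 2.5, 3.5, 4.5, 5.5, 6.5)
  res <- mann_whitney_u(a, a)
  expect_equal(unname(res$statistic), length(a)^2 / 2)
  expect_gt(res$p, 0.99)
  expect_equal(res$z, 0, tolerance = 1e-12)
})

test_that("rm_anova reproduces a hand-worked 2x2 decomposition", {
  # 2 subjects per group, 2 conditions; cell values chosen for easy sums
  d <- data.frame(
    subject = rep(c("s1", "s2", "s3", "s4"), each = 2),
    group = rep(c("g1", "g1", "g2", "g2"), each = 2),
    condition = rep(c("c1", "c2"), 4),
    response = c(10, 12, 14, 18, 20, 26, 24, 32))
  res <- rm_anova(d)
  # hand-worked: grand mean 19.5; subject means 11,16,23,28; group means 13.5,25.5
  # SS_group = 2*2*(13.5-19.5)^2*2 ... computed manually:
  # between-subject SS = 2*sum((subj_mean-19.5)^2) = 2*(72.25+12.25+12.25+72.25)=338
  # SS_group = 4*(6^2)*2/2 = 288; SS_subj_within = 338-288 = 50
  expect_equal(attr(res, "ss_table")["between:group", "Sum Sq"], 288)
  expect_equal(attr(res, "ss_table")["between:Residuals", "Sum Sq"], 50)
  # condition means 17, 22 -> SS_condition = 4*( (17-19.5)^2+(22-19.5)^2 ) = 50
  expect_equal(attr(res, "ss_table")["within:condition", "Sum Sq"], 50)
  expect_equal(unname(res$group$statistic), 288 / (50 / 2))
  expect_equal(res$group$df, c(1, 2))
})

test_that("rm_anova SS decomposition is exact and df follow the cohort size", {
  set.seed(5)
  n1 <- 10; n2 <- 15
  d <- expand.grid(subject = sprintf("S%02d", 1:(n1 + n2)),
                   condition = eeg_conditions())
  d$group <- ifelse(as.integer(sub("S", "", d$subject)) <= n1,
                    "patient", "control")
  d$response <- rnorm(nrow(d))
  res <- rm_anova(d)
  expect_equal(res$group$df, c(1, 23))        # 25 subjects -> F(1, 23)
  expect_equal(res$condition$df, c(4, 92))
  ss <- attr(res, "ss_table")
  total <- sum((d$response - mean(d$response))^2)
  expect_equal(sum(ss[, "Sum Sq"]), total, tolerance = 1e-9)
})

test_that("rm_anova matches a one-way ANOVA on subject means without condition effects", {
  set.seed(6)
  subj_mean <- c(rnorm(6, 0), rnorm(6, 1))
  d <- expand.grid(subject = sprintf("S%02d", 1:12),
                   condition = c("c1", "c2", "c3"))
  d$group <- ifelse(as.integer(sub("S", "", d$subject)) <= 6, "a", "b")
  d$response <- subj_mean[as.integer(sub("S", "", d$subject))]
  res <- rm_anova(d)
  oneway <- summary(aov(subj_mean ~ rep(c("a", "b"), each = 6)))[[1]]
  expect_equal(unname(res$group$statistic), oneway$`F value`[1],
               tolerance = 1e-9)
  # no condition variation at all -> within effects degenerate to F=0, p=1
  expect_equal(unname(res$condition$statistic), 0)
  expect_equal(res$condition$p, 1)
})

test_that("rm_anova handles exclusions and degenerate input", {
  d <- expand.grid(subject = sprintf("S%d", 1:6), condition = c("c1", "c2"))
  d$group <- rep(c("a", "b"), each = 6)
  d$response <- 3
  # all equal -> all F = 0, p = 1 convention
  res <- rm_anova(d)
  expect_equal(unname(res$group$statistic), 0)
  expect_equal(res$group$p, 1)
  # drop one subject's condition -> listwise exclusion warning
  expect_warning(rm_anova(d[-1, ]), "excluding")
  # exclusion leaving one subject in a group is an error
  d2 <- expand.grid(subject = sprintf("S%d", 1:4), condition = c("c1", "c2"))
  d2$group <- ifelse(d2$subject %in% c("S1", "S2"), "a", "b")
  d2$response <- rnorm(nrow(d2))
  d2 <- d2[!(d2$subject == "S1" & d2$condition == "c1"), ]
  expect_error(suppressWarnings(rm_anova(d2)), "fewer than 2")
})

test_that("ANOVA type-I error is nominal on null designs", {
  set.seed(17)
  n_sim <- 400
  rej <- matrix(FALSE, n_sim, 3)
  for (i in seq_len(n_sim)) {
    d <- expand.grid(subject = sprintf("S%02d", 1:10),
                     condition = c("c1", "c2", "c3"))
    d$group <- ifelse(as.integer(sub("S", "", d$subject)) <= 5, "a", "b")
    d$response <- rnorm(nrow(d)) +
      rep(rnorm(10), 3)[as.integer(sub("S", "", d$subject))]
    res <- rm_anova(d)
    rej[i, ] <- c(res$group$p, res$condition$p, res$interaction$p) < 0.05
  }
  rates <- colMeans(rej)
  expect_true(all(rates > 0.02 & rates < 0.08),
              info = paste(round(rates, 3), collapse = " "))
})

test_that("Bonferroni post-hoc comparisons scale and cap p-values", {
  means <- c(a = 1, b = 1.4, c = 2.4)
  res <- posthoc_bonferroni(means, n_per_cell = 10, ms_error = 0.5,
                            df_error = 27)
  expect_equal(nrow(res), 3)
  expect_true(all(res$p_adj >= res$p))
  expect_equal(res$p_adj, pmin(1, res$p * 3))
  # m = 1 leaves p unchanged
  one <- posthoc_bonferroni(means[1:2], 10, 0.5, 27, m = 1)
  expect_equal(one$p_adj, one$p)
  # hand arithmetic: t for a vs c
  t_ac <- (1 - 2.4) / sqrt(0.5 * (1 / 10 + 1 / 10))
  expect_equal(res$t[res$a == "a" & res$b == "c"], t_ac)
  expect_error(posthoc_bonferroni(means, 10, 0.5, 27, m = 0), "m")
})
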