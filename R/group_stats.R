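#' Mann-Whitney U test with Z statistic
#'
#' Rank-sum comparison of two independent samples (used for the
#' morphometry group comparisons). U is computed by rank summation with
#' midrank ties; the p-value is exact (full enumeration) when
#' `n_a + n_b <= 12` and there are no ties, otherwise the normal
#' approximation with tie and continuity corrections is used. The
#' standardized Z (with the same corrections) is reported alongside, as in
#' conventional morphometry tables.
#'
#' @param a,b Numeric samples (each of length >= 2).
#' @param alternative `"two.sided"`, `"less"` or `"greater"`.
#' @return A `test_result` list: statistic name `"U"`, `statistic`, `z`,
#'   `p`, `medians`, `exact` flag.
#' @export
mann_whitney_u <- function(a, b, alternative = "two.sided") {
  if (length(a) < 2 || length(b) < 2) stop("each sample needs at least 2 values")
  pooled <- c(a, b)
  ties <- anyDuplicated(pooled) > 0
  exact <- (length(a) + length(b) <= 12) && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = alternative,
                                            exact = exact, correct = TRUE))
  u <- unname(wt$statistic)
  z <- mw_zscore(a, b)
  structure(list(statistic_name = "U", statistic = u, z = z, df = NULL,
                 p = wt$p.value,
                 medians = c(a = stats::median(a), b = stats::median(b)),
                 exact = exact),
            class = "test_result")
}

# normal-approximation Z for the U statistic, with midrank tie correction
# and a 0.5 continuity correction toward the null mean
mw_zscore <- function(a, b) {
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  tie_tab <- table(c(a, b))
  tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  sigma <- sqrt(na * nb / 12 * ((n + 1) - tie_term))
  if (sigma == 0) return(0)
  (u - mu - sign(u - mu) * 0.5) / sigma
}

#' @export
print.test_result <- function(x, ...) {
  df_txt <- if (!is.null(x$df)) paste0("(", paste(x$df, collapse = ", "), ")") else ""
  cat(sprintf("%s%s = %.4g, p = %.4g\n", x$statistic_name, df_txt,
              x$statistic, x$p))
  invisible(x)
}

#' @export
as.data.frame.test_result <- function(x, ...) {
  data.frame(statistic = x$statistic_name,
             value = x$statistic,
             z = if (is.null(x$z)) NA_real_ else x$z,
             df1 = if (is.null(x$df)) NA_real_ else x$df[1],
             df2 = if (is.null(x$df) || length(x$df) < 2) NA_real_ else x$df[2],
             ms = if (is.null(x$ms)) NA_real_ else x$ms,
             p = x$p)
}

#' Mixed repeated-measures ANOVA (between GROUP x within CONDITION)
#'
#' Classical sums-of-squares decomposition for a design with one
#' between-subjects factor (group: patient/control) and one within-subjects
#' factor (condition: rest + 4 stimulus types). The group effect is tested
#' against the subjects-within-groups error; condition and the
#' group x condition interaction against the condition x subject error.
#' Subjects missing any condition are excluded listwise with a warning. No
#' sphericity correction is applied by default, matching the plain
#' degrees-of-freedom convention F(1, n - 2) for the group effect;
#' `gg_correction = TRUE` applies Greenhouse-Geisser epsilon to the
#' within-factor tests.
#'
#' @param data Data frame with columns `subject`, `group`, `condition` and
#'   `response` (one electrode-averaged PSD value per subject x condition).
#' @param gg_correction Apply Greenhouse-Geisser df correction to the
#'   within-subject effects.
#' @return Named list of `test_result` objects: `group`, `condition`,
#'   `interaction`, each with F, df, MS and p; attribute `ss_table` carries
#'   the full decomposition.
#' @export
rm_anova <- function(data, gg_correction = FALSE) {
  need <- c("subject", "group", "condition", "response")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) stop("missing column(s): ", paste(miss, collapse = ", "))
  conds <- unique(data$condition)
  counts <- table(data$subject)
  complete <- names(counts)[counts == length(conds)]
  if (length(complete) < length(counts)) {
    warning("excluding subject(s) with missing conditions: ",
            paste(setdiff(names(counts), complete), collapse = ", "))
    data <- data[data$subject %in% complete, , drop = FALSE]
  }
  grp_of <- tapply(as.character(data$group), data$subject, function(g) g[1])
  if (min(table(grp_of)) < 2) stop("fewer than 2 subjects per group after exclusion")

  data$subject <- factor(data$subject)
  data$group <- factor(data$group)
  data$condition <- factor(data$condition)
  fit <- stats::aov(response ~ group * condition + Error(subject),
                    data = data)
  sm <- summary(fit)
  between <- as.data.frame(sm[["Error: subject"]][[1]])
  within <- as.data.frame(sm[["Error: Within"]][[1]])
  rn_b <- trimws(rownames(between)); rn_w <- trimws(rownames(within))

  scale <- mean(data$response^2) + 1e-300
  pick <- function(tab, rn, effect, err_row) {
    i <- match(effect, rn)
    e <- match(err_row, rn)
    ms <- tab[i, "Mean Sq"]; mse <- tab[e, "Mean Sq"]
    df1 <- tab[i, "Df"]; df2 <- tab[e, "Df"]
    # mean squares that are numerically zero relative to the response scale
    # denote a degenerate stratum (no variation), reported as F = 0, p = 1
    if (is.finite(ms) && ms < 1e-12 * scale) ms <- 0
    if (is.finite(mse) && mse < 1e-12 * scale) mse <- 0
    if (!is.finite(ms) || !is.finite(mse) || mse == 0) {
      f <- 0; p <- 1   # degenerate (all responses equal) convention
      if (is.finite(ms) && is.finite(mse) && ms > 0 && mse == 0) {
        f <- Inf; p <- 0
      }
    } else {
      f <- ms / mse
      p <- stats::pf(f, df1, df2, lower.tail = FALSE)
    }
    structure(list(statistic_name = "F", statistic = f, df = c(df1, df2),
                   ms = ms, p = p, z = NULL),
              class = "test_result")
  }
  res <- list(group = pick(between, rn_b, "group", "Residuals"),
              condition = pick(within, rn_w, "condition", "Residuals"),
              interaction = pick(within, rn_w, "group:condition", "Residuals"))

  if (gg_correction) {
    eps <- gg_epsilon(data)
    for (nm in c("condition", "interaction")) {
      r <- res[[nm]]
      r$df <- r$df * eps
      if (is.finite(r$statistic) && r$statistic > 0) {
        r$p <- stats::pf(r$statistic, r$df[1], r$df[2], lower.tail = FALSE)
      }
      res[[nm]] <- r
    }
  }
  ss <- rbind(between[, c("Df", "Sum Sq", "Mean Sq")],
              within[, c("Df", "Sum Sq", "Mean Sq")])
  rownames(ss) <- c(paste0("between:", rn_b), paste0("within:", rn_w))
  attr(res, "ss_table") <- ss
  res
}

# Greenhouse-Geisser epsilon from the subject x condition response matrix
gg_epsilon <- function(data) {
  wide <- stats::xtabs(response ~ subject + condition, data = data)
  # covariance across subjects after removing group means per condition
  grp <- tapply(as.character(data$group), data$subject, function(g) g[1])
  grp <- grp[rownames(wide)]
  centered <- wide
  for (g in unique(grp)) {
    rows <- grp == g
    centered[rows, ] <- sweep(wide[rows, , drop = FALSE], 2,
                              colMeans(wide[rows, , drop = FALSE]))
  }
  s <- stats::cov(centered)
  k <- ncol(s)
  dbar <- mean(diag(s)); sbar <- mean(s)
  num <- (k * (dbar - sbar))^2
  den <- (k - 1) * (sum(s^2) - 2 * k * sum(rowMeans(s)^2) + k^2 * sbar^2)
  max(1 / (k - 1), min(1, num / den))
}

#' Post-hoc pairwise comparisons with Bonferroni adjustment
#'
#' Pairwise t statistics between cell means using the ANOVA error term; each
#' raw p-value is multiplied by the number of comparisons and capped at 1.
#'
#' @param means Named vector of cell means.
#' @param n_per_cell Observations per cell (scalar or named vector).
#' @param ms_error Error mean square from the appropriate ANOVA stratum.
#' @param df_error Its degrees of freedom.
#' @param m Number of comparisons corrected for; defaults to the number of
#'   pairs.
#' @return Tibble with columns a, b, t, df, p, p_adj.
#' @export
posthoc_bonferroni <- function(means, n_per_cell, ms_error, df_error,
                               m = NULL) {
  k <- length(means)
  if (k < 2) stop("need at least two cell means")
  if (length(n_per_cell) == 1) n_per_cell <- rep(n_per_cell, k)
  pairs <- utils::combn(k, 2)
  if (is.null(m)) m <- ncol(pairs)
  if (m < 1) stop("m (number of comparisons) must be >= 1")
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt(ms_error * (1 / n_per_cell[i1] + 1 / n_per_cell[i2]))
    t <- (means[i1] - means[i2]) / se
    p <- 2 * stats::pt(abs(t), df_error, lower.tail = FALSE)
    tibble::tibble(a = names(means)[i1], b = names(means)[i2],
                   t = unname(t), df = df_error, p = unname(p),
                   p_adj = min(1, unname(p) * m))
  })
  do.call(rbind, rows)
}
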