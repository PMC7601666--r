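#' Permutation-test configuration
#'
#' @param n_permutations Number of random permutations of the covariate
#'   (default 500).
#' @param quantiles Lower/upper tail quantiles of the pooled permutation t
#'   distribution used as the cluster-forming threshold (default 2.5th and
#'   97.5th; must be symmetric).
#' @param min_size Minimum cluster size in electrodes (default 1:
#'   singletons survive).
#' @param threshold_mode `"permutation"` thresholds at quantiles of the
#'   pooled permutation t values; `"parametric"` uses the t(n-2)
#'   distribution instead.
#' @param alpha Family-wise alpha for significance flags.
#' @param correction `"covariates"` applies Bonferroni across the covariate
#'   battery; `"none"` leaves cluster p-values unadjusted.
#' @param seed Integer RNG seed for the permutation draw.
#' @return An object of class `perm_config`.
#' @export
perm_config <- function(n_permutations = 500,
                        quantiles = c(0.025, 0.975),
                        min_size = 1,
                        threshold_mode = c("permutation", "parametric"),
                        alpha = 0.05,
                        correction = c("covariates", "none"),
                        seed = 1L) {
  threshold_mode <- match.arg(threshold_mode)
  correction <- match.arg(correction)
  if (n_permutations < 100) stop("n_permutations must be >= 100")
  if (abs(quantiles[1] - (1 - quantiles[2])) > 1e-12) {
    stop("threshold quantiles must be symmetric")
  }
  structure(list(n_permutations = as.integer(n_permutations),
                 quantiles = quantiles, min_size = min_size,
                 threshold_mode = threshold_mode, alpha = alpha,
                 correction = correction, seed = as.integer(seed)),
            class = "perm_config")
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks -- the tie-safe general form of
#' Spearman's rho.
#'
#' @param x,y Numeric vectors of equal length (n >= 4).
#' @return rho in `[-1, 1]`; `NA` (with a warning) if either ranked vector
#'   has zero variance.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 4) stop("need at least 4 observations")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("zero variance in ranked values; correlation undefined")
    return(NA_real_)
  }
  stats::cor(rx, ry)
}

#' t statistic of a correlation
#'
#' The standard transform t = rho * sqrt((n - 2) / (1 - rho^2)), monotone
#' in rho for fixed n; |rho| = 1 maps to signed infinity.
#'
#' @param rho Correlation value(s).
#' @param n Sample size (>= 4).
#' @return t value(s).
#' @export
rho_to_t <- function(rho, n) {
  if (n < 4) stop("need n >= 4")
  out <- ifelse(abs(rho) >= 1, sign(rho) * Inf,
                rho * sqrt((n - 2) / (1 - rho^2)))
  out
}

#' Cluster-forming threshold from a null t distribution
#'
#' Electrodes whose t value lies above the upper or below the lower
#' quantile of the null distribution, kept sign-separated.
#'
#' @param t_map Named numeric vector of electrode t values.
#' @param null_t Numeric pool of null (permutation) t values.
#' @param quantiles `c(lower, upper)` tail probabilities.
#' @return List with logical vectors `positive`, `negative` and the numeric
#'   `thresholds`.
#' @export
threshold_map <- function(t_map, null_t, quantiles = c(0.025, 0.975)) {
  null_t <- null_t[is.finite(null_t)]
  if (length(unique(null_t)) < 2) {
    stop("degenerate null distribution (all values equal)")
  }
  thr <- stats::quantile(null_t, quantiles, names = FALSE)
  list(positive = t_map > thr[2], negative = t_map < thr[1],
       thresholds = thr)
}

#' Form clusters from supra-threshold electrodes
#'
#' Connected components of the supra-threshold electrode sets under the
#' montage adjacency, separately per sign; components smaller than
#' `min_size` are discarded. The cluster-level statistic (mass) is the sum
#' of the member t values.
#'
#' @param positive,negative Logical vectors over electrodes.
#' @param t_map Electrode t values.
#' @param adjacency Adjacency matrix from [montage_adjacency()].
#' @param min_size Minimum component size kept.
#' @return Tibble with columns electrodes (comma-joined labels), size,
#'   sign, mass.
#' @export
form_clusters <- function(positive, negative, t_map, adjacency,
                          min_size = 1) {
  labels <- colnames(adjacency)
  rows <- list()
  for (sgn in c(1, -1)) {
    members <- if (sgn > 0) positive else negative
    for (comp in connected_components(members, adjacency)) {
      if (length(comp) < min_size) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        electrodes = paste(labels[comp], collapse = ","),
        size = length(comp), sign = sgn, mass = sum(t_map[comp]))
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(electrodes = character(0), size = integer(0),
                          sign = numeric(0), mass = numeric(0)))
  }
  do.call(rbind, rows)
}

# max |cluster mass| of one supra-threshold map; 0 when nothing survives
max_cluster_mass <- function(positive, negative, t_vals, adjacency, min_size) {
  best <- 0
  for (sgn in c(1, -1)) {
    members <- which(if (sgn > 0) positive else negative)
    n_mem <- length(members)
    if (n_mem == 0) next
    if (n_mem == 1) {               # fast path: singleton set
      if (min_size <= 1) best <- max(best, abs(t_vals[members]))
      next
    }
    for (comp in connected_components(members, adjacency)) {
      if (length(comp) < min_size) next
      m <- abs(sum(t_vals[comp]))
      if (m > best) best <- m
    }
  }
  best
}

#' Cluster-based permutation test of a correlation topography
#'
#' The core inferential procedure. Per electrode, Spearman's rho between
#' the subjects' band-power contrast and a scalar covariate is transformed
#' to a t value. The cluster-forming threshold is taken at the configured
#' quantiles of the pooled permutation t distribution (t values from
#' `n_permutations` random permutations of the covariate across subjects,
#' pooled over electrodes). Supra-threshold electrodes are clustered by
#' montage adjacency, each cluster scored by its mass (sum of member t
#' values), and compared against the permutation distribution of the
#' maximum absolute cluster mass (each permutation re-runs the full
#' map -> threshold -> cluster chain). Cluster p-values use the add-one
#' estimator (b + 1) / (N + 1), whose floor at N = 500 displays as 0.002.
#'
#' @param contrast Subjects x electrodes contrast matrix (a `contrast_map`
#'   or plain matrix with subject rownames and electrode colnames).
#' @param covariate Numeric vector over the same subjects (names optional;
#'   if named, matched to rownames). Subjects with missing values are
#'   dropped with a warning.
#' @param adjacency Adjacency matrix; defaults to the shipped 10-20 table.
#' @param config A [perm_config()].
#' @param covariate_name Label stored in the result.
#' @param keep_permutations Store the permutation index matrix for exact
#'   replay.
#' @return An object of class `cluster_test_result`: list with `covariate`,
#'   `clusters` (tibble: electrodes, size, sign, mass, p, p_adj,
#'   significant), `map` (tibble: electrode, rho, t, supra), `thresholds`,
#'   `n`, `n_permutations`, `null_max_mass`, `seed`.
#' @export
permutation_test <- function(contrast, covariate,
                             adjacency = montage_adjacency(),
                             config = perm_config(),
                             covariate_name = "covariate",
                             keep_permutations = FALSE) {
  x <- unclass(contrast)
  attr(x, "band") <- NULL; attr(x, "groups") <- NULL
  if (!is.null(names(covariate)) && !is.null(rownames(x))) {
    covariate <- covariate[rownames(x)]
  }
  keep <- !is.na(covariate) & rowSums(is.na(x)) == 0
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " subject(s) with missing data")
    x <- x[keep, , drop = FALSE]; covariate <- covariate[keep]
  }
  n <- nrow(x)
  if (n < 5) stop("need at least 5 subjects with complete data")
  if (length(unique(covariate)) == 1) stop("covariate is constant")

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  rx <- apply(x, 2, rank)             # n x E midranks
  ry <- rank(covariate)
  nperm <- config$n_permutations
  perm_idx <- vapply(seq_len(nperm), function(i) sample.int(n), integer(n))
  ry_perm <- matrix(ry[perm_idx], n, nperm)

  rho_obs <- as.numeric(stats::cor(rx, ry))
  rho_null <- stats::cor(rx, ry_perm)  # E x nperm
  t_obs <- rho_to_t(rho_obs, n)
  t_null <- rho_to_t(rho_null, n)

  if (config$threshold_mode == "parametric") {
    thr <- stats::qt(config$quantiles, df = n - 2)
    supra <- list(positive = t_obs > thr[2], negative = t_obs < thr[1],
                  thresholds = thr)
  } else {
    supra <- threshold_map(t_obs, as.numeric(t_null), config$quantiles)
    thr <- supra$thresholds
  }

  clusters <- form_clusters(supra$positive, supra$negative, t_obs,
                            adjacency, config$min_size)

  null_max <- numeric(nperm)
  for (k in seq_len(nperm)) {
    tk <- t_null[, k]
    null_max[k] <- max_cluster_mass(tk > thr[2], tk < thr[1], tk,
                                    adjacency, config$min_size)
  }
  if (nrow(clusters) > 0) {
    clusters$p <- vapply(clusters$mass, function(m) {
      (sum(null_max >= abs(m)) + 1) / (nperm + 1)
    }, 0)
    clusters$p_adj <- clusters$p
    clusters$significant <- clusters$p < config$alpha
  } else {
    clusters$p <- numeric(0); clusters$p_adj <- numeric(0)
    clusters$significant <- logical(0)
  }

  out <- list(covariate = covariate_name,
              clusters = clusters,
              map = tibble::tibble(electrode = colnames(x), rho = rho_obs,
                                   t = t_obs,
                                   supra = supra$positive | supra$negative),
              thresholds = thr, n = n, n_permutations = nperm,
              null_max_mass = null_max, seed = config$seed)
  if (keep_permutations) out$permutations <- perm_idx
  structure(out, class = "cluster_test_result")
}

#' @export
print.cluster_test_result <- function(x, ...) {
  cat(sprintf("<cluster_test_result> %s (n = %d, %d permutations)\n",
              x$covariate, x$n, x$n_permutations))
  if (nrow(x$clusters) == 0) {
    cat("  no supra-threshold clusters\n")
  } else {
    for (i in seq_len(nrow(x$clusters))) {
      cl <- x$clusters[i, ]
      cat(sprintf("  %s cluster [%s]: mass %.2f, p = %.3f%s\n",
                  if (cl$sign > 0) "positive" else "negative",
                  cl$electrodes, cl$mass, cl$p_adj,
                  if (cl$significant) " *" else ""))
    }
  }
  invisible(x)
}

#' @export
as.data.frame.cluster_test_result <- function(x, ...) {
  cl <- as.data.frame(x$clusters)
  if (nrow(cl) == 0) {
    cl <- data.frame(electrodes = character(0), size = integer(0),
                     sign = numeric(0), mass = numeric(0), p = numeric(0),
                     p_adj = numeric(0), significant = logical(0))
  }
  cbind(covariate = rep(x$covariate, nrow(cl)), cl)
}

#' Run the covariate battery
#'
#' One cluster-permutation test per covariate against a single contrast
#' map. The default battery is the study's set: whole-brain gray-matter
#' volume, right putamen, right insula, surface holes (damaged-tissue
#' proxy), GOSe outcome, and paracentral/precentral thickness. With
#' `correction = "covariates"` cluster p-values are Bonferroni-adjusted
#' across the battery. The contrast is stimulation minus rest, so for
#' theta suppression the expected association is negative for volume
#' covariates and outcome (greater suppression, i.e. more negative
#' contrast, with larger volumes and better outcome) and positive for
#' surface holes.
#'
#' @param contrast A `contrast_map` (patients only are used if group
#'   attributes are present).
#' @param morphometry A `morphometry_set`.
#' @param clinical Clinical table (for `gose`).
#' @param config A [perm_config()]; each covariate gets a distinct seed
#'   derived from `config$seed`.
#' @param covariates Character vector of covariate names understood by
#'   [subject_covariate()].
#' @param adjacency Montage adjacency.
#' @return Named list of `cluster_test_result` objects.
#' @export
run_covariate_battery <- function(contrast, morphometry, clinical,
                                  config = perm_config(),
                                  covariates = c("total_gray_volume",
                                                 "right_putamen",
                                                 "right_insula",
                                                 "surface_holes", "gose",
                                                 "paracentral_thickness",
                                                 "precentral_thickness"),
                                  adjacency = montage_adjacency()) {
  if (length(covariates) == 0) stop("covariate list is empty")
  groups <- attr(contrast, "groups")
  x <- contrast
  if (!is.null(groups)) {
    x <- contrast[groups == "patient", , drop = FALSE]
  }
  subjects <- rownames(x)
  m <- length(covariates)
  results <- list()
  for (i in seq_along(covariates)) {
    nm <- covariates[i]
    cov <- subject_covariate(nm, morphometry, clinical, subjects)
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    res <- permutation_test(x, cov, adjacency, cfg, covariate_name = nm)
    if (config$correction == "covariates" && nrow(res$clusters) > 0) {
      res$clusters$p_adj <- pmin(1, res$clusters$p * m)
      res$clusters$significant <- res$clusters$p_adj < config$alpha
    }
    results[[nm]] <- res
  }
  results
}
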