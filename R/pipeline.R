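#' Run the full analysis pipeline
#'
#' Orchestrates the study replica on a cohort (in memory or on disk):
#' band-power tables, resting-state group comparison, mixed repeated
#' measures ANOVA per 1-Hz bin and per merged band, per-subject
#' significance maps, and the cluster-permutation covariate batteries for
#' the theta contrast (volumes, damage, outcome) and the beta contrast
#' (somatosensory thickness). Writes all result tables plus a run manifest
#' through [write_results()].
#'
#' @param cohort A `synthetic_cohort`, or a directory path readable by
#'   [read_cohort()].
#' @param out_dir Output directory; `NULL` skips writing.
#' @param wspec A [window_spec()].
#' @param normalize See [normalize_spectrum()].
#' @param config A [perm_config()].
#' @param bin_anova Also run the per-1-Hz-bin ANOVA pass (18 models).
#' @param verbose Print stage progress.
#' @return List with elements `band_table`, `resting_tests`, `anova_bins`,
#'   `anova_bands`, `morphometry_tests`, `individual`, `theta_battery`,
#'   `beta_battery`, `contrasts`.
#' @export
run_pipeline <- function(cohort, out_dir = NULL,
                         wspec = window_spec(),
                         normalize = "relative",
                         config = perm_config(),
                         bin_anova = TRUE,
                         verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.character(cohort)) {
    say("loading cohort from %s", cohort)
    cohort <- read_cohort(cohort)
  }
  es_list <- cohort$epoch_sets
  say("cohort: %d subjects", length(es_list))

  say("stage spectra: condition band-power tables")
  tab_stim <- condition_table(es_list, band_scheme("contrast"),
                              merge_rule = "per_stimulus", spec = wspec,
                              normalize = normalize)
  tab_all <- condition_table(es_list, band_scheme("contrast"),
                             merge_rule = "all_stimulation", spec = wspec,
                             normalize = normalize)
  tab_rest <- condition_table(es_list, band_scheme("resting"),
                              merge_rule = "all_stimulation", spec = wspec,
                              normalize = normalize)

  say("stage group_stats: resting-state group comparisons")
  rest_rows <- tab_rest[tab_rest$condition == "rest", ]
  resting_tests <- list()
  for (bnd in unique(rest_rows$band)) {
    sub <- rest_rows[rest_rows$band == bnd, ]
    per_subj <- tapply(sub$power, list(sub$subject, sub$group), mean)
    pat <- stats::na.omit(per_subj[, "patient"])
    ctl <- stats::na.omit(per_subj[, "control"])
    resting_tests[[bnd]] <- mann_whitney_u(pat, ctl)
  }

  say("stage group_stats: repeated-measures ANOVA")
  bins <- stats::setNames(lapply(2:19, function(f) c(f, f + 1)),
                          paste(2:19, 3:20, sep = "-"))
  anova_input <- function(scheme) {
    tab <- condition_table(es_list, scheme, merge_rule = "per_stimulus",
                           spec = wspec, normalize = normalize)
    # electrode-averaged response per subject x condition x band
    stats::aggregate(power ~ subject + group + condition + band, tab, mean)
  }
  anova_bins <- NULL
  if (bin_anova) {
    dat <- anova_input(band_scheme(bins))
    anova_bins <- lapply(split(dat, dat$band), function(d) {
      names(d)[names(d) == "power"] <- "response"
      rm_anova(d)
    })
  }
  datb <- anova_input(band_scheme("resting"))
  anova_bands <- lapply(split(datb, datb$band), function(d) {
    names(d)[names(d) == "power"] <- "response"
    rm_anova(d)
  })

  say("stage group_stats: morphometry comparisons")
  th <- cohort$morphometry$thickness
  morph_rows <- list()
  for (key in unique(paste(th$hemi, th$region))) {
    parts <- strsplit(key, " ")[[1]]
    sub <- th[th$hemi == parts[1] & th$region == parts[2], ]
    grp <- cohort$clinical$group[match(sub$subject_id,
                                       cohort$clinical$subject_id)]
    res <- mann_whitney_u(sub$thickness_mm[grp == "patient"],
                          sub$thickness_mm[grp == "control"])
    morph_rows[[key]] <- tibble::tibble(
      hemi = parts[1], region = parts[2], U = res$statistic, Z = res$z,
      p = res$p, median_patient = unname(res$medians["a"]),
      median_control = unname(res$medians["b"]))
  }
  g <- cohort$morphometry$globals
  grp <- cohort$clinical$group[match(g$subject_id, cohort$clinical$subject_id)]
  for (v in c("total_gray_volume", "surface_holes")) {
    res <- mann_whitney_u(g[[v]][grp == "patient"], g[[v]][grp == "control"])
    morph_rows[[v]] <- tibble::tibble(
      hemi = "both", region = v, U = res$statistic, Z = res$z, p = res$p,
      median_patient = unname(res$medians["a"]),
      median_control = unname(res$medians["b"]))
  }
  morphometry_tests <- do.call(rbind, morph_rows)

  say("stage individual_stats: per-subject maps")
  individual <- list()
  for (bnd in c("theta", "alpha", "beta")) {
    band <- band_scheme("contrast")[[bnd]]
    individual[[bnd]] <- lapply(es_list, individual_map, band = band,
                                spec = wspec, normalize = normalize)
  }

  say("stage cluster_perm: covariate batteries")
  theta_contrast <- band_contrast(tab_all, "theta")
  beta_contrast <- band_contrast(tab_all, "beta")
  theta_battery <- run_covariate_battery(
    theta_contrast, cohort$morphometry, cohort$clinical, config)
  beta_battery <- run_covariate_battery(
    beta_contrast, cohort$morphometry, cohort$clinical, config,
    covariates = c("paracentral_thickness", "precentral_thickness"))

  results <- list(band_table = tab_stim,
                  resting_tests = resting_tests,
                  anova_bins = anova_bins, anova_bands = anova_bands,
                  morphometry_tests = morphometry_tests,
                  individual = individual,
                  theta_battery = theta_battery,
                  beta_battery = beta_battery,
                  contrasts = list(theta = theta_contrast,
                                   beta = beta_contrast))

  if (!is.null(out_dir)) {
    say("writing results to %s", out_dir)
    anova_df <- function(lst) {
      if (is.null(lst)) return(NULL)
      do.call(rbind, lapply(names(lst), function(nm) {
        do.call(rbind, lapply(c("group", "condition", "interaction"),
                              function(eff) {
          cbind(band = nm, effect = eff, as.data.frame(lst[[nm]][[eff]]))
        }))
      }))
    }
    batt_df <- function(batt) do.call(rbind, lapply(batt, as.data.frame))
    indiv_df <- do.call(rbind, lapply(names(individual), function(bnd) {
      do.call(rbind, lapply(individual[[bnd]], function(r) {
        cbind(subject = attr(r, "subject"), band = bnd, as.data.frame(r))
      }))
    }))
    resting_df <- do.call(rbind, lapply(names(resting_tests), function(nm) {
      cbind(band = nm, as.data.frame(resting_tests[[nm]]))
    }))
    tables <- list(band_power = as.data.frame(tab_stim),
                   resting_group_tests = resting_df,
                   anova_bands = anova_df(anova_bands),
                   morphometry_tests = as.data.frame(morphometry_tests),
                   individual_maps = indiv_df,
                   theta_battery = batt_df(theta_battery),
                   beta_battery = batt_df(beta_battery))
    if (!is.null(anova_bins)) tables$anova_bins <- anova_df(anova_bins)
    write_results(tables, out_dir,
                  params = list(normalize = normalize,
                                window_mode = wspec$mode,
                                n_permutations = config$n_permutations,
                                cohort_seed = cohort$spec$seed),
                  seed = config$seed)
  }
  results
}

#' Summarize a results directory
#'
#' Reads the tables written by [run_pipeline()] and renders a short
#' markdown report: group contrasts, responder counts and significant
#' clusters per covariate.
#'
#' @param results_dir Directory written by [run_pipeline()].
#' @param path Optional output file for the report text.
#' @return Character vector of report lines, invisibly if `path` is given.
#' @export
summarize_run <- function(results_dir, path = NULL) {
  need <- file.path(results_dir,
                    c("run_manifest.json", "resting_group_tests.tsv",
                      "individual_maps.tsv", "theta_battery.tsv"))
  if (!all(file.exists(need))) {
    stop("incomplete results directory: missing ",
         paste(basename(need[!file.exists(need)]), collapse = ", "))
  }
  manifest <- jsonlite::read_json(file.path(results_dir, "run_manifest.json"))
  rest <- utils::read.delim(need[2])
  indiv <- utils::read.delim(need[3])
  theta <- utils::read.delim(need[4])

  lines <- c("# Tactile EEG reactivity: run summary", "",
             sprintf("Seed %s, %s permutations.",
                     manifest$seed, manifest$params$n_permutations), "",
             "## Resting-state group comparison (patients vs controls)")
  for (i in seq_len(nrow(rest))) {
    lines <- c(lines, sprintf("- %s band: U = %g, Z = %.2f, p = %.4g",
                              rest$band[i], rest$value[i], rest$z[i],
                              rest$p[i]))
  }
  lines <- c(lines, "", "## Individual theta responders (significant decrease)")
  th <- indiv[indiv$band == "theta", ]
  resp <- tapply(th$significant & th$direction == "decrease", th$subject, any)
  lines <- c(lines, sprintf("- %d of %d subjects show a significant theta decrease",
                            sum(resp), length(resp)))
  lines <- c(lines, "", "## Theta-contrast cluster battery")
  if (nrow(theta) == 0) {
    lines <- c(lines, "- no supra-threshold clusters")
  } else {
    for (i in seq_len(nrow(theta))) {
      lines <- c(lines, sprintf("- %s: %s cluster [%s], mass %.1f, p_adj = %.3f%s",
                                theta$covariate[i],
                                ifelse(theta$sign[i] > 0, "positive", "negative"),
                                theta$electrodes[i], theta$mass[i],
                                theta$p_adj[i],
                                ifelse(theta$significant[i], " *", "")))
    }
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
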