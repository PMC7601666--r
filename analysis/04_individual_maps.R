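#!/usr/bin/env Rscript

# Stage 4: per-subject significance maps.
#
# For every subject, rank-sum tests of the 40 stimulation trials against
# the 40 rest fragments per electrode and band, at the Bonferroni-corrected
# threshold 0.05/19 = 0.0026. Prints the star maps (one row per subject,
# '*' significant decrease, '+' significant increase).

library(tactileEEG)

spec <- read_cohort_spec("results/cohort/cohort.yaml")
cohort <- simulate_cohort(spec)

thr <- bonferroni_threshold(0.05, length(montage_electrodes()))
cat(sprintf("Bonferroni-corrected per-electrode threshold: %.6f (displayed %g)\n\n",
            thr$threshold, thr$display))

rows <- list()
for (bnd in c("theta", "alpha", "beta")) {
  band <- band_scheme("contrast")[[bnd]]
  maps <- lapply(cohort$epoch_sets, individual_map, band = band)
  cat(bnd, "band (", band[1], "-", band[2], "Hz ):\n")
  print(star_map(maps), quote = FALSE)
  cat("\n")
  for (m in maps) {
    rows[[length(rows) + 1L]] <- cbind(subject = attr(m, "subject"),
                                       band = bnd, as.data.frame(m))
  }
  resp <- vapply(maps, attr, TRUE, "responder_decrease")
  grp <- vapply(cohort$epoch_sets, function(e) e$group, "")
  cat(sprintf("  significant decrease: %d/%d patients, %d/%d controls\n\n",
              sum(resp[grp == "patient"]), sum(grp == "patient"),
              sum(resp[grp == "control"]), sum(grp == "control")))
}
write_results(list(individual_maps = do.call(rbind, rows)),
              "results/individual", params = list(threshold = thr$threshold),
              seed = spec$seed)
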