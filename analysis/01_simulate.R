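#!/usr/bin/env Rscript

# Stage 1: simulate the synthetic study cohort.
#
# Generates the default cohort -- 10 comatose TBI patients and 15 healthy
# controls, 19-channel EEG at 250 Hz with 4 tactile stimulus types x 10
# trials x 10 s plus 40 ten-second rest fragments per subject, FreeSurfer-
# style morphometry tables and a clinical table (GCS, GOSe) -- with theta
# suppression rank-coupled to gray-matter volumes and outcome.
#
# The EEG itself is not archived: it regenerates bit-identically from
# cohort.yaml, which this stage writes together with the small tables.

library(tactileEEG)

out <- "results/cohort"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

spec <- cohort_spec(seed = 1012L)
cohort <- simulate_cohort(spec)

write_cohort_spec(spec, file.path(out, "cohort.yaml"))
write_morphometry(cohort$morphometry, file.path(out, "morphometry"))
write_clinical(cohort$clinical, file.path(out, "clinical.tsv"))
write.table(cohort$ground_truth, file.path(out, "ground_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("cohort: %d patients, %d controls, seed %d\n",
            spec$n_patients, spec$n_controls, spec$seed))
cat(sprintf("per subject: %d stimulation trials + %d rest fragments of %g s\n",
            4 * spec$n_trials, spec$n_rest, spec$trial_s))
gt <- cohort$ground_truth
pat <- gt$group == "patient"
cat(sprintf("latent theta suppression in patients: %.2f - %.2f (median %.2f)\n",
            min(gt$d[pat]), max(gt$d[pat]), median(gt$d[pat])))
cat("tables written under", out, "\n")
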