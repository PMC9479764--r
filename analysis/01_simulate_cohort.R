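#!/usr/bin/env Rscript
# Simulate the synthetic trial cohort used by every downstream analysis step:
# 14 patients, 5 planted pathologic responders, with pre/post MIF slides,
# pathology areas, lesion measurements, somatic call sets and ELISpot plates.
# Writes the cohort as plain-text interchange files under results/cohort/.

suppressPackageStartupMessages(library(neocorr))

seed <- 42L
args <- commandArgs(trailingOnly = TRUE)
if (length(args) >= 2 && args[1] == "--seed") seed <- as.integer(args[2])

params <- cohort_params(seed = seed)
cohort <- generate_patient_cohort(params)
out <- file.path("results", "cohort")
write_cohort(cohort, out)

n_cells <- sum(vapply(cohort$patients, function(p) nrow(p$cells), integer(1)))
n_vars <- sum(vapply(cohort$patients, function(p) nrow(p$truth_variants),
                     integer(1)))
cat(sprintf("Simulated %d patients (seed %d): %d planted responders, %d cells, %d truth variants.\n",
            params$n_patients, seed, length(cohort$responder_ids), n_cells,
            n_vars))
cat("Cohort written to", out, "\n")
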