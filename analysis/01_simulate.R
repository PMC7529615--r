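#!/usr/bin/env Rscript
# Build the 81-reading reference cohort and a fresh synthetic cohort, and
# tabulate their label structure.  Usage: Rscript analysis/01_simulate.R [seed]

suppressPackageStartupMessages(library(sbceBayes))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 0L
dir.create("results", showWarnings = FALSE)

cohort <- reference_cohort(seed = seed)
write_readings(cohort, "results/cohort_reference.csv")

cat("Reference cohort (seed ", seed, "): ", nrow(cohort), " readings from ",
    length(unique(cohort$patient_id)), " patients\n", sep = "")
cat("  severity classes: ",
    paste(names(class_counts(cohort, "severity")),
          class_counts(cohort, "severity"), collapse = ", "), "\n", sep = "")
cat("  disease classes:  ",
    paste(names(class_counts(cohort, "disease")),
          class_counts(cohort, "disease"), collapse = ", "), "\n", sep = "")

patients <- cohort[!duplicated(cohort$patient_id), ]
marsh_tab <- table(factor(patients$marsh, marsh_levels()))
cat("  patient-level Marsh distribution:",
    paste(names(marsh_tab), marsh_tab, sep = "=", collapse = " "), "\n")

# a generated cohort under the documented default disease configuration,
# for comparison and reuse by later stages
cfg <- default_config("disease", n_readings = 500L, seed = seed + 1L)
write_generator_config(cfg, "results/generator_config_disease.yaml")
sim <- generate_cohort(cfg)
write_readings(sim, "results/cohort_simulated_disease.csv")
cat("Simulated disease cohort: ", nrow(sim), " readings; class counts ",
    paste(class_counts(sim, "disease"), collapse = "/"), "\n", sep = "")
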