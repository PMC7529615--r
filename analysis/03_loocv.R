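#!/usr/bin/env Rscript
# Leave-one-out cross-validation of both prediction rules on both tasks,
# over the reference cohort.  Run analysis/01_simulate.R first.
# Usage: Rscript analysis/03_loocv.R

suppressPackageStartupMessages(library(sbceBayes))
dir.create("results", showWarnings = FALSE)

cohort <- read_readings("results/cohort_reference.csv")

rows <- list()
for (task in c("severity", "disease")) {
  for (rule in c("max_likelihood", "naive_bayes")) {
    cv <- loocv(cohort, task, rule, alpha = 1)
    write_cv_report(cv, sprintf("results/loocv_%s_%s.txt", task, rule),
                    fold_table = sprintf("results/loocv_%s_%s_folds.csv",
                                         task, rule))
    rows[[length(rows) + 1L]] <- data.frame(
      task = task, rule = rule, n_folds = cv$n_folds,
      accuracy_percent = cv$accuracy_percent,
      accuracy_display = format_accuracy(cv$accuracy_percent)
    )
    cat(sprintf("%-9s %-15s %d folds  accuracy %s%%\n", task, rule,
                cv$n_folds, format_accuracy(cv$accuracy_percent)))
  }
}
utils::write.csv(do.call(rbind, rows), "results/loocv_accuracy.csv",
                 row.names = FALSE)
cat("Note: these accuracies are properties of the synthetic reference\n",
    "cohort, whose joint feature values are generated, not clinical.\n",
    sep = "")
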