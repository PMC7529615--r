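#' Leave-one-out cross-validation of a prediction rule
#'
#' Each held-out unit in turn is removed, the class-conditional model (and,
#' for the naive Bayes rule, the smoothed class prior) is refitted on the
#' remaining readings, the held-out reading(s) are predicted, and each
#' reading scores 1 if the predicted class equals its true class and 0
#' otherwise.  The aggregate is reported as a percentage accuracy.
#'
#' The held-out unit is one reading by default; `fold_unit = "patient"`
#' groups a patient's readings into one fold (all of them held out together),
#' for sensitivity analysis of double-read cohorts.  A fold whose training
#' set loses a class entirely is still fitted: smoothing keeps every
#' probability defined, and the prior falls back on its pseudo-counts.
#'
#' @param data A labelled readings table with at least 2 readings and both
#'   classes represented.
#' @param task `"severity"` or `"disease"`.
#' @param rule `"max_likelihood"` or `"naive_bayes"`.
#' @param alpha Positive Dirichlet pseudo-count used inside every fold
#'   (default 1; no fold-wise tuning).
#' @param prior_mode `"smoothed"` (default) or `"raw"`: how the fold's class
#'   prior is estimated for the naive Bayes rule.
#' @param fold_unit `"reading"` (default) or `"patient"`.
#' @param schema An `sbce_schema`; defaults to [sbce_schema()].
#' @return An object of class `sbce_cv`: `fold_scores` (0/1 per reading, in
#'   row order), `accuracy_percent`, `n_folds`, `predictions` (per-reading
#'   tibble with `true_class` and `score`), `confusion` (2x2 matrix,
#'   true x predicted), plus the run's task/rule/alpha settings.
#' @examples
#' d <- reference_cohort(seed = 0)
#' cv <- loocv(d, "severity", "max_likelihood")
#' cv$n_folds           # 81
#' cv$accuracy_percent
#' @export
loocv <- function(data, task, rule = c("max_likelihood", "naive_bayes"),
                  alpha = 1, prior_mode = c("smoothed", "raw"),
                  fold_unit = c("reading", "patient"),
                  schema = sbce_schema()) {
  task <- match_task(task)
  rule <- match.arg(rule)
  prior_mode <- match.arg(prior_mode)
  fold_unit <- match.arg(fold_unit)
  data <- validate_readings(data, schema)
  if (nrow(data) < 2L) {
    stop("leave-one-out needs at least 2 readings", call. = FALSE)
  }
  truth <- class_codes(data, task)
  if (length(unique(truth)) < 2L) {
    stop("both classes must be represented in the dataset", call. = FALSE)
  }

  folds <- if (fold_unit == "reading") {
    as.list(seq_len(nrow(data)))
  } else {
    if (!"patient_id" %in% names(data)) {
      stop("fold_unit = 'patient' needs a patient_id column", call. = FALSE)
    }
    unname(split(seq_len(nrow(data)), data$patient_id))
  }

  preds <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    held <- folds[[f]]
    train <- data[-held, , drop = FALSE]
    model <- fit_class_model(train, task, alpha = alpha, schema = schema)
    p <- if (rule == "max_likelihood") {
      predict_max_likelihood(model, data[held, , drop = FALSE])
    } else {
      prior <- estimate_class_prior(train, task, mode = prior_mode)
      predict_naive_bayes(model, prior, data[held, , drop = FALSE])
    }
    p$row <- held
    p$fold <- f
    preds[[f]] <- p
  }
  predictions <- do.call(rbind, preds)
  predictions <- predictions[order(predictions$row), , drop = FALSE]
  predictions$true_class <- truth
  predictions$score <- as.integer(predictions$predicted_class == truth)

  confusion <- table(
    factor(truth, levels = 1:2, labels = task_class_labels(task)),
    factor(predictions$predicted_class, levels = 1:2,
           labels = task_class_labels(task)),
    dnn = c("true", "predicted")
  )

  structure(
    list(task = task, rule = rule, alpha = alpha, prior_mode = prior_mode,
         fold_unit = fold_unit, n_folds = length(folds),
         fold_scores = predictions$score,
         accuracy_percent = accuracy(predictions$score),
         predictions = predictions, confusion = unclass(confusion)),
    class = "sbce_cv"
  )
}

#' Percentage accuracy from unity/zero fold scores
#'
#' @param fold_scores Non-empty vector of 0/1 scores.
#' @return `100 * mean(fold_scores)`, full precision (see
#'   [format_accuracy()] for display rounding).
#' @export
accuracy <- function(fold_scores) {
  if (length(fold_scores) == 0L) {
    stop("fold_scores must be non-empty", call. = FALSE)
  }
  if (!all(fold_scores %in% c(0, 1))) {
    stop("fold_scores must be 0 or 1", call. = FALSE)
  }
  100 * mean(fold_scores)
}

#' Display rounding for accuracies
#'
#' One decimal place, rounding half away from zero (so 56.75 prints as
#' "56.8"), as accuracy percentages are conventionally quoted.
#'
#' @param x Numeric percentages.
#' @return Character vector.
#' @export
format_accuracy <- function(x) {
  sprintf("%.1f", sign(x) * floor(abs(x) * 10 + 0.5) / 10)
}

#' @export
print.sbce_cv <- function(x, ...) {
  cat("Leave-one-out cross-validation (task:", x$task, ", rule:", x$rule,
      ")\n")
  cat("  folds:", x$n_folds, " unit:", x$fold_unit, " alpha:", x$alpha, "\n")
  cat("  accuracy:", format_accuracy(x$accuracy_percent), "%\n")
  cat("  confusion (true x predicted):\n")
  print(x$confusion)
  invisible(x)
}

#' Write a cross-validation report
#'
#' A short structured text report (overall accuracy, settings, confusion
#' counts) plus, optionally, the per-fold prediction table as CSV alongside.
#'
#' @param cv An `sbce_cv` from [loocv()].
#' @param path Output path for the text report.
#' @param fold_table Optional CSV path for the per-reading prediction table.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(cv, path, fold_table = NULL) {
  stopifnot(inherits(cv, "sbce_cv"))
  labels <- task_class_labels(cv$task)
  lines <- c(
    "sbceBayes LOOCV report",
    sprintf("task: %s", cv$task),
    sprintf("rule: %s", cv$rule),
    sprintf("alpha: %g", cv$alpha),
    sprintf("prior_mode: %s", cv$prior_mode),
    sprintf("fold_unit: %s", cv$fold_unit),
    sprintf("n_folds: %d", cv$n_folds),
    sprintf("n_readings: %d", length(cv$fold_scores)),
    sprintf("accuracy_percent: %s", format_accuracy(cv$accuracy_percent)),
    "confusion (true,predicted,count):",
    sprintf("  %s,%s,%d",
            rep(labels, each = 2L), rep(labels, 2L),
            as.integer(t(cv$confusion)))
  )
  writeLines(lines, path, useBytes = TRUE)
  if (!is.null(fold_table)) {
    utils::write.csv(cv$predictions, fold_table, row.names = FALSE,
                     fileEncoding = "UTF-8", na = "")
  }
  invisible(path)
}
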