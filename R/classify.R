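#' Estimate the class prior for a task
#'
#' The smoothed marginal probability of each class, under the same symmetric
#' add-one Dirichlet treatment as the feature tables:
#' \deqn{p(c) = \frac{N_c + 1}{N + 2}}
#' where \eqn{N_c} is the number of readings in class `c` and \eqn{N} their
#' total.  `mode = "raw"` returns the unsmoothed proportions \eqn{N_c / N}
#' instead (the figure usually quoted for a cohort, e.g. 63/81 = 77.8\% CD).
#'
#' @param data A labelled readings table.
#' @param task `"severity"` or `"disease"`.
#' @param mode `"smoothed"` (default) or `"raw"`.
#' @return An object of class `sbce_prior`: task, mode, `n` (total), `n_c`
#'   (per-class counts) and `pi` (per-class probabilities summing to 1).
#' @examples
#' d <- reference_cohort(seed = 0)
#' estimate_class_prior(d, "disease")$pi        # (19/83, 64/83)
#' estimate_class_prior(d, "disease", "raw")$pi # (18/81, 63/81)
#' @export
estimate_class_prior <- function(data, task,
                                 mode = c("smoothed", "raw")) {
  task <- match_task(task)
  mode <- match.arg(mode)
  n_c <- as.integer(class_counts(data, task))
  n <- sum(n_c)
  pi <- if (mode == "smoothed") {
    (n_c + 1) / (n + 2)
  } else {
    if (n == 0L) stop("raw prior undefined on an empty dataset", call. = FALSE)
    n_c / n
  }
  structure(
    list(task = task, mode = mode, n = n, n_c = n_c,
         pi = stats::setNames(pi, task_class_labels(task))),
    class = "sbce_prior"
  )
}

#' Uniform class prior
#'
#' A 50/50 prior for a task; with it the naive Bayes rule reduces to the
#' maximum-likelihood rule.
#'
#' @param task `"severity"` or `"disease"`.
#' @return An `sbce_prior` with `pi = (1/2, 1/2)`.
#' @export
uniform_class_prior <- function(task) {
  task <- match_task(task)
  structure(
    list(task = task, mode = "uniform", n = 0L, n_c = c(0L, 0L),
         pi = stats::setNames(c(0.5, 0.5), task_class_labels(task))),
    class = "sbce_prior"
  )
}

#' @export
print.sbce_prior <- function(x, ...) {
  cat("Class prior (task:", x$task, ", mode:", x$mode, ")\n")
  print(round(x$pi, 4))
  invisible(x)
}

## Exact ties in log score predict class 1 (the milder / rarer-intervention
## group) and are flagged.
.tie_tol <- 1e-12

classify_scores <- function(score) {
  # score: n x 2 matrix of log-domain deciding scores
  gap <- score[, 2L] - score[, 1L]
  scale <- pmax(1, abs(score[, 1L]), abs(score[, 2L]))
  tie <- abs(gap) <= .tie_tol * scale
  pred <- ifelse(!tie & gap > 0, 2L, 1L)
  list(pred = pred, tie = tie)
}

#' Classify readings by maximum posterior-predictive likelihood
#'
#' Each reading is assigned the class whose posterior-predictive likelihood
#' \eqn{p(SBCE \mid c)} is larger (compared in log space).  Exact ties
#' (within relative tolerance 1e-12) predict class 1 and set `tie = TRUE`.
#'
#' @param model A fitted `sbce_model`.
#' @param data A readings table (labels not required).
#' @return A tibble with one row per reading: `row`, `rule`,
#'   `predicted_class` (1/2), `predicted_label`, `loglik_1`, `loglik_2`,
#'   `posterior_1`, `posterior_2` (both `NA` for this rule), `tie`.
#' @export
predict_max_likelihood <- function(model, data) {
  stopifnot(inherits(model, "sbce_model"))
  ll <- log_likelihood_matrix(model, data)
  cls <- classify_scores(ll)
  labels <- task_class_labels(model$task)
  tibble::tibble(
    row = seq_len(nrow(ll)),
    rule = "max_likelihood",
    predicted_class = cls$pred,
    predicted_label = labels[cls$pred],
    loglik_1 = ll[, 1L],
    loglik_2 = ll[, 2L],
    posterior_1 = NA_real_,
    posterior_2 = NA_real_,
    tie = cls$tie
  )
}

#' Classify readings by the naive Bayes posterior
#'
#' Bayes' rule combines the class-conditional likelihoods with a class
#' prior:
#' \deqn{p(c \mid SBCE) = \frac{p(SBCE \mid c)\, p(c)}
#'                             {\sum_{c'} p(SBCE \mid c')\, p(c')}}
#' and the reading is assigned the class with the larger posterior.  The
#' posterior pair sums to 1 and is invariant to rescaling both likelihoods
#' by any positive constant.
#'
#' @param model A fitted `sbce_model`.
#' @param prior An `sbce_prior` for the same task (see
#'   [estimate_class_prior()], [uniform_class_prior()]).
#' @param data A readings table (labels not required).
#' @return A tibble as in [predict_max_likelihood()] with
#'   `rule = "naive_bayes"` and the `posterior_*` columns filled.
#' @export
predict_naive_bayes <- function(model, prior, data) {
  stopifnot(inherits(model, "sbce_model"), inherits(prior, "sbce_prior"))
  if (!identical(model$task, prior$task)) {
    stop("model task '", model$task, "' does not match prior task '",
         prior$task, "'", call. = FALSE)
  }
  ll <- log_likelihood_matrix(model, data)
  score <- sweep(ll, 2L, base::log(prior$pi), `+`)
  # normalize in log space: posterior_c = exp(score_c - logsumexp(score))
  mx <- pmax(score[, 1L], score[, 2L])
  lse <- unname(mx + base::log(exp(score[, 1L] - mx) + exp(score[, 2L] - mx)))
  post <- exp(score - cbind(lse, lse, deparse.level = 0))
  dimnames(post) <- NULL
  cls <- classify_scores(score)
  labels <- task_class_labels(model$task)
  tibble::tibble(
    row = seq_len(nrow(ll)),
    rule = "naive_bayes",
    predicted_class = cls$pred,
    predicted_label = labels[cls$pred],
    loglik_1 = ll[, 1L],
    loglik_2 = ll[, 2L],
    posterior_1 = post[, 1L],
    posterior_2 = post[, 2L],
    tie = cls$tie
  )
}

#' Classify readings by either rule
#'
#' Thin dispatcher over [predict_max_likelihood()] and
#' [predict_naive_bayes()].
#'
#' @param model A fitted `sbce_model`.
#' @param data A readings table.
#' @param rule `"max_likelihood"` or `"naive_bayes"`.
#' @param prior An `sbce_prior`; required for the naive Bayes rule.
#' @return Prediction tibble (see [predict_max_likelihood()]).
#' @export
predict_readings <- function(model, data,
                             rule = c("max_likelihood", "naive_bayes"),
                             prior = NULL) {
  rule <- match.arg(rule)
  if (rule == "max_likelihood") {
    predict_max_likelihood(model, data)
  } else {
    if (is.null(prior)) {
      stop("the naive_bayes rule needs a class prior", call. = FALSE)
    }
    predict_naive_bayes(model, prior, data)
  }
}

#' Write a prediction table to a delimited text file
#'
#' @param predictions A tibble from [predict_readings()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  utils::write.csv(predictions, path, row.names = FALSE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}
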