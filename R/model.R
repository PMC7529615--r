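#' Fit the class-conditional Dirichlet-categorical model
#'
#' For each of the two classes of a task and each categorical feature, counts
#' the readings at each level and stores the posterior-predictive probability
#' of every level under a symmetric Dirichlet prior with pseudo-count
#' `alpha`:
#' \deqn{p(f_i = k \mid c) = \frac{N_k + \alpha}{N + K_i\,\alpha}}
#' where \eqn{N_k} is the number of class-`c` readings with level `k` for
#' feature `i`, \eqn{N} their total, and \eqn{K_i} the number of levels.
#' `alpha = 1` is add-one (Laplace) smoothing: every probability is strictly
#' positive, so a level never seen in training cannot zero out a likelihood.
#' A class with no readings gets the prior alone (uniform over levels).
#'
#' @param data A readings table in which every row carries the label the task
#'   needs (`marsh` for severity, `disease` for disease).
#' @param task `"severity"` or `"disease"`.
#' @param alpha Positive Dirichlet pseudo-count applied to every level
#'   (default 1).
#' @param schema An `sbce_schema`; defaults to [sbce_schema()].
#' @return An object of class `sbce_model`: task, alpha, schema, per-class
#'   reading totals `n`, and `tables[[c]][[i]]` with `counts` (length
#'   \eqn{K_i}), `n`, `alpha` and `probs` for class `c`, feature `i`.
#' @examples
#' d <- reference_cohort(seed = 0)
#' m <- fit_class_model(d, "severity")
#' posterior_predictive(m, class = 2, feature = 5, level = 2)
#' @export
fit_class_model <- function(data, task, alpha = 1, schema = sbce_schema()) {
  task <- match_task(task)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0) {
    stop("alpha must be a single positive number", call. = FALSE)
  }
  data <- validate_readings(data, schema)
  cc <- if (nrow(data) > 0L) class_codes(data, task) else integer(0)
  X <- feature_matrix(data, schema)
  Ks <- schema_K(schema)

  tables <- lapply(1:2, function(cl) {
    rows <- which(cc == cl)
    lapply(seq_along(Ks), function(i) {
      counts <- tabulate(X[rows, i], nbins = Ks[i])
      n <- length(rows)
      list(
        feature = i,
        class   = cl,
        counts  = counts,
        n       = n,
        alpha   = rep(alpha, Ks[i]),
        probs   = (counts + alpha) / (n + Ks[i] * alpha)
      )
    })
  })
  structure(
    list(task = task, alpha = alpha, schema = schema,
         n = c(sum(cc == 1L), sum(cc == 2L)), tables = tables),
    class = "sbce_model"
  )
}

#' @export
print.sbce_model <- function(x, ...) {
  cat("Dirichlet-categorical class model (task:", x$task, ")\n")
  cat("  readings per class:", paste(x$n, collapse = " / "),
      " alpha:", x$alpha, "\n")
  cat("  ", 2L * n_features(x$schema),
      "posterior-predictive probability tables\n")
  invisible(x)
}

#' Posterior-predictive probability of one feature level
#'
#' Looks up \eqn{p(f_i = k \mid c)} from a fitted model.
#'
#' @param model An `sbce_model` from [fit_class_model()].
#' @param class Class code, 1 or 2.
#' @param feature Feature index, 1..9.
#' @param level Level code `k`, within the feature's declared range.
#' @return A probability strictly inside (0, 1).
#' @export
posterior_predictive <- function(model, class, feature, level) {
  stopifnot(inherits(model, "sbce_model"))
  if (!(class %in% 1:2)) stop("class must be 1 or 2", call. = FALSE)
  nf <- n_features(model$schema)
  if (!(feature %in% seq_len(nf))) {
    stop("feature index out of range 1..", nf, call. = FALSE)
  }
  tab <- model$tables[[class]][[feature]]
  if (!(level %in% seq_along(tab$probs))) {
    stop("level ", level, " out of range 1..", length(tab$probs),
         " for feature ", feature, call. = FALSE)
  }
  tab$probs[[level]]
}

#' Likelihood of a reading under one class
#'
#' The conditional-independence product over the nine features,
#' \eqn{p(SBCE \mid c) = \prod_i p(f_i = r_i \mid c)}, with each factor the
#' posterior-predictive probability from the fitted model.  Accumulation is
#' done in log space; set `log = TRUE` for the log-likelihood itself.
#'
#' @param model An `sbce_model`.
#' @param reading One reading: an integer vector of level codes (one per
#'   feature) or a one-row readings table.
#' @param class Class code, 1 or 2.
#' @param log Return the log-likelihood instead of the likelihood.
#' @return A single probability (or its log), strictly positive for any
#'   `alpha > 0`.
#' @export
reading_likelihood <- function(model, reading, class, log = FALSE) {
  stopifnot(inherits(model, "sbce_model"))
  if (is.data.frame(reading)) {
    if (nrow(reading) != 1L) {
      stop("'reading' must be a single reading", call. = FALSE)
    }
    reading <- as.integer(feature_matrix(validate_readings(reading,
                                                           model$schema),
                                         model$schema)[1L, ])
  }
  nf <- n_features(model$schema)
  if (length(reading) != nf) {
    stop("a reading has ", nf, " feature values", call. = FALSE)
  }
  ll <- sum(vapply(seq_len(nf), function(i) {
    base::log(posterior_predictive(model, class, i, reading[[i]]))
  }, numeric(1)))
  if (log) ll else exp(ll)
}

#' Per-class log-likelihood matrix for a readings table
#'
#' Vectorised companion of [reading_likelihood()]: row `r`, column `c` holds
#' \eqn{\log p(SBCE_r \mid c)}.
#'
#' @param model An `sbce_model`.
#' @param data A readings table.
#' @return An `n x 2` numeric matrix of log-likelihoods.
#' @export
log_likelihood_matrix <- function(model, data) {
  stopifnot(inherits(model, "sbce_model"))
  data <- validate_readings(data, model$schema)
  X <- feature_matrix(data, model$schema)
  nf <- n_features(model$schema)
  out <- matrix(0, nrow = nrow(X), ncol = 2L)
  for (cl in 1:2) {
    for (i in seq_len(nf)) {
      out[, cl] <- out[, cl] + base::log(model$tables[[cl]][[i]]$probs[X[, i]])
    }
  }
  out
}

#' Class-conditional feature histograms
#'
#' The fitted posterior-predictive tables laid out as a long report: one row
#' per (feature, class, level) with its probability.  Within each (feature,
#' class) group the probabilities sum to 1, so each group is the model's
#' histogram over that feature's conditions given the class.
#'
#' @param model An `sbce_model`.
#' @return A tibble with columns `feature`, `feature_name`, `class`,
#'   `class_label`, `level`, `level_label`, `probability`.
#' @seealso [feature_contrasts()] for the per-feature abnormal-mass
#'   difference between the classes.
#' @export
feature_histograms <- function(model) {
  stopifnot(inherits(model, "sbce_model"))
  labels <- task_class_labels(model$task)
  rows <- list()
  for (cl in 1:2) {
    for (i in seq_len(n_features(model$schema))) {
      f <- model$schema$features[[i]]
      tab <- model$tables[[cl]][[i]]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        feature      = i,
        feature_name = f$name,
        class        = cl,
        class_label  = labels[cl],
        level        = seq_len(f$K),
        level_label  = f$levels,
        probability  = tab$probs
      )
    }
  }
  do.call(rbind, rows)
}

#' Abnormal-mass contrast between classes, per feature
#'
#' For each feature, the probability mass the fitted model puts on abnormal
#' levels (`k > 1`) in class 2 minus the same mass in class 1:
#' \eqn{p(k > 1 \mid c = 2) - p(k > 1 \mid c = 1)}.  Positive values mean the
#' feature is more often abnormal in the severe (or CD) class.
#'
#' @param model An `sbce_model`.
#' @return A tibble with columns `feature`, `feature_name`,
#'   `abnormal_mass_1`, `abnormal_mass_2`, `abnormal_diff`.
#' @export
feature_contrasts <- function(model) {
  stopifnot(inherits(model, "sbce_model"))
  nf <- n_features(model$schema)
  mass <- function(cl, i) sum(model$tables[[cl]][[i]]$probs[-1L])
  tibble::tibble(
    feature         = seq_len(nf),
    feature_name    = vapply(model$schema$features, `[[`, character(1), "name"),
    abnormal_mass_1 = vapply(seq_len(nf), function(i) mass(1L, i), numeric(1)),
    abnormal_mass_2 = vapply(seq_len(nf), function(i) mass(2L, i), numeric(1)),
    abnormal_diff   = vapply(seq_len(nf), function(i) mass(2L, i) - mass(1L, i),
                             numeric(1))
  )
}

#' Serialize a fitted model to a YAML document
#'
#' Human-readable, versioned: schema, task, alpha and all count-and-
#' probability tables.  [read_model()] restores an identical model.
#'
#' @param model An `sbce_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "sbce_model"))
  doc <- list(
    format  = "sbceBayes-model",
    version = 1L,
    task    = model$task,
    alpha   = model$alpha,
    n       = as.integer(model$n),
    schema  = list(features = model$schema$features),
    tables  = lapply(model$tables, function(cls) {
      lapply(cls, function(t) {
        list(feature = t$feature, class = t$class, n = t$n,
             counts = as.integer(t$counts), alpha = t$alpha, probs = t$probs)
      })
    })
  )
  yaml::write_yaml(doc, path, precision = 17L)
  invisible(path)
}

#' Restore a fitted model written by [write_model()]
#'
#' @param path Path to a model YAML document.
#' @return An `sbce_model`.
#' @export
read_model <- function(path) {
  doc <- yaml::read_yaml(path)
  if (!identical(doc$format, "sbceBayes-model")) {
    stop("'", path, "' is not a serialized sbceBayes model", call. = FALSE)
  }
  schema <- structure(list(features = lapply(doc$schema$features, function(f) {
    list(column = f$column, name = f$name, K = as.integer(f$K),
         levels = as.character(unlist(f$levels)))
  })), class = "sbce_schema")
  tables <- lapply(doc$tables, function(cls) {
    lapply(cls, function(t) {
      list(feature = as.integer(t$feature), class = as.integer(t$class),
           counts = as.integer(unlist(t$counts)), n = as.integer(t$n),
           alpha = as.numeric(unlist(t$alpha)),
           probs = as.numeric(unlist(t$probs)))
    })
  })
  structure(
    list(task = doc$task, alpha = as.numeric(doc$alpha), schema = schema,
         n = as.integer(unlist(doc$n)), tables = tables),
    class = "sbce_model"
  )
}
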