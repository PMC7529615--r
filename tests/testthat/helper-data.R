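# Small in-code fixtures and independent oracles shared across tests.

feature_cols <- paste0("f", 1:9)

# A readings tibble from an integer matrix (n x 9) plus optional labels.
tiny_cohort <- function(f, marsh = NULL, disease = NULL,
                        patient_id = NULL, reader_id = NULL) {
  d <- tibble::as_tibble(as.data.frame(f))
  names(d) <- feature_cols
  if (!is.null(marsh)) d$marsh <- marsh
  if (!is.null(disease)) d$disease <- disease
  if (!is.null(patient_id)) d$patient_id <- patient_id
  if (!is.null(reader_id)) d$reader_id <- reader_id
  d
}

# A reading with every feature at its normal level, optionally perturbed.
normal_reading <- function(...) {
  r <- rep(1L, 9L)
  mods <- list(...)
  for (nm in names(mods)) r[as.integer(sub("f", "", nm))] <- mods[[nm]]
  r
}

# Random labelled cohort: uniform feature levels, random labels.
random_labelled_cohort <- function(seed, n, task = "disease",
                                  class_prob = c(0.5, 0.5)) {
  withr::with_seed(seed, {
    f <- cbind(
      sample(1:2, n, TRUE), sample(1:3, n, TRUE),
      matrix(sample(1:2, n * 7L, TRUE), n, 7L)
    )
    cls <- sample(1:2, n, TRUE, prob = class_prob)
    if (task == "disease") {
      tiny_cohort(f, disease = c("SNVA", "CD")[cls])
    } else {
      grades <- list(c("0", "1", "2"), c("3a", "3b", "3c"))
      tiny_cohort(f, marsh = vapply(cls, function(cl) sample(grades[[cl]], 1L),
                                    character(1)))
    }
  })
}

# Independent brute-force oracle for the smoothed posterior-predictive
# tables: explicit row-by-row tallies, no calls into the fitted model.
brute_force_probs <- function(data, task, alpha = 1) {
  schema <- sbce_schema()
  cc <- class_codes(data, task)
  Ks <- vapply(schema$features, `[[`, integer(1), "K")
  out <- list()
  for (cl in 1:2) {
    for (i in seq_along(Ks)) {
      counts <- rep(0L, Ks[i])
      n <- 0L
      for (r in seq_len(nrow(data))) {
        if (cc[r] == cl) {
          k <- data[[feature_cols[i]]][r]
          counts[k] <- counts[k] + 1L
          n <- n + 1L
        }
      }
      out[[paste(cl, i)]] <- (counts + alpha) / (n + Ks[i] * alpha)
    }
  }
  out
}

# The frozen 8-reading cohort on which LOOCV naive-Bayes predictions differ
# depending on whether the class prior is re-estimated inside each fold or
# (incorrectly) taken from the full dataset; found by seeded search and
# verified by the brute-force oracle in test-evaluate.R.
prior_sensitive_cohort <- function() {
  f <- rbind(
    c(2L, 2L, 1L, 1L, 2L, 1L, 2L, 2L, 1L),
    c(2L, 3L, 1L, 2L, 2L, 1L, 2L, 2L, 1L),
    c(1L, 3L, 2L, 1L, 1L, 2L, 2L, 2L, 1L),
    c(1L, 1L, 1L, 1L, 2L, 1L, 1L, 1L, 2L),
    c(1L, 1L, 1L, 2L, 2L, 2L, 1L, 2L, 2L),
    c(1L, 1L, 2L, 1L, 2L, 2L, 2L, 2L, 1L),
    c(1L, 1L, 2L, 2L, 2L, 1L, 2L, 2L, 1L),
    c(2L, 3L, 2L, 2L, 2L, 2L, 2L, 2L, 2L)
  )
  tiny_cohort(f, disease = c("CD", "CD", "CD", "SNVA", "CD", "SNVA",
                             "SNVA", "SNVA"))
}

# Generating parameters with heavily overlapping classes, used for the
# Bayes-rate benchmark.
overlapping_lambda <- function() {
  list(
    list(c(.65, .35), c(.5, .3, .2), c(.65, .35), c(.6, .4), c(.65, .35),
         c(.7, .3), c(.7, .3), c(.9, .1), c(.8, .2)),
    list(c(.45, .55), c(.3, .3, .4), c(.45, .55), c(.4, .6), c(.45, .55),
         c(.55, .45), c(.55, .45), c(.88, .12), c(.6, .4))
  )
}

# Perfectly separable generating parameters: each class puts all its mass on
# a disjoint deterministic feature pattern.
separable_lambda <- function() {
  point <- function(K, k) { v <- rep(0, K); v[k] <- 1; v }
  Ks <- c(2L, 3L, rep(2L, 7L))
  list(
    lapply(Ks, function(K) point(K, 1L)),
    lapply(Ks, function(K) point(K, K))
  )
}
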