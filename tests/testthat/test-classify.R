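test_that("the smoothed class prior follows its add-one closed form", {
  empty <- tiny_cohort(matrix(integer(0), 0, 9))
  empty$disease <- character(0)
  p0 <- estimate_class_prior(empty, "disease")
  expect_equal(unname(p0$pi), c(0.5, 0.5))

  d <- reference_cohort(seed = 0)
  p <- estimate_class_prior(d, "disease")
  expect_equal(unname(p$pi), c(19, 64) / 83)
  expect_equal(unname(p$pi[["CD"]]), 64 / 83)
  praw <- estimate_class_prior(d, "disease", mode = "raw")
  expect_equal(unname(praw$pi), c(18, 63) / 81)
  expect_error(estimate_class_prior(empty, "disease", mode = "raw"),
               "empty")

  for (s in 1:5) {
    dd <- random_labelled_cohort(seed = s, n = sample(2:40, 1))
    pp <- estimate_class_prior(dd, "disease")
    expect_equal(sum(pp$pi), 1, tolerance = 1e-12)
    expect_identical(sum(pp$n_c), pp$n)
  }
})

test_that("a symmetric untrained model ties and falls back to class 1", {
  empty <- tiny_cohort(matrix(integer(0), 0, 9))
  empty$marsh <- character(0)
  m0 <- fit_class_model(empty, "severity")
  d <- tiny_cohort(rbind(normal_reading(), normal_reading(f3 = 2L)))
  p <- predict_max_likelihood(m0, d)
  expect_true(all(p$tie))
  expect_identical(p$predicted_class, c(1L, 1L))
  expect_identical(p$predicted_label, c("mild", "mild"))
  expect_equal(p$loglik_1, p$loglik_2)
})

test_that("a single discriminating feature decides the prediction", {
  # equal class sizes so all shared tables coincide; only scalloping (f5)
  # differs: class 2 always shows it, class 1 never does
  f <- rbind(
    matrix(rep(normal_reading(), 5), 5, 9, byrow = TRUE),
    matrix(rep(normal_reading(f5 = 2L), 5), 5, 9, byrow = TRUE)
  )
  d <- tiny_cohort(f, marsh = c(rep("0", 5), rep("3c", 5)))
  m <- fit_class_model(d, "severity")
  expect_gt(posterior_predictive(m, 2, 5, 2), posterior_predictive(m, 1, 5, 2))
  p <- predict_max_likelihood(m, tiny_cohort(rbind(normal_reading(f5 = 2L))))
  expect_identical(p$predicted_class, 2L)
  expect_false(p$tie)
  p1 <- predict_max_likelihood(m, tiny_cohort(rbind(normal_reading())))
  expect_identical(p1$predicted_class, 1L)
})

test_that("the max-likelihood rule agrees with an exhaustive comparison", {
  d <- random_labelled_cohort(seed = 31, n = 40)
  m <- fit_class_model(d, "disease")
  probe <- random_labelled_cohort(seed = 32, n = 100)
  p <- predict_max_likelihood(m, probe)
  for (r in seq_len(nrow(probe))) {
    reading <- as.integer(unlist(probe[r, feature_cols]))
    l1 <- reading_likelihood(m, reading, 1)
    l2 <- reading_likelihood(m, reading, 2)
    expect_identical(p$predicted_class[r], if (l2 > l1) 2L else 1L)
  }
})

test_that("with a uniform prior naive Bayes reduces to maximum likelihood", {
  d <- random_labelled_cohort(seed = 41, n = 60)
  m <- fit_class_model(d, "disease")
  probe <- random_labelled_cohort(seed = 42, n = 80)
  ml <- predict_max_likelihood(m, probe)
  nb <- predict_naive_bayes(m, uniform_class_prior("disease"), probe)
  expect_identical(nb$predicted_class, ml$predicted_class)
  # balanced training data gives a balanced smoothed prior: same reduction
  bal <- tiny_cohort(rbind(matrix(rep(normal_reading(), 3), 3, 9, byrow = TRUE),
                           matrix(rep(normal_reading(f4 = 2L), 3), 3, 9,
                                  byrow = TRUE)),
                     disease = c("SNVA", "SNVA", "SNVA", "CD", "CD", "CD"))
  mb <- fit_class_model(bal, "disease")
  pb <- estimate_class_prior(bal, "disease")
  expect_identical(
    predict_naive_bayes(mb, pb, probe)$predicted_class,
    predict_max_likelihood(mb, probe)$predicted_class
  )
})

test_that("equal likelihoods let the prior decide the posterior", {
  empty <- tiny_cohort(matrix(integer(0), 0, 9))
  empty$disease <- character(0)
  m0 <- fit_class_model(empty, "disease")
  prior <- structure(
    list(task = "disease", mode = "fixed", n = 0L, n_c = c(0L, 0L),
         pi = c(SNVA = 0.2, CD = 0.8)),
    class = "sbce_prior"
  )
  p <- predict_naive_bayes(m0, prior, tiny_cohort(rbind(normal_reading())))
  expect_equal(p$posterior_1, 0.2, tolerance = 1e-12)
  expect_equal(p$posterior_2, 0.8, tolerance = 1e-12)
  expect_identical(p$predicted_class, 2L)
  expect_identical(p$predicted_label, "CD")
})

test_that("naive Bayes posteriors normalise and obey the odds identity", {
  d <- random_labelled_cohort(seed = 51, n = 35)
  m <- fit_class_model(d, "disease")
  prior <- estimate_class_prior(d, "disease")
  probe <- random_labelled_cohort(seed = 52, n = 50)
  p <- predict_naive_bayes(m, prior, probe)
  expect_equal(p$posterior_1 + p$posterior_2, rep(1, nrow(probe)),
               tolerance = 1e-12)
  # explicit normalization oracle
  l1 <- exp(p$loglik_1); l2 <- exp(p$loglik_2)
  expect_equal(p$posterior_1, l1 * prior$pi[[1]] /
                 (l1 * prior$pi[[1]] + l2 * prior$pi[[2]]),
               tolerance = 1e-12)
  # posterior odds = likelihood ratio x prior odds
  expect_equal(p$posterior_2 / p$posterior_1,
               (l2 / l1) * (prior$pi[[2]] / prior$pi[[1]]),
               tolerance = 1e-12)
  # argmax of the posterior is the predicted class
  expect_identical(p$predicted_class,
                   ifelse(p$posterior_2 > p$posterior_1, 2L, 1L))
})

test_that("task mismatch between model and prior is rejected", {
  d <- random_labelled_cohort(seed = 61, n = 10)
  m <- fit_class_model(d, "disease")
  expect_error(predict_naive_bayes(m, uniform_class_prior("severity"), d),
               "task")
  expect_error(predict_readings(m, d, rule = "naive_bayes"), "prior")
})

test_that("prediction tables serialize to delimited text", {
  d <- random_labelled_cohort(seed = 71, n = 12)
  m <- fit_class_model(d, "disease")
  p <- predict_readings(m, d)
  path <- withr::local_tempfile(fileext = ".csv")
  write_predictions(p, path)
  back <- utils::read.csv(path)
  expect_identical(nrow(back), nrow(p))
  expect_identical(back$predicted_class, p$predicted_class)
})
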