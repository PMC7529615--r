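test_that("smoothed probability tables match hand-evaluated cases", {
  # class with no readings: prior alone, uniform over levels
  d <- tiny_cohort(rbind(normal_reading()), marsh = "3a")
  m <- fit_class_model(d, "severity")
  expect_equal(m$tables[[1]][[1]]$probs, c(0.5, 0.5))
  expect_equal(m$tables[[1]][[2]]$probs, rep(1 / 3, 3))

  # 4 readings in one class, 1 of them abnormal on a binary feature:
  # (4+... ) -> (2/3, 1/3)
  f <- rbind(normal_reading(), normal_reading(), normal_reading(),
             normal_reading(f5 = 2L))
  m2 <- fit_class_model(tiny_cohort(f, marsh = rep("3b", 4)), "severity")
  expect_equal(m2$tables[[2]][[5]]$probs, c(4 / 6, 2 / 6))
  expect_identical(m2$tables[[2]][[5]]$counts, c(3L, 1L))
  expect_identical(m2$tables[[2]][[5]]$n, 4L)

  # 40 of 50 at one level of a binary feature -> 41/52
  f3 <- rbind(matrix(rep(normal_reading(f5 = 2L), 40), 40, 9, byrow = TRUE),
              matrix(rep(normal_reading(), 10), 10, 9, byrow = TRUE))
  m3 <- fit_class_model(tiny_cohort(f3, marsh = rep("3c", 50)), "severity")
  expect_equal(posterior_predictive(m3, class = 2, feature = 5, level = 2),
               41 / 52)
})

test_that("every probability table is a distribution and strictly positive", {
  for (s in 1:5) {
    d <- random_labelled_cohort(seed = s, n = 25)
    m <- fit_class_model(d, "disease")
    for (cl in 1:2) {
      for (i in 1:9) {
        p <- m$tables[[cl]][[i]]$probs
        expect_equal(sum(p), 1, tolerance = 1e-12)
        expect_true(all(p > 0))
        expect_identical(sum(m$tables[[cl]][[i]]$counts),
                         m$tables[[cl]][[i]]$n)
      }
    }
  }
})

test_that("fitted probabilities equal an independent brute-force tally", {
  for (s in 1:10) {
    d <- random_labelled_cohort(seed = 100 + s, n = sample(3:30, 1))
    for (alpha in c(1, 0.5, 3)) {
      m <- fit_class_model(d, "disease", alpha = alpha)
      oracle <- brute_force_probs(d, "disease", alpha = alpha)
      for (cl in 1:2) {
        for (i in 1:9) {
          expect_identical(m$tables[[cl]][[i]]$probs, oracle[[paste(cl, i)]])
        }
      }
    }
  }
})

test_that("fit rejects invalid alpha and unlabelled readings", {
  d <- tiny_cohort(rbind(normal_reading()), marsh = "0")
  expect_error(fit_class_model(d, "severity", alpha = 0), "alpha")
  expect_error(fit_class_model(d, "severity", alpha = -1), "alpha")
  expect_error(fit_class_model(tiny_cohort(rbind(normal_reading())),
                               "severity"), "marsh")
})

test_that("posterior_predictive bounds-checks its indices", {
  d <- tiny_cohort(rbind(normal_reading()), marsh = "0")
  m <- fit_class_model(d, "severity")
  expect_error(posterior_predictive(m, 3, 1, 1), "class")
  expect_error(posterior_predictive(m, 1, 10, 1), "feature")
  expect_error(posterior_predictive(m, 1, 1, 3), "level")
  expect_error(posterior_predictive(m, 1, 2, 4), "level")
})

test_that("a reading's likelihood factorises over features", {
  # fully untrained model: (1/2)^8 * (1/3) = 1/768 for every reading
  empty <- tiny_cohort(matrix(integer(0), 0, 9))
  empty$marsh <- character(0)
  m0 <- fit_class_model(empty, "severity")
  r <- normal_reading(f2 = 2L, f4 = 2L)
  expect_equal(reading_likelihood(m0, r, class = 1), 1 / 768)
  expect_equal(reading_likelihood(m0, normal_reading(), class = 2), 1 / 768)

  # factorisation oracle on a fitted model
  d <- random_labelled_cohort(seed = 5, n = 20)
  m <- fit_class_model(d, "disease")
  for (s in 1:5) {
    r <- withr::with_seed(s, c(sample(1:2, 1), sample(1:3, 1),
                               sample(1:2, 7, TRUE)))
    for (cl in 1:2) {
      by_hand <- prod(vapply(1:9, function(i) {
        posterior_predictive(m, cl, i, r[i])
      }, numeric(1)))
      expect_equal(reading_likelihood(m, r, class = cl), by_hand,
                   tolerance = 1e-12)
      # log-domain companion agrees with the product
      expect_equal(exp(reading_likelihood(m, r, class = cl, log = TRUE)),
                   by_hand, tolerance = 1e-12)
      expect_gt(reading_likelihood(m, r, class = cl), 0)
    }
  }
})

test_that("the log-likelihood matrix agrees with per-reading evaluation", {
  d <- random_labelled_cohort(seed = 9, n = 15)
  m <- fit_class_model(d, "disease")
  ll <- log_likelihood_matrix(m, d)
  for (r in seq_len(nrow(d))) {
    reading <- as.integer(unlist(d[r, feature_cols]))
    expect_equal(ll[r, 1], reading_likelihood(m, reading, 1, log = TRUE))
    expect_equal(ll[r, 2], reading_likelihood(m, reading, 2, log = TRUE))
  }
})

test_that("increasing alpha pulls every table toward the uniform law", {
  d <- random_labelled_cohort(seed = 3, n = 30)
  alphas <- c(0.25, 1, 2, 5, 20, 100)
  fits <- lapply(alphas, function(a) fit_class_model(d, "disease", alpha = a))
  for (cl in 1:2) {
    for (i in 1:9) {
      K <- length(fits[[1]]$tables[[cl]][[i]]$probs)
      dist <- vapply(fits, function(m) {
        max(abs(m$tables[[cl]][[i]]$probs - 1 / K))
      }, numeric(1))
      expect_true(all(diff(dist) <= 1e-12))
    }
  }
})

test_that("feature histograms normalise per group and contrast the classes", {
  # untrained model: both classes uniform, all abnormal-mass contrasts 0
  empty <- tiny_cohort(matrix(integer(0), 0, 9))
  empty$disease <- character(0)
  m0 <- fit_class_model(empty, "disease")
  expect_equal(feature_contrasts(m0)$abnormal_diff, rep(0, 9))

  d <- random_labelled_cohort(seed = 21, n = 40)
  m <- fit_class_model(d, "disease")
  h <- feature_histograms(m)
  expect_identical(nrow(h), sum(rep(c(2L, 3L, rep(2L, 7L)), 2L)))
  groups <- split(h$probability, interaction(h$feature, h$class))
  expect_identical(length(groups), 18L)
  for (g in groups) expect_equal(sum(g), 1, tolerance = 1e-12)
  # contrasts agree with the histogram's own abnormal mass
  contr <- feature_contrasts(m)
  for (i in 1:9) {
    mass2 <- sum(h$probability[h$feature == i & h$class == 2 & h$level > 1])
    mass1 <- sum(h$probability[h$feature == i & h$class == 1 & h$level > 1])
    expect_equal(contr$abnormal_diff[i], mass2 - mass1, tolerance = 1e-12)
  }
})

test_that("fitted models serialize to YAML and back without loss", {
  d <- random_labelled_cohort(seed = 17, n = 25)
  m <- fit_class_model(d, "disease", alpha = 2)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model(m, path)
  back <- read_model(path)
  expect_equal(back$tables, m$tables, tolerance = 1e-15)
  expect_identical(back$task, m$task)
  expect_identical(back$alpha, m$alpha)
  expect_identical(back$n, m$n)
  # serialisation is deterministic: two writes are byte-identical
  path2 <- withr::local_tempfile(fileext = ".yaml")
  write_model(m, path2)
  expect_identical(readLines(path), readLines(path2))
  # predictions from the restored model are identical
  expect_equal(log_likelihood_matrix(back, d), log_likelihood_matrix(m, d))
})
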