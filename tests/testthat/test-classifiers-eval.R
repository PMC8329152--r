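test_that("roc_auc handles perfect, inverted and degenerate rankings", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.1), c(1, 1, 0))$auc, 1)
  expect_equal(roc_auc(c(0.9, 0.8, 0.1), c(0, 0, 1))$auc, 0)
  expect_error(roc_auc(c(0.2, 0.4), c(1, 1)), "single class")
})

test_that("roc curves are monotone with the right endpoints", {
  set.seed(5)
  rc <- roc_auc(runif(50), rbinom(50, 1, 0.4))
  expect_equal(rc$fpr[1], 0); expect_equal(rc$tpr[1], 0)
  expect_equal(rc$fpr[length(rc$fpr)], 1)
  expect_equal(rc$tpr[length(rc$tpr)], 1)
  expect_true(all(diff(rc$fpr) >= 0))
  expect_true(all(diff(rc$tpr) >= 0))
})

test_that("trapezoidal AUC equals the pairwise concordance oracle, with ties", {
  set.seed(6)
  for (rep in 1:25) {
    n <- sample(20:200, 1)
    scores <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # heavy ties
    labels <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels)$auc, concordance_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("the AUC agrees with an independent reference implementation", {
  set.seed(14)
  scores <- runif(150)
  labels <- rbinom(150, 1, 0.5)
  ours <- roc_auc(scores, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("the t test reproduces the pooled-variance closed form", {
  tt <- t_test_auc(c(0.7, 0.8, 0.9), c(0.7, 0.8, 0.9))
  expect_equal(tt$t_stat, 0)
  expect_equal(tt$p_value, 1)
  expect_false(tt$significant)

  expect_warning(td <- t_test_auc(rep(0.8, 4), rep(0.9, 4)), "degenerate")
  expect_lt(td$p_value, 1e-10)
  expect_true(td$significant)

  set.seed(7)
  a <- rnorm(30, 0.85, 0.02); b <- rnorm(30, 0.84, 0.02)
  tt2 <- t_test_auc(a, b)
  sp2 <- ((29 * var(a)) + (29 * var(b))) / 58
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 30 + 1 / 30))
  expect_equal(tt2$t_stat, t_hand, tolerance = 1e-12)
  expect_equal(tt2$df, 58)
  expect_equal(tt2$p_value, 2 * pt(-abs(t_hand), 58), tolerance = 1e-12)
  expect_error(t_test_auc(0.8, c(0.8, 0.9)), "length")
})

test_that("classifiers separate a separable toy and are seed-deterministic", {
  set.seed(8)
  x <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 4), 20, 2))
  y <- rep(0:1, each = 20)
  lg <- fit_classifier(x, y, "logistic")
  expect_equal(as.integer(predict_scores(lg, x) > 0.5), y)

  rf1 <- fit_classifier(x, y, "random_forest", seed = 3L)
  rf2 <- fit_classifier(x, y, "random_forest", seed = 3L)
  expect_identical(predict_scores(rf1, x), predict_scores(rf2, x))
  expect_error(fit_classifier(x, rep(1, 40), "logistic"), "single class")

  # floor frozen from a seeded oracle run on a separable cohort (observed 1.0)
  co <- generate_cohort(generator_config(400L, biomarker_effect = 4,
                                         noise_sd = 0.2, driver_noise = 0,
                                         render = FALSE, seed = 71L))
  sp <- supervised_split(co, "full", seed = 3L)
  fit <- fit_classifier(as.matrix(sp$train$records[, biomarker_names()]),
                        sp$train$labels, "random_forest", seed = 5L)
  auc <- roc_auc(predict_scores(fit, as.matrix(sp$test$records[, biomarker_names()])),
                 sp$test$labels)$auc
  expect_gt(auc, 0.95)
})

test_that("vertical ROC averaging is idempotent and splits extremes", {
  set.seed(9)
  rc <- roc_auc(runif(60), rbinom(60, 1, 0.5))
  one <- average_roc(list(rc))
  two <- average_roc(list(rc, rc))
  expect_equal(one$tpr, two$tpr)
  expect_equal(one$auc, two$auc)
  expect_equal(one$fpr, seq(0, 1, 0.01))

  perfect <- roc_auc(c(1, 1, 0, 0), c(1, 1, 0, 0))
  anti <- roc_auc(c(1, 1, 0, 0), c(0, 0, 1, 1))
  avg <- average_roc(list(perfect, anti))
  expect_equal(avg$auc, 0.5, tolerance = 0.01)
  expect_error(average_roc(list()), "no curves")
})

test_that("experiment repeats are deterministic and conserve sample counts", {
  co <- test_cohort_tabular()
  r1 <- run_experiment(co, 1, "semi", n_repeats = 3, seed = 5L)
  r2 <- run_experiment(co, 1, "semi", n_repeats = 3, seed = 5L)
  expect_identical(r1$random_forest$auc_samples, r2$random_forest$auc_samples)
  expect_identical(r1$logistic$auc_samples, r2$logistic$auc_samples)
  expect_equal(r1$random_forest$n_repeats, 3L)
  expect_error(run_experiment(co, 6, "full"), "1..5")
})

test_that("semi-supervised train sets extend the fully supervised ones", {
  co <- test_cohort_tabular()
  for (s in 1:3) {
    full <- supervised_split(co, "full", seed = s)
    semi <- supervised_split(co, "semi", seed = s)
    expect_true(all(full$train$index %in% semi$train$index))
    expect_identical(full$test$index, semi$test$index)
  }
})

test_that("image experiments refuse cohorts without volumes", {
  co <- test_cohort_tabular()
  expect_error(run_experiment(co, 3, "full", n_repeats = 1), "rendered volumes")
})
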