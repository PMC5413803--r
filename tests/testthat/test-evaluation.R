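test_that("LOOCV holds every subject out exactly once", {
  d <- make_blobs(n_per = 5, sep = 8, seed = 41)
  res <- loocv(d, classifier_spec("svm"))
  expect_equal(nrow(res), 10)
  expect_equal(sort(res$subject), sort(as.character(1:10)))
  expect_equal(res$actual, d$y)
})

test_that("LOOCV is deterministic under a fixed seed", {
  d <- make_blobs(n_per = 6, sep = 6, seed = 42)
  r1 <- loocv(d, classifier_spec("rf", n_trees = 25), seed = 9)
  r2 <- loocv(d, classifier_spec("rf", n_trees = 25), seed = 9)
  expect_identical(r1, r2)
})

test_that("LOOCV refuses folds that collapse to one class", {
  d <- labeled_dataset(matrix(rnorm(6), 3, 2), c(1, 1, -1))
  expect_error(loocv(d, classifier_spec("svm")), "fold",
               class = "pdt_training_error")
})

test_that("confusion metrics reproduce hand-computed reports", {
  # 16 patients / 10 controls with 1 missed patient and 2 false alarms
  pred <- c(rep(1, 15), -1, rep(-1, 8), 1, 1)
  act <- rep(c(1, -1), c(16, 10))
  cm <- confusion_metrics(pred, act)
  expect_equal(cm$tp, 15); expect_equal(cm$fn, 1)
  expect_equal(cm$tn, 8);  expect_equal(cm$fp, 2)
  expect_equal(cm$accuracy, 23 / 26)
  expect_equal(cm$sensitivity, 15 / 16)
  expect_equal(cm$specificity, 8 / 10)
  # F from precision 15/17 and recall 15/16
  p <- 15 / 17; r <- 15 / 16
  expect_equal(cm$f_measure, 2 * p * r / (p + r))

  all_right <- confusion_metrics(act, act)
  expect_equal(all_right$accuracy, 1)
  expect_equal(all_right$f_measure, 1)
})

test_that("undefined rates surface as NaN with a warning", {
  w <- capture_warnings(cm <- confusion_metrics(c(-1, -1), c(-1, -1)))
  expect_true(any(grepl("sensitivity", w)))
  expect_true(any(grepl("F-measure", w)))
  expect_true(is.nan(cm$sensitivity))
  expect_true(is.nan(cm$f_measure))
  expect_equal(cm$specificity, 1)
})

test_that("accuracy decomposes into class-weighted sensitivity/specificity", {
  withr::with_seed(43, {
    act <- rep(c(1, -1), c(9, 7))
    pred <- ifelse(runif(16) < 0.7, act, -act)
  })
  cm <- confusion_metrics(pred, act)
  expect_equal(cm$accuracy,
               (cm$sensitivity * 9 + cm$specificity * 7) / 16)
})

test_that("ROC endpoints, monotonicity and canonical AUCs", {
  act <- c(1, 1, -1, -1)
  perfect <- roc_auc(act, c(0.9, 0.8, 0.2, 0.1))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$roc$fpr[1], 0)
  expect_equal(perfect$roc$tpr[nrow(perfect$roc)], 1)
  expect_true(all(diff(perfect$roc$fpr) >= 0))
  expect_true(all(diff(perfect$roc$tpr) >= 0))

  # 3 concordant pairs of 4
  expect_equal(roc_auc(act, c(0.9, 0.8, 0.85, 0.1))$auc, 0.75)
  # all tied: chance
  expect_equal(roc_auc(act, rep(0.5, 4))$auc, 0.5)
  expect_error(roc_auc(c(1, 1), c(0.1, 0.2)), class = "pdt_contract_error")
})

test_that("trapezoidal AUC equals the concordant-pair oracle", {
  for (s in 1:25) {
    withr::with_seed(s, {
      n <- sample(4:12, 1)
      act <- c(1, -1, sample(c(1, -1), n - 2, replace = TRUE))
      scores <- round(rnorm(n), 1)  # coarse grid forces ties
    })
    expect_equal(roc_auc(act, scores)$auc, auc_by_pairs(act, scores),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  for (s in 1:5) {
    withr::with_seed(s, {
      act <- c(1, -1, sample(c(1, -1), 18, replace = TRUE))
      scores <- round(rnorm(20), 1)
    })
    ref <- as.numeric(pROC::auc(pROC::roc(act, scores, levels = c(-1, 1),
                                          direction = "<", quiet = TRUE)))
    expect_equal(roc_auc(act, scores)$auc, ref, tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  withr::with_seed(44, {
    act <- rep(c(1, -1), 10)
    scores <- rnorm(20)
  })
  base <- roc_auc(act, scores)$auc
  expect_equal(roc_auc(act, exp(scores))$auc, base)
  expect_equal(roc_auc(act, 3 * scores - 7)$auc, base)
})

test_that("group comparison returns 12 Welch tests", {
  co <- simulate_cohort(5, 5, seed = 45)
  f <- cohort_features(co)
  gc <- compare_groups(f)
  expect_equal(nrow(gc), 12)
  expect_equal(gc$feature, pdt_feature_names)
  # strongly shifted features must be highly significant
  expect_lt(gc$p[gc$feature == "WEAK-PRN-MAX"], 0.001)
})

test_that("identical group distributions give t = 0, p = 1", {
  base <- cohort_features(simulate_cohort(3, 0, seed = 46))
  f <- rbind(base, base)
  f$group <- rep(c("patient", "control"), each = 3)
  f$subject_id <- paste0("S", 1:6)
  gc <- compare_groups(f)
  expect_equal(gc$t, rep(0, 12))
  expect_equal(gc$p, rep(1, 12))
})

test_that("well-separated groups reject the null decisively", {
  withr::with_seed(47, {
    f10 <- matrix(rnorm(10 * 12), 10, 12)
    f20 <- matrix(rnorm(10 * 12, mean = 10), 10, 12)
  })
  df <- data.frame(subject_id = paste0("S", 1:20),
                   group = rep(c("patient", "control"), each = 10),
                   mrc = rep(c("4", "5"), each = 10),
                   rbind(f20, f10), check.names = FALSE)
  names(df)[4:15] <- pdt_feature_names
  gc <- compare_groups(df)
  expect_true(all(gc$p < 0.001))
})

test_that("relative improvement matches its printed arithmetic", {
  expect_equal(relative_improvement(.808, .885), 9.53)
  expect_equal(relative_improvement(.846, .923), 9.10)
  expect_equal(relative_improvement(0.5, 0.5), 0)
  expect_error(relative_improvement(0, 0.5), class = "pdt_contract_error")
})

test_that("pooled selection is optimistically biased relative to nested", {
  # weak-signal datasets: the pooled subset has seen the held-out subject
  spec <- classifier_spec("svm")
  accs <- vapply(1:50, function(s) {
    d <- make_informative(n = 10, m_inf = 1, m_noise = 2, effect = 0.5,
                          seed = 100 + s)
    pooled <- mean(with(loocv(d, spec, fs = "pooled", seed = s),
                        predicted == actual))
    nested <- mean(with(loocv(d, spec, fs = "nested", seed = s),
                        predicted == actual))
    pooled - nested
  }, numeric(1))
  expect_gte(mean(accs), 0)
})
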