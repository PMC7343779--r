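test_that("confusion metrics reproduce the published test-cohort arithmetic", {
  cm <- confusion_metrics(published_confusion())
  expect_equal(cm$accuracy, 100 * 50 / 66, tolerance = 1e-12)  # 75.7575...
  pc <- cm$per_class
  expect_equal(pc$n_true, c(24, 18, 15, 9))
  # column-normalised diagonal percentages
  expect_equal(pc$sensitivity_pct, 100 * c(21 / 24, 13 / 18, 10 / 15, 6 / 9),
               tolerance = 1e-12)
  # row-normalised (precision)
  expect_equal(pc$ppv_pct, 100 * c(21 / 25, 13 / 17, 10 / 14, 6 / 10),
               tolerance = 1e-12)
  expect_equal(pc$fdr_pct_row, 100 - pc$ppv_pct)
  expect_equal(pc$fdr_pct_column, 100 - pc$sensitivity_pct)
})

test_that("diagonal counts give perfect metrics and binary arithmetic is exact", {
  d <- diag(c(5, 7, 3, 4)); dimnames(d) <- list(ftd_class_levels(), ftd_class_levels())
  cm <- confusion_metrics(d)
  expect_equal(cm$accuracy, 100)
  expect_true(all(cm$per_class$sensitivity_pct == 100))
  expect_true(all(cm$per_class$ppv_pct == 100))

  b <- matrix(c(3, 1, 1, 3), 2, dimnames = list(c("HS", "FTD"), c("HS", "FTD")))
  cmb <- confusion_metrics(b, positive = "FTD")
  expect_equal(cmb$binary$acc_pct, 75)
  expect_equal(cmb$binary$sens, 0.75)
  expect_equal(cmb$binary$spec, 0.75)
  expect_equal(cmb$binary$ppv, 0.75)
  expect_equal(cmb$binary$npv, 0.75)

  z <- matrix(c(2, 0, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  cz <- confusion_metrics(z)
  expect_true(is.na(cz$per_class$ppv_pct[2]))  # empty predicted row
})

test_that("confusion metrics agree with a brute-force tally over random vectors", {
  set.seed(81)
  classes <- ftd_class_levels()
  for (i in 1:1000) {
    n <- sample(10:60, 1)
    truth <- sample(classes, n, replace = TRUE)
    pred <- sample(classes, n, replace = TRUE)
    counts <- confusion_bruteforce(pred, truth, classes)
    if (sum(diag(counts)) == 0 && sum(counts) == 0) next
    cm <- confusion_metrics(counts)
    expect_equal(cm$accuracy, 100 * mean(pred == truth), tolerance = 1e-12)
    for (k in seq_along(classes)) {
      nk <- sum(truth == classes[k])
      if (nk > 0) {
        expect_equal(cm$per_class$sensitivity_pct[k],
                     100 * sum(pred == classes[k] & truth == classes[k]) / nk,
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("PCA filter keeps informative structure and drops constants", {
  set.seed(91)
  n <- 200
  base1 <- rnorm(n); base2 <- rnorm(n)
  d <- data.frame(
    a1 = base1 + rnorm(n, 0, 0.05), a2 = base1 + rnorm(n, 0, 0.05),
    b1 = base2 + rnorm(n, 0, 0.05), b2 = base2 + rnorm(n, 0, 0.05),
    const = 1
  )
  expect_warning(pf <- pca_filter(d), "constant")
  expect_false("const" %in% pf$selected)
  # both correlation blocks must be represented
  expect_true(any(c("a1", "a2") %in% pf$selected))
  expect_true(any(c("b1", "b2") %in% pf$selected))
  expect_equal(pf$n_retained, 2)

  # i.i.d. features: roughly half the eigenvalues exceed 1, selection non-empty
  set.seed(92)
  d2 <- as.data.frame(matrix(rnorm(500 * 10), 500))
  pf2 <- pca_filter(d2)
  expect_gt(pf2$n_retained, 1)
  expect_lt(pf2$n_retained, 10)
  expect_gt(length(pf2$selected), 0)

  expect_error(pca_filter(d[, 1, drop = FALSE]),
               class = "cortexdti_parameter_error")
})

test_that("classifier selection is deterministic and finds the obvious winner", {
  set.seed(101)
  # tight, well-separated clusters: KNN-friendly geometry
  n <- 30
  d <- data.frame(
    diagnosis = rep(c("A", "B"), each = n),
    f1 = c(rnorm(n, 0, 0.15), rnorm(n, 3, 0.15)),
    f2 = c(rnorm(n, 0, 0.15), rnorm(n, 3, 0.15))
  )
  sr <- select_classifier(d, c("f1", "f2"), n_runs = 20, k_folds = 5,
                          master_seed = 7)
  expect_s3_class(sr, "selection_result")
  expect_equal(sum(sr$wins$wins), 20)
  # perfectly separable: every model ties at 100%, precedence gives KNN
  expect_equal(sr$winner, "KNN")
  expect_gte(max(sr$wins$wins), 18)

  sr2 <- select_classifier(d, c("f1", "f2"), n_runs = 20, k_folds = 5,
                           master_seed = 7)
  expect_identical(sr$wins, sr2$wins)
  expect_identical(sr$winners, sr2$winners)

  sr3 <- select_classifier(d, c("f1", "f2"), n_runs = 1, k_folds = 5,
                           master_seed = 1)
  expect_equal(sum(sr3$wins$wins), 1)
  expect_equal(sort(unique(sr3$wins$wins)), c(0L, 1L))

  expect_error(select_classifier(d, "f1", n_runs = 0),
               class = "cortexdti_parameter_error")
  expect_error(select_classifier(d[c(1:6, 31:36), ], c("f1", "f2"), n_runs = 1,
                                 k_folds = 10),
               class = "cortexdti_stratification_error")
})

test_that("train/test evaluation is exact on separable data and guards classes", {
  d <- data.frame(diagnosis = rep(c("A", "B"), each = 10),
                  f1 = rep(c(0, 5), each = 10) + rnorm(20, 0, 0.1))
  rep1 <- train_and_evaluate(d, d, "LDA", "f1")
  expect_equal(rep1$metrics$accuracy, 100)
  expect_equal(unname(diag(rep1$counts)), c(10, 10))

  expect_error(train_and_evaluate(d, transform(d, diagnosis = "C"), "LDA", "f1"),
               class = "cortexdti_unseen_class_error")
  expect_error(train_and_evaluate(d, d, "XGB", "f1"),
               class = "cortexdti_unknown_model_error")
})

test_that("every zoo model runs and all predictions stay in the label set", {
  set.seed(111)
  n <- 40
  d <- data.frame(
    diagnosis = rep(c("A", "B"), each = n / 2),
    f1 = rnorm(n) + rep(c(0, 1.5), each = n / 2),
    f2 = rnorm(n)
  )
  for (m in classifier_zoo()) {
    r <- train_and_evaluate(d, d, m, c("f1", "f2"), seed = 3)
    expect_equal(sum(r$counts), n)
    expect_gte(r$metrics$accuracy, 50)
  }
})

test_that("full multiclass protocol is deterministic and above chance on default cohorts", {
  cohorts <- make_cohorts(seed = 1)
  sel <- dplyr::filter(cohorts, cohort == "selection")
  train <- dplyr::filter(cohorts, cohort == "training")
  test <- dplyr::filter(cohorts, cohort == "test")

  pf <- pca_filter(sel, features = regional_feature_names())
  feats <- unique(c("angle_r_wb", pf$selected))
  rep1 <- train_and_evaluate(train, test, "KNN", feats, seed = 1)
  rep2 <- train_and_evaluate(train, test, "KNN", feats, seed = 1)
  expect_identical(rep1$counts, rep2$counts)

  # chance level implied by the class priors = majority-class fraction
  chance <- 100 * max(table(test$diagnosis)) / nrow(test)
  expect_gt(rep1$metrics$accuracy, chance)
  expect_equal(unname(colSums(rep1$counts)), c(24, 18, 15, 9))
})

test_that("label-permuted cohorts give chance-level accuracy", {
  cohorts <- make_cohorts(seed = 2)
  train <- dplyr::filter(cohorts, cohort == "training")
  test <- dplyr::filter(cohorts, cohort == "test")
  feats <- c("angle_r_wb", "perp_pd_wb", "md_wb", "gm_fr")
  set.seed(121)
  excess <- replicate(200, {
    tr <- train
    tr$diagnosis <- sample(tr$diagnosis)
    r <- suppressWarnings(train_and_evaluate(tr, test, "GNB", feats,
                                             seed = sample.int(1e6, 1)))
    # chance accuracy for these predictions: the hit rate expected if the
    # predicted labels were independent of the true ones
    pred_frac <- rowSums(r$counts) / sum(r$counts)
    true_frac <- colSums(r$counts) / sum(r$counts)
    r$metrics$accuracy - 100 * sum(pred_frac * true_frac)
  })
  se <- stats::sd(excess) / sqrt(length(excess))
  expect_lt(abs(mean(excess)), 4 * se + 1)
})
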