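#' Diagnostic class order
#'
#' Fixed class ordering used for confusion matrices and reports: healthy
#' subjects first, then the three FTD subtypes.
#'
#' @return Character vector `c("HS", "svPPA", "bvFTD", "nfvPPA")`.
#' @export
ftd_class_levels <- function() c("HS", "svPPA", "bvFTD", "nfvPPA")

#' The supervised classifier zoo
#'
#' The seven models compared during cross-validated selection, in the fixed
#' precedence order used to break ties: K-nearest neighbours, support vector
#' machine, elastic-net penalised logistic regression, logistic regression,
#' random forest, Gaussian naive Bayes, linear discriminant analysis.
#'
#' @return Character vector of model codes.
#' @export
classifier_zoo <- function() c("KNN", "SVM", "EN", "LR", "RF", "GNB", "LDA")

# Deterministic 31-bit seed derived from arbitrary components.
derive_seed <- function(...) {
  h <- rlang::hash(list(...))
  strtoi(substr(h, 1, 7), base = 16L) %% 2147483647L
}

# Stratified fold assignment: shuffle within class, deal round-robin.
stratified_folds <- function(y, k) {
  y <- factor(y)
  if (any(table(y) < k)) {
    abort(sprintf("stratified %d-fold CV needs >= %d subjects per class", k, k),
          class = "cortexdti_stratification_error")
  }
  folds <- integer(length(y))
  for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# Fit one zoo model on (scaled) training features and predict the test rows.
# Returns a factor with the training levels. Models that fail on a
# pathological fold (e.g. LDA with a constant within-class feature) fall
# back to predicting the training majority class.
fit_predict_model <- function(model, x_train, y_train, x_test,
                              knn_k = 5, svm_kernel = "radial",
                              en_alpha = 0.5, en_lambda = 0.05,
                              rf_ntree = 200) {
  y_train <- droplevels(factor(y_train))
  lv <- levels(y_train)
  majority <- lv[which.max(tabulate(y_train))]
  fallback <- function(e) factor(rep(majority, nrow(x_test)), levels = lv)
  pad <- function(m) if (ncol(m) >= 2L) m else cbind(m, .pad = 0)
  pred <- tryCatch(switch(
    model,
    KNN = class::knn(x_train, x_test, y_train, k = min(knn_k, nrow(x_train))),
    SVM = {
      fit <- e1071::svm(x = x_train, y = y_train, kernel = svm_kernel, scale = FALSE)
      predict(fit, x_test)
    },
    EN = {
      fam <- if (length(lv) == 2L) "binomial" else "multinomial"
      fit <- suppressWarnings(glmnet::glmnet(pad(x_train), y_train, family = fam,
                                             alpha = en_alpha, lambda = en_lambda))
      cls <- predict(fit, pad(x_test), type = "class")
      factor(as.vector(cls), levels = lv)
    },
    LR = {
      if (length(lv) == 2L) {
        df <- data.frame(x_train); df$.y <- y_train
        fit <- suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
        pr <- predict(fit, data.frame(x_test), type = "response")
        factor(ifelse(pr > 0.5, lv[2L], lv[1L]), levels = lv)
      } else {
        df <- data.frame(x_train); df$.y <- y_train
        fit <- nnet::multinom(.y ~ ., data = df, trace = FALSE)
        predict(fit, data.frame(x_test))
      }
    },
    RF = {
      fit <- randomForest::randomForest(x = x_train, y = y_train, ntree = rf_ntree)
      predict(fit, x_test)
    },
    GNB = {
      fit <- e1071::naiveBayes(x = data.frame(x_train), y = y_train)
      predict(fit, data.frame(x_test))
    },
    LDA = {
      fit <- MASS::lda(x_train, grouping = y_train)
      predict(fit, x_test)$class
    },
    abort(sprintf("unknown model '%s'; zoo: %s", model,
                  paste(classifier_zoo(), collapse = ", ")),
          class = "cortexdti_unknown_model_error")
  ), error = function(e) {
    if (inherits(e, "cortexdti_unknown_model_error")) stop(e)
    fallback(e)
  })
  factor(as.character(pred), levels = lv)
}

# Column means/sds from training data for z-scoring; constant columns get
# sd 1 so they standardise to 0 rather than NaN.
scale_params <- function(x) {
  mu <- colMeans(x)
  sig <- apply(x, 2L, sd)
  sig[sig == 0 | is.na(sig)] <- 1
  list(mu = mu, sig = sig)
}

apply_scale <- function(x, p) sweep(sweep(x, 2L, p$mu), 2L, p$sig, "/")

#' Select the best classifier by repeated cross-validated majority vote
#'
#' Runs a stratified k-fold cross-validation scheme repeatedly on the
#' selection cohort. In each run every zoo model is scored by its mean
#' held-out-fold accuracy; the run's winner is the highest-scoring model
#' (ties broken by the fixed zoo order), and the overall winner is the model
#' with the most wins over all runs. Features are z-scored with statistics
#' from the training folds only. The whole procedure is deterministic under
#' `master_seed`.
#'
#' @param data Cohort data frame (one row per subject).
#' @param features Character vector of feature column names.
#' @param label Name of the class column (default `"diagnosis"`).
#' @param n_runs Number of cross-validation runs (default 1000).
#' @param k_folds Folds per run (default 10).
#' @param master_seed Master seed; run r uses a seed derived from
#'   (master_seed, r).
#' @param models Candidate model codes (default [classifier_zoo()]).
#' @param ... Passed to the model fitters (e.g. `knn_k`, `rf_ntree`).
#' @return A `selection_result`: `wins` tibble (model, wins), `winner`,
#'   `mean_accuracy` per model, and the run parameters.
#' @export
select_classifier <- function(data, features, label = "diagnosis",
                              n_runs = 1000L, k_folds = 10L, master_seed = 1L,
                              models = classifier_zoo(), ...) {
  if (n_runs < 1L) abort("n_runs must be >= 1", class = "cortexdti_parameter_error")
  if (k_folds < 2L) abort("k_folds must be >= 2", class = "cortexdti_parameter_error")
  y <- factor(data[[label]])
  x <- as.matrix(data[, features, drop = FALSE])
  storage.mode(x) <- "double"
  if (anyNA(x)) abort("missing feature values; impute explicitly first",
                      class = "cortexdti_contract_error")
  if (any(table(y) < k_folds)) {
    abort(sprintf("class smaller than k_folds = %d; cannot stratify", k_folds),
          class = "cortexdti_stratification_error")
  }

  acc_runs <- matrix(NA_real_, n_runs, length(models),
                     dimnames = list(NULL, models))
  winners <- character(n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(derive_seed("folds", master_seed, r))
    folds <- stratified_folds(y, k_folds)
    fold_acc <- matrix(NA_real_, k_folds, length(models))
    for (f in seq_len(k_folds)) {
      tr <- folds != f; te <- folds == f
      sp <- scale_params(x[tr, , drop = FALSE])
      xtr <- apply_scale(x[tr, , drop = FALSE], sp)
      xte <- apply_scale(x[te, , drop = FALSE], sp)
      for (m in seq_along(models)) {
        set.seed(derive_seed("fit", master_seed, r, f, models[m]))
        pred <- fit_predict_model(models[m], xtr, y[tr], xte, ...)
        fold_acc[f, m] <- mean(pred == y[te])
      }
    }
    acc_runs[r, ] <- colMeans(fold_acc)
    winners[r] <- models[which.max(acc_runs[r, ])]  # which.max = first max: zoo-order ties
  }

  wins <- tibble(model = models,
                 wins = vapply(models, function(m) sum(winners == m), 0L),
                 mean_accuracy = colMeans(acc_runs))
  structure(
    list(wins = wins, winner = wins$model[which.max(wins$wins)],
         winners = winners, n_runs = n_runs, k_folds = k_folds,
         master_seed = master_seed, models = models),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> winner: %s (%d/%d runs, %d-fold CV, seed %d)\n",
              x$winner, max(x$wins$wins), x$n_runs, x$k_folds, x$master_seed))
  invisible(x)
}

#' @exportS3Method
tidy.selection_result <- function(x, ...) x$wins

#' @exportS3Method
glance.selection_result <- function(x, ...) {
  tibble(winner = x$winner, wins = max(x$wins$wins), n_runs = x$n_runs,
         win_fraction = max(x$wins$wins) / x$n_runs, k_folds = x$k_folds,
         master_seed = x$master_seed)
}

#' Train the chosen classifier and evaluate it on the test cohort
#'
#' Fits the named model on the training cohort (features z-scored with
#' training statistics only) and predicts the test cohort, assembling the
#' confusion counts (rows = predicted, columns = true) in a fixed class
#' order and deriving the performance report via [confusion_metrics()].
#'
#' @param train,test Cohort data frames.
#' @param model Model code from [classifier_zoo()].
#' @param features Feature column names.
#' @param label Class column name (default `"diagnosis"`).
#' @param class_order Class ordering for the confusion matrix; defaults to
#'   [ftd_class_levels()] when the labels match it, else sorted levels.
#' @param positive Positive class for binary reductions (defaults to the
#'   second class in `class_order` for 2-class problems, i.e. the patient
#'   group when the order is control-first).
#' @param seed Seed for stochastic fitters.
#' @param ... Passed to the model fitter.
#' @return A `classification_report`: confusion `counts`, `metrics`
#'   ([confusion_metrics()] output), `model`, `features`.
#' @export
train_and_evaluate <- function(train, test, model, features,
                               label = "diagnosis", class_order = NULL,
                               positive = NULL, seed = 1L, ...) {
  ytr <- factor(train[[label]]); yte_chr <- as.character(test[[label]])
  unseen <- setdiff(unique(yte_chr), levels(ytr))
  if (length(unseen)) {
    abort(paste("test classes absent from training data:",
                paste(unseen, collapse = ", ")),
          class = "cortexdti_unseen_class_error")
  }
  if (is.null(class_order)) {
    class_order <- if (all(levels(ytr) %in% ftd_class_levels())) {
      intersect(ftd_class_levels(), levels(ytr))
    } else sort(levels(ytr))
  }
  ytr <- factor(as.character(ytr), levels = class_order)
  yte <- factor(yte_chr, levels = class_order)

  xtr <- as.matrix(train[, features, drop = FALSE])
  xte <- as.matrix(test[, features, drop = FALSE])
  storage.mode(xtr) <- "double"; storage.mode(xte) <- "double"
  sp <- scale_params(xtr)
  set.seed(derive_seed("train", seed, model))
  pred <- fit_predict_model(model, apply_scale(xtr, sp), ytr,
                            apply_scale(xte, sp), ...)
  pred <- factor(as.character(pred), levels = class_order)

  counts <- table(predicted = pred, true = yte)
  counts <- unclass(counts)
  if (is.null(positive) && length(class_order) == 2L) positive <- class_order[2L]
  metrics <- confusion_metrics(counts, positive = positive)
  structure(
    list(counts = counts, metrics = metrics, model = model,
         features = features, class_order = class_order, seed = seed),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> %s on %d features: accuracy %.2f%%\n",
              x$model, length(x$features), x$metrics$accuracy))
  print(x$counts)
  invisible(x)
}

#' @exportS3Method
tidy.classification_report <- function(x, ...) x$metrics$per_class

#' @exportS3Method
glance.classification_report <- function(x, ...) {
  g <- tibble(model = x$model, n_features = length(x$features),
              accuracy = x$metrics$accuracy, n_test = sum(x$counts))
  if (!is.null(x$metrics$binary)) g <- dplyr::bind_cols(g, x$metrics$binary)
  g
}

#' Performance metrics from a confusion matrix
#'
#' Computes overall accuracy and per-class metrics from square confusion
#' counts with rows = predicted class and columns = true class. Two
#' normalisations of the per-class false discovery rate are reported
#' explicitly: `fdr_pct_row` = 100 - precision (the usual FDR) and
#' `fdr_pct_column` = 100 - recall (the column-normalised complement some
#' reports use); consumers choose by name rather than by guessing the
#' convention. Classes with an empty row or column get NA (undefined)
#' metrics rather than NaN propagation.
#'
#' @param counts Square numeric matrix of confusion counts (rows predicted,
#'   columns true), with dimnames giving the class order.
#' @param positive For 2-class problems, the positive class; enables the
#'   binary ACC/SENS/SPEC/PPV/NPV reduction.
#' @return A `metric_report`: `accuracy` (percent), `per_class` tibble
#'   (class, n_true, sensitivity_pct, specificity_pct, ppv_pct, npv_pct,
#'   fdr_pct_row, fdr_pct_column), and `binary` one-row tibble (or NULL).
#' @export
#' @examples
#' counts <- matrix(c(3, 1, 1, 3), 2, dimnames = list(c("HS", "FTD"), c("HS", "FTD")))
#' confusion_metrics(counts, positive = "FTD")$accuracy  # 75
confusion_metrics <- function(counts, positive = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts) || nrow(counts) < 2L) {
    abort("counts must be a square matrix with >= 2 classes",
          class = "cortexdti_contract_error")
  }
  if (any(counts < 0) || sum(counts) == 0) {
    abort("counts must be non-negative and non-empty",
          class = "cortexdti_contract_error")
  }
  classes <- rownames(counts) %||% paste0("class", seq_len(nrow(counts)))
  total <- sum(counts)
  accuracy <- 100 * sum(diag(counts)) / total

  per_class <- purrr::map_dfr(seq_along(classes), function(i) {
    tp <- counts[i, i]
    fn <- sum(counts[, i]) - tp
    fp <- sum(counts[i, ]) - tp
    tn <- total - tp - fn - fp
    col_n <- tp + fn; row_n <- tp + fp
    sens <- if (col_n > 0) 100 * tp / col_n else NA_real_
    spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
    ppv <- if (row_n > 0) 100 * tp / row_n else NA_real_
    npv <- if (tn + fn > 0) 100 * tn / (tn + fn) else NA_real_
    tibble(
      class = classes[i], n_true = col_n,
      sensitivity_pct = sens, specificity_pct = spec,
      ppv_pct = ppv, npv_pct = npv,
      fdr_pct_row = if (is.na(ppv)) NA_real_ else 100 - ppv,
      fdr_pct_column = if (is.na(sens)) NA_real_ else 100 - sens
    )
  })

  binary <- NULL
  if (!is.null(positive)) {
    if (nrow(counts) != 2L) {
      abort("binary reduction needs a 2 x 2 confusion matrix",
            class = "cortexdti_contract_error")
    }
    if (!positive %in% classes) {
      abort(sprintf("positive class '%s' not among classes", positive),
            class = "cortexdti_contract_error")
    }
    pc <- per_class[per_class$class == positive, ]
    binary <- tibble(positive = positive, acc_pct = accuracy,
                     sens = pc$sensitivity_pct / 100,
                     spec = pc$specificity_pct / 100,
                     ppv = pc$ppv_pct / 100, npv = pc$npv_pct / 100)
  }

  structure(list(accuracy = accuracy, per_class = per_class, binary = binary,
                 counts = counts),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> overall accuracy %.2f%% (n = %d)\n",
              x$accuracy, sum(x$counts)))
  print(x$per_class)
  invisible(x)
}

#' @exportS3Method
tidy.metric_report <- function(x, ...) x$per_class

#' @exportS3Method
glance.metric_report <- function(x, ...) {
  tibble(accuracy = x$accuracy, n = sum(x$counts), n_classes = nrow(x$per_class))
}

#' PCA-based feature filter
#'
#' Filters a feature set the way a factor-analysis screen does: features are
#' standardised, principal components with eigenvalue > 1 retained (Kaiser
#' criterion; alternatively a fixed number), and a feature is selected when
#' the absolute value of its loading (component correlation, i.e.
#' eigenvector scaled by the component standard deviation) on any retained
#' component reaches `loading_threshold`. Constant features are dropped with
#' a warning before the PCA. If no feature reaches the threshold the
#' highest-loading feature of each retained component is selected so the
#' filter never returns an empty set.
#'
#' @param data Data frame of observations.
#' @param features Feature column names (default: all numeric columns).
#' @param retention `"kaiser"` (default) or `"n_components"`.
#' @param n_components Number of components when `retention = "n_components"`.
#' @param loading_threshold Minimum absolute loading (default 0.5).
#' @return A `pca_filter` object: `selected` feature names (input order),
#'   `eigenvalues`, `loadings` (features x retained components),
#'   `dropped_constant`.
#' @export
pca_filter <- function(data, features = NULL,
                       retention = c("kaiser", "n_components"),
                       n_components = NULL, loading_threshold = 0.5) {
  retention <- match.arg(retention)
  if (is.null(features)) {
    features <- names(data)[vapply(data, is.numeric, TRUE)]
  }
  if (length(features) < 2L) {
    abort("pca_filter needs >= 2 features", class = "cortexdti_parameter_error")
  }
  x <- as.matrix(data[, features, drop = FALSE])
  if (nrow(x) <= 2L) {
    abort("pca_filter needs n > 2 observations", class = "cortexdti_parameter_error")
  }
  sds <- apply(x, 2L, sd)
  dropped <- features[sds == 0 | is.na(sds)]
  if (length(dropped)) {
    warn(paste("dropping constant features:", paste(dropped, collapse = ", ")))
    features <- setdiff(features, dropped)
    x <- x[, features, drop = FALSE]
  }
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  eigenvalues <- pc$sdev^2
  n_ret <- if (retention == "kaiser") max(1L, sum(eigenvalues > 1)) else {
    if (is.null(n_components)) {
      abort("n_components required", class = "cortexdti_parameter_error")
    }
    min(n_components, length(eigenvalues))
  }
  # Component loadings = eigenvector * sqrt(eigenvalue): the feature-component
  # correlations on standardised data.
  load <- pc$rotation[, seq_len(n_ret), drop = FALSE] %*%
    diag(pc$sdev[seq_len(n_ret)], n_ret)
  colnames(load) <- paste0("PC", seq_len(n_ret))
  hit <- apply(abs(load) >= loading_threshold, 1L, any)
  if (!any(hit)) {
    hit[unique(apply(abs(load), 2L, which.max))] <- TRUE
  }
  selected <- features[hit]
  structure(
    list(selected = selected, eigenvalues = eigenvalues, loadings = load,
         n_retained = n_ret, loading_threshold = loading_threshold,
         dropped_constant = dropped),
    class = "pca_filter"
  )
}

#' @export
print.pca_filter <- function(x, ...) {
  cat(sprintf("<pca_filter> %d components retained, %d features selected\n",
              x$n_retained, length(x$selected)))
  cat(" ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method
tidy.pca_filter <- function(x, ...) {
  as_tibble(x$loadings, rownames = "feature") |>
    tidyr::pivot_longer(-"feature", names_to = "component", values_to = "loading") |>
    dplyr::mutate(selected = .data$feature %in% x$selected)
}

#' @exportS3Method
glance.pca_filter <- function(x, ...) {
  tibble(n_features = nrow(x$loadings), n_retained = x$n_retained,
         n_selected = length(x$selected),
         loading_threshold = x$loading_threshold)
}
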