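#' Evaluate work-task classifiers on a feature table
#'
#' A stratified test split is carved out first and never seen during
#' training or validation. The remaining windows are divided into `k`
#' stratified folds; for every classifier family the model trained on each
#' fold complement is scored on its validation fold, the fold-model with the
#' highest validation accuracy is retained, and that model is evaluated once
#' on the held-out test split.
#'
#' Five classical families are evaluated: multinomial logistic regression,
#' decision tree, RBF support-vector machine, random forest and k-nearest
#' neighbors. Accuracy, precision, recall and F1 are reported as
#' support-weighted averages over classes; ROC AUC and AUPRC are
#' micro-averaged one-vs-rest over the predicted class-probability matrix.
#'
#' @param dataset data frame from [build_dataset()]: a `label` factor column
#'   followed by numeric features.
#' @param k number of cross-validation folds (default 10).
#' @param test_fraction stratified held-out test share (default 0.2).
#' @param seed integer seed; the whole evaluation is deterministic given it.
#' @param classifiers subset of
#'   `c("logistic", "tree", "svm", "random_forest", "knn")`.
#' @param config hyperparameters: `svm_cost`, `rf_trees`, `knn_k`,
#'   `logit_maxit`.
#' @return an `"evaluation_report"`: per classifier the test metrics
#'   (`accuracy`, `precision`, `recall`, `f1`, `auc`, `auprc`), per-class
#'   precision/recall/F1 and the per-fold validation accuracies.
#' @export
evaluate_classifiers <- function(dataset, k = 10, test_fraction = 0.2, seed = 1,
                                 classifiers = c("logistic", "tree", "svm",
                                                 "random_forest", "knn"),
                                 config = list()) {
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  cfg <- utils::modifyList(
    list(svm_cost = 1, rf_trees = 100, knn_k = 5, logit_maxit = 200), config)
  y <- dataset$label
  if (!is.factor(y)) y <- factor(y)
  X <- as.matrix(dataset[, setdiff(names(dataset), "label"), drop = FALSE])
  if (any(!is.finite(X)))
    pk_stop("posturekit_malformed_trace", "feature table contains non-finite values")
  classes <- levels(y)
  set.seed(seed)

  test_idx <- stratified_sample(y, test_fraction)
  trainval <- setdiff(seq_along(y), test_idx)
  if (any(table(y[trainval]) < k))
    pk_stop("posturekit_insufficient_samples",
            sprintf("every class needs at least %d training windows for %d-fold CV", k, k))
  folds <- stratified_folds(y[trainval], k)

  report <- list()
  for (clf in classifiers) {
    fold_acc <- numeric(k)
    best <- NULL
    for (f in seq_len(k)) {
      tr <- trainval[folds != f]
      va <- trainval[folds == f]
      fit <- fit_classifier(clf, X[tr, , drop = FALSE], y[tr], cfg)
      pred <- predict_classifier(fit, X[va, , drop = FALSE])
      fold_acc[f] <- mean(pred$class == y[va])
      if (is.null(best) || fold_acc[f] > best$acc) best <- list(fit = fit, acc = fold_acc[f])
    }
    pred <- predict_classifier(best$fit, X[test_idx, , drop = FALSE])
    report[[clf]] <- c(
      test_metrics(y[test_idx], pred$class, pred$prob, classes),
      list(fold_accuracy = fold_acc, validation_accuracy = best$acc)
    )
  }
  structure(list(classifiers = report, k = k, seed = seed,
                 n_test = length(test_idx), n_train = length(trainval),
                 classes = classes),
            class = "evaluation_report")
}

stratified_sample <- function(y, fraction) {
  unlist(lapply(split(seq_along(y), y), function(i)
    sample(i, max(1L, round(length(i) * fraction)))), use.names = FALSE)
}

stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (i in split(seq_along(y), y))
    folds[sample(i)] <- rep_len(seq_len(k), length(i))
  folds
}

fit_classifier <- function(clf, X, y, cfg) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, ctr, scl)
  fit <- switch(clf,
    logistic = {
      df <- data.frame(y = y, Xs, check.names = TRUE)
      nnet::multinom(y ~ ., data = df, trace = FALSE,
                     maxit = cfg$logit_maxit, MaxNWts = 5000)
    },
    tree = {
      df <- data.frame(y = y, Xs, check.names = TRUE)
      rpart::rpart(y ~ ., data = df, method = "class")
    },
    svm = e1071::svm(Xs, y, kernel = "radial", cost = cfg$svm_cost,
                     probability = TRUE, scale = FALSE),
    random_forest = randomForest::randomForest(Xs, y, ntree = cfg$rf_trees),
    knn = caret::knn3(Xs, y, k = cfg$knn_k)
  )
  list(clf = clf, fit = fit, center = ctr, scale = scl, levels = levels(y))
}

predict_classifier <- function(model, X) {
  Xs <- scale(X, model$center, model$scale)
  prob <- switch(model$clf,
    logistic = {
      df <- data.frame(Xs, check.names = TRUE)
      p <- stats::predict(model$fit, newdata = df, type = "probs")
      if (is.null(dim(p))) p <- matrix(p, nrow = nrow(Xs), byrow = TRUE)
      p
    },
    tree = stats::predict(model$fit, data.frame(Xs, check.names = TRUE), type = "prob"),
    svm = {
      p <- stats::predict(model$fit, Xs, probability = TRUE)
      attr(p, "probabilities")[, model$levels, drop = FALSE]
    },
    random_forest = stats::predict(model$fit, Xs, type = "prob"),
    knn = stats::predict(model$fit, Xs, type = "prob")
  )
  prob <- as.matrix(prob)
  colnames(prob) <- colnames(prob) %||% model$levels
  prob <- prob[, model$levels, drop = FALSE]
  cls <- factor(model$levels[max.col(prob, ties.method = "first")],
                levels = model$levels)
  list(class = cls, prob = prob)
}

test_metrics <- function(truth, pred, prob, classes) {
  truth <- factor(truth, levels = classes)
  pred <- factor(pred, levels = classes)
  cm <- table(truth, pred)
  support <- rowSums(cm)
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  wts <- support / sum(support)
  onehot <- outer(as.character(truth), classes, "==") * 1
  list(
    accuracy = sum(tp) / sum(cm),
    precision = sum(wts * prec),
    recall = sum(wts * rec),
    f1 = sum(wts * f1),
    auc = micro_auc(onehot, prob),
    auprc = micro_auprc(onehot, prob),
    per_class = data.frame(class = classes, support = as.numeric(support),
                           precision = as.numeric(prec), recall = as.numeric(rec),
                           f1 = as.numeric(f1))
  )
}

# Micro-averaged one-vs-rest ROC AUC: flatten the indicator matrix against
# the probability matrix and treat it as one binary problem.
micro_auc <- function(onehot, prob) {
  resp <- as.vector(onehot)
  sc <- as.vector(prob)
  if (length(unique(resp)) < 2L) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(resp, sc, quiet = TRUE, direction = "<")))
}

# Micro-averaged average precision (area under the precision-recall curve,
# step interpolation): AP = sum over positives of precision at each recall step.
micro_auprc <- function(onehot, prob) {
  resp <- as.vector(onehot)
  sc <- as.vector(prob)
  ord <- order(sc, decreasing = TRUE)
  resp <- resp[ord]
  tp <- cumsum(resp)
  precision <- tp / seq_along(resp)
  recall <- tp / sum(resp)
  dr <- diff(c(0, recall))
  sum(precision * dr)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d-fold CV, %d train / %d test windows, seed %d\n",
              x$k, x$n_train, x$n_test, x$seed))
  m <- t(vapply(x$classifiers, function(r)
    unlist(r[c("accuracy", "precision", "recall", "f1", "auc", "auprc")]),
    numeric(6)))
  print(round(m, 4))
  invisible(x)
}
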