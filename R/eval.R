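#' Confusion matrix
#'
#' Rows index the true class, columns the predicted class; entry `(t, p)`
#' counts items of true class `t` predicted as `p`.
#'
#' @param y_true,y_pred Integer labels in `0..num_classes-1`, equal lengths.
#' @param num_classes Number of classes; inferred from the labels when `NULL`.
#' @param class_names Optional label names (defaults to `"0"`, `"1"`, ...).
#' @return Integer matrix of class `fwn_confusion`.
#' @export
confusion <- function(y_true, y_pred, num_classes = NULL,
                      class_names = NULL) {
  if (length(y_true) != length(y_pred))
    stop("confusion: label vectors differ in length", call. = FALSE)
  if (is.null(num_classes)) num_classes <- max(y_true, y_pred) + 1L
  if (any(y_true < 0 | y_true >= num_classes |
          y_pred < 0 | y_pred >= num_classes))
    stop("confusion: labels out of range", call. = FALSE)
  cm <- matrix(0L, num_classes, num_classes)
  for (i in seq_along(y_true))
    cm[y_true[i] + 1L, y_pred[i] + 1L] <- cm[y_true[i] + 1L,
                                             y_pred[i] + 1L] + 1L
  if (is.null(class_names)) class_names <- as.character(0:(num_classes - 1L))
  dimnames(cm) <- list(true = class_names, predicted = class_names)
  class(cm) <- c("fwn_confusion", class(cm))
  cm
}

#' Per-class sensitivity (recall)
#'
#' Fraction of items of true class `c` that were predicted as class `c`:
#' the diagonal entry over its row sum.
#'
#' @param cm A confusion matrix (true classes in rows).
#' @param c Zero-based class index.
#' @return Fraction in `[0, 1]`; `NA` with a warning when the class has no
#'   support.
#' @examples
#' cm <- matrix(c(480, 6, 12, 2), 1, 4)
#' # sensitivity of a 1-row slice: 480 / 500 = 0.96
#' @export
sensitivity <- function(cm, c) {
  i <- c + 1L
  denom <- sum(cm[i, ])
  if (denom == 0) {
    warning("sensitivity undefined: class has zero support")
    return(NA_real_)
  }
  cm[i, i] / denom
}

#' Per-class precision (positive predictive value)
#'
#' Fraction of items predicted as class `c` that truly are class `c`: the
#' diagonal entry over its column sum.
#'
#' @inheritParams sensitivity
#' @return Fraction in `[0, 1]`; `NA` with a warning for an empty column.
#' @export
precision <- function(cm, c) {
  i <- c + 1L
  denom <- sum(cm[, i])
  if (denom == 0) {
    warning("precision undefined: nothing predicted as this class")
    return(NA_real_)
  }
  cm[i, i] / denom
}

#' Overall accuracy of a confusion matrix
#' @param cm A confusion matrix.
#' @return Trace over total count.
#' @export
accuracy <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("accuracy: empty confusion matrix", call. = FALSE)
  sum(diag(cm)) / total
}

#' ROC curve by threshold sweep, with trapezoidal AUC
#'
#' Sweeps the decision threshold across the unique score values (classifying
#' `score >= threshold` as positive), yielding one (FPR, TPR) point per
#' threshold plus the fixed endpoints (0,0) and (1,1); the AUC is the
#' trapezoidal area under the resulting curve.
#'
#' @param scores Numeric scores, higher meaning more positive.
#' @param y_true Binary labels (0/1 or logical); both classes must appear.
#' @return List of class `fwn_roc`: `fpr`, `tpr` (ascending), `thresholds`,
#'   `auc`.
#' @export
roc_points <- function(scores, y_true) {
  y_true <- as.integer(as.logical(y_true))
  stopifnot(length(scores) == length(y_true))
  P <- sum(y_true == 1L); Nn <- sum(y_true == 0L)
  if (P == 0L || Nn == 0L)
    stop("roc_points: need both classes present", call. = FALSE)
  thr <- sort(unique(scores), decreasing = TRUE)
  ord <- order(scores, decreasing = TRUE)
  s_sorted <- scores[ord]; y_sorted <- y_true[ord]
  cum_tp <- cumsum(y_sorted); cum_fp <- cumsum(1L - y_sorted)
  last_of_thr <- cumsum(rle(s_sorted)$lengths)
  tpr <- c(0, cum_tp[last_of_thr] / P, 1)
  fpr <- c(0, cum_fp[last_of_thr] / Nn, 1)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(fpr = fpr, tpr = tpr,
                 thresholds = c(Inf, thr, -Inf), auc = auc),
            class = "fwn_roc")
}

#' Metric suite for one confusion matrix
#' @param cm A confusion matrix.
#' @return List with `accuracy` and per-class `sensitivity`, `precision`.
#' @export
cm_metrics <- function(cm) {
  K <- nrow(cm)
  list(accuracy = accuracy(cm),
       sensitivity = vapply(0:(K - 1L), function(c)
         suppressWarnings(sensitivity(cm, c)), 0),
       precision = vapply(0:(K - 1L), function(c)
         suppressWarnings(precision(cm, c)), 0))
}

#' Standard baseline classifiers for side-by-side comparison
#'
#' Fits the comparison harness — decision tree, k-nearest neighbors, linear
#' discriminant analysis, naive Bayes, a single-hidden-layer perceptron, and
#' a support vector machine — each from its standard implementation with
#' library-default settings and a fixed seed, and reports the same metric
#' suite as the fuzzy wavelet network.
#'
#' @param X_train,y_train Training features (matrix) and labels (`0..C-1`).
#' @param X_test,y_test Held-out features and labels.
#' @param baselines Character subset of
#'   `c("DT", "KNN", "LDA", "NB", "MLP", "SVM")`.
#' @param seed Integer seed fixed before each fit.
#' @return Named list; per baseline a list with `confusion`, `metrics`, and
#'   `settings` (the recorded defaults).
#' @export
run_baselines <- function(X_train, y_train, X_test, y_test,
                          baselines = c("DT", "KNN", "LDA", "NB", "MLP",
                                        "SVM"),
                          seed = 1L) {
  known <- c("DT", "KNN", "LDA", "NB", "MLP", "SVM")
  bad <- setdiff(baselines, known)
  if (length(bad))
    stop(sprintf("run_baselines: unknown baseline(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  X_train <- as.matrix(X_train); X_test <- as.matrix(X_test)
  stopifnot(ncol(X_train) == ncol(X_test),
            nrow(X_train) == length(y_train),
            nrow(X_test) == length(y_test))
  colnames(X_train) <- colnames(X_test) <-
    paste0("f", seq_len(ncol(X_train)))
  ytr <- factor(y_train, levels = sort(unique(c(y_train, y_test))))
  num_classes <- nlevels(ytr)
  dtr <- data.frame(X_train, .y = ytr)
  dte <- data.frame(X_test)
  predict_label <- function(name) {
    set.seed(seed)
    switch(name,
      DT = {
        fit <- rpart::rpart(.y ~ ., data = dtr, method = "class")
        list(pred = predict(fit, dte, type = "class"),
             settings = "rpart defaults (gini, cp=0.01)")
      },
      KNN = {
        list(pred = class::knn(X_train, X_test, ytr, k = 1L),
             settings = "class::knn, k=1")
      },
      LDA = {
        fit <- MASS::lda(X_train, grouping = ytr)
        list(pred = predict(fit, X_test)$class,
             settings = "MASS::lda defaults")
      },
      NB = {
        fit <- e1071::naiveBayes(X_train, ytr)
        list(pred = predict(fit, X_test),
             settings = "e1071::naiveBayes defaults (Gaussian)")
      },
      MLP = {
        # nnet needs roughly unit-scale inputs; z-score by the train stats
        ctr <- colMeans(X_train)
        scl <- apply(X_train, 2, stats::sd); scl[scl <= 0] <- 1
        dtr_s <- data.frame(scale(X_train, ctr, scl), .y = ytr)
        dte_s <- data.frame(scale(X_test, ctr, scl))
        fit <- nnet::nnet(.y ~ ., data = dtr_s, size = 10L, decay = 1e-4,
                          maxit = 300L, trace = FALSE)
        list(pred = factor(predict(fit, dte_s, type = "class"),
                           levels = levels(ytr)),
             settings = "nnet, size=10, decay=1e-4, maxit=300, z-scored inputs")
      },
      SVM = {
        fit <- e1071::svm(X_train, ytr)
        list(pred = predict(fit, X_test),
             settings = "e1071::svm defaults (RBF, C=1)")
      })
  }
  out <- lapply(baselines, function(nm) {
    res <- predict_label(nm)
    pred <- as.integer(as.character(res$pred))
    pred[is.na(pred)] <- 0L
    cm <- confusion(y_test, pred, num_classes = num_classes)
    list(confusion = cm, metrics = cm_metrics(cm), settings = res$settings)
  })
  names(out) <- baselines
  out
}
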