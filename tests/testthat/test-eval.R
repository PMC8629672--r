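test_that("confusion matrix counts true/predicted pairs", {
  y_true <- c(0, 0, 1, 1, 2, 2)
  y_pred <- c(0, 1, 1, 1, 0, 2)
  cm <- confusion(y_true, y_pred, 3)
  expect_equal(unclass(cm)[cbind(1:3, 1:3)], c(1L, 2L, 1L),
               ignore_attr = TRUE)
  expect_equal(cm[1, 2], 1L); expect_equal(cm[3, 1], 1L)
  expect_equal(sum(cm), 6L)
  expect_true(all(rowSums(cm) == c(2, 2, 2)))
  perfect <- confusion(0:3, 0:3, 4)
  expect_equal(sum(diag(perfect)), 4L); expect_equal(sum(perfect), 4L)
  all0 <- confusion(c(0, 1, 2), c(0, 0, 0), 3)
  expect_true(all(all0[, 2:3] == 0))
  expect_error(confusion(0:2, 0:1), "length")
  expect_error(confusion(0:2, c(0, 1, 5), 3), "range")
})

test_that("sensitivity and precision reproduce the worked confusion-matrix numbers", {
  # class-0 row (480, 6, 12, 2): 480 of 500 detected -> 96%
  cm <- matrix(0L, 4, 4)
  cm[1, ] <- c(480L, 6L, 12L, 2L)
  cm[2, 2] <- 450L; cm[3, 3] <- 470L; cm[4, 4] <- 455L
  expect_equal(sensitivity(cm, 0), 0.96)
  # a predicted column holding 373 correct plus 15, 20, 14 strays -> 88.4%
  cm2 <- matrix(0L, 4, 4)
  cm2[3, 3] <- 373L
  cm2[4, 3] <- 15L; cm2[2, 3] <- 20L; cm2[1, 3] <- 14L
  expect_equal(round(100 * precision(cm2, 2), 1), 88.4)
  expect_equal(precision(cm2, 2), 373 / 422)
})

test_that("degenerate rows and columns signal undefined metrics", {
  cm <- matrix(c(0L, 0L, 10L, 5L), 2, 2, byrow = TRUE)
  expect_warning(s <- sensitivity(cm, 0), "undefined")
  expect_true(is.na(s))
  expect_equal(sensitivity(matrix(c(0L, 10L, 0L, 0L), 2, 2, byrow = TRUE),
                           0), 0)
  cm3 <- matrix(c(0L, 1L, 0L, 5L), 2, 2, byrow = TRUE)
  expect_warning(p <- precision(cm3, 0), "undefined")
  expect_true(is.na(p))
  diagm <- diag(3L); storage.mode(diagm) <- "integer"
  expect_equal(sensitivity(diagm, 1), 1)
  expect_equal(precision(diagm, 1), 1)
})

test_that("accuracy is the trace over the total, and micro-averages are consistent", {
  diagm <- diag(4L) * 5L
  expect_equal(accuracy(diagm), 1)
  anti <- matrix(c(0L, 3L, 2L, 0L), 2, 2)
  expect_equal(accuracy(anti), 0)
  set.seed(4)
  cm <- matrix(sample(0:20, 16, TRUE), 4, 4)
  expect_equal(accuracy(cm), sum(diag(cm)) / sum(cm))
  sens <- vapply(0:3, function(c) sensitivity(cm, c), 0)
  expect_equal(sum(rowSums(cm) * sens) / sum(cm), accuracy(cm))
  expect_error(accuracy(matrix(0L, 2, 2)), "empty")
})

test_that("ROC sweep yields the Mann-Whitney AUC and canonical endpoints", {
  # perfectly separated
  expect_equal(roc_points(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))$auc, 1)
  # scores carry no information
  expect_equal(roc_points(rep(0.5, 10), rep(0:1, 5))$auc, 0.5)
  # 8-item toy set vs exhaustive pairwise concordance
  set.seed(11)
  sc <- c(0.9, 0.8, 0.7, 0.65, 0.5, 0.4, 0.3, 0.3)
  yv <- c(1, 0, 1, 1, 0, 1, 0, 0)
  r <- roc_points(sc, yv)
  mw <- mean(outer(sc[yv == 1], sc[yv == 0],
                   function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(r$auc, mw)
  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
  expect_equal(r$fpr[length(r$fpr)], 1)
  expect_equal(r$tpr[length(r$tpr)], 1)
  # invariance under strictly monotone transformation
  expect_equal(roc_points(exp(3 * sc), yv)$auc, r$auc)
  expect_error(roc_points(sc, rep(1, 8)), "both classes")
})

test_that("ROC AUC agrees with an established implementation", {
  set.seed(2)
  sc <- rnorm(60); yv <- as.integer(runif(60) < 0.4)
  ref <- as.numeric(pROC::auc(pROC::roc(yv, sc, quiet = TRUE,
                                        levels = c(0, 1),
                                        direction = "<")))
  expect_equal(roc_points(sc, yv)$auc, ref, tolerance = 1e-12)
})

test_that("baseline classifiers all separate an easy synthetic set and are seed-stable", {
  ds <- generate_class_dataset(40, seed = 6)
  sp <- split_stratified(ds$y, 0.7, 6)
  bl <- run_baselines(ds$X[sp$train, ], ds$y[sp$train],
                      ds$X[sp$test, ], ds$y[sp$test], seed = 6)
  for (nm in names(bl))
    expect_gt(bl[[nm]]$metrics$accuracy, 0.9)
  bl2 <- run_baselines(ds$X[sp$train, ], ds$y[sp$train],
                       ds$X[sp$test, ], ds$y[sp$test], seed = 6)
  expect_identical(lapply(bl, `[[`, "confusion"),
                   lapply(bl2, `[[`, "confusion"))
  expect_error(run_baselines(ds$X[sp$train, ], ds$y[sp$train],
                             ds$X[sp$test, ], ds$y[sp$test],
                             baselines = "RF"), "unknown baseline")
})

test_that("baselines sit at chance on label-shuffled data", {
  ds <- generate_class_dataset(40, seed = 8)
  set.seed(80)
  y_shuf <- sample(ds$y)
  sp <- split_stratified(y_shuf, 0.7, 8)
  bl <- run_baselines(ds$X[sp$train, ], y_shuf[sp$train],
                      ds$X[sp$test, ], y_shuf[sp$test],
                      baselines = c("DT", "KNN", "LDA", "NB"), seed = 8)
  for (nm in names(bl))
    expect_lt(abs(bl[[nm]]$metrics$accuracy - 0.25), 0.1)
})
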