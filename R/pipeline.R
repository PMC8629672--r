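#' Stratified train/test split
#'
#' Seeded shuffling within each class, then a fixed fraction to training.
#'
#' @param y Label vector.
#' @param train_frac Fraction per class assigned to training (default 0.7).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_stratified <- function(y, train_frac = 0.7, seed = 1L) {
  set.seed(seed)
  train <- integer(0)
  for (cl in sort(unique(y))) {
    idx <- sample(which(y == cl))
    k <- max(1L, floor(train_frac * length(idx)))
    train <- c(train, idx[seq_len(k)])
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(y), train))
}

#' End-to-end classification experiment
#'
#' Splits the data (stratified 70/30 by default), trains the fuzzy wavelet
#' network by the hybrid scheme against the numeric labels, evaluates it
#' alongside the standard baselines, and returns the full metric suite with
#' one-vs-rest ROC curves (the network's pre-rounding output serves as its
#' score).
#'
#' @param X Feature matrix.
#' @param y Integer labels `0..C-1`.
#' @param config [fwn_config()]; default is the compact reference
#'   architecture, `M = 2` rules and `N = 2` wavelets per rule, sized to
#'   the data.
#' @param train_config,pso_config Training settings; the experiment default
#'   is online (per-sample) gradient descent for 12 epochs after the swarm
#'   stage, which descends this objective much faster than full-batch
#'   updates.
#' @param train_frac Training fraction for the stratified split; `1` trains
#'   (and evaluates the confusion matrix) on the full set, as when
#'   reproducing a training-accuracy figure.
#' @param baselines Baselines to run (see [run_baselines()]); `NULL` skips
#'   them.
#' @param standardize Z-score the features inside the fit (default `TRUE`;
#'   histogram-mean features live on a 0-255 scale).
#' @param n_restarts Hybrid restarts with training-accuracy selection (see
#'   [fwn_train()]).
#' @param seed Integer seed (split, swarm, baselines).
#' @return List of class `fwn_experiment`: `fit`, `split`, `confusion`,
#'   `metrics` (`train_accuracy`, `test_accuracy`, per-class suites), `roc`
#'   (per class, one-vs-rest on the test set), `baselines`.
#' @export
classification_experiment <- function(X, y, config = NULL,
                                      train_config =
                                        fwn_train_config(max_epochs = 12L,
                                                         batch_mode =
                                                           "online"),
                                      pso_config = NULL,
                                      train_frac = 0.7,
                                      baselines = c("DT", "KNN", "LDA",
                                                    "NB", "MLP", "SVM"),
                                      standardize = TRUE, n_restarts = 3L,
                                      seed = 1L) {
  X <- as.matrix(X)
  num_classes <- length(unique(y))
  if (is.null(config))
    config <- fwn_config(n = ncol(X), M = 2L, N = 2L,
                         num_classes = num_classes)
  if (is.null(pso_config)) pso_config <- fwn_pso_config(rng_seed = seed)
  train_config$rng_seed <- seed
  if (train_frac >= 1) {
    sp <- list(train = seq_along(y), test = seq_along(y))
  } else {
    sp <- split_stratified(y, train_frac, seed)
  }
  Xtr <- X[sp$train, , drop = FALSE]; ytr <- y[sp$train]
  Xte <- X[sp$test, , drop = FALSE]; yte <- y[sp$test]
  fit <- fwn_train(Xtr, ytr, config, train_config, pso_config,
                   X_test = Xte, y_test = yte,
                   standardize = standardize, n_restarts = n_restarts)
  pred_tr <- predict(fit, Xtr, type = "class")
  score_te <- predict(fit, Xte)
  pred_te <- fwn_classify(score_te, config$num_classes)
  cm <- confusion(yte, pred_te, num_classes = config$num_classes)
  roc <- lapply(0:(config$num_classes - 1L), function(cl) {
    if (length(unique(yte == cl)) < 2L) return(NULL)
    # one-vs-rest: proximity of the continuous output to the class label
    roc_points(-abs(score_te - cl), yte == cl)
  })
  names(roc) <- paste0("class", 0:(config$num_classes - 1L))
  bl <- if (is.null(baselines)) NULL else
    run_baselines(Xtr, ytr, Xte, yte, baselines, seed = seed)
  structure(list(fit = fit, split = sp, confusion = cm,
                 metrics = c(list(train_accuracy = mean(pred_tr == ytr),
                                  test_accuracy = mean(pred_te == yte)),
                             cm_metrics(cm)),
                 roc = roc, baselines = bl),
            class = "fwn_experiment")
}

#' End-to-end supervised segmentation experiment
#'
#' Gabor-transforms every image, sweeps paired patches on the training
#' images, trains the patch regressor by the hybrid scheme, segments the
#' held-out images, and evaluates pixel-level ROC curves on them.
#'
#' @param pairs List of `list(image, mask)` pairs (e.g. from
#'   [generate_segmentation_set()]).
#' @param n_train Number of leading pairs used for training; the rest are
#'   the test set.
#' @param scheme A [patch_scheme()]. The experiment default fully overlaps
#'   the target patches (`stride = 1`), so each pixel's score averages the
#'   predictions of every shifted window covering it — a pixel-centered
#'   smoothing that sharpens the score map near tumor boundaries.
#' @param bank A [gabor_bank()].
#' @param train_config,pso_config Training settings (see
#'   [train_segmenter()]).
#' @param threshold Mask threshold on the score map.
#' @param max_rows Training-row cap (balanced subsample).
#' @param seed Integer seed.
#' @return List of class `fwn_seg_experiment`: `model`, `test` (per-image
#'   `scores`, `mask`), `roc` (from [segmentation_roc()] on the test set),
#'   `dice` (per test image).
#' @export
segmentation_experiment <- function(pairs, n_train,
                                    scheme = patch_scheme(m = 4L,
                                                          stride = 1L),
                                    bank = gabor_bank(),
                                    train_config =
                                      fwn_train_config(max_epochs = 60L),
                                    pso_config = NULL,
                                    threshold = 0.5, max_rows = 3000L,
                                    seed = 1L) {
  stopifnot(n_train >= 1L, n_train < length(pairs))
  if (is.null(pso_config)) pso_config <- fwn_pso_config(rng_seed = seed)
  transformed <- lapply(pairs, function(p)
    gabor_transform(p$image, bank))
  train_sets <- lapply(seq_len(n_train), function(i)
    sweep_patches(transformed[[i]], pairs[[i]]$mask, scheme))
  model <- train_segmenter(train_sets, train_config = train_config,
                           pso_config = pso_config, max_rows = max_rows,
                           seed = seed)
  test_idx <- (n_train + 1L):length(pairs)
  test <- lapply(test_idx, function(i)
    segment_image(transformed[[i]], model, threshold))
  true_masks <- lapply(test_idx, function(i) pairs[[i]]$mask)
  roc <- segmentation_roc(lapply(test, `[[`, "scores"), true_masks)
  dice <- vapply(seq_along(test), function(i) {
    pred <- test[[i]]$mask == 255; truth <- true_masks[[i]] == 255
    denom <- sum(pred) + sum(truth)
    if (denom == 0) return(NA_real_)
    2 * sum(pred & truth) / denom
  }, 0)
  structure(list(model = model, test = test, roc = roc, dice = dice),
            class = "fwn_seg_experiment")
}
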