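test_that("Gabor transform maps flat regions low, matches grating orientation, stays in [0, 1]", {
  flat <- matrix(100, 48, 48)
  g <- gabor_transform(flat)
  expect_true(all(g >= 0 & g <= 1))
  expect_lt(max(g), 1e-8)            # no texture -> no response
  # vertical grating at the bank wavelength: strongest response at the
  # orientation whose sinusoid varies along the same axis
  wl <- 6
  grating <- matrix(rep(127 + 100 * sin(2 * pi * (1:48) / wl), each = 48),
                    48, 48, byrow = TRUE)
  per_or <- gabor_transform(grating,
                            gabor_bank(wavelength = wl,
                                       aggregation = "concat"))
  strength <- apply(per_or[9:40, 9:40, ], 3, mean)   # interior only
  expect_equal(which.max(strength), 1L)              # theta = 0
  agg <- gabor_transform(grating, gabor_bank(wavelength = wl))
  expect_gte(min(agg), 0); expect_lte(max(agg), 1)
})

test_that("patch sweep enumerates positions and shapes per the 2m-to-m pairing", {
  img <- matrix(runif(64), 8, 8)
  mask <- matrix(0, 8, 8); mask[3:6, 3:6] <- 255
  ps <- sweep_patches(img, mask, patch_scheme(m = 2, stride = 2))
  expect_equal(nrow(ps$X), 16L)                 # 4 x 4 grid of positions
  expect_equal(ncol(ps$X), 16L)                 # (2m)^2
  expect_equal(ncol(ps$T), 4L)                  # m^2
  expect_true(all(ps$T %in% c(0, 1)))
  # all-zero mask -> all-zero targets
  ps0 <- sweep_patches(img, matrix(0, 8, 8), patch_scheme(m = 2, stride = 2))
  expect_true(all(ps0$T == 0))
  # stride = image side -> a single pair
  ps1 <- sweep_patches(img, mask, patch_scheme(m = 2, stride = 8))
  expect_equal(nrow(ps1$X), 1L)
  expect_error(sweep_patches(img, mask / 2, patch_scheme(m = 2)),
               "binary")
  expect_error(sweep_patches(img, matrix(0, 6, 6), patch_scheme(m = 2)),
               "sizes differ")
})

test_that("interior input windows are co-centered on their mask patches", {
  side <- 12L
  img <- matrix(seq_len(side^2), side, side)
  mask <- matrix(0, side, side)
  ps <- sweep_patches(img, mask, patch_scheme(m = 4, stride = 4))
  # position (5, 5): mask rows 5..8 -> input rows 3..10 of the raw image
  p_idx <- which(ps$positions$row == 5 & ps$positions$col == 5)
  expect_equal(matrix(ps$X[p_idx, ], 8, 8), img[3:10, 3:10])
})

test_that("mask-side patch pairing is exactly invertible at stride m", {
  set.seed(12)
  mask <- matrix(sample(c(0, 255), 64 * 64, TRUE, prob = c(0.9, 0.1)),
                 64, 64)
  img <- matrix(runif(64 * 64), 64, 64)
  scheme <- patch_scheme(m = 4, stride = 4)
  ps <- sweep_patches(img, mask, scheme)
  rebuilt <- reassemble_mask(ps$T, ps$positions, scheme, 64) * 255
  expect_identical(rebuilt, mask)
})

test_that("training on all-background patches regresses to zero and is seed-stable", {
  set.seed(14)
  img <- matrix(runif(32 * 32), 32, 32)
  ps <- sweep_patches(img, matrix(0, 32, 32), patch_scheme(m = 2))
  tc <- fwn_train_config(max_epochs = 30L)
  pc <- fwn_pso_config(psize = 8L, maxgen = 10L, rng_seed = 3)
  model <- train_segmenter(ps, train_config = tc, pso_config = pc,
                           max_rows = 100L, seed = 3)
  expect_lt(tail(model$fits[[1]]$trace$train_rmse, 1), 1e-2)
  model2 <- train_segmenter(ps, train_config = tc, pso_config = pc,
                            max_rows = 100L, seed = 3)
  expect_identical(model$fits[[1]]$params, model2$fits[[1]]$params)
  seg <- segment_image(img, model)
  expect_true(all(seg$scores >= 0 & seg$scores <= 1))
  # thresholding contract
  expect_true(all(segment_image(img, model, threshold = 0)$mask == 255))
  expect_true(all(segment_image(img, model, threshold = 1.01)$mask == 0))
  expect_error(train_segmenter(list()), "empty")
})

test_that("pixel-level ROC behaves at the extremes and pools correctly", {
  set.seed(15)
  mask <- matrix(0, 50, 50); mask[11:30, 11:30] <- 255
  # score map equal to the (scaled) mask separates perfectly
  expect_equal(segmentation_roc(list(mask / 255), list(mask))$pooled_auc, 1)
  # random scores are chance-level at 10^4 pixels
  r <- segmentation_roc(list(matrix(runif(10000), 100, 100)),
                        list(rbind(matrix(255, 50, 100),
                                   matrix(0, 50, 100))))
  expect_lt(abs(r$pooled_auc - 0.5), 0.05)
  # equal class balance: pooled AUC lies within the per-image range
  masks <- list(rbind(matrix(255, 20, 40), matrix(0, 20, 40)),
                rbind(matrix(255, 20, 40), matrix(0, 20, 40)))
  scores <- list(matrix(runif(1600, 0.2, 1) * (masks[[1]] / 255) +
                          runif(1600, 0, 0.5), 40, 40),
                 matrix(runif(1600, 0.1, 0.9) * (masks[[2]] / 255) +
                          runif(1600, 0, 0.6), 40, 40))
  rr <- segmentation_roc(scores, masks)
  aucs <- vapply(rr$per_image, `[[`, 0, "auc")
  expect_gte(rr$pooled_auc, min(aucs) - 1e-9)
  expect_lte(rr$pooled_auc, max(aucs) + 1e-9)
  # single-class mask excluded with a warning
  expect_warning(
    r1 <- segmentation_roc(list(matrix(runif(100), 10, 10), mask / 255),
                           list(matrix(0, 10, 10), mask)),
    "single-class")
  expect_null(r1$per_image[[1]])
  expect_equal(r1$per_image[[2]]$auc, 1)
})
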