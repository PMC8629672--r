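#' Gabor filter bank
#'
#' A set of oriented Gabor filters (sinusoid under a Gaussian envelope) used
#' to texture-transform an image before patch sweeping, so that flat regions
#' map near zero and textured regions light up.
#'
#' @param orientations Angles in radians (default 0, 45, 90, 135 degrees).
#' @param wavelength Sinusoid wavelength in pixels (> 1). The default 3 px
#'   tunes the bank to fine-grained texture: the kernel support then stays
#'   narrower than the structures being segmented, so smooth regions map low
#'   and pixel-scale texture maps high, rather than everything being
#'   swamped by edge halos.
#' @param aspect Envelope aspect ratio (gamma).
#' @param bandwidth Half-response spatial-frequency bandwidth in octaves;
#'   sets the envelope width from the wavelength.
#' @param aggregation How per-orientation magnitude responses are combined:
#'   `"max"` (default), `"mean"`, or `"concat"` (returns a channel stack).
#' @return An object of class `fwn_gabor_bank`.
#' @export
gabor_bank <- function(orientations = c(0, pi / 4, pi / 2, 3 * pi / 4),
                       wavelength = 3, aspect = 0.5, bandwidth = 1,
                       aggregation = c("max", "mean", "concat")) {
  aggregation <- match.arg(aggregation)
  if (length(orientations) < 1L)
    stop("gabor_bank: need at least one orientation", call. = FALSE)
  if (wavelength <= 1)
    stop("gabor_bank: wavelength must exceed 1 pixel", call. = FALSE)
  structure(list(orientations = orientations, wavelength = wavelength,
                 aspect = aspect, bandwidth = bandwidth,
                 aggregation = aggregation),
            class = "fwn_gabor_bank")
}

# even/odd Gabor kernel pair for one orientation
gabor_kernel <- function(theta, wavelength, aspect, bandwidth) {
  sigma <- wavelength / pi * sqrt(log(2) / 2) *
    (2^bandwidth + 1) / (2^bandwidth - 1)
  half <- max(3L, ceiling(3 * sigma))
  if (half %% 2L == 0L) half <- half  # any half works; size is 2*half+1 (odd)
  g <- expand.grid(x = -half:half, y = -half:half)
  xr <- g$x * cos(theta) + g$y * sin(theta)
  yr <- -g$x * sin(theta) + g$y * cos(theta)
  env <- exp(-(xr^2 + aspect^2 * yr^2) / (2 * sigma^2))
  side <- 2L * half + 1L
  list(even = matrix(env * cos(2 * pi * xr / wavelength), side, side),
       odd = matrix(env * sin(2 * pi * xr / wavelength), side, side))
}

#' Gabor transform of a grayscale image
#'
#' Convolves the image with each orientation's quadrature (even/odd) kernel
#' pair, takes the magnitude response, removes the DC sensitivity of the even
#' kernel (its mean is subtracted so a constant image maps to zero), and
#' aggregates across orientations. The result is min-max rescaled to
#' `[0, 1]`.
#'
#' @param image Numeric matrix (any scale; 8-bit images work as-is).
#' @param bank A [gabor_bank()].
#' @return Matrix in `[0, 1]` (same size), or a 3-d array with one slice per
#'   orientation when `aggregation = "concat"`.
#' @export
gabor_transform <- function(image, bank = gabor_bank()) {
  stopifnot(inherits(bank, "fwn_gabor_bank"), is.matrix(image))
  responses <- lapply(bank$orientations, function(th) {
    kk <- gabor_kernel(th, bank$wavelength, bank$aspect, bank$bandwidth)
    ke <- kk$even - mean(kk$even)   # zero-DC so flat regions respond ~0
    re <- EBImage::filter2(image, ke, boundary = "replicate")
    ro <- EBImage::filter2(image, kk$odd, boundary = "replicate")
    sqrt(re^2 + ro^2)
  })
  rescale01 <- function(m) {
    rng <- range(m)
    if (rng[2] <= rng[1]) return(m * 0)
    (m - rng[1]) / (rng[2] - rng[1])
  }
  if (bank$aggregation == "concat") {
    out <- array(0, c(dim(image), length(responses)))
    for (i in seq_along(responses)) out[, , i] <- rescale01(responses[[i]])
    return(out)
  }
  agg <- Reduce(if (bank$aggregation == "max") pmax else `+`, responses)
  if (bank$aggregation == "mean") agg <- agg / length(responses)
  rescale01(agg)
}

#' Geometry of the segmentation patch sweep
#'
#' Each `m x m` ground-truth patch is paired with the co-centered
#' `2m x 2m` window of the (transformed) input image — the input window
#' carries twice the spatial context of the target patch.
#'
#' @param m Mask patch side in pixels (even, >= 2); the input window side is
#'   `2m`.
#' @param stride Step between patch positions (default `m`: non-overlapping
#'   targets tiling the mask exactly).
#' @param padding `"reflect"` (default) or `"zero"` for input-window pixels
#'   falling outside the image.
#' @return An object of class `fwn_patch_scheme`.
#' @export
patch_scheme <- function(m = 4L, stride = m,
                         padding = c("reflect", "zero")) {
  padding <- match.arg(padding)
  m <- as.integer(m); stride <- as.integer(stride)
  if (m < 2L || m %% 2L != 0L)
    stop("patch_scheme: m must be an even integer >= 2 (the 2m window must be co-centered on the m patch)",
         call. = FALSE)
  if (stride < 1L) stop("patch_scheme: stride must be >= 1", call. = FALSE)
  structure(list(m = m, input_side = 2L * m, stride = stride,
                 padding = padding), class = "fwn_patch_scheme")
}

# pad an image by m/2 on every side so every co-centered 2m window exists
pad_image <- function(image, pad, padding) {
  nr <- nrow(image); nc <- ncol(image)
  if (padding == "zero") {
    out <- matrix(0, nr + 2L * pad, nc + 2L * pad)
    out[pad + seq_len(nr), pad + seq_len(nc)] <- image
    return(out)
  }
  idx <- function(n) {                      # reflect without edge repeat
    i <- c(rev(seq_len(pad) + 1L), seq_len(n), n - seq_len(pad))
    pmin(pmax(i, 1L), n)
  }
  image[idx(nr), idx(nc)]
}

# top-left mask-patch positions (row-major over rows then columns)
patch_positions <- function(side, scheme) {
  starts <- seq.int(1L, side - scheme$m + 1L, by = scheme$stride)
  expand.grid(col = starts, row = starts)[, c("row", "col")]
}

#' Sweep paired input/target patches from an image and its mask
#'
#' Slides an `m x m` window over the mask (row-major, given stride); at each
#' position the vectorized co-centered `2m x 2m` input window is paired with
#' the vectorized binary mask patch. The mask must contain only the values 0
#' and 255 (tumor pixels are labeled 255) and is thresholded to 0/1 targets.
#'
#' @param input_image Numeric matrix (typically the Gabor-transformed image),
#'   same size as the mask.
#' @param mask_image Matrix with values in `{0, 255}`.
#' @param scheme A [patch_scheme()].
#' @return List of class `fwn_patch_set`: `X` (`P x (2m)^2` input matrix),
#'   `T` (`P x m^2` 0/1 target matrix), `positions` (data frame of top-left
#'   mask coordinates), `scheme`, `image_side`.
#' @export
sweep_patches <- function(input_image, mask_image, scheme = patch_scheme()) {
  stopifnot(inherits(scheme, "fwn_patch_scheme"))
  if (!all(dim(input_image) == dim(mask_image)))
    stop("sweep_patches: input and mask sizes differ", call. = FALSE)
  if (!all(mask_image %in% c(0, 255)))
    stop("sweep_patches: mask must be binary with tumor pixels = 255",
         call. = FALSE)
  side <- nrow(input_image)
  if (ncol(input_image) != side)
    stop("sweep_patches: images must be square", call. = FALSE)
  m <- scheme$m; pad <- m %/% 2L
  padded <- pad_image(input_image, pad, scheme$padding)
  pos <- patch_positions(side, scheme)
  P <- nrow(pos)
  X <- matrix(0, P, (2L * m)^2)
  Tm <- matrix(0, P, m^2)
  for (p in seq_len(P)) {
    r <- pos$row[p]; cc <- pos$col[p]
    # mask patch rows r..r+m-1 map to padded input rows r..r+2m-1
    X[p, ] <- as.vector(padded[r:(r + 2L * m - 1L),
                               cc:(cc + 2L * m - 1L)])
    Tm[p, ] <- as.vector(mask_image[r:(r + m - 1L),
                                    cc:(cc + m - 1L)] / 255)
  }
  structure(list(X = X, T = Tm, positions = pos, scheme = scheme,
                 image_side = side), class = "fwn_patch_set")
}

#' Reassemble target vectors back into a mask
#'
#' Inverse of the target side of [sweep_patches()]: overlapping patches are
#' averaged; with `stride = m` the reconstruction is exact.
#'
#' @param values `P x m^2` matrix of patch values (targets or predictions).
#' @param positions Data frame of top-left positions from [sweep_patches()].
#' @param scheme The [patch_scheme()] used for the sweep.
#' @param side Mask side in pixels.
#' @return Numeric `side x side` matrix (NA where no patch covered a pixel).
#' @export
reassemble_mask <- function(values, positions, scheme, side) {
  acc <- matrix(0, side, side)
  cnt <- matrix(0, side, side)
  m <- scheme$m
  for (p in seq_len(nrow(positions))) {
    r <- positions$row[p]; cc <- positions$col[p]
    acc[r:(r + m - 1L), cc:(cc + m - 1L)] <-
      acc[r:(r + m - 1L), cc:(cc + m - 1L)] + matrix(values[p, ], m, m)
    cnt[r:(r + m - 1L), cc:(cc + m - 1L)] <-
      cnt[r:(r + m - 1L), cc:(cc + m - 1L)] + 1
  }
  out <- acc / cnt
  out[cnt == 0] <- NA_real_
  out
}

# expand a patch set into per-pixel training rows for the shared network:
# input = [window vector, row offset / m, col offset / m], target = pixel bit
patch_rows_shared <- function(ps, pixel_idx = NULL) {
  m <- ps$scheme$m
  if (is.null(pixel_idx)) pixel_idx <- seq_len(m^2)
  off <- cbind((pixel_idx - 1L) %% m, (pixel_idx - 1L) %/% m) / m
  P <- nrow(ps$X)
  X <- do.call(rbind, lapply(seq_along(pixel_idx), function(ii) {
    cbind(ps$X, matrix(off[ii, ], P, 2, byrow = TRUE))
  }))
  y <- as.vector(ps$T[, pixel_idx])
  list(X = X, y = y)
}

#' Train the patch-based segmenter
#'
#' Builds per-pixel training rows from the swept patch pairs and trains a
#' fuzzy wavelet network regressor by the hybrid swarm + gradient scheme. The
#' default (`shared = TRUE`) trains one network over all target pixels with
#' the normalized pixel offset inside the patch appended as two extra inputs;
#' `shared = FALSE` trains one independent network per target-pixel
#' coordinate.
#'
#' Training uses a class-balanced random subsample of the available rows
#' (tumor patches are rare), capped at `max_rows`.
#'
#' @param pairs An `fwn_patch_set` (or list of them, one per training image).
#' @param config An [fwn_config()] for the patch networks; `n` must equal
#'   `(2m)^2 + 2` (shared) or `(2m)^2` (per-pixel). If `NULL`, a regression
#'   config with `M = 2`, `N = 2`, log-space firing strengths is built.
#' @param train_config,pso_config Training settings (defaults as in
#'   [fwn_train()]).
#' @param shared Share one network across target pixels (default) or fit one
#'   per pixel.
#' @param max_rows Training-row cap (balanced subsample).
#' @param seed Integer seed for subsampling.
#' @return List of class `fwn_segmenter`: `fits` (one or `m^2` `fwn_fit`s),
#'   `scheme`, `config`, `shared`.
#' @export
train_segmenter <- function(pairs, config = NULL,
                            train_config = fwn_train_config(max_epochs = 60L),
                            pso_config = fwn_pso_config(),
                            shared = TRUE, max_rows = 3000L, seed = 1L) {
  if (inherits(pairs, "fwn_patch_set")) pairs <- list(pairs)
  if (length(pairs) == 0L || nrow(pairs[[1]]$X) == 0L)
    stop("train_segmenter: empty patch set", call. = FALSE)
  scheme <- pairs[[1]]$scheme
  m <- scheme$m
  Xall <- do.call(rbind, lapply(pairs, `[[`, "X"))
  Tall <- do.call(rbind, lapply(pairs, `[[`, "T"))
  ps_all <- list(X = Xall, T = Tall, scheme = scheme)
  class(ps_all) <- "fwn_patch_set"
  if (is.null(config)) {
    n_in <- if (shared) (2L * m)^2 + 2L else (2L * m)^2
    config <- fwn_config(n = n_in, M = 2L, N = 2L, num_classes = 0L,
                         log_space = TRUE)
  }
  set.seed(seed)
  balanced_sample <- function(y, cap) {
    pos <- which(y > 0); neg <- which(y == 0)
    k <- min(cap %/% 2L, length(pos), length(neg))
    if (k == 0L) return(sample(seq_along(y), min(cap, length(y))))
    c(sample(pos, k), sample(neg, min(cap - k, length(neg))))
  }
  if (shared) {
    rows <- patch_rows_shared(ps_all)
    take <- balanced_sample(rows$y, max_rows)
    fit <- fwn_train(rows$X[take, , drop = FALSE], rows$y[take], config,
                     train_config, pso_config)
    fits <- list(fit)
  } else {
    fits <- lapply(seq_len(m^2), function(px) {
      ypx <- ps_all$T[, px]
      take <- balanced_sample(ypx, max_rows)
      fwn_train(ps_all$X[take, , drop = FALSE], ypx[take], config,
                train_config, pso_config)
    })
  }
  structure(list(fits = fits, scheme = scheme, config = config,
                 shared = shared), class = "fwn_segmenter")
}

#' Segment an image with a trained patch model
#'
#' Sweeps the (transformed) image, predicts each patch's per-pixel tumor
#' scores, averages overlapping predictions into a full-resolution score map
#' clipped to `[0, 1]`, and thresholds it into a binary mask.
#'
#' @param input_image Numeric matrix on the same scale the model was trained
#'   on (i.e. already Gabor-transformed if training inputs were).
#' @param model An `fwn_segmenter` from [train_segmenter()].
#' @param threshold Score cut for the binary mask (default 0.5).
#' @return List with `scores` (matrix in `[0, 1]`) and `mask` (0/255 matrix,
#'   tumor pixels 255).
#' @export
segment_image <- function(input_image, model, threshold = 0.5) {
  scheme <- model$scheme
  m <- scheme$m
  zero_mask <- matrix(0, nrow(input_image), ncol(input_image))
  ps <- sweep_patches(input_image, zero_mask, scheme)
  P <- nrow(ps$X)
  preds <- matrix(0, P, m^2)
  if (model$shared) {
    for (px in seq_len(m^2)) {
      rows <- patch_rows_shared(ps, pixel_idx = px)
      preds[, px] <- fwn_predict(rows$X, model$fits[[1]]$params,
                                 model$config)
    }
  } else {
    for (px in seq_len(m^2))
      preds[, px] <- fwn_predict(ps$X, model$fits[[px]]$params,
                                 model$config)
  }
  preds <- pmin(pmax(preds, 0), 1)
  scores <- reassemble_mask(preds, ps$positions, scheme,
                            nrow(input_image))
  scores[is.na(scores)] <- 0
  list(scores = scores, mask = (scores >= threshold) * 255)
}

#' Pixel-level ROC analysis of segmentation scores
#'
#' Computes one ROC curve per image and a pooled curve over all pixels.
#' Images whose mask contains a single class are excluded from the per-image
#' list with a warning (their pixels still enter the pooled curve when both
#' classes are present overall).
#'
#' @param score_maps List of score matrices in `[0, 1]`.
#' @param true_masks List of matching 0/255 mask matrices.
#' @return List with `per_image` (list of `fwn_roc`, `NULL` where excluded),
#'   `pooled` (`fwn_roc`), `pooled_auc`.
#' @export
segmentation_roc <- function(score_maps, true_masks) {
  stopifnot(length(score_maps) == length(true_masks))
  per_image <- vector("list", length(score_maps))
  all_s <- numeric(0); all_y <- integer(0)
  for (i in seq_along(score_maps)) {
    s <- as.vector(score_maps[[i]])
    yv <- as.integer(as.vector(true_masks[[i]]) == 255)
    stopifnot(length(s) == length(yv))
    all_s <- c(all_s, s); all_y <- c(all_y, yv)
    if (length(unique(yv)) < 2L) {
      warning(sprintf("image %d has a single-class mask; excluded from per-image ROC", i))
    } else {
      per_image[[i]] <- roc_points(s, yv)
    }
  }
  pooled <- roc_points(all_s, all_y)
  list(per_image = per_image, pooled = pooled, pooled_auc = pooled$auc)
}
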