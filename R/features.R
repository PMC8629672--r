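#' Normalized 256-bin intensity histogram
#'
#' @param image Matrix (or array coercible to a vector) of 8-bit intensities
#'   in `0..255`.
#' @return Numeric vector of length 256 summing to 1; element `v + 1` is the
#'   density of intensity `v`.
#' @export
image_histogram <- function(image) {
  v <- as.vector(image)
  if (length(v) == 0L) stop("image_histogram: empty image", call. = FALSE)
  if (any(v < 0 | v > 255))
    stop("image_histogram: pixel values must lie in [0, 255]", call. = FALSE)
  counts <- tabulate(as.integer(round(v)) + 1L, nbins = 256L)
  counts / sum(counts)
}

#' Fit a sum of four Gaussian modes to an intensity histogram
#'
#' Models the histogram as
#' \eqn{h(v) \approx \sum_{g=1}^{4} A_g \exp(-((v - m_g)/s_g)^2)}
#' over the bin centers \eqn{v = 0..255} (same width convention as the fuzzy
#' memberships: no 1/2 factor). The fit is bounded Levenberg-Marquardt least
#' squares with a small multi-start: means start at the histogram's
#' quartile-spaced quantiles, at the four strongest peaks of a smoothed copy
#' of the histogram, at fixed equal spacing, and at seeded perturbations of
#' the quantile start; amplitudes start at the histogram value over each
#' starting mean. The lowest-residual solution is kept with the modes
#' re-ordered so the means ascend.
#'
#' @param hist Normalized 256-bin density (see [image_histogram()]).
#' @param seed Integer seed controlling the start perturbations.
#' @param n_starts Number of starts (default 5).
#' @return An object of class `fwn_histmodel`: list with `A`, `m`, `s`
#'   (length-4, means ascending), `residual_norm`, and `bin_centers`.
#' @export
fit_four_gaussians <- function(hist, seed = 1L, n_starts = 5L) {
  hist <- as.numeric(hist)
  if (length(hist) != 256L)
    stop("fit_four_gaussians: expected a 256-bin density", call. = FALSE)
  if (abs(sum(hist) - 1) > 1e-6)
    stop("fit_four_gaussians: density must sum to 1", call. = FALSE)
  v <- 0:255
  set.seed(seed)
  cdf <- cumsum(hist)
  qs <- vapply(c(0.125, 0.375, 0.625, 0.875),
               function(p) v[which.max(cdf >= p)], 0)
  # peaks of a smoothed histogram, strongest four, as a second start family
  sm <- stats::filter(hist, rep(1 / 9, 9), sides = 2)
  sm[is.na(sm)] <- 0
  is_peak <- which(diff(sign(diff(sm))) == -2) + 1L
  peaks <- is_peak[order(sm[is_peak], decreasing = TRUE)]
  pk <- sort(v[utils::head(peaks, 4L)])
  if (length(pk) < 4L) pk <- sort(c(pk, qs))[seq_len(4L)]
  amp0 <- max(hist)
  lower <- c(A = rep(0, 4), m = rep(0, 4), s = rep(1, 4))
  upper <- c(A = rep(2 * max(amp0, 1e-6), 4), m = rep(255, 4),
             s = rep(128, 4))
  model_fun <- function(par) {
    A <- par[1:4]; m <- par[5:8]; s <- par[9:12]
    rowSums(vapply(1:4,
                   function(g) A[g] * exp(-((v - m[g]) / s[g])^2),
                   numeric(256L)))
  }
  best <- NULL
  for (st in seq_len(n_starts)) {
    m0 <- switch(as.character(st),
                 "1" = qs,
                 "2" = pk,
                 "3" = c(32, 96, 160, 224),
                 pmin(pmax(qs + stats::rnorm(4, 0, 20), 0), 255))
    m0 <- sort(m0)
    A0 <- pmax(hist[pmin(pmax(round(m0), 0), 255) + 1L], amp0 / 20)
    start <- c(A0, m0, rep(15, 4))
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = pmin(pmax(start, lower), upper),
        lower = lower, upper = upper,
        fn = function(par) hist - model_fun(par),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rn <- sqrt(sum(stats::residuals(fit)^2))
    if (is.null(best) || rn < best$rn) best <- list(par = fit$par, rn = rn)
  }
  if (is.null(best))
    stop("fit_four_gaussians: every start failed to converge", call. = FALSE)
  A <- best$par[1:4]; m <- best$par[5:8]; s <- best$par[9:12]
  ord <- order(m)
  structure(list(A = A[ord], m = m[ord], s = s[ord],
                 residual_norm = best$rn, bin_centers = v),
            class = "fwn_histmodel")
}

#' Evaluate a fitted histogram model at the bin centers
#' @param model An `fwn_histmodel`.
#' @return Length-256 fitted curve.
#' @export
histmodel_curve <- function(model) {
  v <- model$bin_centers
  rowSums(vapply(1:4,
                 function(g) model$A[g] * exp(-((v - model$m[g]) /
                                                  model$s[g])^2),
                 numeric(length(v))))
}

#' Per-image features from the fitted histogram model
#'
#' The default feature set is the four mode means (ascending), one value per
#' Gaussian; alternatives expose the amplitudes or the full 12-parameter
#' description.
#'
#' @param model An `fwn_histmodel` from [fit_four_gaussians()].
#' @param mode `"means"` (default, length 4), `"amplitudes"` (length 4) or
#'   `"all12"` (A, m, s concatenated, length 12).
#' @return Numeric feature vector.
#' @export
extract_features <- function(model, mode = c("means", "amplitudes",
                                             "all12")) {
  mode <- match.arg(mode)
  switch(mode,
         means = model$m,
         amplitudes = model$A,
         all12 = c(model$A, model$m, model$s))
}

#' Histogram features straight from an image
#'
#' Convenience wrapper: [image_histogram()] then [fit_four_gaussians()] then
#' [extract_features()].
#'
#' @inheritParams fit_four_gaussians
#' @inheritParams extract_features
#' @param image 8-bit grayscale matrix.
#' @return Numeric feature vector.
#' @export
image_features <- function(image, mode = "means", seed = 1L) {
  extract_features(fit_four_gaussians(image_histogram(image), seed = seed),
                   mode = mode)
}

#' Eigen decomposition of an image stack's covariance
#'
#' Vectorizes each image into a column, subtracts the mean image, and
#' computes the covariance eigen-pairs using the small inner-product (Gram)
#' matrix of size `images x images` rather than the full `pixels x pixels`
#' covariance — the classical trick for stacks with far fewer images than
#' pixels. Eigenvalues use the sample-covariance convention (division by
#' `M - 1`).
#'
#' @param images A `pixels x M` matrix whose columns are vectorized images,
#'   or a list of equal-size matrices.
#' @param tol Eigenvalues at or below `tol` count as zero for
#'   `retained_count`.
#' @return An object of class `fwn_eigen`: `mean_image`, `values`
#'   (descending), `vectors` (orthonormal columns in pixel space, one per
#'   retained eigenvalue), `retained_count`.
#' @export
eigen_reduce <- function(images, tol = 1e-10) {
  if (is.list(images)) {
    sides <- vapply(images, function(im) length(im), 0L)
    if (length(unique(sides)) != 1L)
      stop("eigen_reduce: images must all have equal size", call. = FALSE)
    images <- vapply(images, as.numeric, numeric(sides[1]))
  }
  images <- as.matrix(images)
  Mimg <- ncol(images)
  if (Mimg < 2L)
    stop("eigen_reduce: need at least 2 images", call. = FALSE)
  mean_image <- rowMeans(images)
  Ac <- images - mean_image
  G <- crossprod(Ac) / (Mimg - 1)          # M x M inner-product matrix
  eg <- eigen(G, symmetric = TRUE)
  values <- pmax(eg$values, 0)
  keep <- values > tol
  vectors <- NULL
  if (any(keep)) {
    vectors <- Ac %*% eg$vectors[, keep, drop = FALSE]
    norms <- sqrt(colSums(vectors^2))
    vectors <- sweep(vectors, 2, norms, "/")
  }
  structure(list(mean_image = mean_image, values = values,
                 vectors = vectors, retained_count = sum(keep)),
            class = "fwn_eigen")
}
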