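#' Specification of a synthetic MRI-like phantom
#'
#' A phantom is an 8-bit grayscale image whose background intensities are
#' drawn from a four-mode Gaussian mixture (so its histogram is a sum of four
#' Gaussian functions, matching the feature extractor's model), optionally
#' with an elliptical "tumor" blob of near-constant intensity and a matching
#' binary ground-truth mask (tumor pixels 255).
#'
#' The mixture is parameterized exactly in the histogram model's convention:
#' mode `g` contributes \eqn{A_g \exp(-((v - m_g)/s_g)^2)} to the intensity
#' density, i.e. pixels are normal with mean \eqn{m_g} and standard deviation
#' \eqn{s_g/\sqrt{2}}, drawn with probability proportional to
#' \eqn{A_g s_g}. The class id shifts every mode mean by
#' `(class_id - 1.5) * separation` so histogram features discriminate the
#' four classes.
#'
#' @param image_side Image side in pixels (default 256).
#' @param class_id Class label 0-3 (0 Normal, 1 Glioma, 2 Meningioma,
#'   3 Pituitary).
#' @param modes 4 x 3 matrix of mixture parameters, columns `A`, `m`, `s`.
#'   Default amplitudes 0.012/0.02/0.016/0.01, means 40/100/160/220,
#'   widths 12/10/12/9.
#' @param separation Intensity-unit spacing of the per-class mean shifts
#'   (default 10).
#' @param tumor `NULL` for no tumor, or a list with `center` (length 2,
#'   pixels), `axes` (semi-axes, pixels), `angle` (radians), `intensity`
#'   (0-255).
#' @param noise_sd Gaussian noise added to tumor pixels (intensity units).
#' @param rng_seed Integer seed.
#' @return An object of class `fwn_phantom_spec`.
#' @export
phantom_spec <- function(image_side = 256L, class_id = 0L,
                         modes = default_modes(), separation = 10,
                         tumor = NULL, noise_sd = 5, rng_seed = 1L) {
  image_side <- as.integer(image_side)
  stopifnot(image_side >= 8L, class_id %in% 0:3)
  modes <- as.matrix(modes)
  stopifnot(nrow(modes) == 4L, ncol(modes) == 3L)
  if (any(modes[, 2] < 0 | modes[, 2] > 255))
    stop("phantom_spec: mode means must lie in [0, 255]", call. = FALSE)
  if (!is.null(tumor)) {
    stopifnot(all(c("center", "axes") %in% names(tumor)))
    tumor$angle <- if (is.null(tumor$angle)) 0 else tumor$angle
    tumor$intensity <- if (is.null(tumor$intensity)) 230 else tumor$intensity
    reach <- max(tumor$axes)
    if (any(tumor$center - reach < 1) ||
        any(tumor$center + reach > image_side))
      stop("phantom_spec: tumor ellipse must lie fully inside the image",
           call. = FALSE)
  }
  structure(list(image_side = image_side, class_id = as.integer(class_id),
                 modes = modes, separation = separation, tumor = tumor,
                 noise_sd = noise_sd, rng_seed = as.integer(rng_seed)),
            class = "fwn_phantom_spec")
}

#' Default histogram mixture modes
#' @return 4 x 3 matrix with columns `A`, `m`, `s`.
#' @export
default_modes <- function() {
  cbind(A = c(0.012, 0.02, 0.016, 0.01),
        m = c(40, 100, 160, 220),
        s = c(12, 10, 12, 9))
}

#' Generate one phantom image and its ground-truth mask
#'
#' @param spec An [phantom_spec()].
#' @return List with `image` (integer matrix, 0-255) and `mask` (matrix with
#'   values in `{0, 255}`, 255 inside the tumor ellipse).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "fwn_phantom_spec"))
  set.seed(spec$rng_seed)
  side <- spec$image_side
  npix <- side * side
  A <- spec$modes[, 1]; mns <- spec$modes[, 2]; s <- spec$modes[, 3]
  mns <- mns + (spec$class_id - 1.5) * spec$separation
  wts <- A * s; wts <- wts / sum(wts)
  comp <- sample.int(4L, npix, replace = TRUE, prob = wts)
  vals <- stats::rnorm(npix, mean = mns[comp], sd = s[comp] / sqrt(2))
  img <- matrix(pmin(pmax(round(vals), 0), 255), side, side)
  mask <- matrix(0, side, side)
  if (!is.null(spec$tumor)) {
    tu <- spec$tumor
    rr <- matrix(seq_len(side), side, side)
    cc <- matrix(seq_len(side), side, side, byrow = TRUE)
    dx <- cc - tu$center[2]; dy <- rr - tu$center[1]
    xr <- dx * cos(tu$angle) + dy * sin(tu$angle)
    yr <- -dx * sin(tu$angle) + dy * cos(tu$angle)
    inside <- (xr / tu$axes[1])^2 + (yr / tu$axes[2])^2 <= 1
    tum_vals <- round(tu$intensity +
                        stats::rnorm(sum(inside), 0, spec$noise_sd))
    img[inside] <- pmin(pmax(tum_vals, 0), 255)
    mask[inside] <- 255
  }
  list(image = img, mask = mask)
}

#' Balanced four-class synthetic dataset
#'
#' Emulates a 4-class brain-MRI labeling problem (Normal / Glioma /
#' Meningioma / Pituitary) at a chosen scale. In `"features"` mode (default, fast) each
#' item is the vector of four histogram mode means its class would produce:
#' base means shifted by `(class - 1.5) * separation` plus Gaussian feature
#' noise — the idealized output of the histogram fit. In `"images"` mode each
#' item is a full phantom image and the features must be extracted with
#' [image_features()].
#'
#' @param n_per_class Items per class (>= 1); 500 gives the reference scale
#'   of 2000 items.
#' @param seed Integer seed.
#' @param mode `"features"` or `"images"`.
#' @param separation Per-class mean shift spacing; 0 makes the labels
#'   independent of the features (a chance-level sanity set).
#' @param feature_noise_sd In `"features"` mode, the sd of the noise on each
#'   mode mean (default 2 intensity units).
#' @param image_side Image side in `"images"` mode.
#' @return List with `X` (feature matrix `4n x 4`, or list of images),
#'   `y` (labels 0-3), and the generating settings.
#' @export
generate_class_dataset <- function(n_per_class, seed = 1L,
                                   mode = c("features", "images"),
                                   separation = 10, feature_noise_sd = 2,
                                   image_side = 256L) {
  mode <- match.arg(mode)
  stopifnot(n_per_class >= 1L)
  set.seed(seed)
  y <- rep(0:3, each = n_per_class)
  base_m <- default_modes()[, 2]
  if (mode == "features") {
    total <- 4L * n_per_class
    shift <- (y - 1.5) * separation
    X <- matrix(rep(base_m, each = total), total, 4) + shift +
      matrix(stats::rnorm(total * 4L, 0, feature_noise_sd), total, 4)
    colnames(X) <- paste0("mean", 1:4)
    return(list(X = X, y = y, mode = mode, separation = separation,
                feature_noise_sd = feature_noise_sd, seed = seed))
  }
  seeds <- sample.int(.Machine$integer.max %/% 2L, 4L * n_per_class)
  images <- lapply(seq_along(y), function(i) {
    generate_phantom(phantom_spec(image_side = image_side,
                                  class_id = y[i],
                                  separation = separation,
                                  rng_seed = seeds[i]))$image
  })
  list(X = images, y = y, mode = mode, separation = separation, seed = seed)
}

#' Paired phantom images and tumor masks for segmentation
#'
#' Phantoms with randomized elliptical tumors (position, semi-axes, angle,
#' intensity) and matching 0/255 ground-truth masks; 80 pairs is the
#' reference scale.
#'
#' @param n_images Number of pairs (>= 1).
#' @param seed Integer seed.
#' @param image_side Image side in pixels (default 256).
#' @param axes_frac Range of tumor semi-axes as a fraction of the side
#'   (default 0.06-0.15).
#' @param intensity_range Range of tumor intensities (default 215-245).
#' @return List of `n_images` elements, each a list with `image` and `mask`.
#' @export
generate_segmentation_set <- function(n_images, seed = 1L,
                                      image_side = 256L,
                                      axes_frac = c(0.06, 0.15),
                                      intensity_range = c(215, 245)) {
  stopifnot(n_images >= 1L)
  set.seed(seed)
  side <- as.integer(image_side)
  out <- vector("list", n_images)
  seeds <- sample.int(.Machine$integer.max %/% 2L, n_images)
  for (i in seq_len(n_images)) {
    set.seed(seeds[i])
    axes <- stats::runif(2, axes_frac[1], axes_frac[2]) * side
    reach <- ceiling(max(axes)) + 2
    center <- stats::runif(2, reach + 1, side - reach)
    tumor <- list(center = center, axes = axes,
                  angle = stats::runif(1, 0, pi),
                  intensity = stats::runif(1, intensity_range[1],
                                           intensity_range[2]))
    out[[i]] <- generate_phantom(
      phantom_spec(image_side = side, class_id = sample(0:3, 1),
                   tumor = tumor, rng_seed = seeds[i]))
  }
  out
}
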