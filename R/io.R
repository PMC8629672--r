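#' Load a directory of PNG images as 8-bit grayscale matrices
#'
#' Files are read in filename-sorted order (a fixed ordering keeps seeded
#' train/test splits reproducible). RGB images are converted to grayscale by
#' the standard luminance weights 0.299 R + 0.587 G + 0.114 B; an alpha
#' channel, if present, is ignored.
#'
#' @param dir Directory containing `.png` files.
#' @param expected_side If not `NULL`, every image must be square with this
#'   side; a mismatch is an error naming the file.
#' @return List with `images` (list of integer matrices, 0-255) and `files`
#'   (sorted file names).
#' @export
load_images <- function(dir, expected_side = NULL) {
  files <- sort(list.files(dir, pattern = "\\.png$", ignore.case = TRUE))
  if (length(files) == 0L)
    stop(sprintf("load_images: no PNG files in '%s'", dir), call. = FALSE)
  images <- vector("list", length(files))
  failed <- character(0)
  for (i in seq_along(files)) {
    path <- file.path(dir, files[i])
    arr <- tryCatch(png::readPNG(path), error = function(e) {
      message(sprintf("load_images: cannot read '%s': %s", files[i],
                      conditionMessage(e)))
      NULL
    })
    if (is.null(arr)) { failed <- c(failed, files[i]); next }
    gray <- if (length(dim(arr)) == 3L) {
      if (dim(arr)[3] >= 3L)
        0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
      else arr[, , 1]
    } else arr
    if (!is.null(expected_side) &&
        !all(dim(gray) == c(expected_side, expected_side)))
      stop(sprintf("load_images: '%s' is %dx%d, expected %dx%d", files[i],
                   nrow(gray), ncol(gray), expected_side, expected_side),
           call. = FALSE)
    images[[i]] <- matrix(as.integer(round(gray * 255)), nrow(gray))
  }
  keep <- !(files %in% failed)
  if (!any(keep))
    stop("load_images: every file failed to read", call. = FALSE)
  list(images = images[keep], files = files[keep])
}

#' Write an 8-bit grayscale matrix (or 0/255 mask) as PNG
#' @param image Matrix with values in 0-255.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 255) / 255, path)
  invisible(path)
}

#' Serialize network parameters to JSON / read them back
#'
#' The JSON document mirrors the parameter fields (`c`, `sigma`, `b`, `a`,
#' `w`, `ybar`) with their shapes, plus the architecture needed to rebuild
#' them.
#'
#' @param params An `fwn_params`.
#' @param config The matching [fwn_config()].
#' @param path Output / input JSON path.
#' @param center,scale Optional feature standardization recorded with the
#'   fit (see [fwn_train()]), to be applied before prediction.
#' @return `write_model`: `path` invisibly. `read_model`: list with
#'   `params`, `config`, `center`, `scale`.
#' @export
write_model <- function(params, config, path, center = NULL, scale = NULL) {
  doc <- list(config = unclass(config), params = params_doc(params),
              center = center, scale = scale)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

# flat column-major values + explicit shapes (JSON has no array layout)
params_doc <- function(params) {
  list(c = as.numeric(params$c), sigma = as.numeric(params$sigma),
       b = as.numeric(params$b), a = as.numeric(params$a),
       w = as.numeric(params$w), ybar = as.numeric(params$ybar),
       shapes = list(c = dim(params$c), b = dim(params$b),
                     w = dim(params$w)))
}

params_from_doc <- function(p, config) {
  fwn_params(config,
             c = matrix(unlist(p$c), config$M, config$n),
             sigma = matrix(unlist(p$sigma), config$M, config$n),
             b = array(unlist(p$b), c(config$N, config$n, config$M)),
             a = array(unlist(p$a), c(config$N, config$n, config$M)),
             w = matrix(unlist(p$w), config$N, config$M),
             ybar = unlist(p$ybar))
}

config_from_doc <- function(cfg) {
  fwn_config(n = cfg$n, M = cfg$M, N = cfg$N,
             num_classes = cfg$num_classes,
             wavelet_family = cfg$wavelet_family,
             normalize_wavelet = cfg$normalize_wavelet,
             a_min = cfg$a_min, sigma_min = cfg$sigma_min,
             eps_den = cfg$eps_den, log_space = cfg$log_space)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  config <- config_from_doc(doc$config)
  list(params = params_from_doc(doc$params, config), config = config,
       center = doc$center, scale = doc$scale)
}

#' Load a run configuration from YAML
#'
#' Recognized top-level blocks: `network` (arguments of [fwn_config()]),
#' `training` ([fwn_train_config()]), `pso` ([fwn_pso_config()]), `patch`
#' ([patch_scheme()]), and `seed`.
#'
#' Because bare `n`, `N` and `y` are booleans in YAML 1.1, the `network`
#' block accepts the spelled-out aliases `features` (for `n`), `rules`
#' (`M`) and `wavelets` (`N`); quoted short keys work too.
#'
#' @param path YAML file path.
#' @return List with `network`, `training`, `pso`, `patch` (constructed
#'   objects or `NULL`) and `seed`.
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$network)) {
    alias <- c(features = "n", rules = "M", wavelets = "N")
    for (from in names(alias)) {
      if (!is.null(raw$network[[from]])) {
        raw$network[[alias[[from]]]] <- raw$network[[from]]
        raw$network[[from]] <- NULL
      }
    }
  }
  build <- function(block, fn) {
    if (is.null(raw[[block]])) NULL else do.call(fn, raw[[block]])
  }
  list(network = build("network", fwn_config),
       training = build("training", fwn_train_config),
       pso = build("pso", fwn_pso_config),
       patch = build("patch", patch_scheme),
       seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed))
}

#' Write a JSON run report
#'
#' Collects the configuration echo, the seed, metrics, confusion matrices,
#' and MD5 hashes of the input files into one JSON document.
#'
#' @param path Output path.
#' @param seed Integer seed used by the run.
#' @param config_echo List describing the configuration.
#' @param metrics Named list of metric values.
#' @param confusions Optional named list of confusion matrices.
#' @param input_files Optional character vector of files to hash.
#' @return The report list, invisibly.
#' @export
run_report <- function(path, seed, config_echo = list(),
                       metrics = list(), confusions = NULL,
                       input_files = NULL) {
  report <- list(seed = seed, config = config_echo, metrics = metrics)
  if (!is.null(confusions))
    report$confusions <- lapply(confusions, function(cm)
      unclass(cm))
  if (!is.null(input_files))
    report$input_hashes <- as.list(tools::md5sum(input_files))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       matrix = "columnmajor", pretty = TRUE)
  invisible(report)
}

#' Serialize a trained segmenter to JSON / read it back
#'
#' Stores the patch scheme, the network configuration, and the parameter
#' set(s) of the trained patch model.
#'
#' @param model An `fwn_segmenter` from [train_segmenter()].
#' @param path Output / input JSON path.
#' @return `write_segmenter`: `path` invisibly. `read_segmenter`: an
#'   `fwn_segmenter`.
#' @export
write_segmenter <- function(model, path) {
  doc <- list(
    scheme = unclass(model$scheme),
    config = unclass(model$config),
    shared = model$shared,
    fits = lapply(model$fits, function(f) params_doc(f$params)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_segmenter
#' @export
read_segmenter <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  config <- config_from_doc(doc$config)
  scheme <- patch_scheme(m = doc$scheme$m, stride = doc$scheme$stride,
                         padding = doc$scheme$padding)
  fits <- lapply(doc$fits, function(f)
    structure(list(params = params_from_doc(f, config), config = config,
                   trace = list()), class = "fwn_fit"))
  structure(list(fits = fits, scheme = scheme, config = config,
                 shared = isTRUE(doc$shared[[1]] == TRUE) ||
                   isTRUE(doc$shared)), class = "fwn_segmenter")
}
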