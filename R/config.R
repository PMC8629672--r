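#' Network architecture configuration
#'
#' Describes the shape of a fuzzy wavelet neural network: `n` input features,
#' `M` Takagi-Sugeno-Kang fuzzy rules, and `N` wavelet neurons in each rule's
#' consequent wavelet network.
#'
#' @param n Number of input features (>= 1).
#' @param M Number of fuzzy rules (>= 1).
#' @param N Number of wavelet neurons per rule (>= 1, uniform across rules).
#' @param num_classes Number of output labels for classification, or `0` for
#'   regression mode (no rounding layer).
#' @param wavelet_family Mother wavelet, `"mexican_hat"` (default) or
#'   `"morlet"`.
#' @param normalize_wavelet If `TRUE`, each wavelet activation carries the
#'   \eqn{|a|^{-1/2}} energy-normalizing prefactor; the default `FALSE` uses
#'   the bare dilated-translated form.
#' @param a_min Floor on the absolute dilation \eqn{|a|}; dilations are
#'   projected back to this floor (sign preserved) during training, enforcing
#'   \eqn{a \neq 0}.
#' @param sigma_min Floor on membership widths \eqn{\sigma > 0}.
#' @param eps_den Denominator floor for defuzzification; if the summed firing
#'   strength falls at or below it, no rule fires and the output is undefined.
#' @param log_space If `TRUE`, the network output is computed with
#'   log-sum-exp-stabilized firing-strength weights. The defuzzified output is
#'   invariant to a common rescaling of the firing strengths, so this changes
#'   nothing mathematically; it keeps the softmax weights well defined when
#'   `n` is large and the raw product of `n` memberships underflows to zero.
#'   Used by the segmentation mode, where `n = (2m)^2 + 2`.
#'
#' @return An object of class `fwn_config`.
#' @examples
#' fwn_config(n = 4, M = 2, N = 2, num_classes = 4)
#' @export
fwn_config <- function(n, M = 2L, N = 2L, num_classes = 0L,
                       wavelet_family = c("mexican_hat", "morlet"),
                       normalize_wavelet = FALSE,
                       a_min = 1e-3, sigma_min = 1e-3, eps_den = 1e-12,
                       log_space = FALSE) {
  wavelet_family <- match.arg(wavelet_family)
  n <- as.integer(n); M <- as.integer(M); N <- as.integer(N)
  num_classes <- as.integer(num_classes)
  if (n < 1L || M < 1L || N < 1L)
    stop("fwn_config: n, M and N must all be >= 1", call. = FALSE)
  if (num_classes < 0L)
    stop("fwn_config: num_classes must be >= 0", call. = FALSE)
  if (a_min <= 0 || sigma_min <= 0 || eps_den <= 0)
    stop("fwn_config: floors a_min, sigma_min, eps_den must be positive",
         call. = FALSE)
  structure(list(n = n, M = M, N = N, num_classes = num_classes,
                 wavelet_family = wavelet_family,
                 normalize_wavelet = isTRUE(normalize_wavelet),
                 a_min = a_min, sigma_min = sigma_min, eps_den = eps_den,
                 log_space = isTRUE(log_space)),
            class = "fwn_config")
}

#' @export
print.fwn_config <- function(x, ...) {
  cat(sprintf(
    "FWNN config: n=%d features, M=%d rules, N=%d wavelets/rule, %s\n",
    x$n, x$M, x$N,
    if (x$num_classes > 0L) sprintf("%d classes", x$num_classes) else
      "regression"))
  cat(sprintf("  wavelet: %s%s; floors: a_min=%g sigma_min=%g eps_den=%g%s\n",
              x$wavelet_family,
              if (x$normalize_wavelet) " (|a|^-1/2 normalized)" else "",
              x$a_min, x$sigma_min, x$eps_den,
              if (x$log_space) "; log-space firing strengths" else ""))
  invisible(x)
}

#' Construct a parameter set for a fuzzy wavelet neural network
#'
#' The trainable set comprises the rule antecedent Gaussians (centers `c`,
#' widths `sigma`), the per-wavelet translations `b` and dilations `a`, the
#' consequent weights `w` and the rule biases `ybar`.
#'
#' @param config An [fwn_config()].
#' @param c `M x n` matrix of membership centers.
#' @param sigma `M x n` matrix of membership widths (all > 0).
#' @param b `N x n x M` array of wavelet translations.
#' @param a `N x n x M` array of wavelet dilations (all `|a| >= a_min`).
#' @param w `N x M` matrix of consequent weights.
#' @param ybar Length-`M` vector of rule biases.
#' @return An object of class `fwn_params`.
#' @export
fwn_params <- function(config, c, sigma, b, a, w, ybar) {
  stopifnot(inherits(config, "fwn_config"))
  c <- as.matrix(c); sigma <- as.matrix(sigma)
  b <- as_param_array(b, config); a <- as_param_array(a, config)
  w <- matrix(w, config$N, config$M); ybar <- as.numeric(ybar)
  p <- structure(list(c = c, sigma = sigma, b = b, a = a, w = w, ybar = ybar),
                 class = "fwn_params")
  validate_params(p, config)
  p
}

as_param_array <- function(x, config) {
  array(as.numeric(x), dim = c(config$N, config$n, config$M))
}

validate_params <- function(params, config) {
  with(config, {
    if (!all(dim(params$c) == c(M, n)) || !all(dim(params$sigma) == c(M, n)))
      stop("fwn_params: c and sigma must be M x n", call. = FALSE)
    if (!all(dim(params$b) == c(N, n, M)) || !all(dim(params$a) == c(N, n, M)))
      stop("fwn_params: b and a must be N x n x M", call. = FALSE)
    if (!all(dim(params$w) == c(N, M)) || length(params$ybar) != M)
      stop("fwn_params: w must be N x M and ybar length M", call. = FALSE)
  })
  if (any(params$sigma <= 0))
    stop("fwn_params: all widths sigma must be > 0", call. = FALSE)
  if (any(abs(params$a) < config$a_min))
    stop("fwn_params: all |a| must be >= a_min", call. = FALSE)
  invisible(params)
}

#' Random parameter initialization
#'
#' Draws parameters uniformly inside the same per-group box that bounds the
#' swarm search (see [fwn_bounds()]), derived from the range of the training
#' features when supplied.
#'
#' @param config An [fwn_config()].
#' @param X Optional feature matrix used to set the box; defaults to
#'   \eqn{[-1, 1]} per feature.
#' @param seed Optional integer seed for reproducibility.
#' @return An `fwn_params` object.
#' @export
fwn_params_random <- function(config, X = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bx <- fwn_bounds(config, X)
  lo <- bx$bounds[, 1]; hi <- bx$bounds[, 2]
  # keep random widths away from the floor: near-zero sigma kills every
  # membership and leaves the defuzzifier with an empty rule set
  lo[bx$groups$sigma] <- lo[bx$groups$sigma] +
    0.1 * (hi[bx$groups$sigma] - lo[bx$groups$sigma])
  theta <- stats::runif(length(lo), lo, hi)
  fwn_unflatten(theta, config)
}

#' Per-group search box for the swarm and random initialization
#'
#' Centers and translations range over the observed feature range, widths over
#' `(sigma_min, feature range)`, dilations over `[a_min, feature range]`
#' (positive branch), weights and biases over `[-2, 2]`.
#'
#' @param config An [fwn_config()].
#' @param X Optional feature matrix (rows = samples); `NULL` uses
#'   \eqn{[-1, 1]} per feature.
#' @return List with `bounds` (d x 2 matrix over the flattened parameter
#'   vector) and `groups` (named list of flat indices per parameter group,
#'   in the order c, sigma, b, a, w, ybar).
#' @export
fwn_bounds <- function(config, X = NULL) {
  n <- config$n; M <- config$M; N <- config$N
  if (is.null(X)) {
    lo_f <- rep(-1, n); hi_f <- rep(1, n)
  } else {
    X <- as.matrix(X)
    lo_f <- apply(X, 2, min); hi_f <- apply(X, 2, max)
    flat <- hi_f <= lo_f
    hi_f[flat] <- lo_f[flat] + 1
  }
  rng <- hi_f - lo_f
  per_feature <- function(lo, hi, times) {
    cbind(rep(lo, times = times), rep(hi, times = times))
  }
  # flat layout mirrors fwn_flatten(): c (M*n), sigma, b (N*n*M), a, w, ybar
  b_c <- per_feature(rep(lo_f, each = M), rep(hi_f, each = M), 1)
  b_s <- per_feature(rep(config$sigma_min * 2, M * n),
                     rep(pmax(rng, 1), each = M), 1)
  b_b <- per_feature(rep(rep(lo_f, each = N), times = M),
                     rep(rep(hi_f, each = N), times = M), 1)
  b_a <- per_feature(rep(config$a_min, N * n * M),
                     rep(rep(pmax(rng, 1), each = N), times = M), 1)
  b_w <- per_feature(rep(-2, N * M), rep(2, N * M), 1)
  b_y <- per_feature(rep(-2, M), rep(2, M), 1)
  bounds <- rbind(b_c, b_s, b_b, b_a, b_w, b_y)
  sizes <- c(c = M * n, sigma = M * n, b = N * n * M, a = N * n * M,
             w = N * M, ybar = M)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  groups <- Map(seq.int, starts, ends)
  names(groups) <- names(sizes)
  list(bounds = bounds, groups = groups)
}

#' Flatten parameters to a vector / rebuild them
#'
#' Used by the swarm optimizer, which searches the concatenated parameter
#' vector. Layout: centers, widths, translations, dilations, weights, biases.
#'
#' @param params An `fwn_params` object.
#' @param theta Numeric vector from [fwn_flatten()].
#' @param config The matching [fwn_config()].
#' @return `fwn_flatten`: numeric vector; `fwn_unflatten`: `fwn_params`.
#' @export
fwn_flatten <- function(params) {
  c(as.numeric(params$c), as.numeric(params$sigma),
    as.numeric(params$b), as.numeric(params$a),
    as.numeric(params$w), params$ybar)
}

#' @rdname fwn_flatten
#' @export
fwn_unflatten <- function(theta, config) {
  n <- config$n; M <- config$M; N <- config$N
  sizes <- c(M * n, M * n, N * n * M, N * n * M, N * M, M)
  stopifnot(length(theta) == sum(sizes))
  idx <- cumsum(sizes)
  take <- function(k) theta[(c(0, idx)[k] + 1L):idx[k]]
  p <- structure(list(
    c = matrix(take(1), M, n),
    sigma = matrix(pmax(take(2), config$sigma_min), M, n),
    b = array(take(3), c(N, n, M)),
    a = array(take(4), c(N, n, M)),
    w = matrix(take(5), N, M),
    ybar = take(6)), class = "fwn_params")
  small <- abs(p$a) < config$a_min
  if (any(small)) {
    s <- sign(p$a[small]); s[s == 0] <- 1
    p$a[small] <- s * config$a_min
  }
  p
}

#' Count of trainable parameters
#' @param config An [fwn_config()].
#' @return Integer.
#' @export
fwn_n_params <- function(config) {
  with(config, 2L * M * n + 2L * N * n * M + N * M + M)
}
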