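#' Gaussian fuzzy membership
#'
#' Degree of truth that feature value `x` belongs to a rule's fuzzy set:
#' \eqn{\mu = \exp(-((x - c)/\sigma)^2)}. Note the exponent carries no 1/2
#' factor; the width convention matches the histogram Gaussian model used in
#' feature extraction.
#'
#' @param x Feature value(s).
#' @param c Membership center.
#' @param sigma Membership width, > 0.
#' @return Membership value(s) in \eqn{(0, 1]}.
#' @examples
#' membership(3, 3, 1)      # 1
#' membership(4, 3, 1)      # exp(-1)
#' @export
membership <- function(x, c, sigma) {
  if (any(sigma <= 0))
    stop("membership: sigma must be > 0", call. = FALSE)
  exp(-((x - c) / sigma)^2)
}

#' Rule firing strength (product t-norm)
#'
#' AND-combines a rule's memberships across the input features:
#' \eqn{O_k = \prod_j \mu_{kj}}.
#'
#' @param mu Vector of memberships for one rule, each in \eqn{(0, 1]}.
#' @return Firing strength in \eqn{(0, 1]}.
#' @export
firing_strength <- function(mu) prod(mu)

#' Product of a wavelet neuron's activations across features
#'
#' \eqn{\Psi_{ik} = \prod_j \psi_{ijk}}: the multidimensional wavelet used in
#' rule `k`'s consequent is the tensor product of the one-dimensional
#' activations.
#'
#' @param psi Vector of one-dimensional wavelet activations over features.
#' @return Scalar product.
#' @export
rule_wavelet_product <- function(psi) prod(psi)

#' Consequent output of one fuzzy rule
#'
#' The THEN-part of rule `k` is a wavelet network:
#' \eqn{Y_k = \sum_i w_i^k \Psi_{ik} + \bar y_k}.
#'
#' @param x Feature vector of length `config$n`.
#' @param k Rule index in `1..M`.
#' @param params An `fwn_params` object.
#' @param config The matching [fwn_config()].
#' @return Scalar rule output \eqn{Y_k}.
#' @export
rule_output <- function(x, k, params, config) {
  Psi <- vapply(seq_len(config$N), function(i) {
    rule_wavelet_product(wavelet_activation(x, params$b[i, , k],
                                            params$a[i, , k], config))
  }, 0)
  sum(params$w[, k] * Psi) + params$ybar[k]
}

#' Defuzzification: firing-strength-weighted mean of rule outputs
#'
#' \eqn{y = \sum_k O_k Y_k / \sum_k O_k}. Undefined when no rule fires, i.e.
#' when the denominator falls at or below the floor `eps_den`.
#'
#' @param O Vector of firing strengths, all >= 0.
#' @param Y Vector of rule outputs (same length).
#' @param eps_den Denominator floor.
#' @return Crisp output `y`, guaranteed within `[min(Y), max(Y)]`.
#' @examples
#' defuzzify(c(0.9, 0.1), c(1, 3))  # 1.2
#' @export
defuzzify <- function(O, Y, eps_den = 1e-12) {
  stopifnot(length(O) == length(Y))
  if (any(O < 0)) stop("defuzzify: firing strengths must be >= 0",
                       call. = FALSE)
  den <- sum(O)
  if (!is.finite(den) || den <= eps_den)
    stop("defuzzify: no rule fires (denominator below eps_den)",
         call. = FALSE)
  sum(O * Y) / den
}

#' Full forward pass with all layer outputs
#'
#' Runs one feature vector through the eight-layer network and records every
#' intermediate quantity: memberships, one-dimensional and product wavelets,
#' firing strengths, rule outputs, the two sixth-layer sums, and the
#' defuzzified output. Layer 8 (rounding to a class label) is applied
#' separately by [fwn_classify()].
#'
#' @param x Feature vector of length `config$n`, finite.
#' @param params An `fwn_params` object.
#' @param config The matching [fwn_config()].
#' @return A list of class `fwn_trace` with elements `mu` (`M x n`), `psi`
#'   (`N x n x M`), `Psi` (`N x M`), `O` (length `M`), `Y` (length `M`),
#'   `O5` (length `M`), `O6_1`, `O6_2`, and `y`.
#' @export
fwn_forward <- function(x, params, config) {
  stopifnot(length(x) == config$n, all(is.finite(x)))
  validate_params(params, config)
  M <- config$M; N <- config$N; n <- config$n
  mu <- matrix(0, M, n)
  for (k in seq_len(M))
    mu[k, ] <- membership(x, params$c[k, ], params$sigma[k, ])
  psi <- array(0, c(N, n, M))
  Psi <- matrix(0, N, M)
  for (k in seq_len(M)) for (i in seq_len(N)) {
    psi[i, , k] <- wavelet_activation(x, params$b[i, , k], params$a[i, , k],
                                      config)
    Psi[i, k] <- rule_wavelet_product(psi[i, , k])
  }
  O <- apply(mu, 1, firing_strength)
  Y <- params$ybar + colSums(params$w * Psi)
  O5 <- O * Y
  y <- defuzzify(O, Y, config$eps_den)
  structure(list(mu = mu, psi = psi, Psi = Psi, O = O, Y = Y, O5 = O5,
                 O6_1 = sum(O5), O6_2 = sum(O), y = y),
            class = "fwn_trace")
}

#' Rounding output layer
#'
#' Converts the continuous network output into a class label: round half away
#' from zero, then clamp into `[0, num_classes - 1]`.
#'
#' @param y Continuous output value(s).
#' @param num_classes Number of labels, >= 2.
#' @return Integer label(s) in `0..num_classes-1`.
#' @examples
#' fwn_classify(c(1.4, 2.5, 3.6), 4)  # 1 3 3
#' @export
fwn_classify <- function(y, num_classes) {
  stopifnot(num_classes >= 2)
  r <- sign(y) * floor(abs(y) + 0.5)   # round half away from zero
  as.integer(pmin(pmax(r, 0), num_classes - 1))
}

# Vectorized forward pass over a sample matrix.
#
# X: S x n matrix. Returns y (length S) plus, when keep = TRUE, the
# intermediates needed by the analytic gradients: U (list over k of S x n
# standardized distances), lo (S x M log firing strengths), O or stabilized
# weights q (S x M), Y (S x M), Psi (S x N x M), psi/dpsi component lists.
fwn_forward_batch <- function(X, params, config, keep = FALSE) {
  X <- as.matrix(X)
  S <- nrow(X); n <- config$n; M <- config$M; N <- config$N
  stopifnot(ncol(X) == n)
  lo <- matrix(0, S, M)
  U <- if (keep) vector("list", M) else NULL
  for (k in seq_len(M)) {
    Uk <- sweep(sweep(X, 2, params$c[k, ], "-"), 2, params$sigma[k, ], "/")
    lo[, k] <- -rowSums(Uk * Uk)
    if (keep) U[[k]] <- Uk
  }
  Psi <- array(0, c(S, N, M))
  psi_l <- if (keep) vector("list", M * N) else NULL
  dps_l <- if (keep) vector("list", M * N) else NULL
  Z_l <- if (keep) vector("list", M * N) else NULL
  for (k in seq_len(M)) for (i in seq_len(N)) {
    aik <- params$a[i, , k]
    Zik <- sweep(sweep(X, 2, params$b[i, , k], "-"), 2, aik, "/")
    P <- mother_wavelet(Zik, config$wavelet_family)
    if (config$normalize_wavelet)
      P <- sweep(P, 2, sqrt(abs(aik)), "/")
    pr <- P[, 1]
    if (n > 1L) for (j in 2:n) pr <- pr * P[, j]
    Psi[, i, k] <- pr
    if (keep) {
      idx <- (k - 1L) * N + i
      D <- mother_wavelet_deriv(Zik, config$wavelet_family)
      if (config$normalize_wavelet)
        D <- sweep(D, 2, sqrt(abs(aik)), "/")
      psi_l[[idx]] <- P; dps_l[[idx]] <- D; Z_l[[idx]] <- Zik
    }
  }
  Y <- matrix(params$ybar, S, M, byrow = TRUE)
  for (k in seq_len(M))
    Y[, k] <- Y[, k] + matrix(Psi[, , k], S, N) %*% params$w[, k]
  if (config$log_space) {
    mx <- lo[, 1]
    if (M > 1L) for (k in 2:M) mx <- pmax(mx, lo[, k])
    Ow <- exp(lo - mx)
  } else {
    Ow <- exp(lo)
    den <- rowSums(Ow)
    if (any(!is.finite(den)) || any(den <= config$eps_den))
      stop("fwn_forward_batch: no rule fires for some input (denominator below eps_den); consider log_space = TRUE",
           call. = FALSE)
  }
  SOw <- rowSums(Ow)
  q <- Ow / SOw
  y <- rowSums(q * Y)
  if (!keep) return(list(y = y, O = Ow, Y = Y))
  list(y = y, q = q, Y = Y, Psi = Psi, lo = lo, U = U,
       psi = psi_l, dpsi = dps_l, Z = Z_l, O = Ow)
}

#' Network predictions for a feature matrix
#'
#' Vectorized forward pass; optionally applies the rounding output layer.
#'
#' @param X `S x n` feature matrix (rows are samples).
#' @param params An `fwn_params` object.
#' @param config The matching [fwn_config()].
#' @param type `"response"` for the continuous output `y`, `"class"` for
#'   rounded labels (requires `config$num_classes >= 2`).
#' @param chunk Number of rows evaluated per block (bounds memory on large
#'   sweeps).
#' @return Numeric (or integer) vector of length `S`.
#' @export
fwn_predict <- function(X, params, config,
                        type = c("response", "class"), chunk = 20000L) {
  type <- match.arg(type)
  X <- as.matrix(X)
  S <- nrow(X)
  y <- numeric(S)
  for (s0 in seq(1L, S, by = chunk)) {
    s1 <- min(s0 + chunk - 1L, S)
    y[s0:s1] <- fwn_forward_batch(X[s0:s1, , drop = FALSE], params, config)$y
  }
  if (type == "class") fwn_classify(y, config$num_classes) else y
}
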