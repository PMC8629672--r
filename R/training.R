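#' Gradient-descent training configuration
#'
#' One learning rate per parameter group, following the per-group update
#' \eqn{\Delta\Theta = (-\gamma_c \partial E/\partial c, \ldots,
#' -\gamma_{\bar y} \partial E/\partial \bar y)}.
#'
#' @param gamma_c,gamma_sigma,gamma_b,gamma_a,gamma_w,gamma_ybar Positive
#'   learning rates for centers, widths, translations, dilations, weights and
#'   biases. Default 0.01 each.
#' @param max_epochs Number of gradient epochs (>= 1).
#' @param batch_mode `"full"` (one averaged update per epoch) or `"online"`
#'   (one update per sample, in order).
#' @param rng_seed Integer seed (used by online shuffling and any stochastic
#'   downstream consumer).
#' @param loss_floor Stop early once the training RMSE falls below this.
#' @return An object of class `fwn_train_config`.
#' @export
fwn_train_config <- function(gamma_c = 0.01, gamma_sigma = 0.01,
                             gamma_b = 0.01, gamma_a = 0.01,
                             gamma_w = 0.01, gamma_ybar = 0.01,
                             max_epochs = 300L,
                             batch_mode = c("full", "online"),
                             rng_seed = 1L, loss_floor = 0) {
  batch_mode <- match.arg(batch_mode)
  rates <- c(gamma_c, gamma_sigma, gamma_b, gamma_a, gamma_w, gamma_ybar)
  if (any(rates <= 0)) stop("all learning rates must be > 0", call. = FALSE)
  if (max_epochs < 1L) stop("max_epochs must be >= 1", call. = FALSE)
  structure(list(gamma = list(c = gamma_c, sigma = gamma_sigma, b = gamma_b,
                              a = gamma_a, w = gamma_w, ybar = gamma_ybar),
                 max_epochs = as.integer(max_epochs),
                 batch_mode = batch_mode,
                 rng_seed = as.integer(rng_seed),
                 loss_floor = loss_floor),
            class = "fwn_train_config")
}

#' Particle swarm configuration
#'
#' Settings for the global-best swarm used to initialize the network before
#' gradient descent. Defaults: 20 particles, 50 generations, both
#' acceleration coefficients 2, linearly decreasing inertia (0.9 to 0.4,
#' the canonical schedule).
#'
#' @param psize Particle count (>= 2).
#' @param maxgen Generation count (>= 1).
#' @param c1,c2 Cognitive and social acceleration coefficients, > 0.
#' @param w_start,w_end Inertia endpoints, `w_start >= w_end > 0`.
#' @param rng_seed Integer seed.
#' @param mode `"inline_pso"` (default): each generation cycles through the
#'   parameter-group blocks (centers+widths, translations+dilations,
#'   weights+biases), moving and re-evaluating one block at a time —
#'   coordinate-blockwise swarm search matched to the grouped gradient
#'   updates that follow. `"plain_pso"` moves the full concatenated vector.
#' @return An object of class `fwn_pso_config`.
#' @export
fwn_pso_config <- function(psize = 20L, maxgen = 50L, c1 = 2, c2 = 2,
                           w_start = 0.9, w_end = 0.4, rng_seed = 1L,
                           mode = c("inline_pso", "plain_pso")) {
  mode <- match.arg(mode)
  if (psize < 2L) stop("psize must be >= 2", call. = FALSE)
  if (maxgen < 1L) stop("maxgen must be >= 1", call. = FALSE)
  if (c1 <= 0 || c2 <= 0) stop("c1, c2 must be > 0", call. = FALSE)
  if (!(w_start >= w_end && w_end > 0))
    stop("need w_start >= w_end > 0", call. = FALSE)
  structure(list(psize = as.integer(psize), maxgen = as.integer(maxgen),
                 c1 = c1, c2 = c2, w_start = w_start, w_end = w_end,
                 rng_seed = as.integer(rng_seed), mode = mode),
            class = "fwn_pso_config")
}

#' Squared-error loss
#'
#' \eqn{E = \frac{1}{2}(y_{true} - y_{pred})^2}. The dataset-level RMSE is
#' \eqn{\sqrt{\mathrm{mean}(2E)}}.
#'
#' @param y_pred Predicted value(s).
#' @param y_true Target value(s).
#' @return Loss value(s).
#' @export
fwn_loss <- function(y_pred, y_true) 0.5 * (y_true - y_pred)^2

#' Dataset root-mean-square error of the network
#' @param X Feature matrix.
#' @param y Numeric targets.
#' @param params,config Network parameters and configuration.
#' @return Scalar RMSE.
#' @export
fwn_rmse <- function(X, y, params, config) {
  sqrt(mean((fwn_predict(X, params, config) - y)^2))
}

#' Analytic gradients of the mean squared-error loss
#'
#' Exact partial derivatives of \eqn{\bar E = \mathrm{mean}_s
#' \frac{1}{2}(y_s - f_s)^2} with respect to every parameter group, obtained
#' by the chain rule through the forward pass. With a single sample this is
#' the per-sample gradient of \eqn{E}.
#'
#' The membership path is differentiated through the log firing strength
#' \eqn{\log O_k = -\sum_j u_{kj}^2}, which avoids dividing by memberships
#' that may underflow; the wavelet path uses exact leave-one-out products so
#' activations equal to zero are handled without special cases.
#'
#' @param X Feature matrix (`S x n`), or a single feature vector.
#' @param y Numeric target(s), length `S`.
#' @param params,config Network parameters and configuration.
#' @return A list with elements `c`, `sigma`, `b`, `a`, `w`, `ybar` shaped
#'   like the corresponding entries of `params`.
#' @export
fwn_gradients <- function(X, y, params, config) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  S <- nrow(X); n <- config$n; M <- config$M; N <- config$N
  stopifnot(length(y) == S)
  fw <- fwn_forward_batch(X, params, config, keep = TRUE)
  e <- fw$y - y                       # dEbar/df per sample / S handled below
  g <- list(c = matrix(0, M, n), sigma = matrix(0, M, n),
            b = array(0, c(N, n, M)), a = array(0, c(N, n, M)),
            w = matrix(0, N, M), ybar = numeric(M))
  for (k in seq_len(M)) {
    qk <- fw$q[, k]
    gY <- e * qk                      # dEbar/dY_k per sample
    g$ybar[k] <- mean(gY)
    g$w[, k] <- colMeans(gY * matrix(fw$Psi[, , k], S, N))
    glo <- e * qk * (fw$Y[, k] - fw$y)   # dEbar/d log O_k per sample
    Uk <- fw$U[[k]]
    g$c[k, ] <- colMeans(glo * Uk) * 2 / params$sigma[k, ]
    g$sigma[k, ] <- colMeans(glo * Uk * Uk) * 2 / params$sigma[k, ]
    for (i in seq_len(N)) {
      idx <- (k - 1L) * N + i
      P <- fw$psi[[idx]]; D <- fw$dpsi[[idx]]; Z <- fw$Z[[idx]]
      # leave-one-out products of the 1-d activations
      L <- matrix(1, S, n); R <- matrix(1, S, n)
      if (n > 1L) {
        for (j in 2:n) L[, j] <- L[, j - 1L] * P[, j - 1L]
        for (j in (n - 1L):1L) R[, j] <- R[, j + 1L] * P[, j + 1L]
      }
      Exc <- L * R
      gPsi <- gY * params$w[i, k]
      aik <- params$a[i, , k]
      dpb <- sweep(D, 2, -aik, "/")          # dpsi/db = -psi'(z)/a
      g$b[i, , k] <- colMeans(gPsi * Exc * dpb)
      # dpsi/da = -(z psi'(z) + [normalized] psi/2) / a
      num <- Z * D
      if (config$normalize_wavelet) num <- num + 0.5 * P
      dpa <- sweep(num, 2, -aik, "/")
      g$a[i, , k] <- colMeans(gPsi * Exc * dpa)
    }
  }
  g
}

#' One gradient-descent update
#'
#' Applies \eqn{\Theta \leftarrow \Theta - \gamma_g \,
#' \partial E/\partial \Theta_g} per parameter group, then projects widths
#' onto the `sigma_min` floor and dilations onto the sign-preserving `a_min`
#' floor.
#'
#' @param params Current `fwn_params`.
#' @param gradients Output of [fwn_gradients()].
#' @param train_config An [fwn_train_config()].
#' @param config The [fwn_config()] (supplies the floors).
#' @return Updated `fwn_params`.
#' @export
gradient_step <- function(params, gradients, train_config, config) {
  gm <- train_config$gamma
  p <- params
  p$c <- p$c - gm$c * gradients$c
  p$sigma <- pmax(p$sigma - gm$sigma * gradients$sigma, config$sigma_min)
  p$b <- p$b - gm$b * gradients$b
  a_new <- p$a - gm$a * gradients$a
  small <- abs(a_new) < config$a_min
  if (any(small)) {
    s <- sign(p$a[small]); s[s == 0] <- 1     # sign before the update
    a_new[small] <- s * config$a_min
  }
  p$a <- a_new
  p$w <- p$w - gm$w * gradients$w
  p$ybar <- p$ybar - gm$ybar * gradients$ybar
  p
}

#' Global-best particle swarm optimization
#'
#' Minimizes `objective` over a box. Velocities follow the standard update
#' \eqn{v \leftarrow w v + c_1 r_1 (p - x) + c_2 r_2 (g - x)} with inertia
#' decreasing linearly from `w_start` to `w_end` over the generations,
#' velocities clamped to half the box width per dimension, and positions
#' clamped to the box. Generation 1 is the evaluated initial population
#' (so `maxgen = 1` returns the best random particle); movement starts at
#' generation 2. In `inline_pso` mode the swarm moves and re-evaluates
#' one index block at a time within each generation (blockwise coordinate
#' search); with no `blocks` given the mode reduces to plain PSO.
#'
#' @param objective Function mapping a numeric vector (a flattened parameter
#'   set) to a scalar fitness; non-finite values are treated as infinitely
#'   bad.
#' @param bounds `d x 2` matrix of lower/upper limits.
#' @param pso_config An [fwn_pso_config()].
#' @param blocks Optional list of integer index vectors defining the blocks
#'   cycled through in `inline_pso` mode.
#' @return List with `par` (best-ever position), `value` (its fitness), and
#'   `trace` (best fitness after each generation, non-increasing).
#' @export
pso_optimize <- function(objective, bounds, pso_config, blocks = NULL) {
  stopifnot(is.matrix(bounds), ncol(bounds) == 2)
  set.seed(pso_config$rng_seed)
  d <- nrow(bounds)
  lo <- bounds[, 1]; hi <- bounds[, 2]
  vmax <- (hi - lo) / 2
  ps <- pso_config$psize
  X <- matrix(stats::runif(ps * d, rep(lo, each = ps), rep(hi, each = ps)),
              ps, d)
  V <- matrix(0, ps, d)
  eval1 <- function(x) {
    f <- tryCatch(objective(x), error = function(e) Inf)
    if (!is.finite(f)) Inf else f
  }
  fit <- apply(X, 1, eval1)
  if (all(!is.finite(fit)))
    stop("pso_optimize: objective non-finite on every initial particle",
         call. = FALSE)
  Pb <- X; pb_fit <- fit
  gi <- which.min(pb_fit)
  gb <- Pb[gi, ]; gb_fit <- pb_fit[gi]
  use_blocks <- pso_config$mode == "inline_pso" && !is.null(blocks)
  block_list <- if (use_blocks) blocks else list(seq_len(d))
  # generation 1 is the evaluated initial population; movement starts at 2
  trace <- numeric(pso_config$maxgen)
  trace[1] <- gb_fit
  if (pso_config$maxgen >= 2L) for (gen in 2:pso_config$maxgen) {
    w_in <- pso_config$w_start - (pso_config$w_start - pso_config$w_end) *
        (gen - 1) / (pso_config$maxgen - 1)
    for (bl in block_list) {
      r1 <- matrix(stats::runif(ps * length(bl)), ps)
      r2 <- matrix(stats::runif(ps * length(bl)), ps)
      V[, bl] <- w_in * V[, bl] +
        pso_config$c1 * r1 * (Pb[, bl, drop = FALSE] - X[, bl, drop = FALSE]) +
        pso_config$c2 * r2 * (matrix(gb[bl], ps, length(bl), byrow = TRUE) -
                                X[, bl, drop = FALSE])
      V[, bl] <- pmin(pmax(V[, bl], matrix(-vmax[bl], ps, length(bl),
                                           byrow = TRUE)),
                      matrix(vmax[bl], ps, length(bl), byrow = TRUE))
      X[, bl] <- X[, bl] + V[, bl]
      X[, bl] <- pmin(pmax(X[, bl], matrix(lo[bl], ps, length(bl),
                                           byrow = TRUE)),
                      matrix(hi[bl], ps, length(bl), byrow = TRUE))
      fit <- apply(X, 1, eval1)
      better <- fit < pb_fit
      Pb[better, ] <- X[better, , drop = FALSE]
      pb_fit[better] <- fit[better]
      gi <- which.min(pb_fit)
      if (pb_fit[gi] < gb_fit) { gb <- Pb[gi, ]; gb_fit <- pb_fit[gi] }
    }
    trace[gen] <- gb_fit
  }
  list(par = gb, value = gb_fit, trace = trace)
}

#' Hybrid training: swarm initialization followed by gradient descent
#'
#' Runs [pso_optimize()] on the dataset RMSE to initialize the parameter set
#' (the "inline" blockwise variant by default), then refines it by gradient
#' descent with the analytic gradients, recording per-epoch train (and
#' optionally test) RMSE.
#'
#' @param X `S x n` feature matrix.
#' @param y Numeric targets of length `S` (for classification, the labels
#'   `0..C-1` themselves).
#' @param config An [fwn_config()].
#' @param train_config An [fwn_train_config()].
#' @param pso_config An [fwn_pso_config()], or `NULL` to skip the swarm stage
#'   and start from a random parameter set (plain gradient descent).
#' @param X_test,y_test Optional held-out set whose RMSE is traced per epoch.
#' @param bounds Optional list from [fwn_bounds()]; computed from `X` when
#'   missing.
#' @param init Optional `fwn_params` starting point (overrides both the swarm
#'   stage and random initialization).
#' @param standardize If `TRUE`, features are z-scored before training (the
#'   centering/scaling is stored in the fit and applied by
#'   [predict.fwn_fit()]). Recommended when feature magnitudes are far from
#'   unit scale: it conditions the antecedent gradients.
#' @param n_restarts Number of hybrid restarts; restart `r` offsets every
#'   seed by `r - 1`. The best restart is kept — highest training accuracy
#'   (classification mode), ties and regression decided by final training
#'   RMSE — stopping early once training accuracy reaches 1.
#' @return A list of class `fwn_fit`: `params`, `config` (with the
#'   log-space weighting enabled, the form used during training, so
#'   predictions from the fit share its numerics), `center`/`scale` (or
#'   `NULL`), and `trace` (list with per-epoch `train_rmse`, `test_rmse`,
#'   and per-generation `pso_fitness`).
#' @export
fwn_train <- function(X, y, config, train_config = fwn_train_config(),
                      pso_config = fwn_pso_config(), X_test = NULL,
                      y_test = NULL, bounds = NULL, init = NULL,
                      standardize = FALSE, n_restarts = 1L) {
  X <- as.matrix(X)
  if (nrow(X) == 0L) stop("fwn_train: empty dataset", call. = FALSE)
  stopifnot(ncol(X) == config$n, length(y) == nrow(X))
  ctr <- NULL; scl <- NULL
  if (standardize) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, stats::sd); scl[scl <= 0] <- 1
    X <- sweep(sweep(X, 2, ctr, "-"), 2, scl, "/")
    if (!is.null(X_test))
      X_test <- sweep(sweep(as.matrix(X_test), 2, ctr, "-"), 2, scl, "/")
  }
  if (n_restarts > 1L) {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      tc <- train_config; tc$rng_seed <- train_config$rng_seed + r - 1L
      pc <- pso_config
      if (!is.null(pc)) pc$rng_seed <- pso_config$rng_seed + r - 1L
      fit <- fwn_train(X, y, config, tc, pc, X_test, y_test, bounds, init)
      fit$restart <- r
      rmse_r <- utils::tail(fit$trace$train_rmse, 1)
      acc_r <- if (config$num_classes >= 2L)
        mean(fwn_predict(X, fit$params, fit$config, type = "class") == y) else
          NA_real_
      if (is.null(best) ||
          (!is.na(acc_r) && acc_r > best$acc) ||
          ((is.na(acc_r) || acc_r == best$acc) && rmse_r < best$rmse))
        best <- list(fit = fit, acc = acc_r, rmse = rmse_r)
      if (!is.na(acc_r) && acc_r >= 1) break
    }
    out <- best$fit
    out$center <- ctr; out$scale <- scl
    return(out)
  }
  bx <- if (is.null(bounds)) fwn_bounds(config, X) else bounds
  blocks <- list(c(bx$groups$c, bx$groups$sigma),
                 c(bx$groups$b, bx$groups$a),
                 c(bx$groups$w, bx$groups$ybar))
  # train on the log-sum-exp-stabilized weighting: identical output wherever
  # the strict path is defined, but search points where no rule fires on
  # some sample do not abort the run
  cfg_tr <- config; cfg_tr$log_space <- TRUE
  objective <- function(theta) {
    p <- fwn_unflatten(theta, config)
    fwn_rmse(X, y, p, cfg_tr)
  }
  pso_trace <- numeric(0)
  if (!is.null(init)) {
    params <- init
  } else if (!is.null(pso_config)) {
    sol <- pso_optimize(objective, bx$bounds, pso_config, blocks = blocks)
    params <- fwn_unflatten(sol$par, config)
    pso_trace <- sol$trace
  } else {
    params <- fwn_params_random(config, X, seed = train_config$rng_seed)
  }
  n_ep <- train_config$max_epochs
  train_rmse <- numeric(n_ep)
  test_rmse <- if (is.null(X_test)) NULL else numeric(n_ep)
  # keep the best epoch seen (including the initialization): a too-large
  # step can overshoot, and the returned fit should never be worse than
  # its starting point
  best_rmse <- fwn_rmse(X, y, params, cfg_tr)
  best_params <- params
  set.seed(train_config$rng_seed)
  for (ep in seq_len(n_ep)) {
    if (train_config$batch_mode == "full") {
      gr <- fwn_gradients(X, y, params, cfg_tr)
      params <- gradient_step(params, gr, train_config, config)
    } else {
      for (s in sample.int(nrow(X))) {
        gr <- fwn_gradients(X[s, , drop = FALSE], y[s], params, cfg_tr)
        params <- gradient_step(params, gr, train_config, config)
      }
    }
    train_rmse[ep] <- fwn_rmse(X, y, params, cfg_tr)
    if (!is.null(X_test))
      test_rmse[ep] <- fwn_rmse(X_test, y_test, params, cfg_tr)
    if (train_rmse[ep] < best_rmse) {
      best_rmse <- train_rmse[ep]
      best_params <- params
    }
    if (train_rmse[ep] <= train_config$loss_floor) {
      train_rmse <- train_rmse[seq_len(ep)]
      if (!is.null(test_rmse)) test_rmse <- test_rmse[seq_len(ep)]
      break
    }
  }
  params <- best_params
  structure(list(params = params, config = cfg_tr,
                 center = ctr, scale = scl,
                 trace = list(train_rmse = train_rmse,
                              test_rmse = test_rmse,
                              pso_fitness = pso_trace)),
            class = "fwn_fit")
}

#' Predict from a trained network fit
#'
#' Applies the feature standardization stored in the fit (if any), then the
#' forward pass.
#'
#' @param object An `fwn_fit` from [fwn_train()].
#' @param newdata Feature matrix.
#' @param type `"response"` or `"class"` (see [fwn_predict()]).
#' @param ... Unused.
#' @return Prediction vector.
#' @export
predict.fwn_fit <- function(object, newdata,
                            type = c("response", "class"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (!is.null(object$center))
    X <- sweep(sweep(X, 2, object$center, "-"), 2, object$scale, "/")
  fwn_predict(X, object$params, object$config, type = type)
}

#' @export
print.fwn_fit <- function(x, ...) {
  tr <- x$trace$train_rmse
  cat(sprintf("FWNN fit: %d epochs, final train RMSE %.5g%s\n",
              length(tr), tr[length(tr)],
              if (length(x$trace$pso_fitness))
                sprintf(" (swarm best %.5g)",
                        min(x$trace$pso_fitness)) else ""))
  invisible(x)
}
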