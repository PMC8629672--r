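# Shared fixtures: benign random parameter draws and independent oracles.

# random parameters with moderate widths/dilations so memberships stay far
# from underflow in small-n tests
benign_params <- function(cfg, seed) {
  set.seed(seed)
  nb <- cfg$N * cfg$n * cfg$M
  fwn_params(
    cfg,
    c = matrix(runif(cfg$M * cfg$n, -1, 1), cfg$M, cfg$n),
    sigma = matrix(runif(cfg$M * cfg$n, 0.5, 2), cfg$M, cfg$n),
    b = array(runif(nb, -1, 1), c(cfg$N, cfg$n, cfg$M)),
    a = array(sample(c(-1, 1), nb, TRUE) * runif(nb, 0.5, 2),
              c(cfg$N, cfg$n, cfg$M)),
    w = matrix(runif(cfg$N * cfg$M, -1, 1), cfg$N, cfg$M),
    ybar = runif(cfg$M, -1, 1))
}

# Independent scalar re-implementation of the eight-layer forward pass:
# plain loops and explicit formulas, no shared code with the package paths.
naive_forward <- function(x, p, cfg) {
  psi_fun <- function(z) {
    if (cfg$wavelet_family == "mexican_hat") (1 - z^2) * exp(-z^2 / 2)
    else cos(5 * z) * exp(-z^2 / 2)
  }
  M <- cfg$M; N <- cfg$N; n <- cfg$n
  O <- numeric(M); Y <- numeric(M)
  for (k in 1:M) {
    ok <- 1
    for (j in 1:n)
      ok <- ok * exp(-((x[j] - p$c[k, j]) / p$sigma[k, j])^2)
    O[k] <- ok
    yk <- p$ybar[k]
    for (i in 1:N) {
      prod_ik <- 1
      for (j in 1:n) {
        z <- (x[j] - p$b[i, j, k]) / p$a[i, j, k]
        v <- psi_fun(z)
        if (cfg$normalize_wavelet) v <- v / sqrt(abs(p$a[i, j, k]))
        prod_ik <- prod_ik * v
      }
      yk <- yk + p$w[i, k] * prod_ik
    }
    Y[k] <- yk
  }
  sum(O * Y) / sum(O)
}

# central finite differences of the mean loss over the flattened parameters
fd_gradients <- function(X, y, params, cfg, h = 1e-6) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  th <- fwn_flatten(params)
  loss_at <- function(v) {
    p <- fwn_unflatten(v, cfg)
    mean(vapply(seq_len(nrow(X)), function(s)
      fwn_loss(fwn_forward(X[s, ], p, cfg)$y, y[s]), 0))
  }
  vapply(seq_along(th), function(j) {
    t1 <- th; t1[j] <- t1[j] + h
    t2 <- th; t2[j] <- t2[j] - h
    (loss_at(t1) - loss_at(t2)) / (2 * h)
  }, 0)
}

flatten_gradients <- function(g) {
  c(as.numeric(g$c), as.numeric(g$sigma), as.numeric(g$b),
    as.numeric(g$a), as.numeric(g$w), g$ybar)
}

# exact synthetic histogram from known mode parameters, normalized
synthetic_histogram <- function(A, m, s) {
  v <- 0:255
  h <- rowSums(vapply(seq_along(A), function(g)
    A[g] * exp(-((v - m[g]) / s[g])^2), numeric(256)))
  h / sum(h)
}
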