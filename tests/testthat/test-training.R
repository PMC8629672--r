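test_that("squared-error loss matches its definition", {
  expect_equal(fwn_loss(2, 2), 0)
  expect_equal(fwn_loss(0, 2), 2)
  expect_equal(fwn_loss(1.5, 1.0), 0.125)
})

test_that("analytic gradients match central finite differences in every group", {
  for (seed in 1:10) {
    set.seed(seed)
    cfg <- fwn_config(n = sample(1:3, 1), M = sample(1:2, 1),
                      N = sample(1:2, 1),
                      normalize_wavelet = seed %% 2 == 0)
    p <- benign_params(cfg, seed + 40)
    X <- matrix(runif(3 * cfg$n, -1, 1), 3, cfg$n)
    y <- rnorm(3, 0, 2)
    an <- flatten_gradients(fwn_gradients(X, y, p, cfg))
    fd <- fd_gradients(X, y, p, cfg)
    expect_lt(max(abs(an - fd) / pmax(1, abs(fd))), 1e-5)
  }
})

test_that("bias gradient at M = 1 with zero weights is the prediction error", {
  cfg <- fwn_config(n = 2, M = 1, N = 2)
  p <- benign_params(cfg, 5); p$w[] <- 0
  x <- c(0.3, -0.4); y_true <- 2
  g <- fwn_gradients(x, y_true, p, cfg)
  expect_equal(g$ybar, p$ybar[1] - y_true)  # y_pred = ybar when w = 0
})

test_that("gradients vanish at a perfect fit", {
  cfg <- fwn_config(n = 2, M = 2, N = 1)
  p <- benign_params(cfg, 6)
  x <- c(0.1, 0.2)
  y_true <- fwn_forward(x, p, cfg)$y
  g <- fwn_gradients(x, y_true, p, cfg)
  expect_equal(max(abs(flatten_gradients(g))), 0)
})

test_that("gradient step applies per-group rates and projects the floors", {
  cfg <- fwn_config(n = 1, M = 1, N = 1)
  p <- fwn_params(cfg, c = 0, sigma = 0.5, b = 0, a = 0.01, w = 1, ybar = 2)
  zero <- fwn_gradients(0.5, fwn_forward(0.5, p, cfg)$y, p, cfg)
  expect_equal(gradient_step(p, zero, fwn_train_config(), cfg), p)
  g <- zero; g$ybar <- 1
  p2 <- gradient_step(p, g, fwn_train_config(gamma_ybar = 0.1), cfg)
  expect_equal(p2$ybar, 2 - 0.1)
  # dilation update crossing zero projects to sign-preserving floor
  g2 <- zero; g2$a[1, 1, 1] <- 5          # 0.01 - 0.01*5 = -0.04 -> |a|<a_min? no
  g2$a[1, 1, 1] <- 1.001                   # 0.01 - 0.01*1.001 = -1e-5
  p3 <- gradient_step(p, g2, fwn_train_config(), cfg)
  expect_equal(p3$a[1, 1, 1], cfg$a_min)   # sign of previous a (+) preserved
  # width floor
  g3 <- zero; g3$sigma[1, 1] <- 100
  p4 <- gradient_step(p, g3, fwn_train_config(), cfg)
  expect_equal(p4$sigma[1, 1], cfg$sigma_min)
})

test_that("the swarm minimizes a sphere, its best fitness is monotone, and seeding reproduces it", {
  sphere <- function(v) sum(v^2)
  bounds <- cbind(rep(-5, 5), rep(5, 5))
  runs <- lapply(1:5, function(sd)
    pso_optimize(sphere, bounds, fwn_pso_config(rng_seed = sd,
                                                mode = "plain_pso")))
  expect_lt(median(vapply(runs, `[[`, 0, "value")), 1e-2)
  for (res in runs) expect_true(all(diff(res$trace) <= 0))
  res2 <- pso_optimize(sphere, bounds, fwn_pso_config(rng_seed = 1,
                                                      mode = "plain_pso"))
  expect_identical(res2, runs[[1]])
  # inline (blockwise) mode also descends and stays monotone
  res3 <- pso_optimize(sphere, bounds, fwn_pso_config(rng_seed = 7),
                       blocks = list(1:2, 3:5))
  expect_true(all(diff(res3$trace) <= 0))
  expect_lt(res3$value, 1e-2)
})

test_that("maxgen = 1 returns the best particle of the initial population", {
  sphere <- function(v) sum(v^2)
  bounds <- cbind(rep(-5, 3), rep(5, 3))
  cfgp <- fwn_pso_config(psize = 8L, maxgen = 1L, rng_seed = 21)
  res <- pso_optimize(sphere, bounds, cfgp)
  set.seed(21)
  X0 <- matrix(runif(8 * 3, rep(-5, each = 8), rep(5, each = 8)), 8, 3)
  expect_equal(res$value, min(apply(X0, 1, sphere)))
  expect_length(res$trace, 1L)
})

test_that("swarm errors when the objective is non-finite everywhere", {
  bounds <- cbind(rep(-1, 2), rep(1, 2))
  expect_error(pso_optimize(function(v) NaN, bounds, fwn_pso_config()),
               "non-finite")
})

test_that("a single training pair drives the bias to the target", {
  cfg <- fwn_config(n = 1, M = 1, N = 1)
  init <- fwn_params(cfg, c = 0, sigma = 1, b = 0, a = 1, w = 0, ybar = 0)
  fit <- fwn_train(matrix(0.3), 1.7, cfg,
                   fwn_train_config(max_epochs = 2000L, loss_floor = 1e-9),
                   pso_config = NULL, init = init)
  expect_lt(abs(fwn_predict(matrix(0.3), fit$params, cfg) - 1.7), 1e-3)
})

test_that("full-batch RMSE is non-increasing for almost all epochs at small rates", {
  set.seed(31)
  cfg <- fwn_config(n = 2, M = 2, N = 2)
  X <- matrix(runif(60, -1, 1), 30, 2)
  y <- 0.5 * X[, 1] - X[, 2]^2
  tc <- fwn_train_config(gamma_c = 1e-3, gamma_sigma = 1e-3, gamma_b = 1e-3,
                         gamma_a = 1e-3, gamma_w = 1e-3, gamma_ybar = 1e-3,
                         max_epochs = 100L)
  fit <- fwn_train(X, y, cfg, tc, pso_config = NULL,
                   init = benign_params(cfg, 32))
  drops <- diff(fit$trace$train_rmse) <= 1e-12
  expect_gte(mean(drops), 0.9)
})

test_that("seeded hybrid training is bit-identical across runs", {
  ds <- generate_class_dataset(10, seed = 3)
  cfg <- fwn_config(n = 4, M = 2, N = 2, num_classes = 4)
  tc <- fwn_train_config(max_epochs = 5L)
  pc <- fwn_pso_config(psize = 8L, maxgen = 10L, rng_seed = 2)
  f1 <- fwn_train(ds$X, ds$y, cfg, tc, pc)
  f2 <- fwn_train(ds$X, ds$y, cfg, tc, pc)
  expect_identical(f1, f2)
})

test_that("swarm initialization beats random initialization on most seeded datasets", {
  wins <- 0L
  for (seed in 1:10) {
    ds <- generate_class_dataset(15, seed = seed)
    Xs <- scale(ds$X)
    cfg <- fwn_config(n = 4, M = 2, N = 2, num_classes = 4)
    tc <- fwn_train_config(max_epochs = 60L, rng_seed = seed)
    pc <- fwn_pso_config(psize = 10L, maxgen = 15L, rng_seed = seed)
    hybrid <- fwn_train(Xs, ds$y, cfg, tc, pc)
    plain <- fwn_train(Xs, ds$y, cfg, tc, pso_config = NULL)
    r_h <- tail(hybrid$trace$train_rmse, 1)
    r_p <- tail(plain$trace$train_rmse, 1)
    if (r_h <= r_p + 1e-9) wins <- wins + 1L
  }
  expect_gte(wins, 7L)
})
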