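test_that("mother wavelets match their closed forms and reject unknown families", {
  expect_equal(mother_wavelet(0), 1)
  expect_equal(mother_wavelet(1), 0)
  expect_equal(mother_wavelet(2), -3 * exp(-2))
  expect_equal(mother_wavelet(0.5, "morlet"), cos(2.5) * exp(-0.125))
  expect_error(mother_wavelet(0, "haar"), "unknown wavelet family")
})

test_that("admissibility holds for shipped families and fails for a nonzero-mean function", {
  expect_true(check_admissibility("mexican_hat"))
  expect_true(check_admissibility("morlet"))
  expect_false(check_admissibility(function(x) rep(1, length(x))))
  expect_false(check_admissibility(function(x) exp(-x^2 / 2)))
})

test_that("wavelet activation applies translation, dilation, the optional prefactor and the dilation floor", {
  cfg <- fwn_config(n = 1)
  expect_equal(wavelet_activation(3.7, b = 3.7, a = 2, cfg), 1)
  expect_equal(wavelet_activation(2, b = 0, a = 1, cfg), -3 * exp(-2))
  cfg_norm <- fwn_config(n = 1, normalize_wavelet = TRUE)
  expect_equal(wavelet_activation(5, b = 5, a = 4, cfg_norm), 0.5)
  expect_error(wavelet_activation(0, b = 0, a = 1e-6, cfg),
               "dilation floor")
})

test_that("membership is the squared-exponential without the 1/2 factor", {
  expect_equal(membership(3, 3, 1), 1)
  expect_equal(membership(4, 3, 1), exp(-1))
  expect_equal(membership(5, 3, 1), exp(-4))
  expect_error(membership(1, 0, 0), "sigma")
  # bounds: in (0, 1], equal to 1 iff x = c
  xs <- seq(-5, 5, by = 0.5)
  mu <- membership(xs, 0.5, 1.3)
  expect_true(all(mu > 0 & mu <= 1))
  expect_identical(which(mu == 1), which(xs == 0.5))
})

test_that("firing strength and wavelet products are plain products", {
  expect_equal(firing_strength(c(1, 1, 1)), 1)
  expect_equal(firing_strength(c(0.5, 0.5)), 0.25)
  expect_equal(firing_strength(c(exp(-1), exp(-4))), exp(-5))
  expect_equal(rule_wavelet_product(0.7), 0.7)          # n = 1 reduction
  expect_equal(rule_wavelet_product(c(1, 0)), 0)        # annihilator
  expect_equal(rule_wavelet_product(c(-0.406, -0.406)), 0.406^2)
})

test_that("rule output is the weighted wavelet sum plus bias", {
  cfg <- fwn_config(n = 2, M = 1, N = 2)
  p <- benign_params(cfg, 1)
  p$w[] <- 0
  expect_equal(rule_output(c(0.1, 0.2), 1, p, cfg), p$ybar[1])
  # hand-built single-wavelet case: w * Psi + ybar = 2 * 0.5 + 1
  cfg1 <- fwn_config(n = 1, M = 1, N = 1)
  p1 <- fwn_params(cfg1, c = 0, sigma = 1, b = 0, a = 1, w = 2, ybar = 1)
  x0 <- uniroot(function(x) mother_wavelet(x) - 0.5, c(0, 1),
                tol = 1e-12)$root
  expect_equal(rule_output(x0, 1, p1, cfg1), 2, tolerance = 1e-8)
  # cancellation
  p2 <- benign_params(fwn_config(n = 1, M = 1, N = 2), 2)
  p2$w[, 1] <- c(1, -1); p2$b[1, 1, 1] <- p2$b[2, 1, 1]
  p2$a[1, 1, 1] <- p2$a[2, 1, 1]; p2$ybar <- 0
  expect_equal(rule_output(0.3, 1, p2, fwn_config(n = 1, M = 1, N = 2)), 0)
})

test_that("defuzzification is the firing-strength-weighted mean with a denominator floor", {
  expect_equal(defuzzify(0.37, 5.1), 5.1)               # M = 1 collapse
  expect_equal(defuzzify(c(0.5, 0.5), c(0, 2)), 1)
  expect_equal(defuzzify(c(0.9, 0.1), c(1, 3)), 1.2)
  expect_error(defuzzify(c(1e-13, 1e-13), c(1, 2)), "no rule fires")
  expect_error(defuzzify(c(-0.1, 0.5), c(1, 2)), ">= 0")
})

test_that("forward trace satisfies the layer identities, convexity and permutation symmetry", {
  for (seed in 1:20) {
    set.seed(seed)
    cfg <- fwn_config(n = sample(1:3, 1), M = sample(1:3, 1),
                      N = sample(1:3, 1))
    p <- benign_params(cfg, seed + 50)
    x <- runif(cfg$n, -1.5, 1.5)
    tr <- fwn_forward(x, p, cfg)
    expect_true(all(tr$O > 0 & tr$O <= 1))
    expect_equal(tr$O6_2, sum(tr$O))
    expect_equal(tr$O6_1, sum(tr$O5))
    expect_equal(tr$y * tr$O6_2, tr$O6_1, tolerance = 1e-12)
    expect_gte(tr$y, min(tr$Y) - 1e-12)
    expect_lte(tr$y, max(tr$Y) + 1e-12)
    if (cfg$M > 1) {
      perm <- sample(cfg$M)
      pp <- p
      pp$c <- p$c[perm, , drop = FALSE]
      pp$sigma <- p$sigma[perm, , drop = FALSE]
      pp$b <- p$b[, , perm, drop = FALSE]
      pp$a <- p$a[, , perm, drop = FALSE]
      pp$w <- p$w[, perm, drop = FALSE]
      pp$ybar <- p$ybar[perm]
      expect_equal(fwn_forward(x, pp, cfg)$y, tr$y, tolerance = 1e-12)
    }
  }
})

test_that("forward pass agrees with the independent scalar oracle", {
  for (seed in 1:25) {
    set.seed(seed)
    cfg <- fwn_config(n = sample(1:3, 1), M = sample(1:3, 1),
                      N = sample(1:3, 1),
                      normalize_wavelet = seed %% 2 == 0,
                      wavelet_family = if (seed %% 3 == 0) "morlet" else
                        "mexican_hat")
    p <- benign_params(cfg, seed + 500)
    x <- runif(cfg$n, -1.5, 1.5)
    expect_equal(fwn_forward(x, p, cfg)$y, naive_forward(x, p, cfg),
                 tolerance = 1e-12)
    expect_equal(fwn_predict(matrix(x, 1), p, cfg), naive_forward(x, p, cfg),
                 tolerance = 1e-12)
  }
})

test_that("constant-consequent network returns its bias regardless of input", {
  cfg <- fwn_config(n = 2, M = 1, N = 2)
  p <- benign_params(cfg, 3)
  p$w[] <- 0
  for (x1 in c(-1, 0, 2))
    expect_equal(fwn_forward(c(x1, 0.5), p, cfg)$y, p$ybar[1])
})

test_that("log-space output equals the strict output where both are defined", {
  cfg <- fwn_config(n = 3, M = 2, N = 2)
  cfg_log <- fwn_config(n = 3, M = 2, N = 2, log_space = TRUE)
  p <- benign_params(cfg, 9)
  X <- matrix(runif(30, -1, 1), 10, 3)
  expect_equal(fwn_predict(X, p, cfg_log), fwn_predict(X, p, cfg),
               tolerance = 1e-12)
})

test_that("rounding layer rounds half away from zero and clamps to the label range", {
  expect_identical(fwn_classify(1.4, 4), 1L)
  expect_identical(fwn_classify(3.6, 4), 3L)   # clamped after rounding to 4
  expect_identical(fwn_classify(2.5, 4), 3L)   # half away from zero
  expect_identical(fwn_classify(-0.7, 4), 0L)  # clamped from below
  expect_identical(fwn_classify(c(0.49, 0.5, 1.49), 3), c(0L, 1L, 1L))
})
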