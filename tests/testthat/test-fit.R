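test_that("the Poisson NLL matches hand computations and is minimized at rate = count", {
  expect_equal(poisson_nll(1, 0), 1)
  expect_equal(poisson_nll(c(2, 2), c(2, 2)), 2 * (2 - 2 * log(2)))
  ## element-wise minimum at rate == count
  cts <- c(1, 3, 7)
  at_min <- poisson_nll(cts, cts)
  for (eps in c(-0.3, 0.4)) {
    expect_gt(poisson_nll(cts + eps, cts), at_min)
  }
  expect_error(poisson_nll(c(0, 1), c(2, 0)), "undefined")
  expect_error(poisson_nll(1, 1.5), "integer")
})

test_that("the analytic gradient matches central finite differences for all model variants", {
  mv <- tiny_movie(T = 30, H = 6, W = 6, seed = 31)
  cfg <- patch_config(5, 5, 1L, 2L)            # P = 25
  specs <- list(model_spec(TRUE, TRUE, "softplus"),
                model_spec(TRUE, TRUE, "logistic"),
                model_spec(TRUE, FALSE, "softplus"),
                model_spec(FALSE, TRUE, "softplus"),
                model_spec(FALSE, FALSE, "logistic"))
  cts <- sample_spikes(rep(1.2, 30), seed = 32)
  for (si in seq_along(specs)) {
    spec <- specs[[si]]
    K <- qconv:::model_pool_length(c(6, 6), cfg, spec)
    p <- rand_params(25, K, seed = 40 + si, quadratic = spec$quadratic)
    g <- nll_gradient(p, spec, mv, cts, cfg)
    gv <- c(g$a1, g$v1, as.vector(g$J), g$v2, g$a2, g$d)
    design <- qconv:::model_design(mv, cfg, spec)
    cuse <- qconv:::usable_counts(cts, design)
    f <- function(v) {
      prm <- qconv:::param_from_vector(v, 25, K)
      qconv:::nll_from_forward(qconv:::qc_forward(design, prm, spec), cuse)
    }
    v0 <- as.vector(p)
    idx <- with_seed_test(50 + si, sample(length(v0), 40))
    if (!spec$quadratic) idx <- idx[idx <= 1 + 25 | idx > 1 + 25 + 625]
    fd <- vapply(idx, function(i) {
      h <- 1e-5; vp <- v0; vm <- v0
      vp[i] <- vp[i] + h; vm[i] <- vm[i] - h
      (f(vp) - f(vm)) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(fd - gv[idx]) / pmax(abs(fd), 1e-6)), 1e-5)
  }
})

test_that("gradients are additive over duplicated batches and d is stationary for constant models", {
  mv <- tiny_movie(T = 20, H = 5, W = 5, seed = 33)
  cfg <- patch_config(4, 4, 2L, 1L)
  K <- pooling_vector_length(c(5, 5), cfg)
  p <- rand_params(16, K, seed = 34)
  cts <- sample_spikes(rep(1, 20), seed = 35)
  ## additivity: the mean-per-frame gradient is invariant to duplicating the
  ## batch, so the summed gradient doubles exactly
  g1 <- nll_gradient(p, model_spec(), mv, cts, cfg, batch = c(2, 5, 9))
  g2 <- nll_gradient(p, model_spec(), mv, cts, cfg, batch = c(2, 5, 9, 2, 5, 9))
  for (f in c("a1", "v1", "J", "v2", "a2", "d")) expect_equal(g1[[f]], g2[[f]])

  ## v2 = 0 and a2 at the stationary point of the constant-rate model:
  ## softplus(a2) = mean(counts) makes the d-gradient vanish
  p0 <- p
  p0$v2 <- numeric(K)
  p0$a2 <- log(expm1(mean(cts)))
  g0 <- nll_gradient(p0, model_spec(), mv, cts, cfg)
  expect_equal(g0$d, 0, tolerance = 1e-12)
  expect_equal(g0$a2, 0, tolerance = 1e-10)
})

test_that("fits are bit-reproducible given the seed and reject degenerate input", {
  mv <- tiny_movie(T = 60, H = 5, W = 5, seed = 36)
  cfg <- patch_config(4, 4, 2L, 1L)
  cts <- sample_spikes(rep(1, 60), seed = 37)
  fc <- fit_config(learning_rate = 0.05, batch_size = 10, max_epochs = 3,
                   patience = 2, seed = 99)
  f1 <- suppressWarnings(fit_qc(mv, cts, cfg, model_spec(), fc))
  f2 <- suppressWarnings(fit_qc(mv, cts, cfg, model_spec(), fc))
  expect_identical(f1$params, f2$params)
  expect_identical(lapply(f1$folds, `[[`, "trace_val"),
                   lapply(f2$folds, `[[`, "trace_val"))
  expect_error(suppressWarnings(
    fit_qc(mv, integer(60), cfg, model_spec(), fc)), "all-zero")
  expect_error(fit_config(n_folds = 3), "n_folds = 4")
})

test_that("a linear non-convolutional fit recovers the true filter direction", {
  mv <- generate_stimulus("white", 15000, 8, 8, seed = 21)
  cfg <- patch_config(8, 8, 1L, 1L)
  spec <- model_spec(FALSE, FALSE)
  v_true <- gabor_image(list(x0 = 3.5, y0 = 3.5, theta = 0.5, gamma = 1,
                             sigma = 2, lam = 5, phi = 0), c(8, 8))
  X <- qconv:::patch_design(mv, cfg)$X[[1]]
  rate <- softplus(2 * drop(X %*% v_true))
  cts <- sample_spikes(rate, seed = 1)
  fit <- fit_qc(mv, cts, cfg, spec,
                fit_config(learning_rate = 0.2, batch_size = 500,
                           max_epochs = 30, patience = 4, seed = 2))
  cosine <- abs(sum(fit$params$v1 * v_true)) / sqrt(sum(fit$params$v1^2))
  expect_gte(cosine, 0.9)
  ## quadratic kernel stays identically zero for linear specs
  expect_true(all(fit$params$J == 0))
})

test_that("a constant-rate neuron yields a near-constant fitted prediction", {
  mv <- tiny_movie(T = 400, H = 5, W = 5, seed = 38)
  cfg <- patch_config(4, 4, 2L, 1L)
  cts <- sample_spikes(rep(2, 400), seed = 39)
  fit <- fit_qc(mv, cts, cfg, model_spec(),
                fit_config(learning_rate = 0.02, batch_size = 50,
                           max_epochs = 10, patience = 3, seed = 3))
  r <- predict(fit, mv)
  expect_lt(var(r) / mean(r), 0.05)
  expect_equal(mean(r), mean(cts), tolerance = 0.1)
})

test_that("training NLL decreases from initialization during fitting", {
  mv <- generate_stimulus("white", 4000, 6, 6, seed = 44)
  cfg <- patch_config(6, 6, 1L, 1L)
  v_true <- gabor_image(list(x0 = 2.5, y0 = 2.5, theta = 1, gamma = 1,
                             sigma = 1.5, lam = 4, phi = 0), c(6, 6))
  X <- qconv:::patch_design(mv, cfg)$X[[1]]
  cts <- sample_spikes(softplus(2 * drop(X %*% v_true)), seed = 45)
  fit <- fit_qc(mv, cts, cfg, model_spec(FALSE, FALSE),
                fit_config(learning_rate = 0.2, batch_size = 500,
                           max_epochs = 15, patience = 15, seed = 4))
  for (f in fit$folds) {
    tr <- f$trace_train
    expect_lt(tr[length(tr)], tr[1])
  }
})

test_that("noise-corrected correlation is calibrated on simulated repeats", {
  mv <- generate_stimulus("pink", 1500, 8, 8, seed = 46)
  cfg <- patch_config(8, 8, 1L, 1L)
  K <- 1L
  gt <- qc_ground_truth(c(8, 8), cfg, exc_theta = 0.5, sup_weight = 1,
                        exc_weight = 3, a1 = -2, gain = 4, a2 = -2,
                        convolutional = FALSE)
  p <- gt$params
  spec_nc <- gt$spec
  rate <- predict_rate(mv, p, cfg, spec_nc)
  reps <- t(vapply(1:10, function(i) sample_spikes(rate, seed = 600 + i),
                   integer(1500)))
  ## prediction equal to the true rate -> corrected correlation near 1
  cc <- evaluate(p, spec_nc, mv, reps, cfg)
  expect_lt(abs(as.numeric(cc) - 1), 0.05)
  ## a neuron tuned to the orthogonal orientation gives an (approximately)
  ## independent prediction on Gaussian stimuli -> near 0
  gt_ind <- qc_ground_truth(c(8, 8), cfg, exc_theta = 0.5 + pi / 2,
                            sup_weight = 1, exc_weight = 3, a1 = -2,
                            gain = 4, a2 = -2, convolutional = FALSE)
  cc0 <- evaluate(gt_ind$params, spec_nc, mv, reps, cfg)
  expect_lt(as.numeric(cc0), 0.2)
  ## degenerate zero-variance prediction warns and returns 0
  p0 <- p; p0$v2 <- numeric(K)
  expect_warning(cc_flat <- evaluate(p0, spec_nc, mv, reps, cfg),
                 "zero-variance")
  expect_equal(as.numeric(cc_flat), 0)
  expect_error(evaluate(p, spec_nc, mv, reps[1, , drop = FALSE], cfg),
               "2 trials")
})
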