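test_that("lifetime sparseness matches hand computations and is scale invariant", {
  expect_equal(sparseness(rep(2, 50)), 0)
  expect_equal(sparseness(c(1, 0, 0, 1)), 2 / 3)
  expect_gt(sparseness(c(1, numeric(999))), 0.99)
  with_seed_test(61, {
    r <- rexp(200)
    expect_equal(sparseness(3.7 * r), sparseness(r))
  })
  expect_error(sparseness(numeric(10)), "all-zero")
  expect_error(sparseness(c(-1, 2)), "nonnegative")
})

test_that("removing zero-eigenvalue kernel components never changes rates", {
  mv <- tiny_movie(T = 10, H = 6, W = 6, seed = 62)
  cfg <- patch_config(6, 6, 1L, 1L)
  with_seed_test(63, {
    V <- qr.Q(qr(matrix(rnorm(36 * 2), 36)))
    J <- V %*% diag(c(2, -1.5)) %*% t(V)   # rank 2: all other eigenvalues 0
  })
  p <- qc_params(-1, numeric(36), J, 1, 0, 2)
  eg <- eigen(J, symmetric = TRUE)
  keep <- abs(eg$values) > 1e-10
  J2 <- eg$vectors[, keep] %*% diag(eg$values[keep]) %*% t(eg$vectors[, keep])
  p2 <- p; p2$J <- J2
  expect_equal(predict_rate(mv, p, cfg, model_spec(convolutional = FALSE)),
               predict_rate(mv, p2, cfg, model_spec(convolutional = FALSE)),
               tolerance = 1e-12)
})

test_that("suppression removal and orientation randomization shape sparseness", {
  cfg <- patch_config(10, 10, 1L, 1L)
  gt <- qc_ground_truth(c(10, 10), cfg, exc_theta = 0.6, sup_weight = 1.5,
                        exc_weight = 3, a1 = -2, gain = 4, a2 = -2,
                        convolutional = FALSE)
  mv <- generate_stimulus("pink", 2500, 10, 10, seed = 64)
  fe <- significant_features(gt$params$J, n_shuffles = 300, seed = 65)
  sp <- suppression_sparseness_ratio(gt$params, fe, mv, cfg, gt$spec)
  expect_lt(sp$ratio, 1)
  expect_lt(sp$S_no_supp, sp$S_full)
  ## zero-weight suppressive part -> ratio exactly 1 with a note
  gt0 <- qc_ground_truth(c(10, 10), cfg, sup_weight = 0, exc_weight = 3,
                         convolutional = FALSE)
  fe0 <- significant_features(gt0$params$J, n_shuffles = 300, seed = 66)
  sp0 <- suppression_sparseness_ratio(gt0$params, fe0, mv, cfg, gt0$spec)
  expect_equal(sp0$ratio, 1)
  expect_match(sp0$note, "no suppressive")
  ## randomizing suppressive orientations only touches suppressive thetas
  gb2 <- randomize_suppressive_orientations(gt$gabors, seed = 67)
  expect_equal(gb2$theta[gt$gabors$w > 0], gt$gabors$theta[gt$gabors$w > 0])
  expect_false(any(gb2$theta[gt$gabors$w < 0] == gt$gabors$theta[gt$gabors$w < 0]))
})

test_that("angular spread of axial orientations matches the circular moment", {
  expect_equal(angular_std(c(20, 20, 20)), 0, tolerance = 1e-6)
  ## orthogonal pair: doubled-angle resultant length 0, maximal spread
  expect_equal(angular_std(c(0, 90)), sqrt(2) / 2 * 180 / pi)
  ## brute-force circular moment for {0, 10, 20}: double the angles, take
  ## the resultant length, convert the angular deviation back
  doubled <- 2 * c(0, 10, 20) * pi / 180
  R <- sqrt(sum(cos(doubled))^2 + sum(sin(doubled))^2) / 3
  expect_equal(angular_std(c(0, 10, 20)), sqrt(2 * (1 - R)) / 2 * 180 / pi)
  ## axial invariance: adding 180 degrees changes nothing
  with_seed_test(68, {
    th <- runif(6, 0, 180)
    flip <- sample(c(0, 180), 6, replace = TRUE)
    expect_equal(angular_std(th), angular_std(th + flip), tolerance = 1e-12)
  })
})

test_that("neurons are classified by the gap in the spread distribution", {
  with_seed_test(69, {
    spread <- c(rnorm(40, 8, 1.5), rnorm(40, 30, 3))
    lab <- classify_neurons(spread)
    truth <- rep(c("uniform", "nonuniform"), each = 40)
    expect_gt(mean(lab == truth), 0.95)
    expect_gt(attr(lab, "threshold"), 12)
    expect_lt(attr(lab, "threshold"), 26)
  })
  expect_equal(as.character(classify_neurons(10, threshold = 15)), "uniform")
  expect_equal(as.character(classify_neurons(20, threshold = 15)), "nonuniform")
  expect_error(classify_neurons(10), "threshold")
})

test_that("excitatory-suppressive orientation differences histogram correctly", {
  ## constructed orthogonal arrangement: all mass in the last bin
  g <- gabor_set(x0 = c(3, 3.2, 7, 7.1), y0 = c(3, 3.1, 7, 7),
                 theta = c(0, 0.05, pi / 2, pi / 2 + 0.05),
                 gamma = 1, sigma = 2, lam = 4, phi = 0,
                 w = c(1, 1, -1, -1))
  h <- ex_supp_orientation_differences(g, scope = "nearest")
  expect_equal(sum(h$counts), 2)
  expect_equal(h$counts[8], 2)
  ## one pair at exactly 45 degrees: bin 4 ([33.75, 45])
  g45 <- gabor_set(x0 = c(3, 3), y0 = c(3, 3), theta = c(0, pi / 4),
                   gamma = 1, sigma = 2, lam = 4, phi = 0, w = c(1, -1))
  h45 <- ex_supp_orientation_differences(g45)
  expect_equal(which(h45$counts == 1), 4)
  ## scope = "all" uses every excitatory-suppressive combination
  hall <- ex_supp_orientation_differences(g, scope = "all")
  expect_equal(sum(hall$counts), 4)
  ## random orientations: the chi-square test rejects at ~ the nominal level
  with_seed_test(70, {
    rejects <- vapply(1:40, function(i) {
      gr <- gabor_set(x0 = runif(12, 0, 9), y0 = runif(12, 0, 9),
                      theta = runif(12, -pi, pi), gamma = 1, sigma = 2,
                      lam = 4, phi = 0, w = rep(c(1, -1), each = 6))
      ex_supp_orientation_differences(gr, scope = "all")$p_value < 0.05
    }, logical(1))
    expect_lt(mean(rejects), 0.25)
  })
})

test_that("the pooling mask separates into space and time by SVD", {
  grid <- c(3, 3); n_lags <- 4
  s <- c(0.2, 0.5, 0.2, 0.5, 1, 0.5, 0.2, 0.5, 0.2)      # all-positive map
  tk <- c(1, 0.6, 0.2, 0.05)
  v2 <- as.vector(outer(s, tk))                           # lag-major
  pd <- pooling_decomposition(v2, grid, n_lags)
  ## exact rank-1 recovery up to scale
  expect_equal(pd$spatial / max(pd$spatial), matrix(s / max(s), 3, 3, byrow = TRUE),
               tolerance = 1e-10)
  expect_equal(pd$temporal / max(pd$temporal), tk, tolerance = 1e-10)
  expect_equal(pd$pooling_type, "uniform")
  expect_equal(pd$temporal_type, "unimodal")
  expect_lt(pd$singular_values[2] / pd$singular_values[1], 1e-10)
  ## opposed-lobe spatial map -> biphasic
  s2 <- c(1, 1, -0.8, 1, 1, -0.8, 1, 1, -0.8)
  pd2 <- pooling_decomposition(as.vector(outer(s2, tk)), grid, n_lags)
  expect_equal(pd2$pooling_type, "biphasic")
  ## biphasic temporal kernel
  tk3 <- c(1, 0.2, -0.6, -0.9)
  pd3 <- pooling_decomposition(as.vector(outer(s, tk3)), grid, n_lags)
  expect_equal(pd3$temporal_type, "biphasic")
  ## the temporal peak is positive by convention
  expect_gt(pd3$temporal[which.max(abs(pd3$temporal))], 0)
  expect_error(pooling_decomposition(numeric(36), grid, n_lags), "zero")
  expect_error(pooling_decomposition(v2, grid, 3), "length")
})
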