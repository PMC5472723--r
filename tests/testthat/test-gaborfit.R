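test_that("Gabor images have unit norm, a carrier peak at the center, and axial orientation", {
  dims <- c(9, 9)
  g <- list(x0 = 4, y0 = 4, theta = 0.7, gamma = 1.2, sigma = 2, lam = 5,
            phi = 0)
  img <- gabor_image(g, dims, flatten = FALSE)
  expect_equal(sum(img^2), 1)
  ## phi = 0: the carrier factor at the center pixel is cos(0) = 1, so the
  ## center is the envelope peak ("bar" Gabor)
  expect_equal(which.max(img), which(matrix(seq_len(81), 9, 9) == 9 * 4 + 5))
  ## rotating theta by pi flips the carrier direction only: |image| unchanged
  g2 <- g; g2$theta <- g$theta + pi
  expect_equal(abs(gabor_image(g2, dims, flatten = FALSE)), abs(img),
               tolerance = 1e-12)
  ## quadrature orthogonality: same parameters, phases 0 and pi/2
  gq <- g; gq$phi <- pi / 2
  expect_lt(abs(sum(img * gabor_image(gq, dims, flatten = FALSE))), 0.02)
})

test_that("gabor_sum_J equals the brute-force accumulation of outer products", {
  dims <- c(6, 6)
  ## single unit-weight Gabor: rank 1 with eigenvalue 1
  g1 <- gabor_set(2.5, 2.5, 0.4, 1, 1.5, 4, 0, w = 1)
  J1 <- gabor_sum_J(g1, dims)
  ev <- eigen(J1, symmetric = TRUE)
  expect_equal(ev$values[1], 1, tolerance = 1e-12)
  expect_lt(max(abs(ev$values[-1])), 1e-12)

  ## two orthogonal Gabors with weights (1, -1): eigenvalues {+1, -1}
  gq <- gabor_set(x0 = c(2.5, 2.5), y0 = c(2.5, 2.5), theta = 0.4, gamma = 1,
                  sigma = 1.5, lam = 4, phi = c(0, pi / 2), w = c(1, -1))
  ip <- sum(gabor_image(gq[1, ], dims) * gabor_image(gq[2, ], dims))
  Jq <- gabor_sum_J(gq, dims)
  evq <- sort(eigen(Jq, symmetric = TRUE, only.values = TRUE)$values)
  expect_equal(evq[1], -1, tolerance = abs(ip) + 1e-10)
  expect_equal(evq[36], 1, tolerance = abs(ip) + 1e-10)

  ## random 3-Gabor sum vs triple loop
  with_seed_test(21, {
    g3 <- gabor_set(x0 = runif(3, 1, 4), y0 = runif(3, 1, 4),
                    theta = runif(3, -pi, pi), gamma = runif(3, 0.5, 2),
                    sigma = runif(3, 1, 2.5), lam = runif(3, 3, 6),
                    phi = runif(3, -pi, pi), w = rnorm(3))
    J3 <- gabor_sum_J(g3, dims)
    Jb <- matrix(0, 36, 36)
    for (i in 1:3) {
      gi <- gabor_image(g3[i, ], dims)
      for (a in 1:36) for (b in 1:36)
        Jb[a, b] <- Jb[a, b] + g3$w[i] * gi[a] * gi[b]
    }
    expect_lt(max(abs(J3 - Jb)), 1e-12)
  })
})

test_that("differential evolution is greedy, reproducible, and respects bounds", {
  sphere <- function(x) sum((x - c(0.3, -0.2, 0.5))^2)
  with_seed_test(22, {
    r1 <- qconv:::de_optimize(sphere, lower = rep(-1, 3), upper = rep(1, 3),
                              np = 30, max_iter = 60)
  })
  with_seed_test(22, {
    r2 <- qconv:::de_optimize(sphere, lower = rep(-1, 3), upper = rep(1, 3),
                              np = 30, max_iter = 60)
  })
  expect_identical(r1, r2)
  ## population best is monotone non-increasing (greedy replacement)
  expect_true(all(diff(r1$best_trace) <= 0))
  expect_lt(r1$value, 1e-3)
  expect_true(all(r1$par >= -1 & r1$par <= 1))
})

test_that("DE refits a single-Gabor kernel at small scale", {
  dims <- c(8, 8)
  g <- gabor_set(3.5, 3.5, 0.6, 1, 1.8, 4.5, 0.3, w = 1)
  J <- gabor_sum_J(g, dims)
  f <- fit_gabors(J, dims, 1, de = de_config(restarts = 5, seed = 23,
                                             max_iter = 300))
  expect_lt(f$nmse, 0.05)
  expect_gt(f$correlation, 0.95)
  expect_gt(f$gabors$w[1], 0)
  ## reproducibility
  f2 <- fit_gabors(J, dims, 1, de = de_config(restarts = 5, seed = 23,
                                              max_iter = 300))
  expect_identical(f$gabors, f2$gabors)
  ## suppressive part: same kernel negated gives negative weights
  fs <- fit_gabors(-J, dims, 1, de = de_config(restarts = 2, seed = 24,
                                               max_iter = 200))
  expect_lt(fs$gabors$w[1], 0)
  expect_error(fit_gabors(J, dims, 0), "n_gabors")
  expect_error(fit_gabors(matrix(0, 64, 64), dims, 1), "zero")
})

test_that("quadrature-constrained fits share parameters and fix phases at 0 and pi/2", {
  dims <- c(8, 8)
  gq <- gabor_set(x0 = c(3.5, 3.5), y0 = c(3.5, 3.5), theta = 0.6, gamma = 1,
                  sigma = 1.8, lam = 4.5, phi = c(0.9, 0.9 + pi / 2), w = 1)
  Jq <- gabor_sum_J(gq, dims)
  f <- fit_gabors(Jq, dims, 1, quadrature = TRUE,
                  de = de_config(restarts = 2, seed = 25, max_iter = 300))
  expect_equal(nrow(f$gabors), 2)
  expect_equal(f$gabors$phi, c(0, pi / 2))
  for (col in c("x0", "y0", "theta", "gamma", "sigma", "lam"))
    expect_equal(f$gabors[[col]][1], f$gabors[[col]][2])
  ## the energy-model kernel of a quadrature pair is base-phase invariant,
  ## so the constrained fit reaches it despite the fixed phases
  expect_lt(f$nmse, 0.05)
})

test_that("pairing matches co-located like-oriented Gabors and only those", {
  ## two co-located same-orientation Gabors -> one pair
  g2 <- gabor_set(x0 = c(4, 4.2), y0 = c(4, 4), theta = c(0.5, 0.55),
                  gamma = 1, sigma = 2, lam = 5, phi = c(0, 1), w = 1)
  pr <- pair_gabors(g2)
  expect_equal(nrow(pr), 1)
  ## orthogonal and far apart -> no pair
  g0 <- gabor_set(x0 = c(1, 9), y0 = c(1, 9), theta = c(0, pi / 2), gamma = 1,
                  sigma = 2, lam = 4, phi = 0, w = 1)
  expect_equal(nrow(pair_gabors(g0)), 0)
  ## two co-located quadrature pairs at different sites -> exactly 2 pairs
  g4 <- gabor_set(x0 = c(2, 2, 8, 8), y0 = c(2, 2, 8, 8),
                  theta = c(0.3, 0.3, 1.2, 1.2), gamma = 1, sigma = 2,
                  lam = 4, phi = c(0, pi / 2, 0.5, 0.5 + pi / 2), w = 1)
  pr4 <- pair_gabors(g4)
  expect_equal(nrow(pr4), 2)
  expect_setequal(paste(pr4$i, pr4$j), c("1 2", "3 4"))
  expect_equal(pr4$delta_phase, c(90, 90), tolerance = 1e-9)
})

test_that("phase differences are displacement-corrected along the carrier", {
  ## identical position, phases 0 and pi/2 -> 90 degrees
  gq <- gabor_set(x0 = 5, y0 = 5, theta = c(0.3, 0.3), gamma = 1, sigma = 2,
                  lam = 5, phi = c(0, pi / 2), w = 1)
  expect_equal(pair_gabors(gq)$delta_phase, 90)
  ## same phase, displaced one full wavelength along the carrier -> 0
  th <- 0.3; lam <- 5
  g2 <- gabor_set(x0 = c(2, 2 + lam * cos(th)), y0 = c(2, 2 + lam * sin(th)),
                  theta = th, gamma = 1, sigma = 2, lam = lam, phi = 0.4, w = 1)
  expect_equal(pair_gabors(g2, max_dist = 1.5)$delta_phase, 0,
               tolerance = 1e-9)
  ## carrier directions differing by pi describe the same axial Gabor:
  ## phases compare in a common frame
  g3 <- gabor_set(x0 = 5, y0 = 5, theta = c(0.3, 0.3 - pi), gamma = 1,
                  sigma = 2, lam = 5, phi = c(0.8, -0.8 - pi / 2), w = 1)
  expect_equal(pair_gabors(g3)$delta_phase, 90, tolerance = 1e-9)
})
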