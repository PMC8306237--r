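test_that("ATGP extracts maximally distinct pixels in order", {
  X <- rbind(c(3, 0), c(0, 1), c(1, 1))
  a1 <- atgp(X, 1)
  expect_equal(a1$indices, 1L)          # max norm first
  expect_equal(a1$signatures[1, ], c(3, 0))

  a2 <- atgp(X, 2)
  # residuals after projecting out (3,0): both remaining have norm 1;
  # tie resolves to the lower index
  expect_equal(a2$indices, c(1L, 2L))
  expect_true(all(diff(a2$residual_norms) < 0))

  same <- matrix(rep(c(2, 1), 5), 5, 2, byrow = TRUE)
  expect_warning(ar <- atgp(same, 2), "rank")
  expect_length(ar$indices, 1)
})

test_that("ATGP residual norms decrease strictly on random data", {
  set.seed(21)
  for (rep in 1:5) {
    X <- matrix(rnorm(60 * 6), 60, 6)
    a <- atgp(X, 5)
    expect_true(all(diff(a$residual_norms) < 0))
  }
})

test_that("spectral angle behaves like an angle", {
  expect_equal(sam_angle(c(2, 5, 1), c(2, 5, 1)), 0)
  expect_equal(sam_angle(c(1, 0), c(0, 1)), pi / 2)
  expect_equal(sam_angle(c(1, 1), c(1, 0)), pi / 4)
  expect_error(sam_angle(c(0, 0), c(1, 0)), "zero")
})

test_that("signature pooling averages exactly the angle-matched pixels", {
  # seed pixel plus one pixel at angle ~0.05 and one at ~0.5 rad
  seed <- c(1, 0)
  rot <- function(a) c(cos(a), sin(a))
  X <- rbind(seed, rot(0.05), rot(0.5))
  got <- pool_training_signature(X, 1, 0.1)
  expect_equal(got, colMeans(X[1:2, ]), tolerance = 1e-12)
  # threshold 0: the seed itself
  expect_equal(pool_training_signature(X, 1, 0), seed,
               ignore_attr = TRUE)
  # threshold pi: the global mean
  expect_equal(pool_training_signature(X, 1, pi), colMeans(X),
               tolerance = 1e-12)
})

test_that("the CEM filter satisfies its unity constraint and hand examples", {
  # pixels (1,0) and (0,1) equally frequent, d = (1,0): R = I/2,
  # w = (1, 0), so the off-target pixel scores 0
  X <- rbind(c(1, 0), c(0, 1), c(1, 0), c(0, 1))
  f <- cem_filter(X, c(1, 0))
  expect_equal(f$weights, c(1, 0), tolerance = 1e-12)
  expect_equal(f$scores, c(1, 0, 1, 0), tolerance = 1e-12)

  # output at x = d is exactly 1 for arbitrary data
  set.seed(31)
  X2 <- matrix(runif(40 * 3, 0.1, 1), 40, 3)
  d2 <- X2[17, ]
  f2 <- cem_filter(X2, d2)
  expect_equal(sum(f2$weights * d2), 1, tolerance = 1e-12)
  expect_equal(f2$scores[17], 1, tolerance = 1e-10)
})

test_that("CEM weights match an independent constrained-QP oracle", {
  set.seed(41)
  for (rep in 1:100) {
    L <- sample(2:4, 1)
    N <- sample(L:50, 1)
    X <- matrix(rnorm(N * L), N, L)
    d <- rnorm(L)
    while (sum(d^2) < 1e-4) d <- rnorm(L)
    ridge <- 1e-8
    w_pkg <- cem_filter(X, d, ridge)$weights
    w_orc <- cem_qp_oracle(X, d, ridge)
    expect_lt(max(abs(w_pkg - w_orc)), 1e-8)
  }
})

test_that("CEM minimizes output energy among unit-response filters", {
  set.seed(51)
  X <- matrix(rnorm(80 * 4), 80, 4)
  d <- runif(4, 0.5, 1)
  f <- cem_filter(X, d, ridge = 1e-10)
  base <- mean(f$scores^2)
  Z <- qr.Q(qr(cbind(d)), complete = TRUE)[, -1, drop = FALSE]
  for (i in 1:1000) {
    w_alt <- f$weights + Z %*% rnorm(3, sd = 0.1)
    expect_equal(sum(w_alt * d), 1, tolerance = 1e-10)  # still feasible
    expect_gte(mean((X %*% w_alt)^2), base - 1e-12)
  }
})

test_that("Otsu thresholding matches exhaustive search and is scale-equivariant", {
  v <- c(rep(0, 50), rep(10, 50))
  ot <- otsu_threshold(v)
  expect_gt(ot$threshold, 0)
  expect_lt(ot$threshold, 10)
  expect_equal(sum(ot$binary), 50)

  set.seed(61)
  for (rep in 1:100) {
    vals <- switch(1 + rep %% 3,
                   rnorm(200),
                   c(rnorm(150), rnorm(50, mean = 4)),
                   runif(300)^2)
    expect_equal(otsu_threshold(vals)$threshold, otsu_brute(vals))
  }

  vals <- c(rnorm(100), rnorm(40, 5))
  expect_identical(otsu_threshold(vals)$binary,
                   otsu_threshold(2 * vals)$binary)
  expect_error(otsu_threshold(rep(3, 10)), "constant")
})

test_that("I-CEM converges immediately on exactly separable spectra and is seeded", {
  # tumour spectra identical and distinct from background: the first
  # mask is exact, so no label can change and iteration 2 terminates
  ph <- ivim_phantom(noise_sigma = 0, seed = 3)
  mask <- ph$labels >= 2L
  r <- icem(ph$cube, mask, seed = 3)
  expect_identical(r$mask, ph$truth_mask)
  expect_equal(nrow(r$log), 2L)
  expect_equal(r$log$diff_rate[2], 0)

  ph2 <- std_mass_phantom(seed = 5)
  pp <- preprocess_cube(ph2$cube)
  r1 <- icem(pp$cube, pp$breast_mask, seed = 11)
  r2 <- icem(pp$cube, pp$breast_mask, seed = 11)
  expect_identical(r1$mask, r2$mask)
  expect_identical(r1$log, r2$log)

  # difference rates share the breast-mask denominator and end converged
  final <- utils::tail(r1$log$diff_rate, 1)
  expect_lte(final, 0.01)
})

test_that("I-CEM detects the mass lesion through the full preprocessing chain", {
  ph <- std_mass_phantom(seed = 5)
  pp <- preprocess_cube(ph$cube)
  r <- icem(pp$cube, pp$breast_mask, seed = 5)
  expect_gte(dice(r$mask, ph$truth_mask), 0.90)
})

test_that("KCEM honours its unity constraint and reduces to CEM for a linear kernel", {
  set.seed(71)
  X <- matrix(runif(10 * 3, 0.2, 1), 10, 3)
  arr <- array(0, c(2, 5, 3))
  for (j in 1:3) arr[, , j] <- matrix(X[, j], 2, 5)
  cube <- bvalue_cube(arr, c(0, 100, 200))
  mask <- matrix(TRUE, 2, 5)
  d <- colMeans(X[1:3, ])

  cem_y <- cem_filter(X, d)$scores
  lin <- kcem(cube, mask, d = d, bep = FALSE, kernel = "linear",
              sample_size = 10, ridge = 1e-12, seed = 1)
  expect_lt(max(abs(lin$map[mask] - cem_y)), 1e-6)

  # output at r = d is 1 for the RBF kernel
  arr2 <- arr
  arr2[1, 1, ] <- d
  cube2 <- bvalue_cube(arr2, c(0, 100, 200))
  rbf <- kcem(cube2, mask, d = d, bep = FALSE, sigma = 0.5,
              sample_size = 10, seed = 1)
  expect_equal(rbf$map[1, 1], 1, tolerance = 1e-9)

  expect_error(kcem(cube, mask, d = d, bep = FALSE, sigma = -1, seed = 1),
               "positive")
})

test_that("KCEM is seeded and detects the mass lesion", {
  ph <- std_mass_phantom(seed = 5)
  pp <- preprocess_cube(ph$cube)
  r1 <- kcem(pp$cube, pp$breast_mask, seed = 5)
  r2 <- kcem(pp$cube, pp$breast_mask, seed = 5)
  expect_identical(r1$map, r2$map)
  expect_gte(dice(r1$mask, ph$truth_mask), 0.85)
})
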