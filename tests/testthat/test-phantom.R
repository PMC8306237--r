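test_that("label maps place lesions of the requested geometry", {
  labels <- make_label_map(c(64, 64),
                           lesion = list(type = "ellipse",
                                         center = c(32.5, 32.5),
                                         axes = c(5, 7), class = "mass"))
  lesion <- labels == 3L
  expect_equal(sum(lesion), ellipse_count(c(64, 64), c(32.5, 32.5), c(5, 7)))
  expect_true(all(labels[lesion] == 3L))
  expect_true(all((labels >= 2L)[lesion]))  # lesion inside breast
  cc <- EBImage::bwlabel(lesion)
  expect_equal(max(cc), 1)  # one connected component

  blobs <- make_label_map(c(64, 64),
                          lesion = list(type = "blobs", n = 4, radius = 3,
                                        class = "nonmass", seed = 2))
  expect_equal(max(EBImage::bwlabel(blobs == 3L)), 4)

  expect_error(make_label_map(lesion = list(type = "ellipse",
                                            axes = c(0, 0),
                                            class = "mass")),
               "positive")
  expect_error(make_label_map(lesion = list(type = "ellipse",
                                            center = c(5, 5),
                                            axes = c(5, 7),
                                            class = "mass")),
               "inside the breast")
})

test_that("noise-free cubes follow the bi-exponential model exactly", {
  labels <- make_label_map()
  bv <- default_bvalues()
  sim <- simulate_cube(labels, bvalues = bv, noise_sigma = 0)
  p <- ivim_presets()

  # b = 0 band equals each class S0 exactly
  b0 <- sim$cube$data[, , 1]
  for (li in seq_along(attr(labels, "levels"))) {
    cls <- attr(labels, "levels")[li]
    expect_equal(unique(b0[labels == li]), p$S0[p$class == cls])
  }

  # pointwise model check at every band for the mass class
  r <- p[p$class == "mass", ]
  for (j in seq_along(bv)) {
    vals <- unique(sim$cube$data[, , j][labels == 3L])
    expect_equal(vals, ivim_signal(bv[j], r$S0, r$D, r$Dstar, r$PF),
                 tolerance = 1e-12)
  }
  # literature mass parameters at b = 1000, by direct substitution
  expect_equal(unique(sim$cube$data[, , which(bv == 1000)][labels == 3L]),
               1.0 * (0.77 * exp(-0.84) + 0.23 * exp(-6.10)),
               tolerance = 1e-12)

  # signal non-increasing in b
  flat <- matrix(sim$cube$data, 64 * 64, length(bv))
  expect_true(all(apply(flat, 1, function(s) all(diff(s) <= 1e-12))))

  # PF = 0 collapses to a mono-exponential
  p0 <- p
  p0$PF[p0$class == "mass"] <- 0
  sim0 <- simulate_cube(labels, params = p0, bvalues = bv)
  s <- sim0$cube$data[32, 32, ]
  expect_equal(s, p0$S0[p0$class == "mass"] *
                 exp(-bv * p0$D[p0$class == "mass"]),
               tolerance = 1e-12)

  expect_error(simulate_cube(labels, params = p[p$class != "mass", ]),
               "no parameters")
})

test_that("Rician noise is seeded, unbiased at high SNR, and floored at zero signal", {
  labels <- make_label_map()
  s1 <- simulate_cube(labels, noise_sigma = 0.02, seed = 9)
  s2 <- simulate_cube(labels, noise_sigma = 0.02, seed = 9)
  expect_identical(s1$cube$data, s2$cube$data)
  s3 <- simulate_cube(labels, noise_sigma = 0.02, seed = 10)
  expect_false(identical(s1$cube$data, s3$cube$data))

  # class-mean b=0 signal approaches S0 as sigma -> 0
  p <- ivim_presets()
  S0m <- p$S0[p$class == "mass"]
  for (sg in c(0.05, 0.01)) {
    sim <- simulate_cube(labels, noise_sigma = sg, seed = 4)
    m <- mean(sim$cube$data[, , 1][labels == 3L])
    expect_lt(abs(m - S0m), 3 * sg / sqrt(sum(labels == 3L)) + sg^2 / S0m)
  }
  # Rician floor: background (S0 = 0) has Rayleigh mean sigma * sqrt(pi/2)
  sim <- simulate_cube(labels, noise_sigma = 0.05, seed = 4)
  bgm <- mean(sim$cube$data[, , 1][labels == 1L])
  expect_equal(bgm, 0.05 * sqrt(pi / 2), tolerance = 0.05)
})

test_that("bias fields are smooth, mean-one, amplitude-bounded and band-shared", {
  ph <- ivim_phantom(noise_sigma = 0)
  out0 <- apply_bias_field(ph$cube, 0)
  expect_identical(out0$cube$data, ph$cube$data)

  out <- apply_bias_field(ph$cube, 0.3, seed = 3)
  expect_equal(mean(out$field), 1, tolerance = 1e-9)
  expect_lte(max(abs(out$field - 1)), 0.3 + 1e-12)
  # same multiplicative field on every band
  ratio1 <- out$cube$data[, , 2] / pmax(ph$cube$data[, , 2], 1e-12)
  ratio2 <- out$cube$data[, , 7] / pmax(ph$cube$data[, , 7], 1e-12)
  keep <- ph$cube$data[, , 2] > 0 & ph$cube$data[, , 7] > 0
  expect_equal(ratio1[keep], ratio2[keep], tolerance = 1e-12)

  expect_error(apply_bias_field(ph$cube, 1), "\\[0, 1\\)")
})

test_that("band shifts translate, clip, respect the reference, and invert", {
  ph <- ivim_phantom(noise_sigma = 0)
  B <- n_bands(ph$cube)
  zero <- matrix(0L, B, 2)
  expect_identical(apply_shifts(ph$cube, zero)$cube$data, ph$cube$data)

  sh <- zero; sh[6, ] <- c(2L, 0L)
  out <- apply_shifts(ph$cube, sh)
  expect_equal(out$cube$data[10:60, , 6], ph$cube$data[8:58, , 6])

  # shift then unshift restores the interior exactly
  inv <- zero; inv[6, ] <- c(-2L, 0L)
  back <- apply_shifts(out$cube, inv)
  expect_equal(back$cube$data[5:60, 5:60, 6], ph$cube$data[5:60, 5:60, 6])

  big <- zero; big[4, ] <- c(9L, 0L)
  expect_warning(res <- apply_shifts(ph$cube, big), "clipped")
  expect_equal(res$shifts[4, 1], 5L)

  refshift <- zero; refshift[1, ] <- c(1L, 1L)
  expect_warning(res2 <- apply_shifts(ph$cube, refshift), "reference")
  expect_equal(res2$shifts[1, ], c(0L, 0L))
})

test_that("phantom generation is bit-identical under a fixed seed", {
  a <- std_mass_phantom(seed = 5)
  b <- std_mass_phantom(seed = 5)
  expect_identical(a$cube$data, b$cube$data)
  expect_identical(a$shifts, b$shifts)
  expect_identical(a$field, b$field)
})
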