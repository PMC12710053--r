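test_that("mask centroid is the nearest mask pixel to the coordinate mean", {
  sq <- mask_from_xy(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)), 4, 4)
  expect_equal(mask_centroid(sq), c(x = 0L, y = 0L))  # 4-way tie -> smallest (row, col)

  one <- mask_from_xy(rbind(c(3, 7)), 10, 10)
  expect_equal(mask_centroid(one), c(x = 3L, y = 7L))

  expect_error(mask_centroid(matrix(FALSE, 3, 3)), "empty")

  # C-shaped mask: mean falls in the cavity; brute-force nearest-pixel oracle
  cmask <- matrix(FALSE, 9, 9)
  cmask[2:8, 2:3] <- TRUE; cmask[2:3, 2:8] <- TRUE; cmask[7:8, 2:8] <- TRUE
  got <- mask_centroid(cmask)
  expect_true(cmask[got["y"] + 1, got["x"] + 1])
  idx <- which(cmask, arr.ind = TRUE)
  my <- mean(idx[, 1]) - 1; mx <- mean(idx[, 2]) - 1
  d2 <- (idx[, 1] - 1 - my)^2 + (idx[, 2] - 1 - mx)^2
  expect_equal((got["x"] - mx)^2 + (got["y"] - my)^2, min(d2),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("patch features equal per-pixel (R-B, G-B) and clip at borders", {
  img <- flat_image(c(100, 50, 20))
  f <- sample_patch_features(img, c(5, 5), 3)
  expect_equal(nrow(f), 9)
  expect_true(all(f[, "rb"] == 80 & f[, "gb"] == 30))

  expect_equal(nrow(sample_patch_features(img, c(0, 0), 3)), 4)

  set.seed(5)
  px <- array(sample(0:255, 10 * 10 * 3, replace = TRUE), c(10, 10, 3))
  rimg <- seed_image(px)
  f <- sample_patch_features(rimg, c(4, 6), 3)
  # independent per-pixel oracle over the same window
  oracle <- NULL
  for (x in 3:5) for (y in 5:7)
    oracle <- rbind(oracle, c(px[y + 1, x + 1, 1] - px[y + 1, x + 1, 3],
                              px[y + 1, x + 1, 2] - px[y + 1, x + 1, 3]))
  expect_equal(sort(f[, 1] * 1000 + f[, 2]), sort(oracle[, 1] * 1000 + oracle[, 2]))
})

test_that("the Gaussian fit matches a direct covariance oracle and ridges degenerate data", {
  same <- matrix(rep(c(8, 3), each = 9), 9, 2)
  m <- fit_gaussian(same)
  expect_equal(unname(m$m), c(8, 3))
  expect_gt(m$lambda, 0)
  expect_equal(as.numeric(coat_probability(m, c(8, 3))), 1)

  quad <- rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2))
  m <- fit_gaussian(quad)
  expect_equal(unname(m$m), c(1, 1))
  # direct (n-1) covariance formula oracle
  dev <- sweep(quad, 2, c(1, 1))
  expect_equal(unname(m$C), t(dev) %*% dev / 3, ignore_attr = TRUE)

  expect_error(fit_gaussian(matrix(c(1, 2), 1)), "2 samples")

  set.seed(19)
  m_true <- c(85, 55); C_true <- matrix(c(36, 8, 8, 25), 2)
  fit <- fit_gaussian(sample_coat_features(10000, m_true, C_true))
  expect_lt(max(abs(fit$m - m_true)), 1.0)
})

test_that("coat probability follows the Gaussian kernel exactly", {
  m <- fit_gaussian(rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2)))
  expect_equal(as.numeric(coat_probability(m, m$m)), 1)

  # identity covariance closed form: exp(-0.5) at unit offset
  id <- structure(list(m = c(0, 0), C = diag(2), lambda = 0, C_inv = diag(2)),
                  class = "gaussian_coat_model")
  expect_equal(as.numeric(coat_probability(id, c(1, 0))), exp(-0.5))

  set.seed(23)
  for (i in 1:20) {
    f <- sample_coat_features(6, runif(2, -50, 50), matrix(c(9, 2, 2, 5), 2))
    mod <- fit_gaussian(f)
    x <- runif(2, -60, 60)
    d <- x - mod$m
    oracle <- exp(-0.5 * as.numeric(t(d) %*% solve(mod$C + diag(mod$lambda, 2)) %*% d))
    expect_equal(as.numeric(coat_probability(mod, x)), oracle, tolerance = 1e-12)
  }
})

test_that("classification partitions the mask with a strict threshold", {
  img <- flat_image(c(100, 50, 20), 6, 6)
  mask <- matrix(TRUE, 6, 6)
  mod <- fit_gaussian(rbind(c(80, 30), c(81, 31), c(79, 29)))
  cm <- classify_mask(img, mask, mod, 0.006)
  expect_true(all(cm$coat))          # p(m) = 1 > T everywhere
  expect_false(any(cm$radicle))
  expect_false(any(cm$coat & cm$radicle))

  # p exactly equal to T goes to the radicle (strictly greater wins coat)
  idm <- structure(list(m = c(80, 30), C = diag(2), lambda = 0, C_inv = diag(2)),
                   class = "gaussian_coat_model")
  T_here <- as.numeric(coat_probability(idm, c(80, 30 + 2)))
  shifted <- flat_image(c(100, 52, 20), 4, 4)   # feature (80, 32), p = exp(-2)
  cm <- classify_mask(shifted, matrix(TRUE, 4, 4), idm, T_here)
  expect_true(all(cm$radicle))
})

test_that("classification is invariant to uniform brightness shifts", {
  set.seed(31)
  px <- array(sample(30:200, 8 * 8 * 3, replace = TRUE), c(8, 8, 3))
  img1 <- seed_image(px)
  img2 <- seed_image(px + 20L)     # stays within [0, 255]
  mask <- matrix(TRUE, 8, 8)
  mod <- fit_gaussian(sample_patch_features(img1, c(4, 4), 3))
  c1 <- classify_mask(img1, mask, mod, 0.006)
  c2 <- classify_mask(img2, mask, mod, 0.006)
  expect_identical(c1$coat, c2$coat)
})

test_that("coat grows monotonically as the threshold decreases", {
  set.seed(37)
  scene <- generate_scene(scene_params(rng_seed = 37))
  s <- scene$seeds[[1]]
  mask <- s$coat | s$radicle
  mod <- fit_gaussian(sample_coat_features(500, c(85, 55), matrix(c(36, 8, 8, 25), 2)))
  prev <- NULL
  for (T in c(0.001, 0.006, 0.05, 0.3)) {
    cm <- classify_mask(scene$image, mask, mod, T)
    expect_identical(cm$coat | cm$radicle, mask)   # partition at every T
    if (!is.null(prev)) expect_true(all(!cm$coat | prev))  # coat shrinks as T grows
    prev <- cm$coat
  }
})

test_that("with the true model the coat false-negative rate matches the chi-square tail", {
  set.seed(43)
  m_true <- c(85, 55); C_true <- matrix(c(36, 8, 8, 25), 2)
  truth <- structure(list(m = m_true, C = C_true, lambda = 0,
                          C_inv = solve(C_true)),
                     class = "gaussian_coat_model")
  f <- sample_coat_features(10000, m_true, C_true)
  frac <- mean(coat_probability(truth, f) <= 0.006)
  # P(p <= T) = T for a 2-D Gaussian (chi-square_2 tail identity)
  expect_lt(abs(frac - 0.006), 0.003)
})
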