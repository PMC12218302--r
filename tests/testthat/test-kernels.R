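test_that("Matern closed forms match their analytic values", {
  # nu = 3/2, theta = 1, |x - x'| = 1: (1 + sqrt(3)) exp(-sqrt(3))
  expect_equal(k_matern(0, 1, theta = 1, nu = 1.5),
               (1 + sqrt(3)) * exp(-sqrt(3)), tolerance = 1e-12)
  # nu = 5/2, theta = 2, |x - x'| = 2: scaled distance 1
  s <- sqrt(5)
  expect_equal(k_matern(0, 2, theta = 2, nu = 2.5),
               (1 + s + s^2 / 3) * exp(-s), tolerance = 1e-12)
  expect_equal(k_matern(c(1, 2), c(1, 2), theta = c(1, 1)), 1)
  expect_error(k_matern(1, c(1, 2), theta = 1), "dimension")
})

test_that("Matern closed forms agree with the Bessel-function form", {
  d <- seq(0.01, 4, length.out = 60)
  for (nu in c(1.5, 2.5)) {
    closed <- vapply(d, function(di) k_matern(0, di, theta = 1, nu = nu),
                     numeric(1))
    expect_equal(closed, matern_bessel(d, nu), tolerance = 1e-8)
  }
})

test_that("categorical overlap kernel counts matches", {
  expect_equal(k_categorical(0L, 0L, sigma_cat = 1), 1)
  expect_equal(k_categorical(0L, 1L, sigma_cat = 1), 0)
  expect_equal(k_categorical(c(0L, 1L), c(0L, 2L), sigma_cat = 0.8), 0.4)
  expect_error(k_categorical(integer(0), integer(0), c = 0), "undefined")
  # self-similarity is exactly sigma; mismatches only decrease it
  h <- c(1L, 2L, 3L)
  expect_identical(k_categorical(h, h, sigma_cat = 0.7), 0.7)
  vals <- vapply(0:3, function(m) {
    hp <- h
    if (m > 0) hp[seq_len(m)] <- hp[seq_len(m)] + 10L
    k_categorical(h, hp, sigma_cat = 0.7)
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("mixed kernel blends product and sum by alpha", {
  z <- list(x = c(0.2, 0.4), h = 1L)
  zp <- list(x = c(0.6, 0.1), h = 1L)
  p1 <- kernel_params(theta = c(1, 1), nu = 2.5, sigma_cat = 1, alpha = 1)
  p0 <- kernel_params(theta = c(1, 1), nu = 2.5, sigma_cat = 1, alpha = 0)
  kc <- k_categorical(z$h, zp$h, 1)
  km <- k_matern(z$x, zp$x, c(1, 1), 2.5)
  expect_equal(k_mixed(z, zp, p1), kc * km)
  expect_equal(k_mixed(z, zp, p0), kc + km)
  ph <- kernel_params(theta = c(1, 1), nu = 2.5, sigma_cat = 1, alpha = 0.5)
  expect_equal(k_mixed(z, z, ph), 0.5 * 1 + 0.5 * 2) # k_cat = k_cont = 1
  # continuous in alpha, bracketed by the pure product and pure sum
  alphas <- seq(0, 1, by = 0.1)
  vals <- vapply(alphas, function(a) {
    k_mixed(z, zp, kernel_params(theta = c(1, 1), nu = 2.5, sigma_cat = 1,
                                 alpha = a))
  }, numeric(1))
  expect_true(all(vals >= min(kc * km, kc + km) - 1e-12))
  expect_true(all(vals <= max(kc * km, kc + km) + 1e-12))
  expect_true(all(abs(diff(vals, differences = 2)) < 1e-12)) # linear in alpha
})

test_that("kernels are symmetric in their arguments", {
  set.seed(3)
  p <- kernel_params(theta = c(0.5, 2), nu = 1.5, sigma_cat = 0.6,
                     alpha = 0.3)
  for (i in 1:20) {
    z <- list(x = runif(2), h = sample(0:2, 2, replace = TRUE))
    zp <- list(x = runif(2), h = sample(0:2, 2, replace = TRUE))
    expect_equal(k_mixed(z, zp, p), k_mixed(zp, z, p), tolerance = 1e-12)
    expect_equal(k_ohe(z, zp, n_cats = c(3, 3)),
                 k_ohe(zp, z, n_cats = c(3, 3)), tolerance = 1e-12)
  }
})

test_that("Gram matrices are PSD after jitter and noise inflates the diagonal", {
  sp <- small_mixed_space(4)
  pts <- sample_feasible(sp, 50, seed = 5)
  enc <- encode_points(sp, pts)
  p <- kernel_params(theta = c(0.3, 0.7), nu = 2.5, sigma_cat = 1,
                     alpha = 0.5, noise_variance = 0.25)
  K <- gram_matrix(enc, p)
  expect_equal(K, t(K))
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
  Kn <- gram_matrix(enc, p, include_noise = TRUE)
  expect_equal(diag(Kn) - diag(K), rep(0.25, 50))
  expect_equal(Kn[lower.tri(Kn)], K[lower.tri(K)])
  # single continuous-only point
  sp1 <- toy1d_space()
  enc1 <- encode_points(sp1, tibble::tibble(x = 0.3))
  K1 <- gram_matrix(enc1, kernel_params(theta = 1), jitter = 0)
  expect_equal(unname(K1), matrix(1, 1, 1))
})

test_that("one-hot baseline reduces to Matern over indicator coordinates", {
  z <- list(x = 0.4, h = 0L)
  zsame <- list(x = 0.4, h = 0L)
  zdiff <- list(x = 0.4, h = 2L)
  expect_equal(k_ohe(z, zsame, n_cats = 4), 1)
  # same continuous coords, different single category: distance sqrt(2)
  expect_equal(k_ohe(z, zdiff, n_cats = 4),
               k_matern(0, sqrt(2), theta = 1, nu = 2.5), tolerance = 1e-12)
  # relabeling categories leaves the value unchanged
  expect_equal(k_ohe(list(x = 0.4, h = 1L), list(x = 0.4, h = 3L),
                     n_cats = 4),
               k_ohe(z, zdiff, n_cats = 4), tolerance = 1e-12)
})
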