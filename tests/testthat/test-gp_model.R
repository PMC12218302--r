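test_that("noise variance is the pooled unbiased control variance", {
  expect_equal(estimate_noise_variance(c(5, 5, 5)), 0)
  expect_equal(estimate_noise_variance(c(4, 6)), 1)
  it1 <- c(4.9, 5.1, 5.0); it2 <- c(5.3, 4.8); it3 <- c(5.1, 5.2, 4.7)
  pool <- c(it1, it2, it3) # brute-force variance of the concatenation
  expect_equal(estimate_noise_variance(pool),
               sum((pool - mean(pool))^2) / length(pool))
  expect_error(estimate_noise_variance(5), ">= 2")
})

test_that("a noise-free GP interpolates its training data", {
  sp <- toy1d_space()
  dat <- tibble::tibble(x = seq(0, 1, length.out = 5))
  dat$target <- sin(2 * pi * dat$x)
  m <- gp_fit(dat, sp, restarts = 4, seed = 1)
  pr <- predict(m, dat)
  expect_equal(pr$.pred, dat$target, tolerance = 1e-6)
  expect_true(all(pr$.pred_sd <= 1e-3))
})

test_that("fitting is deterministic for a fixed seed", {
  sp <- small_mixed_space()
  set.seed(8)
  dat <- sample_feasible(sp, 15, seed = 8)
  dat$target <- mixed_test_fun(dat) + rnorm(15, 0, 0.05)
  m1 <- gp_fit(dat, sp, noise_variance = 0.0025, restarts = 4, seed = 3)
  m2 <- gp_fit(dat, sp, noise_variance = 0.0025, restarts = 4, seed = 3)
  expect_identical(m1$params$theta, m2$params$theta)
  expect_identical(m1$params$alpha, m2$params$alpha)
})

test_that("the optimizer never degrades the marginal likelihood from its start", {
  sp <- small_mixed_space()
  set.seed(21)
  dat <- sample_feasible(sp, 20, seed = 21)
  dat$target <- mixed_test_fun(dat) + rnorm(20, 0, 0.1)
  m <- gp_fit(dat, sp, noise_variance = 0.01, restarts = 5, seed = 2)
  expect_gte(m$log_marginal, -m$nll_at_init)
  expect_equal(m$init_params$alpha, 0.5) # documented initialization
  expect_true(all(m$init_params$theta == 1))
})

test_that("posterior sd rises to the prior far from data and sd is nonnegative", {
  sp <- toy1d_space()
  # rapidly varying data in [0, 0.3] forces a short fitted length scale
  dat <- tibble::tibble(x = seq(0, 0.3, length.out = 10))
  dat$target <- sin(20 * pi * dat$x)
  m <- gp_fit(dat, sp, noise_variance = 1e-4, restarts = 4, seed = 1)
  expect_lt(m$params$theta, 0.15)
  far <- predict(m, tibble::tibble(x = 1)) # many length scales away
  prior_sd <- m$y_sd # continuous-only prior variance is 1 (standardized)
  expect_lt(abs(far$.pred_sd - prior_sd) / prior_sd, 0.01)
  expect_true(all(predict(m, dat)$.pred_sd >= 0))
})

test_that("prediction handles empty queries and refuses unknown columns", {
  sp <- toy1d_space()
  dat <- tibble::tibble(x = c(0.1, 0.9), target = c(0, 1))
  m <- gp_fit(dat, sp, restarts = 2, seed = 1)
  pr <- predict(m, tibble::tibble(x = numeric(0)))
  expect_equal(nrow(pr), 0L)
  expect_named(pr, c(".pred", ".pred_sd"))
})

test_that("adding a training point shrinks the posterior sd there", {
  sp <- toy1d_space()
  dat <- tibble::tibble(x = c(0.1, 0.9), target = c(0.2, 0.8))
  m1 <- gp_fit(dat, sp, noise_variance = 0.01, restarts = 3, seed = 1)
  at <- tibble::tibble(x = 0.5)
  sd_before <- predict(m1, at)$.pred_sd
  dat2 <- dplyr::bind_rows(dat, tibble::tibble(x = 0.5, target = 0.5))
  m2 <- gp_fit(dat2, sp, noise_variance = 0.01, restarts = 3, seed = 1)
  expect_lt(predict(m2, at)$.pred_sd, sd_before)
})

test_that("length scales are recovered within a factor of two on Matern draws", {
  sp <- toy1d_space()
  theta_true <- 0.3
  hits <- 0L
  n_seeds <- 12L
  for (s in seq_len(n_seeds)) {
    set.seed(100 + s)
    x <- runif(60)
    D <- abs(outer(x, x, "-")) / theta_true
    K <- (1 + sqrt(5) * D + 5 * D^2 / 3) * exp(-sqrt(5) * D)
    diag(K) <- diag(K) + 1e-8
    y <- as.numeric(t(chol(K)) %*% rnorm(60))
    dat <- tibble::tibble(x = x, target = y)
    m <- gp_fit(dat, sp, nu = 2.5, noise_variance = 1e-6, restarts = 4,
                seed = s)
    th <- m$params$theta
    if (th > theta_true / 2 && th < theta_true * 2) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.8)
})

test_that("posterior matches the direct dense-formula oracle", {
  # independent route: naive solve() on the full covariance, no Cholesky reuse
  sp <- small_mixed_space()
  set.seed(14)
  dat <- sample_feasible(sp, 12, seed = 14)
  dat$target <- mixed_test_fun(dat)
  m <- gp_fit(dat, sp, noise_variance = 0.04, restarts = 3, seed = 2)
  new <- sample_feasible(sp, 6, seed = 99)
  pr <- predict(m, new)

  enc_tr <- encode_points(sp, dat[, c("x1", "x2", "cat")])
  enc_nw <- encode_points(sp, new)
  p <- m$params
  kfun <- function(za, zb) {
    kc <- k_categorical(za$h, zb$h, p$sigma_cat)
    km <- k_matern(za$x, zb$x, p$theta, m$nu)
    p$alpha * kc * km + (1 - p$alpha) * (kc + km)
  }
  get <- function(enc, i) list(x = enc$X[i, ], h = enc$H[i, ])
  n <- nrow(dat); q <- nrow(new)
  K <- outer(seq_len(n), seq_len(n),
             Vectorize(function(i, j) kfun(get(enc_tr, i), get(enc_tr, j))))
  Ks <- outer(seq_len(q), seq_len(n),
              Vectorize(function(i, j) kfun(get(enc_nw, i), get(enc_tr, j))))
  y_std <- (dat$target - m$y_mu) / m$y_sd
  A <- K + diag(1e-8 + 0.04 / m$y_sd^2, n)
  mean_oracle <- m$y_mu + m$y_sd * as.numeric(Ks %*% solve(A, y_std))
  kss <- p$alpha * p$sigma_cat + (1 - p$alpha) * (p$sigma_cat + 1)
  var_oracle <- kss - rowSums(Ks * t(solve(A, t(Ks))))
  expect_equal(pr$.pred, mean_oracle, tolerance = 1e-8)
  expect_equal(pr$.pred_sd, m$y_sd * sqrt(pmax(var_oracle, 0)),
               tolerance = 1e-6)
})

test_that("convergence verdicts follow the batch-agreement rule", {
  sp <- toy1d_space()
  dat <- tibble::tibble(x = seq(0, 1, length.out = 6))
  dat$target <- dat$x^2
  m <- gp_fit(dat, sp, noise_variance = 0.01, restarts = 3, seed = 1)
  batch <- tibble::tibble(x = c(0.2, 0.7))
  batch$target <- predict(m, batch)$.pred
  expect_true(check_convergence(m, batch)$converged)
  # one observation 10 combined sd away in a batch of 2: 50% < 80%
  off <- batch
  pr <- predict(m, off)
  off$target[2] <- pr$.pred[2] + 10 * (pr$.pred_sd[2] + sqrt(0.01))
  expect_false(check_convergence(m, off)$converged)
  # 10 of 12 within tolerance converges (83% >= 80%)
  b12 <- tibble::tibble(x = seq(0.02, 0.98, length.out = 12))
  pr12 <- predict(m, b12)
  b12$target <- pr12$.pred
  b12$target[1:2] <- pr12$.pred[1:2] + 10 * (pr12$.pred_sd[1:2] + 0.1)
  res <- check_convergence(m, b12)
  expect_true(res$converged)
  expect_equal(res$fraction, 10 / 12)
  expect_error(check_convergence(m, dat[0, ]), "empty")
})

test_that("tidy and glance expose hyperparameters and fit summaries", {
  sp <- small_mixed_space()
  dat <- sample_feasible(sp, 10, seed = 4)
  dat$target <- mixed_test_fun(dat)
  m <- gp_fit(dat, sp, noise_variance = 0.01, restarts = 3, seed = 1)
  td <- tidy(m)
  expect_true(all(c("theta_x1", "theta_x2", "sigma_cat", "alpha", "nu") %in%
                    td$term))
  expect_true(td$estimate[td$term == "alpha"] >= 0 &&
                td$estimate[td$term == "alpha"] <= 1)
  g <- glance(m)
  expect_equal(g$n, 10L)
  expect_equal(g$kernel, "mixed")
  expect_equal(g$nu, 2.5) # categorical factor present -> twice-differentiable
})
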