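# a small fitted model on a smooth 1-D function, shared across blocks
fit_toy_model <- function(noise = 1e-6) {
  sp <- toy1d_space()
  dat <- tibble::tibble(x = seq(0.05, 0.95, length.out = 7))
  dat$target <- -(dat$x - 0.6)^2
  gp_fit(dat, sp, noise_variance = noise, restarts = 4, seed = 1)
}

test_that("UCB reduces to the mean when kappa or sd vanish", {
  m <- fit_toy_model()
  pts <- tibble::tibble(x = c(0.2, 0.5, 0.8))
  pr <- predict(m, pts)
  expect_equal(acq_ucb(m, pts, kappa = 0), pr$.pred)
  # at noise-free training points the sd is ~0: UCB == mean there too
  tr <- tibble::tibble(x = 0.5)
  expect_lt(abs(acq_ucb(m, tr, kappa = 2) - predict(m, tr)$.pred), 5e-3)
  expect_equal(acq_ucb(m, pts, kappa = 2), pr$.pred + 2 * pr$.pred_sd)
  expect_error(acq_ucb(m, pts, kappa = -1), "nonnegative")
})

test_that("acquisition maximization matches a dense-grid argmax in 1-D", {
  m <- fit_toy_model(noise = 1e-4)
  cfg <- acq_config(kind = "ucb", kappa = 0.5, screen_size = 1000)
  sug <- maximize_acquisition(m, cfg, seed = 2)
  grid <- tibble::tibble(x = seq(0, 1, length.out = 10000))
  gx <- grid$x[which.max(acq_ucb(m, grid, 0.5))]
  expect_lt(abs(sug$x - gx), 1e-3)
})

test_that("constrained suggestions stay on the simplex", {
  sp <- blend_space()
  set.seed(4)
  dat <- sample_feasible(sp, 10, seed = 4)
  dat$target <- 1 - rowSums((as.matrix(dat) - 0.25)^2)
  m <- gp_fit(dat, sp, noise_variance = 1e-4, restarts = 3, seed = 1)
  cfg <- acq_config(kind = "ucb", screen_size = 500)
  sug <- maximize_acquisition(m, cfg, seed = 3)
  expect_equal(sum(as.numeric(sug[1, c("DMEM", "AR5", "XVIVO", "RPMI")])), 1,
               tolerance = 1e-6)
})

test_that("brute-force screening is deterministic per seed", {
  sp <- small_mixed_space()
  dat <- sample_feasible(sp, 12, seed = 3)
  dat$target <- mixed_test_fun(dat)
  m <- gp_fit(dat, sp, noise_variance = 1e-4, restarts = 3, seed = 1)
  cfg <- acq_config(kind = "brute_force_screen", screen_size = 500)
  s1 <- maximize_acquisition(m, cfg, seed = 11)
  s2 <- maximize_acquisition(m, cfg, seed = 11)
  expect_identical(s1, s2)
})

test_that("EXP3 bandit selection is probability-matching and never starves arms", {
  b1 <- bandit_init("only")
  expect_equal(bandit_select(b1, seed = 1)$arm, 1L)
  b4 <- bandit_init(paste0("arm", 1:4))
  expect_equal(bandit_probs(b4), rep(0.25, 4))
  set.seed(5)
  draws <- vapply(1:10000, function(i) bandit_select(b4)$arm, integer(1))
  freq <- table(factor(draws, levels = 1:4)) / 10000
  se <- sqrt(0.25 * 0.75 / 10000)
  expect_true(all(abs(freq - 0.25) < 6 * se))
  # one arm consistently rewarded comes to dominate but never exclusively
  b <- bandit_init(paste0("arm", 1:4))
  for (i in 1:50) {
    b <- bandit_update(b, 2L, 1.0)
    b <- bandit_update(b, 1L, 0.0)
  }
  p <- bandit_probs(b)
  expect_gt(p[2], 0.5)
  expect_true(all(p > 0))
})

test_that("Thompson sampling picks the dominant candidate and is reproducible", {
  m <- fit_toy_model(noise = 1e-6)
  # candidates at training points: posterior sd ~ 0, one dominant mean
  cand <- tibble::tibble(x = c(0.05, 0.6, 0.95))
  hits <- 0L
  for (i in 1:200) {
    pick <- thompson_batch(m, batch_size = 1, seed = i, candidates = cand)
    if (abs(pick$x - 0.6) < 1e-9) hits <- hits + 1L
  }
  expect_gt(hits / 200, 0.99)
  b1 <- thompson_batch(m, batch_size = 3, screen_size = 128, seed = 42)
  b2 <- thompson_batch(m, batch_size = 3, screen_size = 128, seed = 42)
  expect_identical(b1, b2)
  expect_equal(nrow(b1), 3L)
})

test_that("constant liar spreads the batch and deflates lied-at acquisition", {
  m <- fit_toy_model(noise = 1e-4)
  cfg1 <- acq_config(kind = "ucb", batch_size = 1, screen_size = 500)
  single <- maximize_acquisition(m, cfg1, seed = 5 + 7L)
  batch1 <- constant_liar_batch(m, cfg1, seed = 5)
  expect_equal(batch1$x, single$x, tolerance = 1e-9)

  cfg6 <- acq_config(kind = "ucb", batch_size = 6, screen_size = 500)
  batch6 <- constant_liar_batch(m, cfg6, seed = 5)
  expect_equal(nrow(batch6), 6L)
  dmat <- as.matrix(stats::dist(batch6$x))
  expect_gt(min(dmat[upper.tri(dmat)]), 1e-6)

  # inserting the lie shrinks the UCB at the lied point
  p1 <- batch6[1, "x", drop = FALSE]
  before <- acq_ucb(m, p1, kappa = 2)
  lied <- mediabo:::gp_augment(m, p1, mean(m$y_raw))
  after <- acq_ucb(lied, p1, kappa = 2)
  expect_lt(after, before)
})

test_that("larger kappa pushes suggestions toward unexplored regions", {
  sp <- toy1d_space()
  dat <- tibble::tibble(x = c(0.55, 0.6, 0.65))
  dat$target <- c(0.9, 1.0, 0.9)
  m <- gp_fit(dat, sp, noise_variance = 1e-4, restarts = 3, seed = 1)
  cfg_exploit <- acq_config(kind = "ucb", kappa = 0, screen_size = 500)
  cfg_explore <- acq_config(kind = "ucb", kappa = 20, screen_size = 500)
  s0 <- maximize_acquisition(m, cfg_exploit, seed = 2)
  s20 <- maximize_acquisition(m, cfg_explore, seed = 2)
  dist_to_data <- function(x) min(abs(x - dat$x))
  expect_gt(dist_to_data(s20$x), dist_to_data(s0$x))
})

test_that("suggest_batch dispatches by schedule and leaves bandit untouched under ucb", {
  sp <- small_mixed_space()
  camp <- campaign_new(sp, acq_config(kind = "ucb", batch_size = 3,
                                      screen_size = 300, restarts = 2))
  camp <- campaign_init(camp, 8, seed = 1)
  planned <- camp$ledger
  y <- mixed_test_fun(planned)
  camp <- ingest(camp, tibble::tibble(experiment_id = planned$experiment_id,
                                      target = y))
  out <- suggest_batch(camp, seed = 3)
  expect_equal(nrow(out$points), 3L)
  expect_null(out$bandit) # ucb path never touches bandit state
  expect_true(all(validate_points(sp, out$points[, c("x1", "x2", "cat")])$valid))
  # default dispatch on a mixed space in early iterations uses the bandit
  camp$config <- acq_config(kind = "auto", batch_size = 3, screen_size = 300,
                            thompson_screen = 128, restarts = 2)
  out2 <- suggest_batch(camp, seed = 3)
  expect_s3_class(out2$bandit, "bo_bandit")
  expect_equal(out2$kind, "bandit_thompson")
})
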