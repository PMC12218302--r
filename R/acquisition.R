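#' Acquisition settings for a campaign
#'
#' @param kind Acquisition strategy: `"auto"` (dispatch by space
#'   structure and iteration), `"ucb"`, `"thompson"`, `"bandit_thompson"`,
#'   or `"brute_force_screen"`.
#' @param kappa Nonnegative UCB exploration weight (default 2).
#' @param screen_size Candidate-screen size for brute-force acquisition
#'   maximization (default 10000).
#' @param thompson_screen Candidate-screen size for Thompson sampling,
#'   which needs a joint posterior draw over the screen (default 512).
#' @param batch_size Number of experiments per iteration (default 6).
#' @param lie Constant-liar strategy; only `"mean"` is supported.
#' @param phase_schedule Optional named list mapping iteration index to an
#'   acquisition kind, overriding the default dispatch.
#' @param bandit_until For `"auto"` on mixed spaces: last iteration that
#'   uses bandit + Thompson sampling before switching to the brute-force
#'   screen with constant liar (default 3).
#' @param restarts Optimizer restarts used when refitting the surrogate
#'   inside closed loops (default 10).
#' @return An `acq_config` object.
#' @export
acq_config <- function(kind = c("auto", "ucb", "thompson", "bandit_thompson",
                                "brute_force_screen"),
                       kappa = 2, screen_size = 10000, thompson_screen = 512,
                       batch_size = 6, lie = "mean", phase_schedule = NULL,
                       bandit_until = 3, restarts = 10) {
  kind <- match.arg(kind)
  stopifnot(kappa >= 0, batch_size >= 1, screen_size >= batch_size,
            identical(lie, "mean"))
  structure(list(kind = kind, kappa = kappa, screen_size = screen_size,
                 thompson_screen = thompson_screen, batch_size = batch_size,
                 lie = lie, phase_schedule = phase_schedule,
                 bandit_until = bandit_until, restarts = restarts),
            class = "acq_config")
}

#' Upper-confidence-bound score
#'
#' `posterior mean + kappa * posterior sd`, under the maximization
#' convention.
#'
#' @param model A fitted `bo_gp`.
#' @param points Data frame of candidate points.
#' @param kappa Nonnegative exploration weight.
#' @return Numeric score vector.
#' @export
acq_ucb <- function(model, points, kappa = 2) {
  if (kappa < 0) stop("kappa must be nonnegative", call. = FALSE)
  pr <- stats::predict(model, points)
  pr$.pred + kappa * pr$.pred_sd
}

# candidate screen over a space: LHS continuous + uniform categoricals,
# feasible sampling under constraints
candidate_screen <- function(space, n, seed) {
  initial_design(space, n, seed = seed)
}

#' Maximize the acquisition function over a design space
#'
#' Pure continuous unconstrained spaces use multistart bounded
#' quasi-Newton ascent on the UCB surface; constrained spaces screen
#' feasible samples and refine locally on the constraint's affine slice;
#' mixed spaces (or `kind = "brute_force_screen"`) screen `screen_size`
#' LHS/uniform candidates and return the argmax (ties: lowest index).
#'
#' @param model A fitted `bo_gp`.
#' @param config An `acq_config`.
#' @param space Design space to optimize over (default: the model's).
#' @param seed Integer seed for candidate generation.
#' @return One-row tibble: the suggested design point.
#' @export
maximize_acquisition <- function(model, config = acq_config(), space = NULL,
                                 seed = 1) {
  if (is.null(space)) space <- model$space
  kappa <- config$kappa
  has_cat <- n_categorical(space) > 0L
  constrained <- length(space$constraints) > 0L
  if (has_cat || identical(config$kind, "brute_force_screen")) {
    cand <- candidate_screen(space, config$screen_size, seed)
    sc <- acq_ucb(model, cand, kappa)
    return(cand[which.max(sc), , drop = FALSE])
  }
  if (constrained) {
    cand <- sample_feasible(space, config$screen_size, seed = seed)
    sc <- acq_ucb(model, cand, kappa)
    x0 <- cand[which.max(sc), , drop = FALSE]
    return(refine_constrained(model, space, x0, kappa))
  }
  # unconstrained continuous/discrete: multistart L-BFGS-B on encoded coords
  cn <- cont_names(space)
  d <- length(cn)
  obj <- function(u) {
    pt <- decode_points(space, list(X = matrix(pmin(pmax(u, 0), 1), 1, d,
                                               dimnames = list(NULL, cn)),
                                    H = matrix(0L, 1, 0)),
                        snap_discrete = FALSE)
    -acq_ucb(model, pt, kappa)
  }
  set.seed(seed)
  scr <- candidate_screen(space, 256, seed)
  best_scr <- scr[which.max(acq_ucb(model, scr, kappa)), , drop = FALSE]
  starts <- rbind(matrix(stats::runif(5 * d), 5, d),
                  encode_points(space, best_scr)$X)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[i, ], obj, method = "L-BFGS-B", lower = rep(0, d),
                   upper = rep(1, d)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("acquisition maximization failed", call. = FALSE)
  decode_points(space, list(X = matrix(best$par, 1, d,
                                       dimnames = list(NULL, cn)),
                            H = matrix(0L, 1, 0)))
}

# local refinement on the affine slice of a single equality constraint:
# the last constrained coordinate is eliminated, bounds enforced by penalty
refine_constrained <- function(model, space, x0, kappa) {
  cn <- space$constraints[[1L]]
  nmc <- names(cn$coefficients)
  a <- cn$coefficients
  k <- length(nmc)
  other <- setdiff(cont_names(space), nmc)
  lows <- vapply(space$factors[c(nmc, other)], `[[`, numeric(1), "lower")
  ups <- vapply(space$factors[c(nmc, other)], `[[`, numeric(1), "upper")
  free <- c(nmc[-k], other)
  par0 <- as.numeric(unlist(x0[1, free]))
  obj <- function(p) {
    names(p) <- free
    lastv <- (cn$rhs - sum(a[-k] * p[nmc[-k]])) / a[k]
    x <- x0
    for (nm in free) x[[nm]] <- p[[nm]]
    x[[nmc[k]]] <- lastv
    vals <- c(p, lastv); names(vals) <- c(free, nmc[k])
    pen <- sum(pmax(lows[names(vals)] - vals, 0)^2 +
                 pmax(vals - ups[names(vals)], 0)^2) * 1e6
    if (pen > 0) return(1e6 + pen)
    -acq_ucb(model, x, kappa)
  }
  fit <- tryCatch(
    stats::optim(par0, obj, method = "Nelder-Mead",
                 control = list(maxit = 200, reltol = 1e-9)),
    error = function(e) NULL)
  if (is.null(fit) || fit$value >= 1e6) return(x0)
  p <- fit$par; names(p) <- free
  out <- x0
  for (nm in free) out[[nm]] <- p[[nm]]
  out[[nmc[k]]] <- (cn$rhs - sum(a[-k] * p[nmc[-k]])) / a[k]
  if (all(validate_points(space, out)$valid)) out else x0
}

## EXP3 multi-armed bandit ---------------------------------------------------

#' Initialize EXP3 bandit state over categorical arms
#'
#' @param categories Character vector of arm labels.
#' @return A `bo_bandit` state (unit weights, zero pulls).
#' @export
bandit_init <- function(categories) {
  stopifnot(length(categories) >= 1L)
  structure(list(categories = as.character(categories),
                 weights = rep(1, length(categories)), t = 0L),
            class = "bo_bandit")
}

# EXP3 exploration rate at the current round
bandit_gamma <- function(state) {
  K <- length(state$weights)
  if (K == 1L) return(0)
  min(1, sqrt(2 * log(K) / (K * max(1L, state$t))))
}

#' Arm selection probabilities of the bandit
#'
#' EXP3 probability matching: `(1 - gamma) w_a / sum(w) + gamma / K`.
#' Every arm always keeps probability at least `gamma / K > 0`.
#'
#' @param state A `bo_bandit`.
#' @return Probability vector over arms.
#' @export
bandit_probs <- function(state) {
  K <- length(state$weights)
  if (K == 1L) return(1)
  g <- bandit_gamma(state)
  (1 - g) * state$weights / sum(state$weights) + g / K
}

#' Draw a categorical arm
#'
#' @param state A `bo_bandit`.
#' @param seed Optional integer seed.
#' @return List with `arm` (index), `category` (label), `probs`.
#' @export
bandit_select <- function(state, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- bandit_probs(state)
  arm <- sample.int(length(p), 1L, prob = p)
  list(arm = arm, category = state$categories[arm], probs = p)
}

#' Update the bandit with an observed reward
#'
#' Importance-weighted EXP3 update of the chosen arm's weight; rewards are
#' expected on a \eqn{[0, 1]} scale (the campaign uses the min-max-scaled
#' best target achieved by the arm in the latest batch).
#'
#' @param state A `bo_bandit`.
#' @param arm Chosen arm index.
#' @param reward Reward in \eqn{[0, 1]}.
#' @return Updated `bo_bandit`.
#' @export
bandit_update <- function(state, arm, reward) {
  stopifnot(arm >= 1L, arm <= length(state$weights))
  reward <- min(max(reward, 0), 1)
  K <- length(state$weights)
  p <- bandit_probs(state)
  g <- max(bandit_gamma(state), 1e-3)
  state$weights[arm] <- state$weights[arm] * exp(g * reward / (K * p[arm]))
  state$weights <- state$weights / max(state$weights)
  state$t <- state$t + 1L
  state
}

## Thompson sampling ---------------------------------------------------------

#' Thompson-sampling batch
#'
#' Draws `batch_size` joint posterior sample paths over a candidate screen
#' and returns each path's argmax. Independent sample paths give batch
#' diversity directly, without a liar step.
#'
#' @param model A fitted `bo_gp`.
#' @param space Design space (default: the model's).
#' @param batch_size Number of suggestions.
#' @param screen_size Candidate-screen size (joint draws require a dense
#'   covariance over the screen; keep moderate).
#' @param seed Integer seed.
#' @param candidates Optional explicit candidate tibble (overrides the
#'   generated screen, e.g. to fix a bandit-chosen category).
#' @return Tibble of `batch_size` design points.
#' @export
thompson_batch <- function(model, space = NULL, batch_size = 1,
                           screen_size = 512, seed = 1, candidates = NULL) {
  if (is.null(space)) space <- model$space
  if (is.null(candidates)) {
    candidates <- candidate_screen(space, screen_size, seed)
  }
  enc_new <- encode_points(space,
                           candidates[, factor_names(space), drop = FALSE], check = FALSE)
  Ks <- model_cross(model$kernel_type, enc_new, model$enc, model$params,
                    model$n_cats)
  m <- as.numeric(Ks %*% model$alpha_vec)
  v <- forwardsolve(t(model$chol), t(Ks))
  Kss <- model_cross(model$kernel_type, enc_new, enc_new, model$params,
                     model$n_cats)
  S <- Kss - crossprod(v)
  S <- (S + t(S)) / 2
  diag(S) <- diag(S) + 1e-8
  L <- tryCatch(chol(S), error = function(e) {
    diag(S) <- diag(S) + 1e-6
    chol(S)
  })
  set.seed(seed)
  picks <- integer(batch_size)
  for (b in seq_len(batch_size)) {
    f <- m + as.numeric(t(L) %*% stats::rnorm(nrow(candidates)))
    picks[b] <- which.max(f)
  }
  candidates[picks, , drop = FALSE]
}

## constant liar batching ----------------------------------------------------

# append a pseudo-observation without re-optimizing hyperparameters
gp_augment <- function(model, point, y_value_raw, noise_var_raw = NULL) {
  if (is.null(noise_var_raw)) noise_var_raw <- mean(model$noise_variance_raw)
  enc1 <- encode_points(model$space,
                        point[, factor_names(model$space), drop = FALSE], check = FALSE)
  model$enc$X <- rbind(model$enc$X, enc1$X)
  model$enc$H <- rbind(model$enc$H, enc1$H)
  model$y_raw <- c(model$y_raw, y_value_raw)
  model$noise_variance_raw <- c(model$noise_variance_raw, noise_var_raw)
  y <- (model$y_raw - model$y_mu) / model$y_sd
  noise_std <- model$noise_variance_raw / model$y_sd^2
  K <- model_cross(model$kernel_type, model$enc, model$enc, model$params,
                   model$n_cats)
  diag(K) <- diag(K) + 1e-8 + noise_std
  model$chol <- chol(K)
  model$alpha_vec <- backsolve(model$chol,
                               forwardsolve(t(model$chol), y))
  model
}

#' Constant-liar batch construction
#'
#' Sequentially maximizes the acquisition, then inserts a "lie"
#' observation (the mean of the current training targets) at each
#' suggestion so subsequent batch members are pushed elsewhere.
#' Hyperparameters are not re-optimized inside the loop; the original
#' model is untouched.
#'
#' @param model A fitted `bo_gp`.
#' @param config An `acq_config` (kind `"ucb"` or
#'   `"brute_force_screen"`).
#' @param space Design space (default: the model's).
#' @param seed Integer seed.
#' @return Tibble of `batch_size` design points.
#' @export
constant_liar_batch <- function(model, config = acq_config(), space = NULL,
                                seed = 1) {
  if (is.null(space)) space <- model$space
  lie <- mean(model$y_raw)
  scratch <- model
  out <- NULL
  for (b in seq_len(config$batch_size)) {
    p <- maximize_acquisition(scratch, config, space, seed = seed + 7L * b)
    out <- dplyr::bind_rows(out, p)
    if (b < config$batch_size) scratch <- gp_augment(scratch, p, lie)
  }
  out
}

#' Suggest the next batch of experiments for a campaign
#'
#' Dispatches by the campaign's acquisition config and space structure:
#' mixed categorical-continuous spaces default to bandit-selected
#' categories with Thompson sampling in early iterations and a
#' brute-force screen with constant-liar batching afterwards; continuous
#' spaces (constrained or not) use UCB with constant-liar batching. An
#' explicit `phase_schedule` or non-`"auto"` kind overrides the default.
#'
#' @param campaign A `bo_campaign` with a fitted model.
#' @param seed Integer seed.
#' @return List with `points` (tibble of suggestions) and `bandit`
#'   (updated bandit state, if used).
#' @export
suggest_batch <- function(campaign, seed = 1) {
  model <- campaign$model
  if (is.null(model)) stop("campaign has no fitted model", call. = FALSE)
  space <- campaign$space
  config <- campaign$config
  iter <- campaign$iteration + 1L
  kind <- config$kind
  if (!is.null(config$phase_schedule) &&
      !is.null(config$phase_schedule[[as.character(iter)]])) {
    kind <- config$phase_schedule[[as.character(iter)]]
  } else if (kind == "auto") {
    kind <- if (n_categorical(space) > 0L) {
      if (iter <= config$bandit_until) "bandit_thompson"
      else "brute_force_screen"
    } else "ucb"
  }
  bandit <- campaign$bandit
  if (kind == "bandit_thompson") {
    hn <- cat_names(space)
    stopifnot(length(hn) == 1L)
    if (is.null(bandit)) bandit <- bandit_init(space$factors[[hn]]$categories)
    pts <- NULL
    for (b in seq_len(config$batch_size)) {
      sel <- bandit_select(bandit, seed = seed + 31L * b)
      cand <- candidate_screen(space, config$thompson_screen,
                               seed = seed + 31L * b + 1L)
      cand[[hn]] <- sel$category
      p <- thompson_batch(model, space, batch_size = 1,
                          seed = seed + 31L * b + 2L, candidates = cand)
      p$.arm <- sel$arm
      pts <- dplyr::bind_rows(pts, p)
    }
  } else if (kind == "thompson") {
    pts <- thompson_batch(model, space, batch_size = config$batch_size,
                          screen_size = config$thompson_screen, seed = seed)
  } else {
    cfg <- config
    cfg$kind <- if (kind == "brute_force_screen") "brute_force_screen"
                else "ucb"
    pts <- constant_liar_batch(model, cfg, space, seed = seed)
  }
  vd <- validate_points(space, pts[, factor_names(space), drop = FALSE])
  stopifnot(all(vd$valid))
  list(points = pts, bandit = bandit, kind = kind)
}
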