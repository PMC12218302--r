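#' Synthetic mixed categorical-continuous landscape
#'
#' Builds a smooth ground-truth response over `n_cont` continuous factors
#' on \eqn{[0,1]} and one categorical factor: each category has its own
#' radial bump (distinct best continuous location and amplitude) on top of
#' a shared global trend, with one globally best category. The optimum is
#' certified by a dense per-category grid search at construction.
#'
#' @param n_cont Number of continuous factors (>= 1; default 3).
#' @param n_categories Number of categories (>= 2; default 19).
#' @param noise_sd Observation noise standard deviation (default 0.1).
#' @param seed Integer seed fixing the landscape.
#' @param grid_resolution Per-axis certification grid size (default 50;
#'   the certified optimum is resolution-limited).
#' @param bump_width Radial width of the per-category bumps on the scaled
#'   axes (default 0.18; larger values give an easier, smoother landscape).
#' @return A `bo_landscape` with elements `space`, `true_response`
#'   (function of a points tibble), `noise_sd`, `optimum` (point + value).
#' @export
make_mixed_landscape <- function(n_cont = 3, n_categories = 19,
                                 noise_sd = 0.1, seed = 1,
                                 grid_resolution = 50, bump_width = 0.18) {
  stopifnot(n_cont >= 1, n_categories >= 2)
  if (noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  set.seed(seed)
  cats <- sprintf("cat_%02d", seq_len(n_categories))
  centers <- matrix(stats::runif(n_categories * n_cont, 0.15, 0.85),
                    n_categories, n_cont)
  amps <- sort(stats::runif(n_categories, 0.2, 0.8))
  best_cat <- sample.int(n_categories, 1L)
  amps[best_cat] <- 1.0 # one clearly best category
  gcen <- stats::runif(n_cont, 0.3, 0.7)
  width <- bump_width

  factors <- c(
    lapply(seq_len(n_cont), function(j) {
      design_factor(paste0("x", j), "continuous", lower = 0, upper = 1)
    }),
    list(design_factor("category", "categorical", categories = cats)))
  space <- design_space(factors)

  true_response <- function(points) {
    points <- tibble::as_tibble(points)
    X <- as.matrix(points[, paste0("x", seq_len(n_cont)), drop = FALSE])
    hi <- match(as.character(points$category), cats)
    d2 <- rowSums((X - centers[hi, , drop = FALSE])^2)
    g2 <- rowSums(sweep(X, 2, gcen, "-")^2)
    amps[hi] * exp(-d2 / (2 * width^2)) + 0.3 * exp(-g2 / (2 * 0.35^2))
  }

  # certify optimum on a per-category grid
  gr <- seq(0, 1, length.out = grid_resolution)
  grid1 <- as.matrix(expand.grid(rep(list(gr), n_cont)))
  best_val <- -Inf; best_pt <- NULL
  for (h in seq_len(n_categories)) {
    pts <- tibble::as_tibble(as.data.frame(grid1))
    names(pts) <- paste0("x", seq_len(n_cont))
    pts$category <- cats[h]
    vals <- true_response(pts)
    i <- which.max(vals)
    if (vals[i] > best_val) { best_val <- vals[i]; best_pt <- pts[i, ] }
  }
  # polish the grid argmax by local ascent within the winning category
  xn <- paste0("x", seq_len(n_cont))
  opt <- stats::optim(as.numeric(best_pt[1, xn]), function(u) {
    p <- tibble::as_tibble(as.list(stats::setNames(u, xn)))
    p$category <- best_pt$category
    -true_response(p)
  }, method = "L-BFGS-B", lower = 0, upper = 1)
  if (-opt$value > best_val) {
    best_val <- -opt$value
    best_pt[1, xn] <- as.list(opt$par)
  }
  structure(list(space = space, true_response = true_response,
                 noise_sd = noise_sd,
                 optimum = list(point = best_pt, value = best_val),
                 seed = seed, family = "mixed"),
            class = "bo_landscape")
}

#' Synthetic simplex-constrained blend landscape
#'
#' Ground truth over `k_components` blend ratios summing to one, with an
#' interior optimum strictly exceeding every vertex (pure component) —
#' the structure of a basal-media blending problem where the best blend
#' beats each single medium.
#'
#' @param k_components Number of blend components (>= 2; default 4).
#' @param noise_sd Observation noise standard deviation (default 0.03).
#' @param seed Integer seed.
#' @param grid_resolution Simplex-grid resolution for certification
#'   (default 20 subdivisions per edge).
#' @return A `bo_landscape`.
#' @export
make_simplex_landscape <- function(k_components = 4, noise_sd = 0.03,
                                   seed = 1, grid_resolution = 20) {
  stopifnot(k_components >= 2)
  if (noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  set.seed(seed)
  k <- k_components
  # interior peak location: Dirichlet(3,...,3) keeps it away from vertices
  g <- stats::rgamma(k, shape = 3)
  peak <- g / sum(g)
  base <- 0.55; amp <- 0.25; width <- 0.35
  vert_pen <- stats::runif(k, 0, 0.08)

  nms <- paste0("medium_", seq_len(k))
  factors <- lapply(nms, function(nm) {
    design_factor(nm, "continuous", lower = 0, upper = 1)
  })
  space <- design_space(factors,
                        constraints = list(constraint_sum_to_one(nms)))

  true_response <- function(points) {
    X <- as.matrix(tibble::as_tibble(points)[, nms, drop = FALSE])
    d2 <- rowSums(sweep(X, 2, peak, "-")^2)
    base + amp * exp(-d2 / (2 * width^2)) - as.numeric(X %*% vert_pen)
  }

  # certification over the lattice of compositions
  comp <- simplex_grid(k, grid_resolution)
  pts <- tibble::as_tibble(as.data.frame(comp)); names(pts) <- nms
  vals <- true_response(pts)
  i <- which.max(vals)
  structure(list(space = space, true_response = true_response,
                 noise_sd = noise_sd,
                 optimum = list(point = pts[i, ], value = vals[i]),
                 seed = seed, family = "simplex"),
            class = "bo_landscape")
}

# all compositions of m parts into k nonnegative integers, scaled to sum 1
simplex_grid <- function(k, m) {
  if (k == 1L) return(matrix(1, 1, 1))
  rec <- function(k, m) {
    if (k == 1L) return(matrix(m, 1, 1))
    do.call(rbind, lapply(0:m, function(i) cbind(i, rec(k - 1L, m - i))))
  }
  out <- rec(k, m) / m
  dimnames(out) <- NULL
  out
}

#' Synthetic continuous-only landscape
#'
#' Smooth unconstrained response over `n_cont` continuous factors on
#' \eqn{[0,1]}: two radial bumps of different heights plus a gentle
#' linear trend — the structure of a supplement-concentration
#' optimization (e.g. cytokine doses) with a single best region.
#'
#' @param n_cont Number of continuous factors (default 8).
#' @param noise_sd Observation noise standard deviation (default 0.05).
#' @param seed Integer seed.
#' @return A `bo_landscape`; the optimum is certified by dense random
#'   probing at construction.
#' @export
make_continuous_landscape <- function(n_cont = 8, noise_sd = 0.05, seed = 1) {
  stopifnot(n_cont >= 1)
  if (noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  set.seed(seed)
  c1 <- stats::runif(n_cont, 0.2, 0.8)
  c2 <- stats::runif(n_cont, 0.2, 0.8)
  slope <- stats::runif(n_cont, -0.05, 0.05)
  nms <- paste0("x", seq_len(n_cont))
  space <- design_space(lapply(nms, function(nm) {
    design_factor(nm, "continuous", 0, 1)
  }))
  true_response <- function(points) {
    X <- as.matrix(tibble::as_tibble(points)[, nms, drop = FALSE])
    d1 <- rowSums(sweep(X, 2, c1, "-")^2)
    d2 <- rowSums(sweep(X, 2, c2, "-")^2)
    exp(-d1 / (2 * 0.3^2)) + 0.4 * exp(-d2 / (2 * 0.2^2)) +
      as.numeric(X %*% slope)
  }
  probes <- matrix(stats::runif(20000 * n_cont), ncol = n_cont)
  colnames(probes) <- nms
  pts <- tibble::as_tibble(as.data.frame(probes))
  vals <- true_response(pts)
  # polish the probe argmax with local ascent
  opt <- stats::optim(as.numeric(probes[which.max(vals), ]),
                      function(u) {
                        p <- tibble::as_tibble(as.list(stats::setNames(u, nms)))
                        -true_response(p)
                      },
                      method = "L-BFGS-B", lower = 0, upper = 1)
  best_pt <- tibble::as_tibble(as.list(stats::setNames(opt$par, nms)))
  structure(list(space = space, true_response = true_response,
                 noise_sd = noise_sd,
                 optimum = list(point = best_pt, value = -opt$value),
                 seed = seed, family = "continuous"),
            class = "bo_landscape")
}

#' Evaluate a landscape at design points
#'
#' @param landscape A `bo_landscape`.
#' @param points Tibble of valid design points.
#' @param noisy Add Gaussian observation noise (default `TRUE`).
#' @param seed Optional seed for the noise draw.
#' @return Numeric response vector.
#' @export
eval_landscape <- function(landscape, points, noisy = TRUE, seed = NULL) {
  f <- landscape$true_response(points)
  if (noisy && landscape$noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    f <- f + stats::rnorm(length(f), 0, landscape$noise_sd)
  }
  f
}

#' Run a closed-loop simulated campaign on a landscape
#'
#' Initial design, fit, suggest, simulated observation, ingest — repeated
#' until the experiment budget is spent (or the convergence criterion
#' fires, when `stop_on_convergence`).
#'
#' @param landscape A `bo_landscape`.
#' @param config An `acq_config`.
#' @param budget Total experiment budget (>= initial design size).
#' @param seed Integer seed for the whole loop.
#' @param init_size Initial design size (default: `config$batch_size`).
#' @param stop_on_convergence Stop early when the model-agreement check
#'   converges (default `FALSE`).
#' @return List with the final `campaign` and a `trace` tibble
#'   (one row per experiment: iteration, observed value, best-so-far).
#' @export
run_closed_loop <- function(landscape, config = acq_config(), budget,
                            seed = 1, init_size = NULL,
                            stop_on_convergence = FALSE) {
  if (is.null(init_size)) init_size <- config$batch_size
  stopifnot(budget >= init_size)
  camp <- campaign_new(landscape$space, config, seed = seed)
  camp <- campaign_init(camp, init_size, seed = seed)
  k <- 0L
  repeat {
    planned <- dplyr::filter(camp$ledger, .data$role == "planned")
    y <- eval_landscape(landscape, planned, seed = seed + 53L * k)
    camp <- ingest(camp, tibble::tibble(experiment_id = planned$experiment_id,
                                        target = y))
    k <- k + 1L
    done <- sum(camp$ledger$role == "executed")
    if (stop_on_convergence && length(camp$convergence)) {
      last <- camp$convergence[[length(camp$convergence)]]
      if (isTRUE(last$converged)) break
    }
    if (done + config$batch_size > budget) break
    camp <- campaign_suggest(camp, seed = seed + 101L * k)
  }
  ex <- dplyr::filter(camp$ledger, .data$role == "executed")
  y <- internal_target(camp, ex$target)
  trace <- tibble::tibble(experiment_id = ex$experiment_id,
                          iteration = ex$iteration, observed = ex$target,
                          best_so_far = cummax(y) *
                            if (camp$direction == "minimize") -1 else 1)
  list(campaign = camp, trace = trace)
}

#' Continue a simulated closed loop from an existing campaign
#'
#' Runs further suggest/observe/ingest cycles on a campaign that already
#' has a fitted model (e.g. a warm-started transfer campaign), without
#' planning any space-filling design.
#'
#' @param campaign A `bo_campaign` with a fitted model.
#' @param landscape A `bo_landscape` on the campaign's space.
#' @param n_batches Number of additional suggest/ingest cycles.
#' @param seed Integer seed.
#' @return List with the updated `campaign` and a `trace` tibble over the
#'   newly executed experiments.
#' @export
continue_closed_loop <- function(campaign, landscape, n_batches, seed = 1) {
  if (is.null(campaign$model)) {
    stop("campaign has no fitted model", call. = FALSE)
  }
  first_new <- nrow(campaign$ledger) + 1L
  for (k in seq_len(n_batches)) {
    campaign <- campaign_suggest(campaign, seed = seed + 101L * k)
    planned <- dplyr::filter(campaign$ledger, .data$role == "planned")
    y <- eval_landscape(landscape, planned, seed = seed + 53L * k)
    campaign <- ingest(campaign,
                       tibble::tibble(experiment_id = planned$experiment_id,
                                      target = y))
  }
  ex <- campaign$ledger[seq(first_new, nrow(campaign$ledger)), , drop = FALSE]
  ex <- dplyr::filter(ex, .data$role == "executed")
  y <- internal_target(campaign, ex$target)
  trace <- tibble::tibble(experiment_id = ex$experiment_id,
                          iteration = ex$iteration, observed = ex$target,
                          best_so_far = cummax(y) *
                            if (campaign$direction == "minimize") -1 else 1)
  list(campaign = campaign, trace = trace)
}

#' Compare design strategies at equal budget
#'
#' Runs Bayesian optimization, uniform random search, and a fixed grid on
#' the same landscape and budget across seeds, and summarizes the
#' best-found value per strategy.
#'
#' @param landscape A `bo_landscape`.
#' @param budget Experiment budget per run.
#' @param seeds Integer vector of seeds (>= 5).
#' @param config An `acq_config` for the BO runs.
#' @param init_size Initial design size for BO (default
#'   `config$batch_size`).
#' @return Tibble with one row per (strategy, seed): `best_found` and
#'   `n_evaluations`.
#' @export
compare_strategies <- function(landscape, budget, seeds,
                               config = acq_config(), init_size = NULL) {
  stopifnot(length(seeds) >= 5)
  out <- list()
  for (s in seeds) {
    bo <- run_closed_loop(landscape, config, budget, seed = s,
                          init_size = init_size)
    out[[length(out) + 1L]] <- tibble::tibble(
      strategy = "bo", seed = s,
      best_found = max(bo$trace$best_so_far),
      n_evaluations = nrow(bo$trace))
    rnd <- sample_feasible(landscape$space, budget, seed = s)
    yr <- eval_landscape(landscape, rnd, seed = s + 5000L)
    out[[length(out) + 1L]] <- tibble::tibble(
      strategy = "random", seed = s, best_found = max(yr),
      n_evaluations = budget)
    gd <- grid_strategy(landscape$space, budget, seed = s)
    yg <- eval_landscape(landscape, gd, seed = s + 9000L)
    out[[length(out) + 1L]] <- tibble::tibble(
      strategy = "grid", seed = s, best_found = max(yg),
      n_evaluations = nrow(gd))
  }
  dplyr::bind_rows(out)
}

# a feasible grid of about `budget` points
grid_strategy <- function(space, budget, seed = 1) {
  cn <- cont_names(space)
  hn <- cat_names(space)
  if (length(space$constraints)) {
    m <- 2L
    repeat {
      g <- simplex_grid(length(cn), m)
      if (nrow(g) >= budget || m > 50L) break
      m <- m + 1L
    }
    pts <- tibble::as_tibble(as.data.frame(g[seq_len(min(budget, nrow(g))), ,
                                             drop = FALSE]))
    names(pts) <- cn
    return(pts)
  }
  per_cat <- if (length(hn)) {
    length(space$factors[[hn[1]]]$categories)
  } else 1L
  L <- max(2L, floor((budget / per_cat)^(1 / length(cn))))
  b <- cont_bounds(space)
  axes <- lapply(seq_along(cn), function(j) {
    seq(b[j, 1], b[j, 2], length.out = L)
  })
  g <- expand.grid(axes)
  names(g) <- cn
  pts <- tibble::as_tibble(g)
  if (length(hn)) {
    cats <- space$factors[[hn[1]]]$categories
    pts <- tidyr::crossing(pts, !!hn[1] := cats)
  }
  pts[seq_len(min(budget, nrow(pts))), , drop = FALSE]
}

#' Design-of-experiments run counts
#'
#' Standard textbook experiment counts for classical designs, with
#' categorical factors multiplying any continuous design by the product
#' of category counts.
#'
#' @param method One of `"ofat"`, `"full_factorial"`,
#'   `"fractional_factorial"`, `"ccd"`, `"fractional_ccd"`, `"bbd"`,
#'   `"full_screen"`.
#' @param k_continuous Number of continuous factors (>= 1).
#' @param levels Levels per factor for OFAT/factorial/full-screen
#'   (default 3; the full screen conventionally uses a grid of 10).
#' @param category_counts Integer vector of category counts of the
#'   categorical factors (default none).
#' @param center_points Center points for CCD/BBD (default 1).
#' @param fraction Fraction exponent p for fractional designs (runs
#'   divided by `2^p`; default 1).
#' @return Experiment count.
#' @export
#' @examples
#' doe_size("full_factorial", k_continuous = 4, levels = 3) # 81
#' doe_size("ccd", k_continuous = 4) # 25
doe_size <- function(method = c("ofat", "full_factorial",
                                "fractional_factorial", "ccd",
                                "fractional_ccd", "bbd", "full_screen"),
                     k_continuous, levels = 3, category_counts = integer(0),
                     center_points = 1, fraction = 1) {
  method <- match.arg(method)
  k <- k_continuous
  stopifnot(k >= 1)
  cat_mult <- prod(category_counts)
  base <- switch(method,
    ofat = k * (levels - 1) + 1,
    full_factorial = levels^k,
    fractional_factorial = 2^(k - fraction),
    ccd = 2^k + 2 * k + center_points,
    fractional_ccd = 2^(k - fraction) + 2 * k + center_points,
    bbd = {
      if (k < 3) stop("Box-Behnken design undefined for k < 3",
                      call. = FALSE)
      2 * k * (k - 1) + center_points
    },
    full_screen = levels^k)
  base * cat_mult
}

#' Build a transfer-learning test scenario
#'
#' A pair of landscapes sharing structure: the source landscape lives on
#' the original factors; the extended landscape adds a nuisance
#' continuous factor with a mild effect, so knowledge from the source
#' campaign genuinely transfers.
#'
#' @param n_cont Continuous factors in the source space (default 2).
#' @param n_categories Categories of the shared categorical factor
#'   (default 4).
#' @param noise_sd Observation noise (default 0.05).
#' @param seed Integer seed.
#' @param nuisance_amp Amplitude of the added factor's effect
#'   (default 0.1).
#' @return List with `old` (`bo_landscape`), `new` (`bo_landscape` on the
#'   extended space), `new_factor` (name), `fill_value` (the source
#'   campaign's implicit setting of the new factor).
#' @export
make_transfer_scenario <- function(n_cont = 2, n_categories = 3,
                                   noise_sd = 0.03, seed = 1,
                                   nuisance_amp = 0.1) {
  old <- make_mixed_landscape(n_cont, n_categories, noise_sd, seed,
                              grid_resolution = 40, bump_width = 0.3)
  nf <- "supplement"
  fill <- 0
  new_space <- extend_space(old$space,
                            list(design_factor(nf, "continuous", 0, 1)))
  # move factors so the shared categorical stays last-but-one in order
  base_resp <- old$true_response
  peak_u <- 0.6
  new_resp <- function(points) {
    points <- tibble::as_tibble(points)
    u <- as.numeric(points[[nf]])
    base_resp(points) +
      nuisance_amp * (exp(-(u - peak_u)^2 / (2 * 0.2^2)) -
                        exp(-(fill - peak_u)^2 / (2 * 0.2^2)))
  }
  # certify extended optimum on a coarse grid over (x, category, u)
  gr <- seq(0, 1, length.out = 25)
  cats <- old$space$factors[["category"]]$categories
  grid <- expand.grid(c(rep(list(gr), n_cont), list(cats), list(gr)),
                      stringsAsFactors = FALSE)
  names(grid) <- c(paste0("x", seq_len(n_cont)), "category", nf)
  vals <- new_resp(grid)
  i <- which.max(vals)
  new <- structure(list(space = new_space, true_response = new_resp,
                        noise_sd = noise_sd,
                        optimum = list(point = tibble::as_tibble(grid[i, ]),
                                       value = vals[i]),
                        seed = seed, family = "mixed"),
                   class = "bo_landscape")
  list(old = old, new = new, new_factor = nf, fill_value = fill)
}
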