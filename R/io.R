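## design-space / campaign configuration files (YAML or JSON)

space_to_list <- function(space) {
  list(
    factors = lapply(unname(space$factors), function(f) {
      out <- list(name = f$name, kind = f$kind)
      if (f$kind == "continuous") {
        out$lower <- f$lower; out$upper <- f$upper
      } else if (f$kind == "discrete") {
        out$levels <- f$levels
      } else {
        out$categories <- as.list(f$categories)
      }
      if (nzchar(f$units)) out$units <- f$units
      if (nzchar(f$phase)) out$phase <- f$phase
      if (!is.null(f$linked_to)) out$linked_to <- f$linked_to
      out
    }),
    constraints = lapply(space$constraints, function(cn) {
      list(coefficients = as.list(cn$coefficients), rhs = cn$rhs,
           tolerance = cn$tolerance)
    }))
}

space_from_list <- function(x) {
  factors <- lapply(x$factors, function(f) {
    design_factor(f$name, f$kind,
                  lower = f$lower, upper = f$upper,
                  levels = if (!is.null(f$levels)) as.numeric(unlist(f$levels)),
                  categories = if (!is.null(f$categories))
                    as.character(unlist(f$categories)),
                  units = f$units %||% "", phase = f$phase %||% "",
                  linked_to = f$linked_to)
  })
  constraints <- lapply(x$constraints %||% list(), function(cn) {
    co <- unlist(cn$coefficients)
    linear_constraint(co, cn$rhs, cn$tolerance %||% 1e-6)
  })
  design_space(factors, constraints = constraints)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a design space to a structured-text config file
#'
#' @param space A `bo_design_space`.
#' @param path Output path; `.json` writes JSON, anything else YAML.
#' @return `path`, invisibly.
#' @export
write_space_config <- function(space, path) {
  x <- space_to_list(space)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' Read a design space from a config file
#'
#' @param path YAML or JSON config path.
#' @return A `bo_design_space`; round-trips [write_space_config()]
#'   exactly.
#' @export
read_space_config <- function(path) {
  x <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path)
  } else {
    yaml::read_yaml(path)
  }
  space_from_list(x)
}

#' Read a full campaign configuration
#'
#' A campaign config file carries the design space plus acquisition
#' settings, optimization direction, seed, initial design size and any
#' prior noise-variance estimate.
#'
#' @param path YAML or JSON path.
#' @return List with `space`, `config` (an `acq_config`), `direction`,
#'   `seed`, `init_size`, `noise_variance`.
#' @export
read_campaign_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  x <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path)
  } else {
    yaml::read_yaml(path)
  }
  acq <- x$acquisition %||% list()
  sched <- acq$phase_schedule
  config <- acq_config(
    kind = acq$kind %||% "auto",
    kappa = acq$kappa %||% 2,
    screen_size = acq$screen_size %||% 10000,
    thompson_screen = acq$thompson_screen %||% 512,
    batch_size = acq$batch_size %||% 6,
    phase_schedule = sched,
    bandit_until = acq$bandit_until %||% 3,
    restarts = acq$restarts %||% 10)
  list(space = space_from_list(x),
       config = config,
       direction = x$direction %||% "maximize",
       seed = as.integer(x$seed %||% 1),
       init_size = as.integer(x$init_size %||% config$batch_size),
       noise_variance = as.numeric(x$noise_variance %||% 0))
}

## campaign state ------------------------------------------------------------

#' Save campaign state to JSON
#'
#' Serializes the space, acquisition config, ledger, bandit state, pooled
#' controls, noise estimate and the fitted model's hyperparameters with
#' full precision; [campaign_load()] restores predictions bit-identically
#' by rebuilding the factorization from the stored data and
#' hyperparameters (no re-optimization).
#'
#' @param campaign A `bo_campaign`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
campaign_save <- function(campaign, path) {
  mod <- campaign$model
  led <- campaign$ledger
  # doubles are written as %.17g strings: decimal JSON numbers lose the
  # last ulp, which would break bit-identical reload of predictions
  led_out <- lapply(led, function(col) {
    if (is.double(col)) num_to_chr(col) else col
  })
  state <- list(
    space = space_to_list(campaign$space),
    config = unclass(campaign$config),
    direction = campaign$direction,
    seed = campaign$seed,
    iteration = campaign$iteration,
    ledger = led_out,
    control_pool = num_to_chr(campaign$control_pool),
    noise_variance = num_to_chr(campaign$noise_variance),
    convergence = campaign$convergence,
    log = campaign$log,
    bandit = if (!is.null(campaign$bandit)) {
      list(categories = campaign$bandit$categories,
           weights = num_to_chr(campaign$bandit$weights),
           t = campaign$bandit$t)
    },
    model = if (!is.null(mod)) list(
      kernel_type = mod$kernel_type, nu = mod$nu,
      theta = num_to_chr(mod$params$theta),
      sigma_cat = num_to_chr(mod$params$sigma_cat),
      alpha = num_to_chr(mod$params$alpha), seed = mod$seed,
      log_marginal = mod$log_marginal, train_rmse = mod$train_rmse))
  jsonlite::write_json(state, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

num_to_chr <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- NA_character_
  out
}

chr_to_num <- function(x) as.numeric(x)

#' Load campaign state from JSON
#'
#' @param path JSON path written by [campaign_save()].
#' @return A `bo_campaign`; the surrogate is rebuilt from the stored
#'   hyperparameters without re-optimization.
#' @export
campaign_load <- function(path) {
  if (!file.exists(path)) {
    stop("state file not found: ", path, call. = FALSE)
  }
  st <- jsonlite::read_json(path, simplifyVector = TRUE)
  space <- space_from_list(jsonlite::read_json(path)$space)
  cfg <- st$config
  config <- acq_config(kind = cfg$kind, kappa = cfg$kappa,
                       screen_size = cfg$screen_size,
                       thompson_screen = cfg$thompson_screen,
                       batch_size = cfg$batch_size,
                       phase_schedule = cfg$phase_schedule,
                       bandit_until = cfg$bandit_until,
                       restarts = cfg$restarts)
  camp <- campaign_new(space, config, direction = st$direction,
                       seed = as.integer(st$seed),
                       noise_variance = chr_to_num(st$noise_variance))
  led <- tibble::as_tibble(st$ledger)
  if (nrow(led)) {
    led$iteration <- as.integer(led$iteration)
    kinds <- factor_kinds(space)
    for (nm in names(led)) {
      if (nm %in% names(kinds) && kinds[[nm]] != "categorical" ||
          nm == "target" || grepl("^rep_", nm)) {
        led[[nm]] <- chr_to_num(led[[nm]])
      }
    }
  } else {
    led <- empty_ledger(space)
  }
  camp$ledger <- led
  camp$control_pool <- chr_to_num(st$control_pool)
  camp$iteration <- as.integer(st$iteration)
  camp$convergence <- if (length(st$convergence)) {
    apply(as.data.frame(st$convergence), 1, as.list)
  } else list()
  if (!is.null(st$bandit) && length(st$bandit)) {
    camp$bandit <- structure(list(categories = st$bandit$categories,
                                  weights = chr_to_num(st$bandit$weights),
                                  t = as.integer(st$bandit$t)),
                             class = "bo_bandit")
  }
  if (!is.null(st$model) && length(st$model)) {
    camp <- rebuild_model(camp, st$model)
  }
  camp
}

# refit-light: restore the surrogate from stored hyperparameters
rebuild_model <- function(campaign, ms) {
  tr <- training_rows(campaign)
  tr$.y <- internal_target(campaign, tr$target)
  enc <- encode_points(campaign$space,
                       tr[, factor_names(campaign$space), drop = FALSE])
  y_raw <- tr$.y
  mu <- mean(y_raw); sdy <- stats::sd(y_raw)
  if (!is.finite(sdy) || sdy < 1e-12) sdy <- 1
  y <- (y_raw - mu) / sdy
  nv <- rep(campaign$noise_variance, length(y))
  n_cats <- vapply(campaign$space$factors[cat_names(campaign$space)],
                   function(f) length(f$categories), integer(1))
  params <- kernel_params(theta = as.numeric(ms$theta), nu = ms$nu,
                          sigma_cat = as.numeric(ms$sigma_cat %||% 1),
                          alpha = as.numeric(ms$alpha %||% 0.5),
                          noise_variance = nv / sdy^2)
  K <- model_cross(ms$kernel_type, enc, enc, params, n_cats)
  diag(K) <- diag(K) + 1e-8 + nv / sdy^2
  ch <- chol(K)
  model <- structure(
    list(space = campaign$space, enc = enc, data = tr, target = ".y",
         y_raw = y_raw, y_mu = mu, y_sd = sdy, noise_variance_raw = nv,
         params = params, nu = ms$nu, kernel_type = ms$kernel_type,
         n_cats = n_cats, chol = ch,
         alpha_vec = backsolve(ch, forwardsolve(t(ch), y)),
         log_marginal = ms$log_marginal, train_rmse = ms$train_rmse,
         seed = as.integer(ms$seed %||% campaign$seed)),
    class = "bo_gp")
  campaign$model <- model
  campaign
}
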