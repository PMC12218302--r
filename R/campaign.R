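#' Create a new optimization campaign
#'
#' A campaign bundles the design space, acquisition settings, the
#' append-only experiment ledger, the fitted surrogate, bandit state and
#' the pooled control measurements used for the fixed noise estimate.
#'
#' @param space A `bo_design_space`.
#' @param config An `acq_config`.
#' @param direction `"maximize"` or `"minimize"`.
#' @param seed Integer campaign seed.
#' @param noise_variance Initial fixed process-noise variance (raw target
#'   scale), e.g. from a preliminary control campaign.
#' @return A `bo_campaign`.
#' @export
campaign_new <- function(space, config = acq_config(),
                         direction = c("maximize", "minimize"), seed = 1,
                         noise_variance = 0) {
  direction <- match.arg(direction)
  ledger <- empty_ledger(space)
  structure(
    list(space = space, config = config, direction = direction, seed = seed,
         ledger = ledger, model = NULL, bandit = NULL,
         control_pool = numeric(0), noise_variance = noise_variance,
         iteration = -1L, convergence = list(), log = list()),
    class = "bo_campaign")
}

empty_ledger <- function(space) {
  base <- tibble::tibble(experiment_id = character(0),
                         iteration = integer(0), role = character(0))
  for (f in space$factors) {
    base[[f$name]] <- if (f$kind == "categorical") character(0) else numeric(0)
  }
  base$target <- numeric(0)
  base
}

# append planned rows for an iteration
plan_rows <- function(campaign, points, iteration) {
  points <- tibble::as_tibble(points)[, factor_names(campaign$space),
                                      drop = FALSE]
  n0 <- nrow(campaign$ledger)
  rows <- points
  rows$experiment_id <- sprintf("exp_%04d", n0 + seq_len(nrow(points)))
  rows$iteration <- as.integer(iteration)
  rows$role <- "planned"
  rows$target <- NA_real_
  campaign$ledger <- dplyr::bind_rows(campaign$ledger, rows)
  campaign
}

#' Plan the iteration-0 initial design
#'
#' @param campaign A fresh `bo_campaign`.
#' @param n Initial design size.
#' @param seed Integer seed (default: the campaign seed).
#' @return Updated campaign with `n` planned rows at iteration 0.
#' @export
campaign_init <- function(campaign, n, seed = NULL) {
  if (is.null(seed)) seed <- campaign$seed
  if (nrow(campaign$ledger) > 0L) {
    stop("campaign already has ledger rows", call. = FALSE)
  }
  pts <- initial_design(campaign$space, n, seed = seed)
  campaign <- plan_rows(campaign, pts, 0L)
  campaign$iteration <- 0L
  campaign
}

# internal modeling target: negated for minimization
internal_target <- function(campaign, y) {
  if (campaign$direction == "minimize") -y else y
}

training_rows <- function(campaign) {
  dplyr::filter(campaign$ledger,
                .data$role %in% c("executed", "control"),
                !is.na(.data$target))
}

# refit the surrogate on all executed + control rows
campaign_fit <- function(campaign) {
  tr <- training_rows(campaign)
  if (nrow(tr) < 2L) return(campaign)
  tr$.y <- internal_target(campaign, tr$target)
  model <- gp_fit(tr, campaign$space, target = ".y",
                  noise_variance = campaign$noise_variance,
                  restarts = campaign$config$restarts,
                  seed = campaign$seed)
  campaign$model <- model
  campaign$log[[length(campaign$log) + 1L]] <- list(
    event = "fit", n = nrow(tr), train_rmse = model$train_rmse,
    log_marginal = model$log_marginal,
    params = list(theta = model$params$theta, nu = model$nu,
                  sigma_cat = model$params$sigma_cat,
                  alpha = model$params$alpha,
                  noise_variance = campaign$noise_variance))
  campaign
}

#' Ingest executed experiment results
#'
#' Matches results to planned rows by `experiment_id` (or appends declared
#' control/validation rows), computes targets from replicate columns when
#' absent, updates the pooled control-noise estimate, refits the
#' surrogate, records a model-agreement convergence check against the
#' predictions made before refitting, and updates bandit rewards for
#' mixed campaigns.
#'
#' @param campaign A `bo_campaign`.
#' @param results Data frame with `experiment_id` plus either a `target`
#'   column or replicate columns `rep_1`, `rep_2`, ...; optional `role`
#'   for control/validation rows not previously planned.
#' @return Updated campaign.
#' @export
ingest <- function(campaign, results) {
  results <- tibble::as_tibble(results)
  stopifnot("experiment_id" %in% names(results))
  rep_cols <- grep("^rep_", names(results), value = TRUE)
  if (!"target" %in% names(results)) results$target <- NA_real_
  for (i in seq_len(nrow(results))) {
    if (is.na(results$target[i]) && length(rep_cols)) {
      reps <- as.numeric(unlist(results[i, rep_cols]))
      results$target[i] <- replicate_target(reps)
    }
  }
  if (anyNA(results$target)) {
    stop("results rows without target or replicates", call. = FALSE)
  }

  led <- campaign$ledger
  new_ids <- character(0)
  for (i in seq_len(nrow(results))) {
    id <- results$experiment_id[i]
    j <- match(id, led$experiment_id)
    role_i <- if ("role" %in% names(results)) results$role[i] else NA
    if (is.na(j)) {
      if (is.na(role_i) || !role_i %in% c("control", "validation")) {
        stop("unknown experiment_id '", id,
             "' (only control/validation rows may be appended)",
             call. = FALSE)
      }
      row <- results[i, intersect(names(results),
                                  c("experiment_id",
                                    factor_names(campaign$space), "target")),
                     drop = FALSE]
      vd <- validate_points(campaign$space,
                            row[, factor_names(campaign$space), drop = FALSE])
      if (!all(vd$valid)) {
        stop("row '", id, "': ", paste(vd$violations[[1]], collapse = "; "),
             call. = FALSE)
      }
      row$iteration <- max(campaign$iteration, 0L)
      row$role <- role_i
      led <- dplyr::bind_rows(led, row)
      j <- nrow(led)
    } else {
      led$target[j] <- results$target[i]
      led$role[j] <- if (!is.na(role_i) &&
                           role_i %in% c("control", "validation")) role_i
                     else "executed"
    }
    if (identical(led$role[j], "control") && length(rep_cols)) {
      campaign$control_pool <- c(campaign$control_pool,
                                 as.numeric(unlist(results[i, rep_cols])))
    } else if (identical(led$role[j], "control")) {
      campaign$control_pool <- c(campaign$control_pool, results$target[i])
    }
    new_ids <- c(new_ids, id)
  }
  campaign$ledger <- led

  # pooled, contemporaneous-inclusive noise estimate
  pool <- campaign$control_pool[is.finite(campaign$control_pool)]
  if (length(pool) >= 2L) {
    campaign$noise_variance <- estimate_noise_variance(pool)
  }

  # convergence check on newly executed rows against the pre-refit model
  newly <- dplyr::filter(led, .data$experiment_id %in% new_ids,
                         .data$role == "executed")
  if (!is.null(campaign$model) && nrow(newly) > 0L) {
    chk <- newly
    chk$.y <- internal_target(campaign, chk$target)
    cv <- check_convergence(campaign$model, chk, target = ".y")
    campaign$convergence[[length(campaign$convergence) + 1L]] <-
      list(iteration = campaign$iteration, converged = cv$converged,
           fraction = cv$fraction)
  }

  # bandit rewards: best scaled target per arm in the latest batch
  if (!is.null(campaign$bandit) && nrow(newly) > 0L) {
    hn <- cat_names(campaign$space)[1L]
    ally <- internal_target(campaign, training_rows(campaign)$target)
    ylat <- internal_target(campaign, newly$target)
    rng <- range(c(ally, ylat))
    span <- max(rng[2] - rng[1], 1e-12)
    for (cat in unique(newly[[hn]])) {
      arm <- match(cat, campaign$bandit$categories)
      if (is.na(arm)) next
      best <- max(ylat[newly[[hn]] == cat])
      campaign$bandit <- bandit_update(campaign$bandit, arm,
                                       (best - rng[1]) / span)
    }
  }

  campaign <- campaign_fit(campaign)
  campaign
}

#' Plan the next batch of experiments
#'
#' @param campaign A `bo_campaign` with a fitted model.
#' @param seed Integer seed (default derived from campaign seed and
#'   iteration).
#' @return Updated campaign; the new planned rows are the last
#'   `batch_size` ledger rows.
#' @export
campaign_suggest <- function(campaign, seed = NULL) {
  if (is.null(seed)) {
    seed <- campaign$seed + 1009L * (campaign$iteration + 1L)
  }
  sug <- suggest_batch(campaign, seed = seed)
  campaign$bandit <- sug$bandit
  campaign$iteration <- campaign$iteration + 1L
  campaign <- plan_rows(campaign, sug$points, campaign$iteration)
  campaign$log[[length(campaign$log) + 1L]] <- list(
    event = "suggest", iteration = campaign$iteration, kind = sug$kind,
    seed = seed, n = nrow(sug$points))
  campaign
}

#' Best result found so far
#'
#' @param campaign A `bo_campaign`.
#' @return One-row tibble of the best executed experiment (by the
#'   campaign direction), or an empty tibble when nothing is executed.
#' @export
campaign_best <- function(campaign) {
  tr <- training_rows(campaign)
  if (!nrow(tr)) return(tr)
  y <- internal_target(campaign, tr$target)
  tr[which.max(y), , drop = FALSE]
}

#' @export
print.bo_campaign <- function(x, ...) {
  cat("<bo_campaign> iteration ", x$iteration, ", ",
      nrow(x$ledger), " ledger rows (",
      sum(x$ledger$role == "executed"), " executed)\n", sep = "")
  if (!is.null(x$model)) print(x$model) else cat("  no model fitted yet\n")
  best <- campaign_best(x)
  if (nrow(best)) {
    cat("  best target so far: ", format(best$target), " (",
        best$experiment_id, ")\n", sep = "")
  }
  invisible(x)
}

## ledger CSV ----------------------------------------------------------------

#' Read a campaign ledger CSV
#'
#' UTF-8 comma-separated ledger with a header row and columns
#' `experiment_id`, `iteration`, `role`, one column per factor, optional
#' replicate columns `rep_1..rep_n`, and `target`. Empty targets of
#' executed rows are filled with the replicate mean on read.
#'
#' @param path CSV path.
#' @param space A `bo_design_space` used to validate factor values.
#' @return Ledger tibble.
#' @export
read_ledger <- function(path, space) {
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("experiment_id", "iteration", "role")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("ledger missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$experiment_id)) {
    stop("duplicate experiment_id: ",
         df$experiment_id[duplicated(df$experiment_id)][1], call. = FALSE)
  }
  if (!"target" %in% names(df)) df$target <- NA_real_
  rep_cols <- grep("^rep_", names(df), value = TRUE)
  for (i in seq_len(nrow(df))) {
    if (is.na(df$target[i]) && length(rep_cols)) {
      reps <- as.numeric(unlist(df[i, rep_cols]))
      if (any(is.finite(reps))) df$target[i] <- replicate_target(reps)
    }
    vd <- validate_points(space, df[i, factor_names(space), drop = FALSE])
    if (!vd$valid[1]) {
      stop("ledger row ", i, " (", df$experiment_id[i], "): ",
           paste(vd$violations[[1]], collapse = "; "), call. = FALSE)
    }
    if (df$role[i] == "planned" && !is.na(df$target[i]) &&
        !length(rep_cols)) {
      stop("ledger row ", i, ": planned rows must have empty target",
           call. = FALSE)
    }
  }
  df$iteration <- as.integer(df$iteration)
  df
}

#' Write a campaign ledger CSV
#'
#' @param ledger Ledger tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(ledger, path) {
  utils::write.csv(ledger, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
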