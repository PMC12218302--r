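#' Estimate fixed process-noise variance from control replicates
#'
#' Process noise is estimated as the variance across the pooled control
#' measurements (all instances, including the contemporaneous iteration),
#' on the raw target scale. The population convention (denominator `n`) is
#' used, matching the default of the numerical stacks this workflow is
#' usually run with.
#'
#' @param control_measurements Numeric vector of pooled control readings.
#' @return Nonnegative variance estimate.
#' @export
#' @examples
#' estimate_noise_variance(c(4, 6)) # 1
estimate_noise_variance <- function(control_measurements) {
  x <- control_measurements[is.finite(control_measurements)]
  if (length(x) < 2L) {
    stop("need >= 2 control measurements to estimate noise", call. = FALSE)
  }
  mean((x - mean(x))^2)
}

# cross-covariance under the model's kernel (mixed or OHE baseline)
model_cross <- function(kernel_type, enc1, enc2, params, n_cats) {
  if (kernel_type == "mixed") {
    cross_gram(enc1, enc2, params)
  } else {
    X1 <- ohe_expand(enc1, n_cats)
    X2 <- ohe_expand(enc2, n_cats)
    matern_d(sqrt(scaled_dist2(X1, X2, params$theta)), params$nu)
  }
}

# prior variance k(z, z) per point under the model's kernel
model_prior_var <- function(kernel_type, params, n_cat_vars) {
  if (kernel_type == "ohe" || n_cat_vars == 0L) return(1)
  s <- params$sigma_cat
  params$alpha * s + (1 - params$alpha) * (s + 1)
}

# negative log marginal likelihood for standardized targets
gp_nll <- function(par, layout, enc, y, noise_std, nu, kernel_type, n_cats,
                   jitter = 1e-8) {
  params <- layout_to_params(par, layout, nu)
  K <- model_cross(kernel_type, enc, enc, params, n_cats)
  diag(K) <- diag(K) + jitter + noise_std
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  a <- backsolve(ch, forwardsolve(t(ch), y))
  as.numeric(0.5 * sum(y * a) + sum(log(diag(ch))) +
               0.5 * length(y) * log(2 * pi))
}

# parameter vector layout: log(theta) [d], then optionally log(sigma_cat),
# alpha (only when both blocks exist)
make_layout <- function(d, c_vars, kernel_type, d_ohe = d) {
  if (kernel_type == "ohe") {
    list(d = d_ohe, has_cat = FALSE, has_alpha = FALSE)
  } else {
    list(d = d, has_cat = c_vars > 0L,
         has_alpha = c_vars > 0L && d > 0L)
  }
}

layout_to_params <- function(par, layout, nu) {
  d <- layout$d
  theta <- if (d > 0) exp(par[seq_len(d)]) else numeric(0)
  i <- d
  sigma_cat <- 1; alpha <- 0.5
  if (layout$has_cat) { i <- i + 1L; sigma_cat <- exp(par[i]) }
  if (layout$has_alpha) { i <- i + 1L; alpha <- par[i] }
  kernel_params(theta = if (d > 0) theta else 1, nu = nu,
                sigma_cat = sigma_cat, alpha = alpha)
}

layout_bounds <- function(layout) {
  d <- layout$d
  lower <- rep(log(1e-3), d); upper <- rep(log(1e3), d)
  if (layout$has_cat) { lower <- c(lower, log(1e-6)); upper <- c(upper, log(1e3)) }
  if (layout$has_alpha) { lower <- c(lower, 0); upper <- c(upper, 1) }
  list(lower = lower, upper = upper)
}

#' Fit the Gaussian-process surrogate
#'
#' Fits a GP with the mixed categorical-continuous kernel (or the one-hot
#' baseline) to an experiment table by maximizing the log marginal
#' likelihood over length scales, categorical scale and the trade-off
#' weight alpha, using multi-start bounded quasi-Newton optimization.
#' Targets are standardized internally (zero prior mean on the
#' standardized scale); the supplied noise variance is held fixed, never
#' optimized.
#'
#' @param data Data frame with one column per design factor plus a target
#'   column.
#' @param space A `bo_design_space`.
#' @param target Name of the target column (default `"target"`).
#' @param noise_variance Fixed process-noise variance on the raw target
#'   scale; scalar or one value per row.
#' @param nu Matern smoothness; default 2.5 when the space has categorical
#'   factors, 1.5 otherwise.
#' @param kernel `"mixed"` (categorical overlap x Matern blend) or
#'   `"ohe"` (Matern over one-hot expanded coordinates).
#' @param restarts Number of optimizer starts (first from defaults:
#'   unit length scales, alpha = 0.5).
#' @param seed Integer seed controlling the randomized restarts.
#' @return A fitted `bo_gp` object.
#' @export
gp_fit <- function(data, space, target = "target", noise_variance = 0,
                   nu = NULL, kernel = c("mixed", "ohe"), restarts = 10,
                   seed = 1) {
  kernel <- match.arg(kernel)
  data <- tibble::as_tibble(data)
  stopifnot(target %in% names(data), nrow(data) >= 2L)
  y_raw <- as.numeric(data[[target]])
  stopifnot(all(is.finite(y_raw)))
  enc <- encode_points(space, data[, factor_names(space), drop = FALSE])
  mu <- mean(y_raw)
  sdy <- stats::sd(y_raw)
  if (!is.finite(sdy) || sdy < 1e-12) sdy <- 1
  y <- (y_raw - mu) / sdy
  nv <- noise_variance
  if (length(nv) == 1L) nv <- rep(nv, length(y))
  stopifnot(length(nv) == length(y), all(nv >= 0))
  noise_std <- nv / sdy^2

  d <- ncol(enc$X)
  c_vars <- ncol(enc$H)
  n_cats <- vapply(space$factors[cat_names(space)],
                   function(f) length(f$categories), integer(1))
  if (is.null(nu)) nu <- if (c_vars > 0) 2.5 else 1.5
  d_ohe <- d + sum(n_cats)
  layout <- make_layout(d, c_vars, kernel, d_ohe)
  bd <- layout_bounds(layout)

  obj <- function(par) gp_nll(par, layout, enc, y, noise_std, nu, kernel,
                              n_cats)

  # start 1: defaults (unit length scales, sigma_cat = 1, alpha = 0.5)
  start0 <- c(rep(0, layout$d),
              if (layout$has_cat) 0,
              if (layout$has_alpha) 0.5)
  nll0 <- obj(start0)
  set.seed(seed)
  starts <- list(start0)
  for (r in seq_len(max(0L, restarts - 1L))) {
    s <- c(stats::runif(layout$d, log(0.05), log(10)),
           if (layout$has_cat) stats::runif(1, log(0.1), log(10)),
           if (layout$has_alpha) stats::runif(1, 0.05, 0.95))
    starts[[r + 1L]] <- s
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, obj, method = "L-BFGS-B",
                   lower = bd$lower, upper = bd$upper,
                   control = list(maxit = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("hyperparameter optimization failed on all starts",
                          call. = FALSE)
  init_params <- layout_to_params(start0, layout, nu)
  params <- layout_to_params(best$par, layout, nu)
  params$noise_variance <- noise_std

  K <- model_cross(kernel, enc, enc, params, n_cats)
  diag(K) <- diag(K) + 1e-8 + noise_std
  ch <- chol(K)
  alpha_vec <- backsolve(ch, forwardsolve(t(ch), y))

  model <- structure(
    list(space = space, enc = enc, data = data, target = target,
         y_raw = y_raw, y_mu = mu, y_sd = sdy,
         noise_variance_raw = nv, params = params, nu = nu,
         kernel_type = kernel, n_cats = n_cats,
         chol = ch, alpha_vec = alpha_vec,
         log_marginal = -best$value, nll_at_init = nll0,
         init_params = init_params, seed = seed),
    class = "bo_gp")
  model$train_rmse <- sqrt(mean((stats::predict(model, data)$.pred - y_raw)^2))
  model
}

#' Posterior prediction from a fitted surrogate
#'
#' @param object A `bo_gp`.
#' @param newdata Data frame of design points.
#' @param ... Unused.
#' @return Tibble with `.pred` (posterior mean) and `.pred_sd` (posterior
#'   standard deviation, excluding process noise), on the raw target scale.
#' @export
predict.bo_gp <- function(object, newdata, ...) {
  newdata <- tibble::as_tibble(newdata)
  if (nrow(newdata) == 0L) {
    return(tibble::tibble(.pred = numeric(0), .pred_sd = numeric(0)))
  }
  enc_new <- encode_points(object$space,
                           newdata[, factor_names(object$space), drop = FALSE],
                           check = FALSE)
  Ks <- model_cross(object$kernel_type, enc_new, object$enc, object$params,
                    object$n_cats)
  mean_std <- as.numeric(Ks %*% object$alpha_vec)
  v <- forwardsolve(t(object$chol), t(Ks))
  prior <- model_prior_var(object$kernel_type, object$params,
                           ncol(object$enc$H))
  var_std <- pmax(prior - colSums(v^2), 0)
  tibble::tibble(.pred = object$y_mu + object$y_sd * mean_std,
                 .pred_sd = object$y_sd * sqrt(var_std))
}

#' @export
print.bo_gp <- function(x, ...) {
  cat("<bo_gp> ", length(x$y_raw), " experiments, kernel = ", x$kernel_type,
      " (nu = ", x$nu, ")\n", sep = "")
  cat("  log marginal likelihood: ", format(x$log_marginal), "\n", sep = "")
  cat("  training RMSE: ", format(x$train_rmse), "\n", sep = "")
  invisible(x)
}

#' Tidy hyperparameters of a fitted surrogate
#'
#' @param x A `bo_gp`.
#' @param ... Unused.
#' @return Tibble with one row per hyperparameter (`term`, `estimate`).
#' @method tidy bo_gp
#' @export
tidy.bo_gp <- function(x, ...) {
  cn <- cont_names(x$space)
  terms <- character(0); est <- numeric(0)
  th <- x$params$theta
  if (x$kernel_type == "mixed") {
    if (length(cn)) { terms <- paste0("theta_", cn); est <- th }
  } else {
    terms <- paste0("theta_", seq_along(th)); est <- th
  }
  if (x$kernel_type == "mixed" && ncol(x$enc$H) > 0) {
    terms <- c(terms, "sigma_cat", "alpha")
    est <- c(est, x$params$sigma_cat, x$params$alpha)
  }
  terms <- c(terms, "nu", "noise_variance")
  est <- c(est, x$nu, mean(x$noise_variance_raw))
  tibble::tibble(term = terms, estimate = est)
}

#' One-row summary of a fitted surrogate
#'
#' @param x A `bo_gp`.
#' @param ... Unused.
#' @return Tibble with `n`, `log_marginal`, `train_rmse`, `kernel`, `nu`.
#' @method glance bo_gp
#' @export
glance.bo_gp <- function(x, ...) {
  tibble::tibble(n = length(x$y_raw), log_marginal = x$log_marginal,
                 train_rmse = x$train_rmse, kernel = x$kernel_type,
                 nu = x$nu)
}

#' Model-agreement convergence check
#'
#' A campaign is judged converged when the model predicts the latest batch
#' well: an observation agrees when it lies within
#' `z_threshold * (posterior sd + sqrt(noise variance))` of the posterior
#' mean, and the batch converges when at least `min_fraction` of its
#' points agree.
#'
#' @param model A fitted `bo_gp`.
#' @param batch Data frame of the latest executed batch, with factor
#'   columns and observed targets.
#' @param target Target column name.
#' @param z_threshold Agreement width in combined standard deviations
#'   (default 2).
#' @param min_fraction Minimum agreeing fraction (default 0.8).
#' @return List with `converged` (logical), `fraction`, and a tibble
#'   `details` with per-point predictions and z-scores.
#' @export
check_convergence <- function(model, batch, target = "target",
                              z_threshold = 2, min_fraction = 0.8) {
  batch <- tibble::as_tibble(batch)
  if (nrow(batch) == 0L) stop("empty batch", call. = FALSE)
  pr <- stats::predict(model, batch)
  obs <- as.numeric(batch[[target]])
  noise_sd <- sqrt(mean(model$noise_variance_raw))
  combined <- pr$.pred_sd + noise_sd
  z <- abs(obs - pr$.pred) / pmax(combined, 1e-12)
  ok <- z <= z_threshold
  frac <- mean(ok)
  list(converged = frac >= min_fraction, fraction = frac,
       details = tibble::tibble(observed = obs, .pred = pr$.pred,
                                .pred_sd = pr$.pred_sd, z = z, within = ok))
}
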