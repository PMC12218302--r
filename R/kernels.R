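#' Kernel hyperparameters for the mixed-variable GP
#'
#' @param theta Positive length-scale vector, one per continuous/discrete
#'   dimension (on the scaled \eqn{[0,1]} axes).
#' @param nu Matern smoothness, 1.5 or 2.5.
#' @param sigma_cat Nonnegative scale of the categorical overlap kernel.
#' @param alpha Trade-off in \eqn{[0,1]} between the product and sum
#'   combination of the categorical and continuous kernels.
#' @param noise_variance Nonnegative fixed white-noise variance (scalar or
#'   per-point vector), never optimized.
#' @return A `bo_kernel_params` object.
#' @export
kernel_params <- function(theta, nu = 2.5, sigma_cat = 1, alpha = 0.5,
                          noise_variance = 0) {
  stopifnot(all(theta > 0), nu %in% c(1.5, 2.5), sigma_cat >= 0,
            alpha >= 0, alpha <= 1, all(noise_variance >= 0))
  structure(list(theta = theta, nu = nu, sigma_cat = sigma_cat,
                 alpha = alpha, noise_variance = noise_variance),
            class = "bo_kernel_params")
}

#' Matern covariance between scaled continuous vectors
#'
#' Implemented via the closed forms for \eqn{\nu = 1.5} (once
#' differentiable) and \eqn{\nu = 2.5} (twice differentiable); the general
#' Bessel-function form is available as [matern_bessel()] for
#' cross-checking.
#'
#' @param x,x_prime Numeric vectors of equal length (scaled coordinates).
#' @param theta Per-dimension length scales.
#' @param nu Smoothness, 1.5 or 2.5.
#' @return Similarity in \eqn{(0, 1]}; 1 at zero distance.
#' @export
k_matern <- function(x, x_prime, theta, nu = 2.5) {
  if (length(x) != length(x_prime) || length(theta) != length(x)) {
    stop("dimension mismatch in Matern kernel", call. = FALSE)
  }
  d <- sqrt(sum(((x - x_prime) / theta)^2))
  matern_d(d, nu)
}

# closed-form Matern as a function of the scaled distance d = |x-x'|/theta
matern_d <- function(d, nu) {
  if (nu == 1.5) {
    s <- sqrt(3) * d
    (1 + s) * exp(-s)
  } else {
    s <- sqrt(5) * d
    (1 + s + s^2 / 3) * exp(-s)
  }
}

#' Matern covariance via the Bessel-function form
#'
#' Direct numerical evaluation of the general Matern expression
#' \eqn{\frac{2^{1-\nu}}{\Gamma(\nu)} (\sqrt{2\nu} d)^\nu K_\nu(\sqrt{2\nu} d)}
#' with \eqn{d = |x - x'|/\theta}. Used as an independent oracle for the
#' closed forms; numerically fragile at \eqn{d = 0}, where the limit 1 is
#' returned.
#'
#' @param d Nonnegative scaled distance(s).
#' @param nu Smoothness parameter (any positive value).
#' @return Covariance value(s).
#' @export
matern_bessel <- function(d, nu) {
  out <- numeric(length(d))
  for (i in seq_along(d)) {
    if (d[i] < 1e-12) { out[i] <- 1; next }
    s <- sqrt(2 * nu) * d[i]
    out[i] <- 2^(1 - nu) / gamma(nu) * s^nu * besselK(s, nu)
  }
  out
}

#' Categorical overlap covariance
#'
#' \eqn{(\sigma / c) \sum_i 1(h_i = h'_i)}: proportional to the number of
#' categorical coordinates on which the two points agree.
#'
#' @param h,h_prime Integer vectors of category indices, length `c`.
#' @param sigma_cat Kernel scale.
#' @param c Number of categorical variables (defaults to `length(h)`).
#' @return Value in \eqn{[0, \sigma]}.
#' @export
k_categorical <- function(h, h_prime, sigma_cat = 1, c = length(h)) {
  if (c == 0) stop("categorical kernel undefined with zero categorical variables",
                   call. = FALSE)
  if (length(h) != length(h_prime) || length(h) != c) {
    stop("dimension mismatch in categorical kernel", call. = FALSE)
  }
  sigma_cat / c * sum(h == h_prime)
}

#' Mixed categorical-continuous covariance
#'
#' \eqn{\alpha (k_{cat} k_{cont}) + (1 - \alpha)(k_{cat} + k_{cont})}:
#' a weighted blend of the multiplicative and additive combinations of the
#' categorical overlap kernel and the continuous Matern kernel.
#'
#' @param z,z_prime Encoded points: lists with numeric `x` and integer `h`.
#' @param params A `bo_kernel_params`.
#' @return Covariance value.
#' @export
k_mixed <- function(z, z_prime, params) {
  kc <- k_categorical(z$h, z_prime$h, params$sigma_cat)
  km <- k_matern(z$x, z_prime$x, params$theta, params$nu)
  params$alpha * (kc * km) + (1 - params$alpha) * (kc + km)
}

## vectorized Gram machinery -----------------------------------------------

# squared scaled distance matrix between rows of X1 and X2
scaled_dist2 <- function(X1, X2, theta) {
  n1 <- nrow(X1); n2 <- nrow(X2)
  D2 <- matrix(0, n1, n2)
  for (j in seq_len(ncol(X1))) {
    D2 <- D2 + outer(X1[, j], X2[, j], "-")^2 / theta[j]^2
  }
  D2
}

# count of matching categorical coordinates
match_count <- function(H1, H2) {
  n1 <- nrow(H1); n2 <- nrow(H2)
  M <- matrix(0, n1, n2)
  for (j in seq_len(ncol(H1))) {
    M <- M + outer(H1[, j], H2[, j], "==")
  }
  M
}

# cross-covariance matrix under the mixed kernel for encoded sets
cross_gram <- function(enc1, enc2, params) {
  d <- ncol(enc1$X); cc <- ncol(enc1$H)
  Kc <- if (d > 0) {
    matern_d(sqrt(scaled_dist2(enc1$X, enc2$X, params$theta)), params$nu)
  } else NULL
  Kh <- if (cc > 0) {
    params$sigma_cat / cc * match_count(enc1$H, enc2$H)
  } else NULL
  if (is.null(Kh)) return(Kc)
  if (is.null(Kc)) return(Kh)
  params$alpha * (Kh * Kc) + (1 - params$alpha) * (Kh + Kc)
}

#' Gram matrix of encoded design points
#'
#' @param enc Encoded points (list with `X`, `H` from [encode_points()]).
#' @param params A `bo_kernel_params`.
#' @param include_noise Add the fixed noise variance to the diagonal.
#' @param jitter Diagonal jitter for numerical positive semi-definiteness
#'   (default `1e-8`).
#' @return Symmetric covariance matrix.
#' @export
gram_matrix <- function(enc, params, include_noise = FALSE, jitter = 1e-8) {
  K <- cross_gram(enc, enc, params)
  if (any(!is.finite(K))) stop("non-finite kernel entries", call. = FALSE)
  K <- (K + t(K)) / 2
  diag(K) <- diag(K) + jitter
  if (include_noise) {
    nv <- params$noise_variance
    if (length(nv) == 1L) nv <- rep(nv, nrow(K))
    diag(K) <- diag(K) + nv
  }
  K
}

## one-hot-encoding baseline ------------------------------------------------

# expand encoded points into [X | one-hot(H)] given category cardinalities
ohe_expand <- function(enc, n_cats) {
  X <- enc$X
  if (length(n_cats)) {
    for (j in seq_along(n_cats)) {
      Oh <- matrix(0, nrow(enc$H), n_cats[j])
      Oh[cbind(seq_len(nrow(enc$H)), enc$H[, j] + 1L)] <- 1
      X <- cbind(X, Oh)
    }
  }
  X
}

#' One-hot-encoding baseline covariance
#'
#' Matern kernel over the concatenation of the scaled continuous
#' coordinates and one-hot indicator coordinates of each categorical
#' factor; the baseline the mixed kernel is compared against.
#'
#' @param z,z_prime Encoded points (lists with `x`, `h`).
#' @param n_cats Integer vector of category counts per categorical factor.
#' @param theta Length scales over the expanded coordinates (recycled if
#'   scalar).
#' @param nu Matern smoothness.
#' @return Covariance value.
#' @export
k_ohe <- function(z, z_prime, n_cats, theta = 1, nu = 2.5) {
  expand1 <- function(z) {
    v <- z$x
    for (j in seq_along(n_cats)) {
      o <- numeric(n_cats[j]); o[z$h[j] + 1L] <- 1
      v <- c(v, o)
    }
    v
  }
  a <- expand1(z); b <- expand1(z_prime)
  th <- rep_len(theta, length(a))
  k_matern(a, b, th, nu)
}
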