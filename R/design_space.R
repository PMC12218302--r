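#' Declare a single design factor
#'
#' A design factor is one axis of the experimental design space: a
#' continuous concentration (e.g. glycerol in percent), a discrete setting
#' with a fixed menu of levels (e.g. pH), or a categorical identity choice
#' (e.g. the type of carbon co-feed).
#'
#' @param name Factor name; must be unique within a space.
#' @param kind One of `"continuous"`, `"discrete"`, `"categorical"`.
#' @param lower,upper Bounds for continuous factors.
#' @param levels Strictly increasing numeric levels for discrete factors.
#' @param categories Ordered character vector of labels for categorical
#'   factors; declaration order fixes the encoding index.
#' @param units Free-text units (e.g. `"g/L"`, `"%"`).
#' @param phase Free-text process-phase tag (e.g. `"Outgrowth"`,
#'   `"Production"`).
#' @param linked_to Optional name of a categorical factor this continuous
#'   factor is coupled with (e.g. a co-feed concentration linked to the
#'   co-feed type). Metadata only; the model treats the factor as a plain
#'   continuous dimension.
#' @return A `bo_factor` object.
#' @export
#' @examples
#' design_factor("Methanol", "continuous", lower = 0, upper = 10, units = "%")
#' design_factor("pH", "discrete", levels = c(5.75, 6.0, 6.5))
design_factor <- function(name,
                          kind = c("continuous", "discrete", "categorical"),
                          lower = NULL, upper = NULL,
                          levels = NULL, categories = NULL,
                          units = "", phase = "", linked_to = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (kind == "continuous") {
    if (is.null(lower) || is.null(upper) || !(lower < upper)) {
      stop("continuous factor '", name, "' needs lower < upper", call. = FALSE)
    }
    if (!is.null(levels) || !is.null(categories)) {
      stop("continuous factor '", name, "' must not declare levels/categories",
           call. = FALSE)
    }
  } else if (kind == "discrete") {
    if (is.null(levels) || length(levels) < 2L || any(diff(levels) <= 0)) {
      stop("discrete factor '", name,
           "' needs >= 2 strictly increasing levels", call. = FALSE)
    }
    lower <- min(levels); upper <- max(levels)
  } else {
    if (is.null(categories) || length(unique(categories)) < 2L) {
      stop("categorical factor '", name,
           "' needs >= 2 distinct categories", call. = FALSE)
    }
    categories <- as.character(categories)
    if (anyDuplicated(categories)) {
      stop("categorical factor '", name, "' has duplicate categories",
           call. = FALSE)
    }
  }
  structure(
    list(name = name, kind = kind, lower = lower, upper = upper,
         levels = levels, categories = categories, units = units,
         phase = phase, linked_to = linked_to),
    class = "bo_factor"
  )
}

#' Declare a linear equality constraint
#'
#' Constrains a weighted sum of continuous factors to a fixed value, e.g.
#' blend ratios of basal media summing to one.
#'
#' @param coefficients Named numeric vector mapping factor names to
#'   coefficients; at least one must be nonzero.
#' @param rhs Right-hand side value.
#' @param tolerance Feasibility tolerance (default `1e-6`).
#' @return A `bo_constraint` object.
#' @export
linear_constraint <- function(coefficients, rhs, tolerance = 1e-6) {
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)),
            all(nzchar(names(coefficients))), length(rhs) == 1L)
  if (all(coefficients == 0)) {
    stop("constraint needs at least one nonzero coefficient", call. = FALSE)
  }
  structure(list(coefficients = coefficients, rhs = rhs,
                 tolerance = tolerance),
            class = "bo_constraint")
}

#' Sum-to-one blend constraint
#'
#' @param factor_names Names of the blend-ratio factors.
#' @param rhs Total (default 1).
#' @param tolerance Feasibility tolerance.
#' @return A `bo_constraint`.
#' @export
constraint_sum_to_one <- function(factor_names, rhs = 1, tolerance = 1e-6) {
  co <- rep(1, length(factor_names))
  names(co) <- factor_names
  linear_constraint(co, rhs, tolerance)
}

#' Assemble a design space
#'
#' @param ... `bo_factor` objects (or a single list of them).
#' @param constraints List of `bo_constraint` objects.
#' @return A `bo_design_space`.
#' @export
#' @examples
#' space <- design_space(
#'   design_factor("Glycerol", "continuous", 0, 10, units = "%"),
#'   design_factor("CoFeed", "categorical",
#'                 categories = c("Ethanol", "Sorbitol"))
#' )
design_space <- function(..., constraints = list()) {
  factors <- list(...)
  if (length(factors) == 1L && !inherits(factors[[1L]], "bo_factor")) {
    factors <- factors[[1L]]
  }
  stopifnot(length(factors) >= 1L,
            all(vapply(factors, inherits, logical(1), "bo_factor")))
  nms <- vapply(factors, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("factor names must be unique", call. = FALSE)
  names(factors) <- nms
  if (inherits(constraints, "bo_constraint")) constraints <- list(constraints)
  kinds <- vapply(factors, `[[`, character(1), "kind")
  for (f in factors) {
    if (!is.null(f$linked_to)) {
      if (!f$linked_to %in% nms || kinds[[f$linked_to]] != "categorical") {
        stop("linked_to of '", f$name,
             "' must name an existing categorical factor", call. = FALSE)
      }
    }
  }
  for (cn in constraints) {
    stopifnot(inherits(cn, "bo_constraint"))
    bad <- setdiff(names(cn$coefficients), nms)
    if (length(bad)) {
      stop("constraint names unknown factor(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (any(kinds[names(cn$coefficients)] != "continuous")) {
      stop("constraints may only involve continuous factors", call. = FALSE)
    }
  }
  structure(list(factors = factors, constraints = constraints),
            class = "bo_design_space")
}

#' @export
print.bo_design_space <- function(x, ...) {
  cat("<bo_design_space> ", length(x$factors), " factors, ",
      length(x$constraints), " constraint(s)\n", sep = "")
  for (f in x$factors) {
    desc <- switch(f$kind,
      continuous = sprintf("[%g, %g]", f$lower, f$upper),
      discrete = paste0("{", paste(f$levels, collapse = ", "), "}"),
      categorical = paste0(length(f$categories), " categories"))
    cat("  ", format(f$name, width = 18), f$kind, " ", desc, "\n", sep = " ")
  }
  invisible(x)
}

## internal accessors -------------------------------------------------------

factor_names <- function(space) names(space$factors)

factor_kinds <- function(space) {
  vapply(space$factors, `[[`, character(1), "kind")
}

cont_names <- function(space) {
  factor_names(space)[factor_kinds(space) %in% c("continuous", "discrete")]
}

cat_names <- function(space) {
  factor_names(space)[factor_kinds(space) == "categorical"]
}

n_categorical <- function(space) length(cat_names(space))

cont_bounds <- function(space) {
  nm <- cont_names(space)
  lower <- vapply(space$factors[nm], `[[`, numeric(1), "lower")
  upper <- vapply(space$factors[nm], `[[`, numeric(1), "upper")
  cbind(lower = lower, upper = upper)
}

#' Validate candidate design points against a space
#'
#' Checks completeness, bounds, membership of discrete levels and declared
#' categories, and all linear equality constraints.
#'
#' @param space A `bo_design_space`.
#' @param points A data frame with one column per factor, one row per point.
#' @return A tibble with one row per point: `valid` (logical) and
#'   `violations` (list column of character descriptions).
#' @export
validate_points <- function(space, points) {
  points <- tibble::as_tibble(points)
  extra <- setdiff(names(points), factor_names(space))
  extra <- setdiff(extra, c("experiment_id", "iteration", "role", "target",
                            grep("^rep_", names(points), value = TRUE),
                            grep("^\\.", names(points), value = TRUE)))
  if (length(extra)) {
    stop("unknown factor name(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(points)
  viol <- rep(list(character(0)), n)
  flag <- function(idx, msgs) {
    for (i in which(idx)) viol[[i]] <<- c(viol[[i]], msgs[i])
  }
  for (f in space$factors) {
    if (!f$name %in% names(points)) {
      flag(rep(TRUE, n), rep(paste0(f$name, ": missing"), n))
      next
    }
    vals <- points[[f$name]]
    na <- is.na(vals)
    flag(na, rep(paste0(f$name, ": missing"), n))
    if (f$kind == "categorical") {
      bad <- !na & !(as.character(vals) %in% f$categories)
      flag(bad, paste0(f$name, ": unknown category '", vals, "'"))
    } else if (f$kind == "discrete") {
      num <- suppressWarnings(as.numeric(vals))
      bad <- !na & vapply(num, function(v) {
        is.na(v) || min(abs(v - f$levels)) > 1e-9
      }, logical(1))
      flag(bad, rep(paste0(f$name, ": not a declared level"), n))
    } else {
      num <- suppressWarnings(as.numeric(vals))
      bad <- !na & (is.na(num) | num < f$lower - 1e-12 |
                      num > f$upper + 1e-12)
      flag(bad, rep(paste0(f$name, ": out of bounds"), n))
    }
  }
  for (cn in space$constraints) {
    nm <- names(cn$coefficients)
    if (all(nm %in% names(points))) {
      M <- sapply(points[nm], as.numeric)
      if (is.null(dim(M))) M <- matrix(M, nrow = n)
      lhs_val <- as.numeric(M %*% cn$coefficients)
      bad <- !is.na(lhs_val) & abs(lhs_val - cn$rhs) > cn$tolerance
      flag(bad, sprintf("constraint: |%s - %g| = %.3g > %g",
                        paste(nm, collapse = "+"), cn$rhs,
                        abs(lhs_val - cn$rhs), cn$tolerance))
    }
  }
  tibble::tibble(valid = lengths(viol) == 0L, violations = viol)
}

#' Encode design points for modeling
#'
#' Continuous and discrete factors are min-max scaled to \eqn{[0,1]} by
#' their bounds (discrete: by min and max level); categorical factors map
#' to their 0-based index in declaration order. The mapping is invertible
#' via [decode_points()].
#'
#' @param space A `bo_design_space`.
#' @param points Data frame of valid points.
#' @param check Validate points first (default `TRUE`).
#' @return List with `X` (numeric matrix, scaled continuous/discrete
#'   columns) and `H` (integer matrix of 0-based category indices).
#' @export
encode_points <- function(space, points, check = TRUE) {
  points <- tibble::as_tibble(points)
  if (check) {
    vd <- validate_points(space, points)
    if (!all(vd$valid)) {
      bad <- which(!vd$valid)[1L]
      stop("invalid point (row ", bad, "): ",
           paste(vd$violations[[bad]], collapse = "; "), call. = FALSE)
    }
  }
  cn <- cont_names(space)
  b <- cont_bounds(space)
  X <- matrix(0, nrow(points), length(cn), dimnames = list(NULL, cn))
  for (j in seq_along(cn)) {
    X[, j] <- (as.numeric(points[[cn[j]]]) - b[j, 1]) / (b[j, 2] - b[j, 1])
  }
  hn <- cat_names(space)
  H <- matrix(0L, nrow(points), length(hn), dimnames = list(NULL, hn))
  for (j in seq_along(hn)) {
    H[, j] <- match(as.character(points[[hn[j]]]),
                    space$factors[[hn[j]]]$categories) - 1L
  }
  list(X = X, H = H)
}

#' Decode encoded points back to factor values
#'
#' @param space A `bo_design_space`.
#' @param encoded List with `X` and `H` as produced by [encode_points()].
#' @param snap_discrete Snap discrete factors to the nearest declared level
#'   (default `TRUE`).
#' @return Tibble with one column per factor.
#' @export
decode_points <- function(space, encoded, snap_discrete = TRUE) {
  cn <- cont_names(space)
  b <- cont_bounds(space)
  n <- if (length(cn)) nrow(encoded$X) else nrow(encoded$H)
  out <- list()
  for (j in seq_along(cn)) {
    f <- space$factors[[cn[j]]]
    val <- b[j, 1] + encoded$X[, j] * (b[j, 2] - b[j, 1])
    if (f$kind == "discrete" && snap_discrete) {
      val <- vapply(val, function(v) f$levels[which.min(abs(f$levels - v))],
                    numeric(1))
    }
    out[[cn[j]]] <- val
  }
  for (nm in cat_names(space)) {
    out[[nm]] <- space$factors[[nm]]$categories[encoded$H[, nm] + 1L]
  }
  tibble::as_tibble(out)[, factor_names(space), drop = FALSE]
}

## feasible sampling --------------------------------------------------------

rdirichlet1 <- function(n, k) {
  g <- matrix(stats::rgamma(n * k, shape = 1), n, k)
  g / rowSums(g)
}

#' Sample uniformly from the feasible region
#'
#' Unconstrained continuous factors are drawn uniformly within bounds;
#' discrete factors uniformly over their levels; categorical factors
#' uniformly over their categories. A single sum constraint over
#' nonnegative continuous factors is sampled exactly uniformly on the
#' simplex (symmetric Dirichlet, rescaled), with rejection against upper
#' bounds; general equality systems fall back to rejection sampling on the
#' constraint's affine slice.
#'
#' @param space A `bo_design_space`.
#' @param n Number of points.
#' @param seed Integer seed; fixed seed gives identical output.
#' @return Tibble of `n` valid design points.
#' @export
sample_feasible <- function(space, n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  nms <- factor_names(space)
  constrained <- unique(unlist(lapply(space$constraints,
                                      function(cn) names(cn$coefficients))))
  out <- vector("list", length(nms)); names(out) <- nms
  # unconstrained axes
  for (f in space$factors) {
    if (f$name %in% constrained) next
    out[[f$name]] <- switch(f$kind,
      continuous = stats::runif(n, f$lower, f$upper),
      discrete = sample(f$levels, n, replace = TRUE),
      categorical = sample(f$categories, n, replace = TRUE))
  }
  if (length(space$constraints) == 1L) {
    cn <- space$constraints[[1L]]
    nmc <- names(cn$coefficients)
    lows <- vapply(space$factors[nmc], `[[`, numeric(1), "lower")
    ups <- vapply(space$factors[nmc], `[[`, numeric(1), "upper")
    if (all(cn$coefficients > 0) && all(abs(lows) < 1e-12)) {
      # simplex-like: x_i = rhs * w_i / c_i, w ~ Dirichlet(1,...,1)
      k <- length(nmc)
      got <- matrix(NA_real_, 0, k)
      tries <- 0L
      while (nrow(got) < n && tries < 1000L) {
        w <- rdirichlet1(max(n, 64L), k)
        x <- sweep(w * cn$rhs, 2, cn$coefficients, "/")
        ok <- apply(x, 1L, function(r) all(r <= ups + 1e-12))
        got <- rbind(got, x[ok, , drop = FALSE])
        tries <- tries + 1L
      }
      if (nrow(got) < n) stop("constraint system appears infeasible",
                              call. = FALSE)
      got <- got[seq_len(n), , drop = FALSE]
      for (j in seq_len(k)) out[[nmc[j]]] <- got[, j]
    } else {
      out[nmc] <- sample_affine_slice(space, cn, n)
    }
  } else if (length(space$constraints) > 1L) {
    stop("multiple equality constraints are not supported for sampling",
         call. = FALSE)
  }
  pts <- tibble::as_tibble(out)[, nms, drop = FALSE]
  vd <- validate_points(space, pts)
  if (!all(vd$valid)) stop("internal: sampled infeasible point", call. = FALSE)
  pts
}

# rejection sampling on the affine slice of one general equality constraint
sample_affine_slice <- function(space, cn, n) {
  nmc <- names(cn$coefficients)
  k <- length(nmc)
  lows <- vapply(space$factors[nmc], `[[`, numeric(1), "lower")
  ups <- vapply(space$factors[nmc], `[[`, numeric(1), "upper")
  a <- cn$coefficients
  got <- matrix(NA_real_, 0, k)
  for (tries in seq_len(5000L)) {
    x <- matrix(stats::runif(64L * (k - 1L)), 64L, k - 1L)
    x <- sweep(sweep(x, 2, (ups - lows)[-k], "*"), 2, lows[-k], "+")
    last <- (cn$rhs - x %*% a[-k]) / a[k]
    ok <- last >= lows[k] - 1e-12 & last <= ups[k] + 1e-12
    got <- rbind(got, cbind(x, last)[ok, , drop = FALSE])
    if (nrow(got) >= n) break
  }
  if (nrow(got) < n) stop("constraint system appears infeasible", call. = FALSE)
  got <- got[seq_len(n), , drop = FALSE]
  stats::setNames(lapply(seq_len(k), function(j) got[, j]), nmc)
}
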