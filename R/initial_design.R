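#' Latin hypercube design over the continuous/discrete factors
#'
#' Stratified space-filling design: for each continuous axis, each of the
#' `n` equal-width bins contains exactly one point, placed uniformly at
#' random within its bin. Discrete factors are sampled on their
#' \[min level, max level\] range and snapped to the nearest declared
#' level. Constrained spaces are refused; use [sample_feasible()] there.
#'
#' @param space A `bo_design_space` without equality constraints.
#' @param n Number of design points.
#' @param seed Integer seed.
#' @return Tibble of points over the continuous/discrete factors only.
#' @export
design_lhs <- function(space, n, seed = NULL) {
  stopifnot(n >= 1)
  if (length(space$constraints)) {
    stop("space has equality constraints; use sample_feasible()",
         call. = FALSE)
  }
  cn <- cont_names(space)
  if (!length(cn)) stop("no continuous/discrete factors to sample",
                        call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  U <- lhs::randomLHS(n, length(cn))
  b <- cont_bounds(space)
  out <- list()
  for (j in seq_along(cn)) {
    f <- space$factors[[cn[j]]]
    val <- b[j, 1] + U[, j] * (b[j, 2] - b[j, 1])
    if (f$kind == "discrete") {
      val <- vapply(val, function(v) f$levels[which.min(abs(f$levels - v))],
                    numeric(1))
    }
    out[[cn[j]]] <- val
  }
  tibble::as_tibble(out)
}

#' Iteration-0 initial design over a mixed space
#'
#' Continuous/discrete coordinates come from a Latin hypercube (or from
#' uniform feasible sampling when the space carries equality constraints);
#' each categorical coordinate is drawn uniformly over its declared
#' categories, from an RNG stream independent of the continuous one so
#' category-count changes do not perturb continuous reproducibility.
#'
#' @param space A `bo_design_space`.
#' @param n Number of points.
#' @param seed Integer seed.
#' @return Tibble of `n` valid design points.
#' @export
initial_design <- function(space, n, seed = 1) {
  stopifnot(n >= 1)
  hn <- cat_names(space)
  cn <- cont_names(space)
  if (length(space$constraints)) {
    pts <- sample_feasible(space, n, seed = seed)
    if (!length(hn)) return(pts)
    cont_part <- pts[, cn, drop = FALSE]
  } else if (length(cn)) {
    cont_part <- design_lhs(space, n, seed = seed)
  } else {
    cont_part <- tibble::tibble(.rows = n)
  }
  out <- cont_part
  if (length(hn)) {
    # independent stream for the categorical draws
    set.seed(seed + 987653L)
    for (nm in hn) {
      out[[nm]] <- sample(space$factors[[nm]]$categories, n, replace = TRUE)
    }
  }
  out <- tibble::as_tibble(out)[, factor_names(space), drop = FALSE]
  vd <- validate_points(space, out)
  stopifnot(all(vd$valid))
  out
}
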