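#' Replicate-averaged modeling target
#'
#' @param replicates Numeric vector of replicate readings (>= 1 finite
#'   value).
#' @return Arithmetic mean of the replicates.
#' @export
replicate_target <- function(replicates) {
  x <- replicates[is.finite(replicates)]
  if (!length(x)) stop("no finite replicate values", call. = FALSE)
  mean(x)
}

#' Specific productivity
#'
#' Secreted-protein titer normalized by culture density.
#'
#' @param titer Titer in mg/L.
#' @param od600 Optical density at 600 nm (> 0).
#' @return Specific productivity in mg/L/OD600.
#' @export
#' @examples
#' specific_productivity(120, 10) # 12
specific_productivity <- function(titer, od600) {
  if (any(od600 <= 0)) stop("od600 must be positive", call. = FALSE)
  titer / od600
}

#' Aggregated homeostasis target
#'
#' Combines culture viability with the balance of lymphocyte
#' subpopulations: `Target = ViabilityFactor * sum(Frac_j)` over
#' j in \{NK, T, B\}, where the viability factor is `V` when `V <= 1` and
#' `1/V` when `V > 1`, penalizing both cell loss and expansion
#' symmetrically. Inputs are treated as ratios (post- over pre-culture).
#'
#' @param viability Positive viability ratio.
#' @param fractions Numeric vector (length 3, e.g. named NK/T/B) of
#'   nonnegative subpopulation fractions.
#' @return The scalar homeostasis target.
#' @export
#' @examples
#' homeostasis_target(0.8, c(NK = 0.3, T = 0.4, B = 0.1)) # 0.64
homeostasis_target <- function(viability, fractions) {
  if (viability <= 0) stop("viability must be positive", call. = FALSE)
  if (any(fractions < 0)) stop("fractions must be nonnegative", call. = FALSE)
  vf <- if (viability <= 1) viability else 1 / viability
  vf * sum(fractions)
}
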