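#' Extend a design space with new factors
#'
#' @param old A `bo_design_space`.
#' @param new_factors List of `bo_factor` objects with names disjoint from
#'   the old ones.
#' @return The union space: old factors in their original order followed
#'   by the new factors; constraints carried over.
#' @export
extend_space <- function(old, new_factors) {
  if (inherits(new_factors, "bo_factor")) new_factors <- list(new_factors)
  if (!length(new_factors)) return(old)
  new_names <- vapply(new_factors, `[[`, character(1), "name")
  clash <- intersect(new_names, factor_names(old))
  if (length(clash)) {
    stop("factor name collision: ", paste(clash, collapse = ", "),
         call. = FALSE)
  }
  design_space(c(old$factors, new_factors), constraints = old$constraints)
}

#' Embed campaign history into an extended space
#'
#' Maps every historical experiment onto the extended space with the new
#' factors fixed at the conditions under which history was generated
#' (typically the benchmark settings), carrying targets and noise
#' unchanged. With neutral length scales on the new axes, the embedded
#' model's predictions at historical points match the original model's.
#'
#' @param ledger Historical ledger tibble (rows on the old space).
#' @param old_space,new_space The original and extended
#'   `bo_design_space`s.
#' @param fill_values Named list/vector giving a value for every new
#'   factor.
#' @return Ledger tibble on the new space, row count conserved.
#' @export
embed_history <- function(ledger, old_space, new_space, fill_values) {
  new_names <- setdiff(factor_names(new_space), factor_names(old_space))
  miss <- setdiff(new_names, names(fill_values))
  if (length(miss)) {
    stop("missing fill value(s) for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(ledger)
  for (nm in new_names) {
    v <- fill_values[[nm]]
    out[[nm]] <- if (new_space$factors[[nm]]$kind == "categorical") {
      rep(as.character(v), nrow(out))
    } else rep(as.numeric(v), nrow(out))
  }
  meta <- intersect(c("experiment_id", "iteration", "role"), names(out))
  cols <- c(meta, factor_names(new_space),
            grep("^rep_", names(out), value = TRUE),
            intersect("target", names(out)))
  out[, cols, drop = FALSE]
}

#' Warm-start a campaign on an extended design space
#'
#' Uses the existing campaign's data, embedded into the new space, as the
#' prior for the new campaign: the surrogate is refit on the embedded
#' history and iteration-0 suggestions come straight from the acquisition
#' function — no new space-filling design is planned. Bandit state is
#' carried over for shared categorical arms.
#'
#' @param old_campaign A `bo_campaign` with executed history.
#' @param new_space The extended `bo_design_space`.
#' @param fill_values Named values for the new factors under which the
#'   history was generated.
#' @param config An `acq_config` for the new campaign (default: the old
#'   campaign's).
#' @return A new `bo_campaign` on `new_space` with the embedded history
#'   ingested and the model fitted.
#' @export
warm_start_campaign <- function(old_campaign, new_space, fill_values,
                                config = NULL) {
  if (is.null(config)) config <- old_campaign$config
  hist <- dplyr::filter(old_campaign$ledger,
                        .data$role %in% c("executed", "control"),
                        !is.na(.data$target))
  if (nrow(hist) < 2L) stop("old campaign has no usable history",
                            call. = FALSE)
  emb <- embed_history(hist, old_campaign$space, new_space, fill_values)
  camp <- campaign_new(new_space, config, direction = old_campaign$direction,
                       seed = old_campaign$seed,
                       noise_variance = old_campaign$noise_variance)
  camp$control_pool <- old_campaign$control_pool
  camp$ledger <- emb
  camp$iteration <- max(emb$iteration, 0L)
  camp$bandit <- old_campaign$bandit
  campaign_fit(camp)
}
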