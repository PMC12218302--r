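#' Plot a fitted surrogate: predicted vs observed
#'
#' @param object A `bo_gp`.
#' @param ... Unused.
#' @return A ggplot: training observations against posterior means with
#'   +/- 2 sd bars.
#' @method autoplot bo_gp
#' @export
autoplot.bo_gp <- function(object, ...) {
  pr <- stats::predict(object, object$data)
  df <- tibble::tibble(observed = object$y_raw, .pred = pr$.pred,
                       .pred_sd = pr$.pred_sd)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed, y = .data$.pred)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$.pred - 2 * .data$.pred_sd,
                                        ymax = .data$.pred + 2 * .data$.pred_sd),
                           width = 0, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "observed target", y = "posterior mean (+/- 2 sd)",
                  title = "Surrogate fit")
}

#' Plot campaign progress over iterations
#'
#' @param object A `bo_campaign`.
#' @param ... Unused.
#' @return A ggplot of executed targets per iteration with the running
#'   best overlaid.
#' @method autoplot bo_campaign
#' @export
autoplot.bo_campaign <- function(object, ...) {
  ex <- dplyr::filter(object$ledger, .data$role == "executed")
  if (!nrow(ex)) stop("no executed experiments to plot", call. = FALSE)
  y <- internal_target(object, ex$target)
  ex$best <- cummax(y) * if (object$direction == "minimize") -1 else 1
  ggplot2::ggplot(ex, ggplot2::aes(x = factor(.data$iteration),
                                   y = .data$target)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::labs(x = "iteration", y = "target",
                  title = "Campaign progression")
}

#' Plot a strategy comparison
#'
#' @param comparison Output of [compare_strategies()].
#' @return A ggplot of best-found distributions per strategy.
#' @export
plot_strategy_comparison <- function(comparison) {
  ggplot2::ggplot(comparison, ggplot2::aes(x = .data$strategy,
                                           y = .data$best_found)) +
    ggplot2::geom_boxplot(fill = "grey90") +
    ggplot2::labs(x = "strategy", y = "best found at equal budget",
                  title = "Strategy comparison")
}
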