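# ggplot2 displays for the result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a disparity-through-time curve
#'
#' @param object A `radburst_dtt` tibble from [dtt()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.radburst_dtt <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rel_time,
                                       y = .data$disparity)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::labs(x = "Relative time since root",
                  y = "Average subclade disparity") +
    ggplot2::theme_minimal()
}

#' Plot a DTT curve against its null envelope
#'
#' Observed curve over the null median with the 5-95% quantile ribbon.
#'
#' @param object A `radburst_dtt_null` object from [dtt_null()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.radburst_dtt_null <- function(object, ...) {
  cv <- object$curve
  ggplot2::ggplot(cv, ggplot2::aes(x = .data$rel_time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q05, ymax = .data$q95),
                         fill = "grey80") +
    ggplot2::geom_step(ggplot2::aes(y = .data$null_median),
                       linetype = "dashed", direction = "hv") +
    ggplot2::geom_step(ggplot2::aes(y = .data$observed), colour = "#d55e00",
                       direction = "hv") +
    ggplot2::labs(
      x = "Relative time since root", y = "Average subclade disparity",
      subtitle = sprintf("MDI = %.3f vs %s null (n = %d)", object$mdi,
                         object$model, object$n_sims)
    ) +
    ggplot2::theme_minimal()
}

#' Lineage-through-time plot
#'
#' @param tree An ultrametric `phylo`, or a list of them (overlaid).
#' @param log_lineages Plot the lineage count on a log axis (default TRUE).
#' @return A ggplot.
#' @export
plot_ltt <- function(tree, log_lineages = TRUE) {
  if (inherits(tree, "phylo")) tree <- list(tree)
  df <- purrr::imap_dfr(tree, function(tr, i) {
    dplyr::mutate(ltt(tr), tree = as.character(i))
  })
  p <- ggplot2::ggplot(df, ggplot2::aes(x = -.data$age_bp,
                                        y = .data$lineages,
                                        group = .data$tree)) +
    ggplot2::geom_step(alpha = min(1, 5 / length(tree)), direction = "hv") +
    ggplot2::labs(x = "Time before present (myr)", y = "Lineages") +
    ggplot2::theme_minimal()
  if (log_lineages) p <- p + ggplot2::scale_y_log10()
  p
}

#' Density plot of MDI values by simulation condition
#'
#' @param experiment Tibble from [run_stage_experiment()].
#' @return A ggplot faceted by `alpha` with one density per stage.
#' @export
plot_mdi_density <- function(experiment) {
  ggplot2::ggplot(experiment, ggplot2::aes(x = .data$mdi,
                                           colour = .data$stage)) +
    ggplot2::geom_density() +
    ggplot2::facet_wrap(~alpha, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Morphological disparity index", y = "Density") +
    ggplot2::theme_minimal()
}
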