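#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Training history plot
#'
#' Training loss components and validation RMSE per epoch.
#'
#' @param object a `cads_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.cads_fit <- function(object, ...) {
  h <- object$history |>
    tidyr::pivot_longer(cols = c("train_loss", "train_loss_causal",
                                 "train_loss_trivial", "val_rmse"),
                        names_to = "series", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2,
                        colour = "grey50") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL,
                  title = "Dual-branch training history") +
    ggplot2::theme_minimal()
}

#' Causal-score volcano plot
#'
#' Per-gene mean causal score against its standard deviation across cells
#' and runs. Genes far from mean 0.5 with low spread are candidate
#' pan-context causal genes.
#'
#' @param object a `cads_score_stats` tibble from [causal_score_stats()].
#' @param highlight optional character vector of gene ids to label.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.cads_score_stats <- function(object, highlight = NULL, ...) {
  object$flag <- object$gene_id %in% highlight
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$mean, y = .data$sd)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$flag), alpha = 0.6,
                        show.legend = !is.null(highlight)) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = 2, colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "mean causal score", y = "sd of causal score",
                  colour = "highlighted",
                  title = "Per-gene causal score distribution") +
    ggplot2::theme_minimal()
  p
}

#' Few-shot robustness plot
#'
#' Held-out metric against training fraction with the fitted least-squares
#' lines, one facet per metric.
#'
#' @param object a `cads_fewshot` from [fewshot_curve()].
#' @param metrics metrics to display.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.cads_fewshot <- function(object, metrics = c("rmse", "pcc"), ...) {
  pts <- object$points |>
    tidyr::pivot_longer(cols = c("mae", "rmse", "r2", "pcc"),
                        names_to = "metric", values_to = "value") |>
    dplyr::filter(.data$metric %in% metrics)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fraction, y = .data$value,
                                    colour = .data$model)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "training fraction", y = NULL, colour = NULL,
                  title = "Few-shot robustness") +
    ggplot2::theme_minimal()
}
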