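#' Plot benchmark recovery metrics
#'
#' Dot plot of R2, MAE, O95 and FW95 per kinetic parameter, faceted by metric,
#' colored by method.
#'
#' @param object a `burst_metrics` tibble from [compute_metrics()] (or several
#'   row-bound together).
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot burst_metrics
#' @export
autoplot.burst_metrics <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = c("r2", "mae", "o95", "fw95"),
                              names_to = "metric", values_to = "value")
  long$metric <- factor(toupper(long$metric),
                        levels = c("R2", "MAE", "O95", "FW95"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$parameter, y = .data$value,
                                     color = .data$method)) +
    ggplot2::geom_point(size = 2, position = ggplot2::position_dodge(0.4)) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Parameter-recovery metrics (log10 scale)") +
    ggplot2::theme_bw()
}

#' Boxplots of logarithmic residuals per parameter
#'
#' The classic benchmark view: per-method boxplots of `log10(estimate/truth)`
#' for each kinetic parameter and the burst size. A bare method applied to
#' capture-thinned data shows up as a box displaced by roughly
#' `log10(mean capture efficiency)`.
#'
#' @param estimates estimate tibble(s) from the `infer_*` functions (row-bind
#'   several methods to compare them).
#' @param truth [kinetic_params()] table.
#' @return a ggplot object.
#' @export
plot_residuals <- function(estimates, truth) {
  if (inherits(estimates, "burst_abc")) estimates <- estimates$estimates
  joined <- dplyr::inner_join(
    estimates,
    dplyr::rename_with(truth, ~ paste0(.x, "_true"), -"gene"),
    by = "gene") |>
    dplyr::filter(.data$status == "ok")
  long <- dplyr::bind_rows(lapply(
    c("ksyn", "kon", "koff", "burst_size"),
    function(p) tibble::tibble(
      method = joined$method, parameter = p,
      residual = log10(joined[[p]] / joined[[paste0(p, "_true")]]))))
  long$parameter <- factor(long$parameter,
                           levels = c("ksyn", "kon", "koff", "burst_size"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$parameter, y = .data$residual,
                                     fill = .data$method)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey40") +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::labs(x = NULL, y = "log10(estimate / truth)") +
    ggplot2::theme_bw()
}

#' Dropout rate against mean expression
#'
#' @param dropout_table tibble from [dropout_vs_mean()].
#' @return a ggplot object.
#' @export
plot_dropout_curve <- function(dropout_table) {
  ggplot2::ggplot(dropout_table,
                  ggplot2::aes(x = .data$mean_expression, y = .data$dropout)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "mean expression (nonmissing)", y = "zero fraction") +
    ggplot2::theme_bw()
}

#' Plot mean counts by assigned model
#'
#' Boxplots of per-gene mean counts grouped by the AIC-assigned model;
#' genes captured by the Poisson law sit at the low-expression end.
#'
#' @param object a `burst_selection` object.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot burst_selection
#' @export
autoplot.burst_selection <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$assigned, y = .data$mean_count)) +
    ggplot2::geom_boxplot() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "assigned model (lowest AIC)", y = "mean count") +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
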