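#' Plot binary power-amplitude states as a raster
#'
#' @param object a [binary_states()] object.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.binary_states <- function(object, ...) {
  df <- tidyr::expand_grid(channel = seq_len(nrow(object$states)),
                           t = seq_len(ncol(object$states)))
  df$on <- as.vector(object$states)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$channel,
                                   fill = factor(.data$on))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(`0` = "grey95", `1` = "grey20"),
                               name = "state") +
    ggplot2::labs(x = "sample", y = "channel",
                  title = sprintf("power-amplitude states (%s)", object$band)) +
    ggplot2::theme_minimal()
}

#' Plot a functional connectivity matrix as a heatmap
#'
#' @param object an [fc_matrix()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.fc_matrix <- function(object, ...) {
  m <- unclass(object)
  df <- tidyr::expand_grid(i = seq_len(nrow(m)), j = seq_len(ncol(m)))
  df$value <- as.vector(m)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = attr(object, "method")) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a stability curve
#'
#' Mean matrix-norm difference between co-activation matrices estimated from
#' disjoint n- and (n-1)-hour segment sets, with standard-error ribbon.
#'
#' @param object a [stability_curve()] tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.stability_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n_hours,
                                       y = .data$mean_norm_diff)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean_norm_diff - .data$stderr,
      ymax = .data$mean_norm_diff + .data$stderr), alpha = 0.3) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "hours of data (n)",
                  y = "mean norm difference (n vs n-1)") +
    ggplot2::theme_minimal()
}

#' Plot empirical against model state probabilities
#'
#' Log-log scatter of the empirical probability of each observed state against
#' the silent-state-anchored model estimate; points on the identity line
#' indicate a good fit.
#'
#' @param object a `state_prob_table` from [estimate_state_probabilities()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.state_prob_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$p_empirical,
                                       y = .data$p_model,
                                       colour = .data$n_on)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::scale_colour_viridis_c(name = "channels on") +
    ggplot2::labs(x = "empirical probability", y = "model probability") +
    ggplot2::theme_minimal()
}

#' Plot a ROC curve
#'
#' @param object a `roc` object from [roc_auc()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot per-band coupling results from a pipeline run
#'
#' @param coupling the `coupling` tibble from [run_pipeline()].
#' @param stat `"r_structure_function"` or `"auc"`.
#' @return a ggplot object.
#' @export
plot_coupling <- function(coupling, stat = c("r_structure_function", "auc")) {
  stat <- match.arg(stat)
  ggplot2::ggplot(coupling,
                  ggplot2::aes(x = .data$method, y = .data[[stat]],
                               fill = .data$band)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = stat) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
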