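# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @export
tidy.connectome_comparison <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Glance at a subject comparison
#'
#' @param x A `connectome_comparison` from [compare_subject()].
#' @param ... Unused.
#' @return A one-row tibble: subject, number of models, instances, metrics,
#'   and count of undefined metric values.
#' @export
glance.connectome_comparison <- function(x, ...) {
  tibble::tibble(
    subject_id = x$subject_id[1L],
    group = x$group[1L],
    n_models = dplyr::n_distinct(x$model),
    n_instances = max(x$instance),
    n_metrics = dplyr::n_distinct(x$metric),
    n_missing = sum(is.na(x$value))
  )
}

#' @export
tidy.group_summary <- function(x, ...) {
  tibble::as_tibble(x)
}

metric_labeller <- ggplot2::as_labeller(c(
  rgf_distance = "RGF distance",
  gdd_agreement = "GDD agreement",
  pearson_degree_corr = "Pearson r of P(k)",
  path_diff_pct = "PathDiff (%)",
  clust_diff_pct = "ClustDiff (%)",
  small_worldness = "Small-worldness",
  global_efficiency = "Global efficiency"
))

#' Plot per-instance metric values for one subject
#'
#' Boxplots of each similarity metric across model instances, one facet per
#' metric.
#'
#' @param object A `connectome_comparison` from [compare_subject()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.connectome_comparison <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), !is.na(.data$value))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~metric, scales = "free_y",
                        labeller = metric_labeller) +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = sprintf("Model fit to subject %s", object$subject_id[1L])
    ) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot group-level model-fit summaries
#'
#' Mean and +-1 sd per model and group, one facet per metric — the graphical
#' analogue of the group tables.
#'
#' @param object A `group_summary` from [aggregate_group()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.group_summary <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$mean,
                                   colour = .data$group)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(width = 0.5), fatten = 2
    ) +
    ggplot2::facet_wrap(~metric, scales = "free_y",
                        labeller = metric_labeller) +
    ggplot2::labs(x = NULL, y = "mean ± sd over subjects",
                  colour = "group") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
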