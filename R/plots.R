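#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-repetition cross-validated accuracies
#'
#' Boxplot of the repetition accuracy distribution, one box per classifier
#' when given a list from [run_discrimination()].
#'
#' @param object a `skill_cv` or a named list of them.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.skill_cv <- function(object, ...) {
  plot_accuracy(list(object))
}

#' @rdname autoplot.skill_cv
#' @param cv_list named list of `skill_cv` objects.
#' @export
plot_accuracy <- function(cv_list, ...) {
  df <- purrr::map_dfr(cv_list, tidy)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$classifier, y = .data$accuracy)) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::labs(x = NULL, y = "accuracy per repetition",
                  title = "Nested repeated cross-validated accuracy") +
    ggplot2::theme_minimal()
}

#' Loading plot of a fitted PCA
#'
#' Metrics positioned by their loadings on two chosen components, the
#' standard reading aid for which metric families drive each component.
#'
#' @param object a `mocap_pca`.
#' @param components length-2 integer vector of component numbers.
#' @param label_top number of largest-magnitude loadings to label.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.mocap_pca <- function(object, components = c(1, 2), label_top = 12, ...) {
  pcs <- paste0("PC", components)
  df <- object$loadings
  mag <- sqrt(df[[pcs[1]]]^2 + df[[pcs[2]]]^2)
  df$label <- ifelse(rank(-mag) <= label_top, df$metric, "")
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[pcs[1]]], y = .data[[pcs[2]]])) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::geom_segment(ggplot2::aes(xend = 0, yend = 0), alpha = 0.3) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 2.8,
                       vjust = -0.6) +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", pcs[1],
                  100 * object$explained_variance[components[1]]),
      y = sprintf("%s (%.1f%%)", pcs[2],
                  100 * object$explained_variance[components[2]]),
      title = "PCA loading plot") +
    ggplot2::theme_minimal()
}

#' Screening overview plot
#'
#' Per-metric Kruskal-Wallis evidence as -log10 p, coloured by retention.
#'
#' @param object a `metric_screen`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.metric_screen <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$metric <- stats::reorder(df$metric, -df$p_value)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = -log10(.data$p_value),
                                   fill = .data$retained)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "alpha")),
                        linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(-log[10]~p),
                  title = "Kruskal-Wallis metric screen") +
    ggplot2::theme_minimal()
}

#' Plot an instrument track in the working plane
#'
#' Tip trajectory projected on the plane perpendicular to the depth axis,
#' coloured by time.
#'
#' @param object a `mocap_track` or `mocap_kin`.
#' @param depth_axis depth axis to project out.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.mocap_track <- function(object, depth_axis = "z", ...) {
  axes <- setdiff(c("x", "y", "z"), depth_axis)
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data[[axes[1]]], y = .data[[axes[2]]],
                               colour = .data$t)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s (%s hand)", attr(object, "instrument_id"),
                                  attr(object, "hand")),
                  x = paste(axes[1], "(mm)"), y = paste(axes[2], "(mm)"),
                  colour = "t (s)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mocap_kin <- autoplot.mocap_track

#' @importFrom rlang .data
NULL
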