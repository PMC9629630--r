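#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy and summarize fitted result objects
#'
#' Broom-style accessors: `tidy()` returns one row per elementary result
#' (per-repetition accuracy, per-metric screening test, per-loading entry),
#' `glance()` one row of headline summaries.
#'
#' @param x a `skill_cv`, `metric_screen`, `mocap_pca` or
#'   `model_comparison` object.
#' @param ... unused.
#' @return A tibble.
#' @name lapskill-tidiers
NULL

#' @rdname lapskill-tidiers
#' @export
tidy.skill_cv <- function(x, ...) {
  tibble::tibble(classifier = attr(x, "kind"),
                 repetition = x$repetition,
                 accuracy = x$accuracy)
}

#' @rdname lapskill-tidiers
#' @export
glance.skill_cv <- function(x, ...) {
  q <- stats::quantile(x$accuracy, c(0.25, 0.5, 0.75), names = FALSE)
  tibble::tibble(classifier = attr(x, "kind"),
                 scheme = attr(x, "scheme") %||% NA_character_,
                 repetitions = nrow(x),
                 median_accuracy = q[2], q1 = q[1], q3 = q[3])
}

#' @rdname lapskill-tidiers
#' @export
tidy.metric_screen <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname lapskill-tidiers
#' @export
glance.metric_screen <- function(x, ...) {
  tibble::tibble(n_metrics = nrow(x), n_retained = sum(x$retained),
                 alpha = attr(x, "alpha"), holm = attr(x, "holm"))
}

#' @rdname lapskill-tidiers
#' @export
tidy.mocap_pca <- function(x, ...) {
  tidyr::pivot_longer(x$loadings, -"metric", names_to = "component",
                      values_to = "loading")
}

#' @rdname lapskill-tidiers
#' @export
glance.mocap_pca <- function(x, ...) {
  tibble::tibble(n_metrics = nrow(x$loadings),
                 n_components = length(x$explained_variance),
                 pc1_variance = x$explained_variance[1],
                 pc2_variance = if (length(x$explained_variance) > 1)
                   x$explained_variance[2] else NA_real_)
}

#' @rdname lapskill-tidiers
#' @export
tidy.model_comparison <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$pairwise, test = "wilcoxon_signed_rank", .before = 1),
    tibble::tibble(test = "friedman", pair = "omnibus",
                   statistic = x$friedman$statistic,
                   p_value = x$friedman$p_value, degenerate = FALSE)
  )
}

#' @rdname lapskill-tidiers
#' @export
glance.model_comparison <- function(x, ...) {
  best <- x$summary[which.max(x$summary$median), ]
  tibble::tibble(best_classifier = best$classifier,
                 best_median_accuracy = best$median,
                 friedman_p = x$friedman$p_value)
}
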