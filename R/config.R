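#' Analysis run configuration
#'
#' One object carries every tunable of the pipeline: the Savitzky-Golay
#' filter settings, the depth axis convention, gripper event detection
#' thresholds, the screening significance level, and the nested repeated
#' cross-validation layout with the classifier hyperparameter grids.
#'
#' @param window Savitzky-Golay window length, odd samples (default 9, i.e.
#'   0.3 s at 30 Hz).
#' @param polyorder Savitzky-Golay polynomial order (>= 3 so jerk is
#'   estimable; must be `< window`).
#' @param depth_axis which coordinate is the viewing/depth axis.
#' @param grip_threshold,grip_hysteresis gripper event threshold and
#'   hysteresis half-width, degrees.
#' @param bd_lag_window 0 for zero-lag bimanual-dexterity correlation;
#'   positive seconds to use the maximum cross-correlation within that lag.
#' @param alpha significance level of the Kruskal-Wallis screen.
#' @param holm apply a Holm correction across metrics before screening.
#' @param outer_k,inner_k outer and inner fold counts of the nested CV.
#' @param repetitions number of repetitions of the whole nested CV.
#' @param grids hyperparameter grids, see [default_grids()].
#' @param seed base seed for fold generation.
#' @return A list of class `run_config`.
#' @export
run_config <- function(window = 9, polyorder = 3, depth_axis = "z",
                       grip_threshold = 20, grip_hysteresis = 5,
                       bd_lag_window = 0,
                       alpha = 0.05, holm = FALSE,
                       outer_k = 10, inner_k = 10, repetitions = 100,
                       grids = default_grids(), seed = 1L) {
  depth_axis <- match.arg(depth_axis, c("x", "y", "z"))
  if (window %% 2 != 1 || window <= polyorder) {
    stop("window must be odd and greater than polyorder", call. = FALSE)
  }
  if (polyorder < 3) stop("polyorder must be >= 3", call. = FALSE)
  if (outer_k < 2 || inner_k < 2) stop("fold counts must be >= 2", call. = FALSE)
  if (repetitions < 1) stop("repetitions must be >= 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  stopifnot(all(c("svm", "pca_svm", "gbdt") %in% names(grids)))
  structure(list(window = window, polyorder = polyorder,
                 depth_axis = depth_axis,
                 grip_threshold = grip_threshold,
                 grip_hysteresis = grip_hysteresis,
                 bd_lag_window = bd_lag_window,
                 alpha = alpha, holm = holm,
                 outer_k = outer_k, inner_k = inner_k,
                 repetitions = repetitions, grids = grids,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Default hyperparameter grids for the three classifiers
#'
#' Radial-kernel SVM over regularization cost and kernel scale; PCA-SVM adds
#' the retained-variance fraction of the principal-component reduction; the
#' gradient-boosted tree grid spans learning rate, tree count and tree depth.
#'
#' @return Named list of data frames, one grid row per candidate.
#' @export
default_grids <- function() {
  svm <- expand.grid(cost = c(0.1, 1, 10, 100),
                     gamma = c(0.001, 0.01, 0.1, 1),
                     KEEP.OUT.ATTRS = FALSE)
  list(
    svm = svm,
    pca_svm = expand.grid(cost = c(0.1, 1, 10, 100),
                          gamma = c(0.001, 0.01, 0.1, 1),
                          retained_variance = c(0.7, 0.8, 0.9, 0.95),
                          KEEP.OUT.ATTRS = FALSE),
    gbdt = expand.grid(learning_rate = c(0.05, 0.1),
                       n_trees = c(50, 100, 200),
                       max_depth = c(3, 4, 5),
                       KEEP.OUT.ATTRS = FALSE)
  )
}

#' Read / write a run configuration as YAML
#'
#' The YAML file mirrors the [run_config()] fields; grids are stored as
#' named lists of candidate values and expanded to full grids on read.
#'
#' @param path YAML file path.
#' @return A `run_config` (read) or `path` invisibly (write).
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  grids <- if (!is.null(y$grids)) {
    lapply(y$grids, function(g) expand.grid(g, KEEP.OUT.ATTRS = FALSE))
  } else {
    default_grids()
  }
  args <- y[setdiff(names(y), "grids")]
  known <- names(formals(run_config))
  unknown <- setdiff(names(args), known)
  if (length(unknown)) {
    stop("unknown config field: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(run_config, c(args, list(grids = grids)))
}

#' @param config a `run_config`.
#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  y <- unclass(config)
  y$grids <- lapply(config$grids, function(g) {
    lapply(as.list(g), function(col) sort(unique(col)))
  })
  yaml::write_yaml(y, path)
  invisible(path)
}
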