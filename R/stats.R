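#' Robust Z-score normalization
#'
#' Scales each metric column by its median and normalized interquartile
#' range, `z = (x - median) / NIQR` with `NIQR = 0.7414 * IQR`, which makes
#' the NIQR a consistent estimate of the standard deviation under normality
#' while being insensitive to outliers. Quartiles use linear interpolation
#' (type 7), fixed so the transform is reproducible bit-for-bit. Columns
#' with zero IQR are mapped to all zeros and flagged as degenerate.
#'
#' `robust_z_fit()` estimates the per-column parameters and
#' `robust_z_apply()` applies them to (possibly different) data - the split
#' used inside cross-validation so that test rows never inform the scaling.
#'
#' @param features a feature matrix (or any data frame with numeric columns).
#' @param cols columns to normalize; defaults to [metric_columns()].
#' @return For `robust_z_fit()`, a tibble of class `robust_z_params` with
#'   columns `metric`, `median`, `iqr`, `niqr`, `degenerate`. For
#'   `robust_z_apply()` and `robust_z_normalize()`, the input with those
#'   columns replaced by robust Z-scores; `robust_z_normalize()` attaches the
#'   parameters as attribute `"params"`.
#' @export
robust_z_fit <- function(features, cols = metric_columns(features)) {
  core <- rz_core_fit(as.matrix(features[cols]))
  params <- tibble::tibble(metric = cols, median = core$median,
                           iqr = core$iqr, niqr = core$niqr,
                           degenerate = core$degenerate)
  structure(params, class = c("robust_z_params", class(tibble::tibble())))
}

# matrix core shared by the public interface and the cross-validation loop
rz_core_fit <- function(x) {
  q <- apply(x, 2, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) stop("empty column", call. = FALSE)
    stats::quantile(col, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  })
  iqr <- q[3, ] - q[1, ]
  list(median = q[2, ], iqr = iqr, niqr = 0.7414 * iqr, degenerate = iqr == 0)
}

rz_core_apply <- function(x, core) {
  z <- sweep(x, 2, core$median)
  scale_v <- ifelse(core$degenerate, 1, core$niqr)
  z <- sweep(z, 2, scale_v, `/`)
  if (any(core$degenerate)) z[, core$degenerate] <- 0
  z
}

#' @param params a `robust_z_params` from `robust_z_fit()`.
#' @rdname robust_z_fit
#' @export
robust_z_apply <- function(features, params) {
  for (i in seq_len(nrow(params))) {
    ch <- params$metric[i]
    features[[ch]] <- if (params$degenerate[i]) {
      rep(0, nrow(features))
    } else {
      (features[[ch]] - params$median[i]) / params$niqr[i]
    }
  }
  features
}

#' @rdname robust_z_fit
#' @export
robust_z_normalize <- function(features, cols = metric_columns(features)) {
  params <- robust_z_fit(features, cols)
  out <- robust_z_apply(features, params)
  attr(out, "params") <- params
  out
}

#' Kruskal-Wallis omnibus rank test
#'
#' Thin wrapper around [stats::kruskal.test()] returning a tidy one-row
#' tibble: rank-based H with tie correction and the chi-square approximation
#' with `groups - 1` degrees of freedom.
#'
#' @param values numeric vector.
#' @param groups group labels (factor or character), same length.
#' @return One-row tibble with `statistic`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) stop("need at least 2 nonempty groups", call. = FALSE)
  if (length(unique(values)) == 1) {
    return(tibble::tibble(statistic = 0, df = nlevels(groups) - 1L, p_value = 1))
  }
  k <- stats::kruskal.test(values, groups)
  tibble::tibble(statistic = unname(k$statistic), df = unname(k$parameter),
                 p_value = k$p.value)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two samples; `U` counts pairs where the
#' first sample exceeds the second (ties counted half). The p-value is exact
#' for small tie-free samples and uses the normal approximation with tie and
#' continuity corrections otherwise (the [stats::wilcox.test()] policy).
#'
#' @param a,b numeric samples.
#' @return One-row tibble with `statistic` (U for the first sample) and
#'   `p_value`.
#' @export
mann_whitney <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty sample", call. = FALSE)
  w <- suppressWarnings(stats::wilcox.test(a, b))
  tibble::tibble(statistic = unname(w$statistic), p_value = w$p.value)
}

#' Screen metrics by Kruskal-Wallis group differences
#'
#' Applies the omnibus Kruskal-Wallis test per metric against the three-level
#' experience labels; a metric is retained when its p-value falls below
#' `alpha` (optionally after Holm correction across metrics). Pairwise
#' Mann-Whitney comparisons are reported for retained metrics only,
#' mirroring the screen-then-probe convention. Trials with a missing value
#' of a metric are excluded for that metric only.
#'
#' @param features a feature matrix with a `label3` column.
#' @param alpha significance level.
#' @param holm apply Holm correction across metrics.
#' @param cols metric columns to screen.
#' @return A tibble of class `metric_screen`: per metric, `H`, `p_value`,
#'   `retained`, and pairwise p-values `p_novice_intermediate`,
#'   `p_novice_expert`, `p_intermediate_expert` (NA unless retained).
#' @export
screen_metrics <- function(features, alpha = 0.05, holm = FALSE,
                           cols = metric_columns(features)) {
  labels <- features$label3
  rows <- purrr::map_dfr(cols, function(ch) {
    ok <- !is.na(features[[ch]])
    kw <- kruskal_wallis(features[[ch]][ok], labels[ok])
    tibble::tibble(metric = ch, H = kw$statistic, p_value = kw$p_value)
  })
  p_adj <- if (holm) stats::p.adjust(rows$p_value, "holm") else rows$p_value
  rows$retained <- p_adj < alpha
  pairs <- utils::combn(levels(labels), 2, simplify = FALSE)
  for (pr in pairs) {
    col <- paste0("p_", pr[1], "_", pr[2])
    rows[[col]] <- purrr::map2_dbl(rows$metric, rows$retained, function(ch, keep) {
      if (!keep) return(NA_real_)
      ok <- !is.na(features[[ch]])
      mann_whitney(features[[ch]][ok & labels == pr[1]],
                   features[[ch]][ok & labels == pr[2]])$p_value
    })
  }
  structure(rows, class = c("metric_screen", class(tibble::tibble())),
            alpha = alpha, holm = holm)
}

#' Principal component analysis of normalized metrics
#'
#' Eigendecomposition of the sample covariance of the robust-Z-scaled
#' metrics (the columns are not re-standardized to unit variance, so
#' loadings can exceed 1 for heavy-tailed metrics). Loadings are eigenvector
#' times the square root of the eigenvalue; each component's sign is fixed
#' so its largest-magnitude loading is positive.
#'
#' @param features data frame of normalized metric values.
#' @param cols metric columns to include (>= 2 columns, >= 3 rows).
#' @return A list of class `mocap_pca`: `loadings` (metrics x components
#'   tibble), `scores`, `explained_variance` (fractions summing to 1),
#'   `sdev`, `center`, `rotation`.
#' @export
pca_fit <- function(features, cols = metric_columns(features)) {
  x <- as.matrix(features[cols])
  if (ncol(x) < 2 || nrow(x) < 3) stop("need >= 2 metrics and >= 3 trials", call. = FALSE)
  if (anyNA(x)) stop("missing values in PCA input", call. = FALSE)
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  flip <- apply(p$rotation, 2, function(col) sign(col[which.max(abs(col))]))
  flip[flip == 0] <- 1
  p$rotation <- sweep(p$rotation, 2, flip, `*`)
  p$x <- sweep(p$x, 2, flip, `*`)
  loadings <- sweep(p$rotation, 2, p$sdev, `*`)
  ev <- p$sdev^2
  structure(list(
    loadings = tibble::as_tibble(loadings, rownames = "metric"),
    scores = tibble::as_tibble(p$x),
    explained_variance = ev / sum(ev),
    sdev = p$sdev,
    center = p$center,
    rotation = p$rotation
  ), class = "mocap_pca")
}

#' @export
print.mocap_pca <- function(x, ...) {
  ev <- x$explained_variance
  cat(sprintf("<mocap_pca> %d metrics, %d components; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$loadings), length(ev), 100 * ev[1],
              if (length(ev) > 1) 100 * ev[2] else 0))
  invisible(x)
}

# Project new (already normalized) data onto a fitted PCA, keeping the
# smallest set of leading components reaching `retained_variance`.
pca_project <- function(pca, newdata, retained_variance = 1) {
  k <- which(cumsum(pca$explained_variance) >= retained_variance - 1e-12)[1]
  if (is.na(k)) k <- length(pca$explained_variance)
  x <- as.matrix(newdata[rownames(pca$rotation)])
  sweep(x, 2, pca$center) %*% pca$rotation[, seq_len(k), drop = FALSE]
}
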