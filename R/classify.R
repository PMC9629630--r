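#' @importFrom stats predict
NULL

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin so every fold gets its share of every class. Uses the current
# RNG state (callers seed it).
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (lv in levels(as.factor(labels))) {
    idx <- sample(which(labels == lv))
    fold[idx] <- rep_len(sample(k), length(idx))
  }
  fold
}

# Prepare one train/evaluate split for a classifier family: robust-Z
# scaling parameters (and, for pca_svm, the principal-component rotation)
# are estimated from the training rows only and reused for every
# hyperparameter candidate evaluated on this split. `log_fn`, when given,
# receives the row ids actually used for scaling/fitting - the hook behind
# the leakage audit.
prep_split <- function(kind, x_fit, y_fit, x_eval, grid,
                       row_ids = NULL, log_fn = NULL) {
  core <- rz_core_fit(x_fit)
  if (!is.null(log_fn)) log_fn(row_ids)
  x_tr <- rz_core_apply(x_fit, core)
  x_ev <- rz_core_apply(x_eval, core)
  y <- droplevels(as.factor(y_fit))
  prep <- list(kind = kind, y = y, x_tr = x_tr, x_ev = x_ev)
  if (kind == "pca_svm") {
    p <- stats::prcomp(x_tr, center = TRUE, scale. = FALSE)
    prep$ev_frac <- cumsum(p$sdev^2) / sum(p$sdev^2)
    prep$scores <- p$x
    prep$proj_ev <- sweep(x_ev, 2, p$center) %*% p$rotation
  } else if (kind == "gbdt") {
    n_class <- nlevels(y)
    prep$obj <- if (n_class > 2) {
      list(objective = "multi:softmax", num_class = n_class)
    } else {
      list(objective = "binary:logistic")
    }
    prep$dtrain <- xgboost::xgb.DMatrix(x_tr, label = as.integer(y) - 1L,
                                        nthread = 1)
    prep$deval <- xgboost::xgb.DMatrix(x_ev, nthread = 1)
    # one booster per (learning rate, depth), grown to the largest tree
    # count in the grid; smaller counts are read off by iteration slicing
    prep$max_trees <- max(grid$n_trees)
    prep$boosters <- new.env(parent = emptyenv())
  }
  prep
}

# Fit (or reuse) the model for one hyperparameter candidate and predict the
# evaluation rows of the prepared split.
predict_candidate <- function(prep, params) {
  if (prep$kind %in% c("svm", "pca_svm")) {
    if (prep$kind == "pca_svm") {
      k <- which(prep$ev_frac >= params$retained_variance - 1e-12)[1]
      if (is.na(k)) k <- length(prep$ev_frac)
      x_tr <- prep$scores[, seq_len(k), drop = FALSE]
      x_ev <- prep$proj_ev[, seq_len(k), drop = FALSE]
    } else {
      x_tr <- prep$x_tr
      x_ev <- prep$x_ev
    }
    fit <- e1071::svm(x_tr, prep$y, type = "C-classification",
                      kernel = "radial", cost = params$cost,
                      gamma = params$gamma, scale = FALSE)
    as.character(predict(fit, x_ev))
  } else if (prep$kind == "gbdt") {
    key <- paste(params$learning_rate, params$max_depth, sep = "_")
    fit <- prep$boosters[[key]]
    if (is.null(fit)) {
      fit <- xgboost::xgb.train(
        params = c(prep$obj, list(max_depth = params$max_depth,
                                  eta = params$learning_rate,
                                  tree_method = "exact", nthread = 1)),
        data = prep$dtrain, nrounds = prep$max_trees, verbose = 0)
      prep$boosters[[key]] <- fit
    }
    pred <- predict(fit, prep$deval,
                    iterationrange = c(1, params$n_trees))
    lv <- levels(prep$y)
    if (length(lv) > 2) lv[pred + 1L] else lv[as.integer(pred > 0.5) + 1L]
  } else {
    stop("unknown classifier kind: ", prep$kind, call. = FALSE)
  }
}

#' Nested repeated k-fold cross-validated accuracy
#'
#' For each repetition the data are split into stratified outer folds; on
#' each outer-training portion an inner stratified k-fold grid search picks
#' the hyperparameters with the highest mean inner accuracy (ties resolved
#' by grid order), the winning model is refit on the whole outer-training
#' portion and scored on the held-out fold, and the repetition's accuracy is
#' the pooled proportion correct over all outer test folds. Robust-Z scaling
#' and, for PCA-SVM, the principal-component rotation are always estimated
#' on training rows only. All partitions for a repetition are drawn from
#' `base_seed + repetition`, so different classifiers run on identical fold
#' sequences and their accuracies are paired.
#'
#' @param features data frame containing the metric columns (rows without
#'   missing metric values).
#' @param labels class labels, one per row.
#' @param kind `"svm"`, `"pca_svm"` or `"gbdt"`.
#' @param config a [run_config()]; supplies fold counts, repetitions and
#'   grids.
#' @param base_seed base seed for the partition stream.
#' @param cols metric columns used as predictors.
#' @param audit collect a per-fold record of which rows informed scaling and
#'   fitting versus which were tested (attribute `"audit"` of the result).
#' @return A tibble of class `skill_cv` with columns `repetition`,
#'   `accuracy`, `seed`; attributes `kind` and (optionally) `audit`.
#' @export
nested_repeated_cv <- function(features, labels, kind, config = run_config(),
                               base_seed = config$seed,
                               cols = metric_columns(features),
                               audit = FALSE) {
  labels <- droplevels(as.factor(labels))
  stopifnot(nrow(features) == length(labels))
  grid <- config$grids[[kind]]
  if (is.null(grid) || nrow(grid) == 0) stop("empty hyperparameter grid", call. = FALSE)
  if (anyNA(features[cols])) {
    stop("missing metric values; drop incomplete rows first", call. = FALSE)
  }
  small <- table(labels)
  if (any(small < config$outer_k)) {
    stop("class '", names(small)[which.min(small)], "' has fewer members (",
         min(small), ") than outer_k = ", config$outer_k, call. = FALSE)
  }
  x_all <- as.matrix(features[cols])
  row_ids <- seq_len(nrow(x_all))
  audit_log <- if (audit) new.env(parent = emptyenv()) else NULL
  if (audit) audit_log$records <- list()

  acc <- vapply(seq_len(config$repetitions), function(r) {
    seed_r <- base_seed + r
    withr::with_seed(seed_r, {
      outer <- stratified_folds(labels, config$outer_k)
      inner_folds <- lapply(seq_len(config$outer_k), function(f) {
        stratified_folds(labels[outer != f], config$inner_k)
      })
      correct <- 0L
      grid_rows <- lapply(seq_len(nrow(grid)), function(g) as.list(grid[g, ]))
      for (f in seq_len(config$outer_k)) {
        tr_idx <- which(outer != f)
        te_idx <- which(outer == f)
        inner <- inner_folds[[f]]
        log_fn <- if (audit) {
          function(ids) {
            audit_log$records[[length(audit_log$records) + 1L]] <-
              list(repetition = r, outer_fold = f, scaled_ids = ids,
                   train_ids = row_ids[tr_idx],
                   test_ids = row_ids[te_idx])
          }
        } else NULL
        fold_acc <- matrix(NA_real_, nrow(grid), config$inner_k)
        for (j in seq_len(config$inner_k)) {
          fit_idx <- tr_idx[inner != j]
          val_idx <- tr_idx[inner == j]
          if (!length(val_idx) || length(unique(labels[fit_idx])) < 2) next
          prep <- prep_split(kind, x_all[fit_idx, , drop = FALSE],
                             labels[fit_idx],
                             x_all[val_idx, , drop = FALSE], grid,
                             row_ids = row_ids[fit_idx], log_fn = log_fn)
          truth <- as.character(labels[val_idx])
          for (g in seq_len(nrow(grid))) {
            fold_acc[g, j] <- mean(predict_candidate(prep, grid_rows[[g]]) == truth)
          }
        }
        mean_acc <- rowMeans(fold_acc, na.rm = TRUE)
        best <- which.max(mean_acc)   # first index wins ties
        prep_out <- prep_split(kind, x_all[tr_idx, , drop = FALSE],
                               labels[tr_idx],
                               x_all[te_idx, , drop = FALSE], grid,
                               row_ids = row_ids[tr_idx], log_fn = log_fn)
        pred <- predict_candidate(prep_out, grid_rows[[best]])
        correct <- correct + sum(pred == as.character(labels[te_idx]))
      }
      correct / length(labels)
    })
  }, 0)

  out <- tibble::tibble(repetition = seq_len(config$repetitions),
                        accuracy = acc,
                        seed = base_seed + seq_len(config$repetitions))
  out <- structure(out, class = c("skill_cv", class(tibble::tibble())),
                   kind = kind)
  if (audit) attr(out, "audit") <- audit_log$records
  out
}

#' @export
print.skill_cv <- function(x, ...) {
  cat(sprintf("<skill_cv> %s: %d repetitions, median accuracy %.3f (IQR %.3f-%.3f)\n",
              attr(x, "kind"), nrow(x), stats::median(x$accuracy),
              stats::quantile(x$accuracy, 0.25),
              stats::quantile(x$accuracy, 0.75)))
  invisible(x)
}

#' Run the three classifiers on one label scheme
#'
#' Derives labels from the prior-surgery count (`three_group`:
#' expert/intermediate/novice; `two_group`: expert/non-expert), drops trials
#' with any missing metric, and runs [nested_repeated_cv()] for SVM, PCA-SVM
#' and GBDT with identical per-repetition fold sequences so the resulting
#' accuracy vectors are paired.
#'
#' @param features a feature matrix from [compute_features()].
#' @param scheme `"three_group"` or `"two_group"`.
#' @param config a [run_config()].
#' @param audit forward the leakage-audit flag to [nested_repeated_cv()].
#' @return Named list of three `skill_cv` objects (`svm`, `pca_svm`,
#'   `gbdt`), with attribute `scheme`.
#' @export
run_discrimination <- function(features, scheme = c("three_group", "two_group"),
                               config = run_config(), audit = FALSE) {
  scheme <- match.arg(scheme)
  labels <- if (scheme == "three_group") {
    assign_group(features$n_prior_surgeries)
  } else {
    assign_group2(features$n_prior_surgeries)
  }
  cols <- metric_columns(features)
  complete <- stats::complete.cases(features[cols])
  features <- features[complete, ]
  labels <- labels[complete]
  out <- lapply(stats::setNames(nm = c("svm", "pca_svm", "gbdt")), function(kind) {
    cv <- nested_repeated_cv(features, labels, kind, config,
                             base_seed = config$seed, cols = cols,
                             audit = audit)
    attr(cv, "scheme") <- scheme
    cv
  })
  attr(out, "scheme") <- scheme
  out
}

#' Permutation-null distribution of cross-validated accuracy
#'
#' The chance-level calibration companion to [nested_repeated_cv()]: each
#' repetition draws a fresh random permutation of the labels and runs one
#' round of nested cross-validation on it. Redrawing the permutation every
#' repetition is essential - a single fixed permutation can carry a chance
#' feature-label association that flexible models exploit consistently
#' across repetitions, biasing the null median away from the chance rate.
#'
#' @inheritParams nested_repeated_cv
#' @param n_permutations number of label permutations (one CV round each).
#' @return A tibble of class `skill_cv` with one accuracy per permutation.
#' @export
permutation_null_cv <- function(features, labels, kind, config = run_config(),
                                base_seed = config$seed,
                                cols = metric_columns(features),
                                n_permutations = 20) {
  labels <- droplevels(as.factor(labels))
  acc <- vapply(seq_len(n_permutations), function(r) {
    perm <- withr::with_seed(base_seed + 7919L * r, sample(labels))
    cfg_r <- config
    cfg_r$repetitions <- 1L
    nested_repeated_cv(features, perm, kind, cfg_r,
                       base_seed = base_seed + r, cols = cols)$accuracy
  }, 0)
  structure(tibble::tibble(repetition = seq_len(n_permutations),
                           accuracy = acc,
                           seed = base_seed + seq_len(n_permutations)),
            class = c("skill_cv", class(tibble::tibble())),
            kind = kind)
}

#' Friedman rank test over paired accuracy vectors
#'
#' Within-block (per-repetition) ranks of the treatments, mean ranks for
#' ties, chi-square statistic with tie correction and `k - 1` degrees of
#' freedom (the [stats::friedman.test()] computation).
#'
#' @param x numeric matrix, blocks in rows, treatments in columns.
#' @return One-row tibble with `statistic`, `df`, `p_value`.
#' @export
friedman_test <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2) stop("need >= 2 blocks and >= 2 treatments", call. = FALSE)
  if (all(apply(x, 1, function(r) length(unique(r)) == 1))) {
    return(tibble::tibble(statistic = 0, df = ncol(x) - 1L, p_value = 1))
  }
  f <- stats::friedman.test(x)
  tibble::tibble(statistic = unname(f$statistic), df = unname(f$parameter),
                 p_value = f$p.value)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped; the statistic is the sum of the ranks of
#' the positive differences. The two-sided p-value is exact for up to 25
#' tie-free nonzero pairs, computed by full enumeration of sign patterns for
#' up to 15 pairs when ties among the absolute differences rule out the
#' standard exact distribution, and otherwise uses the normal approximation
#' with tie and continuity corrections.
#'
#' @param a,b paired numeric vectors of equal length.
#' @return One-row tibble with `statistic`, `p_value`, `n_nonzero` and
#'   `degenerate` (TRUE when every difference is zero).
#' @export
wilcoxon_signed_rank <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(tibble::tibble(statistic = NA_real_, p_value = 1,
                          n_nonzero = 0L, degenerate = TRUE))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0
  p <- if (!ties && n <= 25) {
    stats::wilcox.test(d, exact = TRUE)$p.value
  } else if (n <= 15) {
    # enumerate all 2^n sign patterns of the tied-rank statistic
    mu <- n * (n + 1) / 4
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w <- as.vector(signs %*% r)
    mean(abs(w - mu) >= abs(v - mu) - 1e-9)
  } else {
    suppressWarnings(stats::wilcox.test(d, exact = FALSE, correct = TRUE)$p.value)
  }
  tibble::tibble(statistic = v, p_value = min(p, 1), n_nonzero = n,
                 degenerate = FALSE)
}

#' Compare the three classifiers' paired accuracies
#'
#' Friedman omnibus test over the repetitions-by-classifiers accuracy
#' matrix, the three pairwise Wilcoxon signed-rank tests, and a summary
#' table of medians with interquartile ranges. Note that repeated-CV
#' accuracies share the same underlying trials, so these p-values describe
#' partition variability, not independent replications.
#'
#' @param cv_list named list of three `skill_cv` objects with equal
#'   repetition counts (from [run_discrimination()]).
#' @return A list of class `model_comparison`: `summary` (per classifier:
#'   median, q1, q3), `friedman`, `pairwise`.
#' @export
compare_models <- function(cv_list) {
  stopifnot(length(cv_list) >= 2)
  reps <- vapply(cv_list, nrow, 0L)
  if (length(unique(reps)) != 1) stop("unequal repetition counts", call. = FALSE)
  seeds <- vapply(cv_list, function(cv) paste(cv$seed, collapse = ","), "")
  if (length(unique(seeds)) != 1) stop("accuracy vectors are not paired", call. = FALSE)
  acc <- sapply(cv_list, function(cv) cv$accuracy)
  summary <- purrr::imap_dfr(cv_list, function(cv, nm) {
    q <- stats::quantile(cv$accuracy, c(0.25, 0.5, 0.75), names = FALSE)
    tibble::tibble(classifier = nm, median = q[2], q1 = q[1], q3 = q[3])
  })
  pairs <- utils::combn(names(cv_list), 2, simplify = FALSE)
  pairwise <- purrr::map_dfr(pairs, function(pr) {
    w <- wilcoxon_signed_rank(acc[, pr[1]], acc[, pr[2]])
    tibble::tibble(pair = paste(pr, collapse = " vs "),
                   statistic = w$statistic, p_value = w$p_value,
                   degenerate = w$degenerate)
  })
  structure(list(summary = summary, friedman = friedman_test(acc),
                 pairwise = pairwise),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison>\n")
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-8s median %.4f (IQR %.4f-%.4f)\n",
                x$summary$classifier[i], x$summary$median[i],
                x$summary$q1[i], x$summary$q3[i]))
  }
  cat(sprintf("  Friedman chi-sq %.3f, p = %.4g\n",
              x$friedman$statistic, x$friedman$p_value))
  for (i in seq_len(nrow(x$pairwise))) {
    cat(sprintf("  %s: p = %.4g\n", x$pairwise$pair[i], x$pairwise$p_value[i]))
  }
  invisible(x)
}

#' Check a leakage audit trail
#'
#' Counts violations in the audit records collected by
#' [nested_repeated_cv()]: any occurrence of a test-fold row among the rows
#' used to estimate scaling parameters or fit the model of its own fold.
#'
#' @param cv a `skill_cv` run with `audit = TRUE`.
#' @return Integer count of violations (0 for a clean run).
#' @export
count_leakage_violations <- function(cv) {
  records <- attr(cv, "audit")
  if (is.null(records)) stop("no audit trail; rerun with audit = TRUE", call. = FALSE)
  sum(vapply(records, function(rec) {
    length(intersect(rec$test_ids, rec$scaled_ids)) +
      length(intersect(rec$test_ids, rec$train_ids))
  }, 0L))
}
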