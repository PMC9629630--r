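#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> metrics -> screening/PCA -> classification as one
#' reproducible run. All artifacts (cohort directory, feature CSV, screening
#' and PCA tables, per-repetition accuracy CSVs, summary JSON) are written
#' under `out_dir` together with a manifest recording the configuration,
#' seeds and content hashes; re-running with the same manifest reproduces
#' hash-identical outputs.
#'
#' @param cohort_config a [synthetic_cohort_config()], or a path to a YAML
#'   file with a `cohort:` section (fields of the config) and optionally a
#'   `run:` section (fields of [run_config()]).
#' @param run_cfg a [run_config()]; ignored when `cohort_config` is a YAML
#'   path that carries its own `run:` section.
#' @param out_dir output directory, created if needed.
#' @param schemes label schemes to classify.
#' @param write_cohort_dir also write the simulated cohort as track CSVs
#'   (off by default; the feature matrix is always written).
#' @return The run manifest (named list), invisibly; the manifest is also
#'   written to `out_dir/manifest.yaml`.
#' @export
run_pipeline <- function(cohort_config, run_cfg = run_config(),
                         out_dir = "lapskill_run",
                         schemes = c("three_group", "two_group"),
                         write_cohort_dir = FALSE) {
  if (is.character(cohort_config)) {
    y <- yaml::read_yaml(cohort_config)
    if (is.null(y$cohort)) stop("config file missing field 'cohort'", call. = FALSE)
    cc <- y$cohort
    if (!is.null(cc$n_per_group)) cc$n_per_group <- unlist(cc$n_per_group)
    if (!is.null(cc$workspace)) cc$workspace <- unlist(cc$workspace)
    if (!is.null(cc$skill_map)) cc$skill_map <- lapply(cc$skill_map, unlist)
    cohort_config <- do.call(synthetic_cohort_config, cc)
    if (!is.null(y$run)) {
      run_cfg <- do.call(run_config, y$run)
    }
  }
  stopifnot(inherits(cohort_config, "synthetic_cohort_config"),
            inherits(run_cfg, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    message(sprintf("[lapskill] stage %-10s started %s", name,
                    format(Sys.time(), "%H:%M:%S")))
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  coh <- stage("simulate", generate_cohort(cohort_config))
  if (write_cohort_dir) stage("export", write_cohort(coh, file.path(out_dir, "cohort")))

  features <- stage("metrics", compute_features(coh, run_cfg))
  feat_path <- file.path(out_dir, "features.csv")
  readr::write_csv(features, feat_path)

  stats_out <- stage("stats", {
    norm <- robust_z_normalize(features)
    screen <- screen_metrics(norm, alpha = run_cfg$alpha, holm = run_cfg$holm)
    kept <- screen$metric[screen$retained]
    pca <- if (length(kept) >= 2) {
      ok <- stats::complete.cases(norm[kept])
      pca_fit(norm[ok, ], kept)
    } else NULL
    readr::write_csv(tibble::as_tibble(screen), file.path(out_dir, "screening.csv"))
    if (!is.null(pca)) {
      readr::write_csv(pca$loadings, file.path(out_dir, "pca_loadings.csv"))
      readr::write_csv(pca$scores, file.path(out_dir, "pca_scores.csv"))
    }
    list(screen = screen, pca = pca)
  })

  classify_out <- stage("classify", {
    res <- lapply(stats::setNames(nm = schemes), function(sc) {
      cvs <- run_discrimination(features, sc, run_cfg)
      comp <- compare_models(cvs)
      acc <- purrr::imap_dfr(cvs, function(cv, nm) {
        tibble::tibble(classifier = nm, repetition = cv$repetition,
                       accuracy = cv$accuracy)
      })
      readr::write_csv(acc, file.path(out_dir, paste0("accuracy_", sc, ".csv")))
      readr::write_csv(comparison_table(comp),
                       file.path(out_dir, paste0("comparison_", sc, ".csv")))
      list(cv = cvs, comparison = comp)
    })
    jsonlite::write_json(
      lapply(res, function(r) {
        list(summary = r$comparison$summary,
             friedman_p = r$comparison$friedman$p_value,
             pairwise = r$comparison$pairwise)
      }),
      file.path(out_dir, "classification_summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    res
  })

  artifacts <- list.files(out_dir, "\\.(csv|json)$", full.names = TRUE)
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
    cohort_seed = cohort_config$seed,
    run_seed = run_cfg$seed,
    n_trials = length(coh),
    schemes = as.list(schemes),
    files = stats::setNames(as.list(unname(tools::md5sum(artifacts))),
                            basename(artifacts))
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(list(manifest = manifest, features = features,
                 stats = stats_out, classification = classify_out))
}

# Accuracy comparison in the conventional median (IQR) layout.
comparison_table <- function(comp) {
  wide <- tibble::as_tibble(as.list(stats::setNames(
    sprintf("%.4f (%.4f-%.4f)", comp$summary$median, comp$summary$q1,
            comp$summary$q3),
    comp$summary$classifier)))
  wide$friedman_p <- comp$friedman$p_value
  for (i in seq_len(nrow(comp$pairwise))) {
    wide[[paste0("p_", gsub(" ", "_", comp$pairwise$pair[i]))]] <-
      comp$pairwise$p_value[i]
  }
  wide
}

#' Summarize a completed pipeline run
#'
#' Reads the artifacts written by [run_pipeline()] and renders a plain-text
#' report: screening counts, the top PCA loadings per leading component, and
#' the median (IQR) accuracy comparison for each label scheme.
#'
#' @param out_dir directory of a completed run.
#' @param top_n loadings listed per component.
#' @param n_components leading components to describe.
#' @return Character vector of report lines, invisibly; also printed.
#' @export
report_run <- function(out_dir, top_n = 5, n_components = 5) {
  screen_path <- file.path(out_dir, "screening.csv")
  if (!file.exists(screen_path)) {
    stop("incomplete results directory: ", out_dir, call. = FALSE)
  }
  screen <- readr::read_csv(screen_path, show_col_types = FALSE)
  lines <- c("# lapskill run report", "",
             sprintf("Metrics screened: %d; retained at the significance screen: %d",
                     nrow(screen), sum(screen$retained)))
  load_path <- file.path(out_dir, "pca_loadings.csv")
  if (file.exists(load_path)) {
    loadings <- readr::read_csv(load_path, show_col_types = FALSE)
    pcs <- intersect(paste0("PC", seq_len(n_components)), names(loadings))
    lines <- c(lines, "", "## Top PCA loadings")
    for (pc in pcs) {
      ord <- order(-abs(loadings[[pc]]))[seq_len(min(top_n, nrow(loadings)))]
      lines <- c(lines, sprintf("%s: %s", pc,
                                paste(sprintf("%s (%.2f)", loadings$metric[ord],
                                              loadings[[pc]][ord]),
                                      collapse = ", ")))
    }
  }
  for (sc in c("three_group", "two_group")) {
    cmp_path <- file.path(out_dir, paste0("comparison_", sc, ".csv"))
    if (file.exists(cmp_path)) {
      cmp <- readr::read_csv(cmp_path, show_col_types = FALSE)
      lines <- c(lines, "", sprintf("## Accuracy, %s discrimination", sc),
                 sprintf("median (IQR): PCA-SVM %s | SVM %s | GBDT %s",
                         cmp$pca_svm, cmp$svm, cmp$gbdt),
                 sprintf("Friedman p = %.4g", cmp$friedman_p))
    }
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
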