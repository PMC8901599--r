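# Orchestration: validated run configuration, staged execution
# (FC -> selection -> LOOCV -> permutation -> patterns -> clinical),
# per-stage artifacts, and a consolidated self-describing report.

#' Pipeline run configuration
#'
#' @param output_dir directory for stage artifacts (created if missing).
#' @param seed master seed; every stage derives a named substream from it.
#' @param simulate [synthetic_config()] to generate the inputs, or NULL to
#'   read them from files.
#' @param manifest,atlas,clinical input file paths (ignored when
#'   `simulate` is given): subject manifest CSV, atlas TSV, clinical CSV.
#' @param feature_table optional path to a precomputed feature CSV
#'   (skips the FC stage).
#' @param boruta [boruta_config()].
#' @param svm [svm_config()].
#' @param n_perm permutations for the accuracy test (default 10000; use a
#'   few hundred for exploratory runs).
#' @param selection_mode `"once"` (selection on all subjects, then LOOCV —
#'   the classical whole-sample design) or `"nested"` (selection repeated inside
#'   every fold and permutation; slower, leakage-free).
#' @param k_patterns clusters for the pattern decomposition (default 3).
#' @param include_tentative also feed tentative features to the classifier
#'   (default FALSE: confirmed only).
#' @return a validated `run_config` list.
#' @export
run_config <- function(output_dir = tempfile("fcrun"), seed = 1L,
                       simulate = synthetic_config(seed = seed),
                       manifest = NULL, atlas = NULL, clinical = NULL,
                       feature_table = NULL,
                       boruta = boruta_config(seed = sub_seed(seed, "boruta")),
                       svm = svm_config(), n_perm = 10000,
                       selection_mode = c("once", "nested"),
                       k_patterns = 3, include_tentative = FALSE) {
  selection_mode <- match.arg(selection_mode)
  if (n_perm < 1) abort("validation error: n_perm must be at least 1")
  if (k_patterns < 1) abort("validation error: k_patterns must be at least 1")
  if (is.null(simulate)) {
    for (f in c(manifest, atlas, clinical, feature_table)) {
      if (!is.null(f) && !file.exists(f)) {
        abort(paste0("validation error: input file does not exist: ", f))
      }
    }
    if (is.null(feature_table) && (is.null(manifest) || is.null(atlas))) {
      abort("validation error: need simulate, feature_table, or manifest + atlas")
    }
  }
  structure(
    list(output_dir = output_dir, seed = as.integer(seed), simulate = simulate,
         manifest = manifest, atlas = atlas, clinical = clinical,
         feature_table = feature_table, boruta = boruta, svm = svm,
         n_perm = as.integer(n_perm), selection_mode = selection_mode,
         k_patterns = as.integer(k_patterns),
         include_tentative = isTRUE(include_tentative)),
    class = "run_config"
  )
}

stage_try <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("stage '", stage, "' failed: ", conditionMessage(e)))
  })
}

#' Run the full classification pipeline
#'
#' Executes the stages in order — feature construction, all-relevant
#' selection, LOOCV SVM classification, label-permutation test, pattern
#' analytics, clinical correlation — writing each stage's artifact to
#' `output_dir` before the next stage starts, and returns a consolidated
#' report. A rerun with the same configuration and seed reproduces every
#' decision and metric.
#'
#' @param cfg [run_config()].
#' @return object of class `run_report` with the effective configuration,
#'   stage summaries, and the full stage objects.
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "run_config")) abort("cfg must come from run_config()")
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  tic <- function() Sys.time()
  lap <- function(t0) as.numeric(difftime(Sys.time(), t0, units = "secs"))

  # --- inputs / FC stage -----------------------------------------------
  t0 <- tic()
  truth <- NULL; clinical <- NULL
  if (!is.null(cfg$simulate)) {
    ds <- stage_try("fc", generate_dataset(cfg$simulate))
    atlas <- ds$atlas; table <- ds$feature_table
    clinical <- ds$clinical; truth <- ds$truth
  } else if (!is.null(cfg$feature_table)) {
    atlas <- if (!is.null(cfg$atlas)) stage_try("fc", read_atlas(cfg$atlas)) else NULL
    table <- stage_try("fc", read_feature_table(cfg$feature_table, atlas = atlas))
    if (!is.null(cfg$clinical)) clinical <- stage_try("fc", readr::read_csv(cfg$clinical, show_col_types = FALSE))
  } else {
    atlas <- stage_try("fc", read_atlas(cfg$atlas))
    mf <- stage_try("fc", read_manifest(cfg$manifest))
    ts_list <- stage_try("fc", setNames(
      lapply(mf$file, read_time_series, atlas = atlas), mf$subject_id))
    table <- stage_try("fc", assemble_feature_table(
      ts_list, atlas, mf[, c("subject_id", "label")]))
    if (!is.null(cfg$clinical)) clinical <- stage_try("fc", readr::read_csv(cfg$clinical, show_col_types = FALSE))
  }
  if (!is.null(atlas)) write_atlas(atlas, file.path(cfg$output_dir, "atlas.tsv"))
  write_feature_table(table, file.path(cfg$output_dir, "features.csv"))
  timings$fc <- lap(t0)

  # --- selection stage --------------------------------------------------
  t0 <- tic()
  bres <- stage_try("boruta", run_boruta(table, cfg$boruta))
  write_boruta_result(bres, file.path(cfg$output_dir, "boruta.json"),
                      file.path(cfg$output_dir, "importance_history.csv"))
  keep <- if (cfg$include_tentative) {
    which(bres$decision %in% c("confirmed", "tentative"))
  } else {
    which(bres$decision == "confirmed")
  }
  if (length(keep) == 0L) {
    abort("stage 'classify' failed: the confirmed connection set is empty; nothing to classify")
  }
  timings$boruta <- lap(t0)

  # --- classification stage --------------------------------------------
  t0 <- tic()
  sel_table <- select_confirmed(table, bres,
                                include_tentative = cfg$include_tentative)
  nested_sel <- if (cfg$selection_mode == "nested") cfg$boruta else NULL
  report <- stage_try("classify",
                      loocv_classify(if (is.null(nested_sel)) sel_table else table,
                                     cfg$svm, selection = nested_sel))
  timings$classify <- lap(t0)

  # --- permutation stage -----------------------------------------------
  t0 <- tic()
  obs_acc <- report$metrics$proportion[report$metrics$metric == "accuracy"]
  perm <- stage_try("permute", permutation_test(
    if (is.null(nested_sel)) sel_table else table, cfg$svm,
    n_perm = cfg$n_perm, seed = sub_seed(cfg$seed, "permutation"),
    selection_mode = cfg$selection_mode, boruta_cfg = nested_sel,
    observed_accuracy = obs_acc
  ))
  report$permutation <- perm
  readr::write_csv(tibble::tibble(null_accuracy = perm$null_accuracies),
                   file.path(cfg$output_dir, "permutation_null.csv"),
                   progress = FALSE)
  jsonlite::write_json(
    list(metrics = report$metrics, folds = report$folds,
         mean_weights = setNames(as.list(report$mean_weights), report$features),
         p_value = perm$p_value, n_perm = cfg$n_perm,
         svm_config = unclass(cfg$svm), selection_mode = cfg$selection_mode),
    file.path(cfg$output_dir, "classification.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE
  )
  timings$permute <- lap(t0)

  # --- pattern stage ----------------------------------------------------
  t0 <- tic()
  patterns <- NULL
  if (is.null(nested_sel) && !is.null(atlas)) {
    cs <- connection_set(ft_connections(table)[keep, , drop = FALSE],
                         report$mean_weights, atlas)
    profile <- t(ft_feature_matrix(sel_table))   # connections x subjects
    patterns <- stage_try("patterns", pattern_summary(
      cs, profile, k = min(cfg$k_patterns, nrow(cs)),
      seed = sub_seed(cfg$seed, "patterns")
    ))
    readr::write_csv(dplyr::left_join(patterns$nd,
                                      patterns$network_weight, by = "network"),
                     file.path(cfg$output_dir, "network_summary.csv"),
                     progress = FALSE)
    readr::write_csv(patterns$pattern_labels,
                     file.path(cfg$output_dir, "connection_patterns.csv"),
                     progress = FALSE)
    jsonlite::write_json(
      list(region_weight = patterns$region_weight,
           network_weight = patterns$network_weight,
           important_regions = patterns$important_regions,
           nd = patterns$nd, per_pattern = patterns$per_pattern,
           weight_mode = patterns$mode, sd_convention = "sample (n-1)"),
      file.path(cfg$output_dir, "patterns.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE
    )
  }
  timings$patterns <- lap(t0)

  # --- clinical stage ---------------------------------------------------
  t0 <- tic()
  correlations <- NULL
  if (!is.null(clinical) && is.null(nested_sel)) {
    pat_table <- dplyr::filter(sel_table, .data$label == 1L)
    scores <- stage_try("clinical", classification_scores(
      new_feature_table(ft_feature_matrix(pat_table),
                        pat_table$subject_id, pat_table$label,
                        connections = ft_connections(sel_table)),
      report$mean_weights
    ))
    correlations <- stage_try("clinical", correlate_with_scales(scores, clinical))
    readr::write_csv(tibble::as_tibble(correlations),
                     file.path(cfg$output_dir, "clinical_correlations.csv"),
                     progress = FALSE)
  }
  timings$clinical <- lap(t0)

  out <- structure(
    list(
      config = cfg,
      effective = list(
        gamma_rule = if (is.numeric(cfg$svm$gamma)) cfg$svm$gamma else "1/(p*var)",
        null_hit_prob = cfg$boruta$null_hit_prob,
        correction = cfg$boruta$correction,
        selection_mode = cfg$selection_mode,
        k_patterns = cfg$k_patterns,
        seed = cfg$seed
      ),
      selection = bres,
      classification = report,
      patterns = patterns,
      correlations = correlations,
      truth = truth,
      timings = timings
    ),
    class = "run_report"
  )
  write_run_report(out, file.path(cfg$output_dir, "report.json"))
  out
}

#' Serialize a run report to JSON
#'
#' Timestamps/timings are written under their own key so that two runs with
#' the same seed produce identical reports modulo that block.
#'
#' @param report `run_report`.
#' @param path output path.
#' @export
write_run_report <- function(report, path) {
  body <- list(
    effective_config = report$effective,
    selection = as.list(glance(report$selection)),
    classification = as.list(glance(report$classification)),
    confirmed_connections = report$selection$confirmed_features
  )
  if (!is.null(report$patterns)) {
    body$network_degree <- report$patterns$nd
    body$important_regions <- report$patterns$important_regions
    body$pattern_sizes <- report$patterns$per_pattern
  }
  if (!is.null(report$correlations)) {
    body$clinical <- as.list(glance(report$correlations))
  }
  jsonlite::write_json(list(report = body, timings = report$timings), path,
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run (seed", x$config$seed, ")\n")
  print(x$selection)
  print(x$classification)
  if (!is.null(x$patterns)) print(x$patterns)
  if (!is.null(x$correlations)) {
    g <- glance(x$correlations)
    cat(sprintf("clinical: %d of %d (connection, scale) pairs significant at alpha = %g\n",
                g$n_significant, g$n_pairs, g$alpha))
  }
  invisible(x)
}

#' Export a synthetic dataset to files
#'
#' Writes the manifest, atlas TSV, per-subject time-series TSVs (when
#' present), feature CSV, clinical CSV, and a truth JSON — the file layout
#' the pipeline reads back.
#'
#' @param ds `fc_synthetic` from [generate_dataset()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
export_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_atlas(ds$atlas, file.path(dir, "atlas.tsv"))
  write_feature_table(ds$feature_table, file.path(dir, "features.csv"))
  readr::write_csv(ds$clinical, file.path(dir, "clinical.csv"), progress = FALSE)
  jsonlite::write_json(
    list(discriminative = ds$truth$discriminative,
         clinical_linked = ds$truth$clinical_linked),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE
  )
  if (!is.null(ds$time_series)) {
    tsdir <- file.path(dir, "timeseries")
    dir.create(tsdir, showWarnings = FALSE)
    files <- vapply(names(ds$time_series$time_series), function(id) {
      f <- file.path(tsdir, paste0(id, ".tsv"))
      readr::write_tsv(tibble::as_tibble(ds$time_series$time_series[[id]]), f,
                       progress = FALSE)
      f
    }, character(1))
    mf <- dplyr::mutate(ds$time_series$labels, file = unname(files),
                        .after = "subject_id")
    readr::write_csv(mf, file.path(dir, "manifest.csv"), progress = FALSE)
  }
  invisible(dir)
}
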