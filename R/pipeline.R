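#' Run the full TNT-fingerprint analysis pipeline
#'
#' Chains the stages on a loaded (or generated) dataset: replicate
#' averaging and guideline curation, response binarization, feature
#' engineering (threshold filter at ASV rank, then agglomeration),
#' repeated splits, grid search scored by out-of-bag balanced accuracy,
#' holdout evaluation at the chosen hyperparameters, corrected-impurity
#' importance with Top-feature selection, unsupervised-proximity
#' ordination with environmental vector fitting, classification
#' consistency, and the false-positive resilience summary. Every stage is
#' seeded from `seed`, so the bundle is fully reproducible.
#'
#' Stage scales default to desk-size settings; pass the full-scale values
#' (e.g. `n_trees = 10000`, `models_per_combo = 50`,
#' `consistency_models = 1000`) to reproduce the full protocol.
#'
#' @param community counts [community_table()] at ASV rank.
#' @param taxonomy a [taxonomy_table()].
#' @param samples a [sample_table()].
#' @param rank rank modelled after agglomeration (`"genus"` default;
#'   `"asv"` skips agglomeration).
#' @param threshold relative-abundance threshold in percent (default 0.08).
#' @param n_trees,mtry_factor forest hyperparameters used after the grid
#'   stage (defaults 500 and 5).
#' @param grid optional list with `thresholds`, `n_trees`, `mtry_factors`
#'   to search; `NULL` skips the grid stage.
#' @param models_per_combo forests per grid combination (default 2).
#' @param k_splits number of train/holdout splits (default 6).
#' @param n_top number of Top features selected (default 25).
#' @param importance_models replicate forests for the importance stage
#'   (default 10).
#' @param consistency_models repeated forests for the consistency stage
#'   (default 200).
#' @param detection_limit_pmol_g TNT detection limit (default 0.044).
#' @param guideline a [guideline_params()].
#' @param out_dir optional directory; when given, every artifact is written
#'   there as TSV/JSON via [export_results()].
#' @param seed master seed.
#' @return object of class `tnt_pipeline` bundling all stage artifacts.
#' @export
run_pipeline <- function(community, taxonomy, samples,
                         rank = "genus", threshold = 0.08,
                         n_trees = 500, mtry_factor = 5,
                         grid = NULL, models_per_combo = 2,
                         k_splits = 6, n_top = 25,
                         importance_models = 10,
                         consistency_models = 200,
                         detection_limit_pmol_g = 0.044,
                         guideline = guideline_params(),
                         out_dir = NULL, seed = 1) {
  rng <- local_rng(seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # curation ------------------------------------------------------------
  averaged <- stage("curate", average_replicates(community, samples))
  grp_meta <- samples[!duplicated(samples$replicate_group), , drop = FALSE]
  rownames(grp_meta) <- grp_meta$replicate_group
  grp_meta$sample_id <- grp_meta$replicate_group
  grp_meta <- sample_table(as.data.frame(grp_meta),
                           env_cols = env_columns(samples),
                           metabolite_cols = metabolite_columns(samples))
  response <- stage("curate",
                    binarize_response(grp_meta, detection_limit_pmol_g))
  report <- stage("curate",
                  apply_exclusion_guideline(grp_meta, response, guideline))
  keep <- report$kept_ids
  comm <- structure(list(values = averaged$values[keep, , drop = FALSE],
                         unit = "percent", rank = "asv"),
                    class = "community_table")
  grp_meta <- grp_meta[keep, , drop = FALSE]
  response <- response[keep]

  # features ------------------------------------------------------------
  filtered <- stage("features", filter_by_threshold(comm, threshold))
  modelled <- stage("features",
                    if (rank == "asv") filtered
                    else agglomerate_rank(filtered, taxonomy, rank))
  x <- as_feature_matrix(modelled)

  # splits + grid + holdout ---------------------------------------------
  splits <- stage("splits", make_splits(keep, 0.25, k_splits,
                                        seed = rng$int()))
  grid_result <- if (!is.null(grid))
    stage("grid", grid_search(comm, taxonomy, response, splits,
                              thresholds = grid$thresholds,
                              ranks = grid$ranks %||% rank,
                              n_trees_grid = grid$n_trees,
                              mtry_factors = grid$mtry_factors,
                              models_per_combo = models_per_combo,
                              seed = rng$int()))
  hp <- hyper_params(n_trees, mtry_factor, seed = rng$int())
  holdout <- stage("holdout", evaluate_holdout(x, response, hp, splits,
                                               seed = rng$int()))

  # importance + Top selection ------------------------------------------
  imp <- stage("importance",
               importance_corrected_janitza(x, response,
                                            hyper_params(n_trees, mtry_factor,
                                                         seed = rng$int()),
                                            m_models = importance_models))
  top <- stage("importance",
               select_top_features(imp, -Inf, 1.01, n_top = n_top))

  # ordination on the Top features --------------------------------------
  x_top <- x[, top, drop = FALSE]
  unsup <- stage("ordination",
                 unsupervised_forest(x_top,
                                     hyper_params(n_trees, 1,
                                                  seed = rng$int())))
  ord <- stage("ordination", ordinate_from_proximity(unsup$proximity, 2))
  env <- as.matrix(grp_meta[, env_columns(grp_meta), drop = FALSE])
  vectors <- stage("ordination",
                   fit_environment_vectors(ord, env, n_perm = 999,
                                           seed = rng$int()))

  # robustness + resilience ---------------------------------------------
  cons <- stage("robustness",
                consistency_analysis(x, response,
                                     hyper_params(n_trees, 1,
                                                  seed = rng$int()),
                                     m_models = consistency_models))
  resil <- stage("resilience", false_positive_resilience(cons, grp_meta))

  out <- structure(list(
    curation = report, response = response, splits = splits,
    features = x, grid = grid_result, holdout = holdout,
    importance = imp, top_features = top,
    ordination = ord, vectors = vectors,
    consistency = cons, resilience = resil,
    seed = seed), class = "tnt_pipeline")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    export_results(imp, file.path(out_dir, "importance.tsv"), "tsv")
    export_results(cons, file.path(out_dir, "consistency.tsv"), "tsv")
    export_results(data.frame(split = seq_along(holdout$scores),
                              balanced_accuracy = holdout$scores),
                   file.path(out_dir, "holdout.tsv"), "tsv")
    if (!is.null(grid_result))
      export_results(as.data.frame(grid_result),
                     file.path(out_dir, "grid.tsv"), "tsv")
    export_results(list(seed = seed, top_features = top,
                        explained = ord$explained),
                   file.path(out_dir, "pipeline.json"), "json")
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.tnt_pipeline <- function(x, ...) {
  cat("<tnt_pipeline>\n")
  cat(sprintf("  curation: kept %d / removed %d samples\n",
              length(x$curation$kept_ids), length(x$curation$removed_ids)))
  cat(sprintf("  holdout balanced accuracy: %.3f +/- %.3f over %d splits\n",
              x$holdout$mean, x$holdout$sd, length(x$holdout$scores)))
  cat(sprintf("  top features: %s, ...\n",
              paste(utils::head(x$top_features, 3), collapse = ", ")))
  cat(sprintf("  ordination axis 1 explains %.1f%%\n",
              100 * x$ordination$explained[1]))
  cat(sprintf("  consistency: %d majority-misclassified sample(s)\n",
              sum(x$consistency$misclassification_pct > 50)))
  invisible(x)
}
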