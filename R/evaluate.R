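#' Repeated pseudo-random train/holdout splits
#'
#' Draws `k` independent splits of the sample ids into a training-validation
#' set and a holdout test set. The training size is `n * (1 - fraction)`
#' rounded half-down (150 samples at 25% give 112 train / 38 holdout);
#' sampling is uniform without stratification. Reproducible from `seed`.
#'
#' @param sample_ids character vector of sample ids.
#' @param holdout_fraction fraction held out (0 < f < 1, default 0.25).
#' @param k number of splits (default 6).
#' @param seed integer master seed.
#' @return an object of class `split_set`: list of `k` lists with `train`
#'   and `holdout` id vectors.
#' @export
make_splits <- function(sample_ids, holdout_fraction = 0.25, k = 6, seed = 1) {
  stopifnot(holdout_fraction > 0, holdout_fraction < 1, k >= 1)
  n <- length(sample_ids)
  n_train <- ceiling(n * (1 - holdout_fraction) - 0.5)  # round half down
  n_hold <- n - n_train
  if (n_hold < 1 || n_train < 1)
    stop("too few samples for a non-empty holdout")
  rng <- local_rng(seed)
  splits <- lapply(seq_len(k), function(i) {
    train <- sort(sample_ids[rng$sample(n, n_train)])
    list(train = train, holdout = sort(setdiff(sample_ids, train)))
  })
  structure(list(splits = splits, seed = seed,
                 holdout_fraction = holdout_fraction),
            class = "split_set")
}

#' @export
print.split_set <- function(x, ...) {
  cat(sprintf("<split_set> %d splits, %d train / %d holdout (seed %d)\n",
              length(x$splits), length(x$splits[[1]]$train),
              length(x$splits[[1]]$holdout), x$seed))
  invisible(x)
}

#' Balanced accuracy
#'
#' Mean of sensitivity and specificity; corrects for class imbalance, so a
#' constant single-class predictor scores 0.5 whatever the prevalence. Both
#' truth classes must be present.
#'
#' @param truth factor (or 2x2 confusion matrix with truth in rows).
#' @param predicted factor aligned with `truth` (ignored when `truth` is a
#'   confusion matrix).
#' @return balanced accuracy in [0, 1].
#' @export
balanced_accuracy <- function(truth, predicted = NULL) {
  if (is.matrix(truth)) {
    cm <- truth
    if (!all(dim(cm) == c(2, 2))) stop("confusion matrix must be 2x2")
  } else {
    truth <- as.factor(truth)
    lev <- levels(truth)
    if (length(lev) != 2) stop("balanced accuracy needs exactly 2 classes")
    predicted <- factor(as.character(predicted), levels = lev)
    cm <- table(truth = truth, predicted = predicted)
  }
  if (any(rowSums(cm) == 0))
    stop("a class is absent from the truth; recall undefined")
  recalls <- diag(cm) / rowSums(cm)
  mean(recalls)
}

#' Grid search over thresholds, ranks and forest hyperparameters
#'
#' For every combination of relative-abundance threshold, taxonomic rank,
#' tree count and mtry factor, and for every split, `models_per_combo`
#' forests are trained on the training set only; the validation score is the
#' out-of-bag balanced accuracy. Thresholding and agglomeration are computed
#' from the training samples, so no holdout sample influences feature
#' selection (leakage guard).
#'
#' @param community a percent-unit ASV [community_table()].
#' @param taxonomy a [taxonomy_table()] (needed for non-ASV ranks).
#' @param response binarized response covering all samples.
#' @param splits a [make_splits()] result.
#' @param thresholds numeric vector of percent thresholds.
#' @param ranks character vector of ranks (`"asv"` or agglomeration ranks).
#' @param n_trees_grid,mtry_factors integer vectors.
#' @param models_per_combo forests per combination and split.
#' @param seed integer seed for the model replicates.
#' @return object of class `grid_result`: data.frame with one row per
#'   (threshold, rank, trees, mtry_factor, split, replicate) and its
#'   validation balanced accuracy.
#' @export
grid_search <- function(community, taxonomy, response, splits,
                        thresholds = default_thresholds(),
                        ranks = "asv",
                        n_trees_grid = c(100, 500, 1000, 5000, 10000, 20000),
                        mtry_factors = seq(1, 13, by = 2),
                        models_per_combo = 50, seed = 1) {
  if (community$unit != "percent")
    stop("grid_search expects a percent community table")
  rng <- local_rng(seed)
  rows <- list()
  for (s in seq_along(splits$splits)) {
    train_ids <- splits$splits[[s]]$train
    train_ct <- structure(list(
      values = community$values[train_ids, , drop = FALSE],
      unit = "percent", rank = community$rank), class = "community_table")
    y_train <- response[train_ids]
    for (th in thresholds) {
      filt <- filter_by_threshold(train_ct, th)
      for (rk in ranks) {
        tab <- if (rk == "asv") filt
               else agglomerate_rank(filt, taxonomy, rk)
        x <- as_feature_matrix(tab)
        for (nt in n_trees_grid) for (mf in mtry_factors) {
          for (rep_i in seq_len(models_per_combo)) {
            fit <- train_forest(x, y_train,
                                hyper_params(nt, mf, seed = rng$int()))
            oob <- fit$oob_predictions
            ok <- !is.na(oob)
            ba <- balanced_accuracy(y_train[ok], oob[ok])
            rows[[length(rows) + 1]] <- data.frame(
              threshold = th, rank = rk, n_trees = nt, mtry_factor = mf,
              split = s, replicate = rep_i, phase = "validation",
              balanced_accuracy = ba, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("grid_result", "data.frame")
  out
}

#' @export
print.grid_result <- function(x, ...) {
  cat(sprintf("<grid_result> %d score records\n", nrow(x)))
  agg <- stats::aggregate(balanced_accuracy ~ threshold + rank + n_trees +
                            mtry_factor, data = x, FUN = mean)
  print.data.frame(utils::head(agg[order(-agg$balanced_accuracy), ], 10),
                   digits = 3)
  invisible(x)
}

#' Summarize a grid result per hyperparameter combination
#'
#' @param object a [grid_search()] result.
#' @param ... unused.
#' @return data.frame of mean/sd balanced accuracy per combination, sorted
#'   by mean descending.
#' @export
summary.grid_result <- function(object, ...) {
  agg <- stats::aggregate(balanced_accuracy ~ threshold + rank + n_trees +
                            mtry_factor, data = object,
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v),
                                              n = length(v)))
  out <- cbind(agg[, 1:4], agg$balanced_accuracy)
  out[order(-out[, "mean"]), ]
}

#' Evaluate fixed hyperparameters on the holdout sets
#'
#' For each split, one forest is trained on the full training set with the
#' chosen hyperparameters and scored by balanced accuracy on the holdout
#' set. Hyperparameters must be fixed before this call; any overlap between
#' a split's training and holdout ids is refused.
#'
#' @param x feature matrix over all samples (feature engineering already
#'   applied; for a faithful protocol derive features from training data).
#' @param response binarized response covering all samples.
#' @param hp a [hyper_params()].
#' @param splits a [make_splits()] result.
#' @param seed integer seed for the per-split models.
#' @return list with `scores` (per split), `mean`, `sd`.
#' @export
evaluate_holdout <- function(x, response, hp, splits, seed = 1) {
  x <- as_plain_matrix(x)
  rng <- local_rng(seed)
  scores <- vapply(seq_along(splits$splits), function(s) {
    sp <- splits$splits[[s]]
    leak <- intersect(sp$train, sp$holdout)
    if (length(leak))
      stop("holdout leakage: sample(s) in both sets: ",
           paste(leak, collapse = ", "))
    fit <- train_forest(x[sp$train, , drop = FALSE], response[sp$train],
                        hyper_params(hp$n_trees, hp$mtry_factor,
                                     seed = rng$int()))
    pred <- predict(fit, x[sp$holdout, , drop = FALSE])
    balanced_accuracy(response[sp$holdout], pred$predicted)
  }, numeric(1))
  list(scores = scores, mean = mean(scores), sd = stats::sd(scores))
}

#' Compare balanced-accuracy distributions between input sets
#'
#' Welch's (unequal-variance) one-way ANOVA across the score groups, plus
#' classical one-way ANOVA with Tukey's honestly-significant-difference
#' multiple comparisons of means at 95% family-wise confidence; pairwise
#' comparisons are flagged significant at the adjusted threshold.
#'
#' @param groups named list mapping input-set name to a numeric score
#'   vector.
#' @param alpha_adjusted significance threshold on Tukey-adjusted p-values
#'   (default 0.005).
#' @return list with `welch` (htest), `anova` (aov fit), `tukey`
#'   (data.frame of pairwise comparisons with `significant` flags).
#' @export
compare_input_sets <- function(groups, alpha_adjusted = 0.005) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, 1L) < 2))
    stop("each group needs at least 2 scores")
  df <- data.frame(
    score = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, 1L))))
  if (all(vapply(split(df$score, df$group), stats::var, 1) == 0))
    stop("zero variance in every group; ANOVA degenerate")
  welch <- stats::oneway.test(score ~ group, data = df, var.equal = FALSE)
  fit <- stats::aov(score ~ group, data = df)
  tk <- stats::TukeyHSD(fit, conf.level = 0.95)$group
  tukey <- data.frame(comparison = rownames(tk),
                      diff = tk[, "diff"],
                      p_adjusted = tk[, "p adj"],
                      significant = tk[, "p adj"] < alpha_adjusted,
                      stringsAsFactors = FALSE)
  rownames(tukey) <- NULL
  list(welch = welch, anova = fit, tukey = tukey)
}
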