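#' Corrected-impurity importance with mirrored-null p-values
#'
#' Plain Gini-impurity importance is non-negative and biased; a debiased,
#' signed score is obtained by shadow-variable augmentation: every feature
#' gets a column-permuted copy ("shadow") appended, a forest is trained on
#' the augmented matrix, and the corrected importance of a feature is its
#' impurity reduction minus that of its matched shadow. Shadows carry the
#' same marginal but no relationship to the response, so under the null the
#' corrected score is symmetric around zero. The shadow augmentation is
#' drawn once per call; scores are then averaged over `m_models`
#' independently seeded forests on the same augmented data.
#'
#' P-values follow the mirrored empirical-null idea: all non-positive mean
#' scores and their mirror images form the null sample, and
#' `p = (# null >= observed + 1) / (|null| + 1)`.
#'
#' @param x feature matrix.
#' @param y response factor.
#' @param hp a [hyper_params()]; `hp$seed` seeds the model replicates.
#' @param m_models number of replicate forests averaged.
#' @return an `importance_result` data.frame: `feature`, `importance`,
#'   `p_value`, `method`.
#' @export
importance_corrected_janitza <- function(x, y, hp = hyper_params(),
                                         m_models = 100) {
  x <- as_plain_matrix(x)
  y <- align_response(y, rownames(x))
  p <- ncol(x)
  if (p < 1) stop("need at least one feature")
  rng <- local_rng(hp$seed)
  # the shadow assignment is part of the augmented dataset: drawn once, so
  # that model averaging reduces forest noise symmetrically for real and
  # shadow columns (re-drawing shadows per model would leave only the real
  # features' chance association with y in the average, skewing the null)
  shadow <- apply(x, 2, function(col) col[rng$sample(length(col))])
  colnames(shadow) <- paste0(".shadow_", colnames(x))
  rownames(shadow) <- rownames(x)
  aug <- cbind(x, shadow)
  scores <- matrix(0, m_models, p, dimnames = list(NULL, colnames(x)))
  for (m in seq_len(m_models)) {
    fit <- train_forest(aug, y,
                        hyper_params(hp$n_trees, hp$mtry_factor,
                                     seed = rng$int()),
                        importance = "impurity")
    imp <- fit$fit$variable.importance
    scores[m, ] <- imp[colnames(x)] - imp[paste0(".shadow_", colnames(x))]
  }
  mean_imp <- colMeans(scores)
  nonpos <- mean_imp[mean_imp <= 0]
  if (!length(nonpos))
    stop("no non-positive importance scores available to build the null; ",
         "use more features or models")
  null <- c(nonpos, -nonpos)
  pval <- vapply(mean_imp,
                 function(s) (sum(null >= s) + 1) / (length(null) + 1),
                 numeric(1))
  importance_result(colnames(x), mean_imp, pval,
                    "corrected_impurity_janitza")
}

#' Permutation importance with response-permutation p-values
#'
#' Observed permutation importance per feature, with a per-feature null
#' distribution obtained by re-training the forest on a response vector
#' permuted `n_perm` times; `p = (r + 1) / (n_perm + 1)` where `r` counts
#' null scores at least as large as the observed one. The smallest
#' attainable p-value is therefore `1 / (n_perm + 1)`.
#'
#' @param x feature matrix.
#' @param y response factor.
#' @param hp a [hyper_params()].
#' @param n_perm number of response permutations (>= 1).
#' @return an `importance_result` data.frame.
#' @export
importance_permutation_altmann <- function(x, y, hp = hyper_params(),
                                           n_perm = 1000) {
  stopifnot(n_perm >= 1)
  x <- as_plain_matrix(x)
  y <- align_response(y, rownames(x))
  rng <- local_rng(hp$seed)
  obs_fit <- train_forest(x, y, hp, importance = "permutation")
  obs <- obs_fit$fit$variable.importance[colnames(x)]
  exceed <- numeric(ncol(x))
  for (i in seq_len(n_perm)) {
    yp <- y[rng$sample(length(y))]
    names(yp) <- rownames(x)
    fit <- train_forest(x, yp,
                        hyper_params(hp$n_trees, hp$mtry_factor,
                                     seed = rng$int()),
                        importance = "permutation")
    exceed <- exceed +
      (fit$fit$variable.importance[colnames(x)] >= obs)
  }
  pval <- (exceed + 1) / (n_perm + 1)
  importance_result(colnames(x), obs, pval, "permutation_altmann")
}

importance_result <- function(feature, importance, p_value, method) {
  out <- data.frame(feature = feature,
                    importance = unname(importance),
                    p_value = unname(p_value),
                    method = method,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("importance_result", "data.frame")
  out
}

#' @export
print.importance_result <- function(x, n = 10, ...) {
  cat(sprintf("<importance_result> %d features, method %s\n",
              nrow(x), x$method[1]))
  ord <- order(-x$importance)
  print.data.frame(utils::head(x[ord, ], n), digits = 4)
  invisible(x)
}

#' Select the top-ranked features
#'
#' Features with `importance > importance_cutoff` (strict) and
#' `p_value < p_cutoff` (strict), ordered by importance descending.
#' Alternatively `n_top` caps the selection at the best `n_top` features
#' after the cutoffs.
#'
#' @param imp an `importance_result`.
#' @param importance_cutoff strict lower bound on the importance score
#'   (`-Inf` disables).
#' @param p_cutoff strict upper bound on the p-value (`1` effectively
#'   disables, as p-values never exceed 1 but equal 1 is excluded; use `Inf`
#'   to disable entirely).
#' @param n_top optional cap on the number of selected features.
#' @return character vector of selected feature names, importance-ordered.
#' @export
select_top_features <- function(imp, importance_cutoff, p_cutoff,
                                n_top = NULL) {
  stopifnot(is.finite(importance_cutoff) || importance_cutoff == -Inf)
  keep <- imp$importance > importance_cutoff & imp$p_value < p_cutoff
  sel <- imp[keep, , drop = FALSE]
  sel <- sel[order(-sel$importance, sel$feature), , drop = FALSE]
  if (!is.null(n_top)) sel <- utils::head(sel, n_top)
  sel$feature
}
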