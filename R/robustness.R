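#' Classification-consistency analysis over repeated forests
#'
#' Trains `m_models` forests with distinct seeds on all samples and records,
#' per sample, the percentage of models whose out-of-bag prediction for that
#' sample is wrong. OOB predictions are used so that a sample is only ever
#' judged by trees that did not see it. Rates below 0.5% are rounded to 0
#' and above 99.5% to 100 (a model either "knows" a sample or it does not);
#' rates inside \[0.5, 99.5\] are never altered.
#'
#' @param x feature matrix over all samples.
#' @param y response factor.
#' @param hp a [hyper_params()]; `hp$seed` spawns the model seeds.
#' @param m_models number of repeated models (default 1000).
#' @return object of class `consistency_result`: data.frame `sample_id`,
#'   `truth`, `majority_predicted`, `misclassification_pct`, `rounded`.
#' @export
consistency_analysis <- function(x, y, hp = hyper_params(), m_models = 1000) {
  stopifnot(m_models >= 2)
  x <- as_plain_matrix(x)
  y <- align_response(y, rownames(x))
  rng <- local_rng(hp$seed)
  n <- nrow(x)
  wrong <- integer(n); judged <- integer(n)
  votes <- matrix(0L, n, nlevels(y), dimnames = list(rownames(x), levels(y)))
  for (m in seq_len(m_models)) {
    fit <- train_forest(x, y, hyper_params(hp$n_trees, hp$mtry_factor,
                                           seed = rng$int()))
    oob <- fit$oob_predictions
    ok <- !is.na(oob)
    wrong[ok] <- wrong[ok] + (oob[ok] != y[ok])
    judged[ok] <- judged[ok] + 1L
    votes[cbind(which(ok), as.integer(oob[ok]))] <-
      votes[cbind(which(ok), as.integer(oob[ok]))] + 1L
  }
  if (any(judged == 0))
    stop("sample(s) never out of bag across all models; increase n_trees")
  raw <- 100 * wrong / judged
  rounded <- raw < 0.5 | raw > 99.5
  rate <- ifelse(raw < 0.5, 0, ifelse(raw > 99.5, 100, raw))
  maj <- levels(y)[max.col(votes, ties.method = "first")]
  out <- data.frame(sample_id = rownames(x),
                    truth = y,
                    majority_predicted = factor(maj, levels = levels(y)),
                    misclassification_pct = rate,
                    rounded = rounded,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("consistency_result", "data.frame")
  out
}

#' @export
print.consistency_result <- function(x, ...) {
  n_wrong <- sum(x$misclassification_pct > 50)
  cat(sprintf(paste0("<consistency_result> %d samples; %d majority-",
                     "misclassified; %d with unstable (0-100%%) rates\n"),
              nrow(x), n_wrong,
              sum(x$misclassification_pct > 0 &
                    x$misclassification_pct < 100)))
  invisible(x)
}

#' False-positive resilience summary
#'
#' Among samples whose true class is `absent` but which are (at least
#' sometimes) predicted `present`, partitions by munition-metabolite
#' presence (any ADNT/DANT concentration > 0) and summarizes the
#' false-positive rates per partition. A higher rate in the
#' metabolite-bearing partition indicates that the community still carries
#' the trace of a historical contamination although TNT itself is no longer
#' detectable. Also reports the Spearman correlation of the rate with the
#' summed metabolite concentration.
#'
#' @param consistency a [consistency_analysis()] result.
#' @param samples a [sample_table()] with declared metabolite columns.
#' @return object of class `resilience_summary`: per-partition counts,
#'   mean/min/max false-positive rate, plus `rate_vs_metabolites`
#'   (Spearman rho and p, `NA` when fewer than 3 metabolite-bearing false
#'   positives).
#' @export
false_positive_resilience <- function(consistency, samples) {
  met_cols <- metabolite_columns(samples)
  if (!length(met_cols)) stop("samples declare no metabolite columns")
  cons <- consistency[consistency$truth == "absent" &
                        consistency$misclassification_pct > 0, , drop = FALSE]
  if (!nrow(cons)) {
    out <- list(partitions = data.frame(), rate_vs_metabolites = c(
      rho = NA_real_, p = NA_real_), n_false_positive = 0L)
    class(out) <- "resilience_summary"
    return(out)
  }
  met_sum <- rowSums(as.matrix(samples[cons$sample_id, met_cols,
                                       drop = FALSE]))
  has_met <- met_sum > 0
  part <- function(sel, label) {
    if (!any(sel)) return(data.frame(partition = label, n = 0L,
                                     mean_rate = NA_real_, min_rate = NA_real_,
                                     max_rate = NA_real_))
    r <- cons$misclassification_pct[sel]
    data.frame(partition = label, n = sum(sel), mean_rate = mean(r),
               min_rate = min(r), max_rate = max(r))
  }
  partitions <- rbind(part(has_met, "metabolites_present"),
                      part(!has_met, "clean"))
  corr <- c(rho = NA_real_, p = NA_real_)
  if (sum(has_met) >= 3) {
    ct <- suppressWarnings(stats::cor.test(
      cons$misclassification_pct[has_met], met_sum[has_met],
      method = "spearman", exact = FALSE))
    corr <- c(rho = unname(ct$estimate), p = ct$p.value)
  }
  out <- list(partitions = partitions,
              rate_vs_metabolites = corr,
              n_false_positive = nrow(cons),
              sample_ids = split(cons$sample_id, ifelse(
                has_met, "metabolites_present", "clean")))
  class(out) <- "resilience_summary"
  out
}

#' @export
print.resilience_summary <- function(x, ...) {
  cat(sprintf("<resilience_summary> %d false-positive sample(s)\n",
              x$n_false_positive))
  if (nrow(x$partitions)) print.data.frame(x$partitions, digits = 3)
  invisible(x)
}

#' ANN architecture for the cross-algorithm validator
#'
#' @param hidden hidden layer sizes (default `c(50, 40)`).
#' @param batch_size mini-batch size (default 4).
#' @param epochs maximum epochs (default 100).
#' @param patience early-stopping patience on validation loss (default 2).
#' @param learning_rate Adam step size (default 1e-3).
#' @return an object of class `ann_spec`.
#' @export
ann_spec <- function(hidden = c(50, 40), batch_size = 4, epochs = 100,
                     patience = 2, learning_rate = 1e-3) {
  structure(list(hidden = hidden, batch_size = batch_size, epochs = epochs,
                 patience = patience, learning_rate = learning_rate),
            class = "ann_spec")
}

#' Repeated k-fold neural-network cross-validation
#'
#' Repeated stratification-free threefold cross-validation of the MLP
#' validator: per repeat the samples are partitioned into `folds` subsets
#' (reshuffled every repeat), each subset in turn serves as the validation
#' fold (used both for early stopping and for prediction), the rest for
#' training. `repeats x folds` model fits yield `repeats` validated
#' predictions per sample; the per-sample misclassification rate is
#' aggregated over all of them. A sigmoid output > 0.5 predicts `present`.
#'
#' Inputs must be z-scored (the scaling contract of the network); pass the
#' matrix through [encode_and_scale()] first.
#'
#' @param x z-scored [feature_matrix()].
#' @param y response factor (`absent`/`present`).
#' @param spec an [ann_spec()].
#' @param repeats number of repeats (default 333).
#' @param folds folds per repeat (default 3).
#' @param seed integer seed.
#' @return object of class `ann_result`: data.frame `sample_id`, `truth`,
#'   `misclassification_pct`, `n_validations`; attribute `n_fits` counts the
#'   fitted models.
#' @export
ann_cross_validate <- function(x, y, spec = ann_spec(), repeats = 333,
                               folds = 3, seed = 1) {
  stopifnot(folds >= 2, repeats >= 1)
  if (!identical(attr(x, "scaling"), "zscored"))
    stop("ann_cross_validate requires z-scored input (see encode_and_scale)")
  xm <- as_plain_matrix(x)
  y <- align_response(y, rownames(xm))
  y01 <- as.numeric(y == "present")
  rng <- local_rng(seed)
  n <- nrow(xm)
  wrong <- integer(n); seen <- integer(n)
  n_fits <- 0L
  for (r in seq_len(repeats)) {
    fold_of <- rng$sample(rep(seq_len(folds), length.out = n))
    for (f in seq_len(folds)) {
      val <- which(fold_of == f)
      trn <- which(fold_of != f)
      fit <- mlp_fit(xm[trn, , drop = FALSE], y01[trn],
                     hidden = spec$hidden, batch_size = spec$batch_size,
                     epochs = spec$epochs, patience = spec$patience,
                     learning_rate = spec$learning_rate,
                     x_val = xm[val, , drop = FALSE], y_val = y01[val],
                     seed = rng$int())
      n_fits <- n_fits + 1L
      pred <- as.numeric(predict(fit, xm[val, , drop = FALSE]) > 0.5)
      wrong[val] <- wrong[val] + (pred != y01[val])
      seen[val] <- seen[val] + 1L
    }
  }
  out <- data.frame(sample_id = rownames(xm), truth = y,
                    misclassification_pct = 100 * wrong / seen,
                    n_validations = seen, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_fits") <- n_fits
  class(out) <- c("ann_result", "data.frame")
  out
}

#' Cross-algorithm agreement between forest and network
#'
#' Contingency of majority-misclassification (> 50% of repeated
#' predictions wrong) between the random-forest consistency analysis and
#' the ANN cross-validation, with the sample ids per cell.
#'
#' @param rf a [consistency_analysis()] result.
#' @param ann an [ann_cross_validate()] result (or any data.frame with
#'   `sample_id` and `misclassification_pct`).
#' @return list with `table` (2x2 counts) and `samples` (ids per cell).
#' @export
cross_algorithm_agreement <- function(rf, ann) {
  if (!setequal(rf$sample_id, ann$sample_id))
    stop("sample sets differ between the two analyses")
  ann <- ann[match(rf$sample_id, ann$sample_id), ]
  rf_wrong <- rf$misclassification_pct > 50
  ann_wrong <- ann$misclassification_pct > 50
  tab <- table(rf = factor(ifelse(rf_wrong, "wrong", "right"),
                           levels = c("wrong", "right")),
               ann = factor(ifelse(ann_wrong, "wrong", "right"),
                            levels = c("wrong", "right")))
  cells <- list(
    both_wrong = rf$sample_id[rf_wrong & ann_wrong],
    rf_only = rf$sample_id[rf_wrong & !ann_wrong],
    ann_only = rf$sample_id[!rf_wrong & ann_wrong],
    both_right = rf$sample_id[!rf_wrong & !ann_wrong])
  list(table = tab, samples = cells)
}
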