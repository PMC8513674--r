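#' Random-forest hyperparameters
#'
#' The forests are controlled by the number of trees and the "mtry factor":
#' the square-root default for classification mtry, multiplied by an integer
#' factor (and capped at the number of features).
#'
#' @param n_trees number of trees per forest.
#' @param mtry_factor integer multiplier of the floor-square-root default.
#' @param seed integer seed making training reproducible.
#' @return an object of class `hyper_params`.
#' @export
hyper_params <- function(n_trees = 10000, mtry_factor = 1, seed = 1) {
  stopifnot(n_trees >= 1, mtry_factor >= 1)
  structure(list(n_trees = as.integer(n_trees),
                 mtry_factor = as.integer(mtry_factor),
                 seed = as.integer(seed)),
            class = "hyper_params")
}

#' Number of candidate variables per tree node
#'
#' `min(floor(sqrt(n_features)) * mtry_factor, n_features)`. With factor 1
#' this is the classification default; larger factors widen the candidate
#' set, which helps with sparse abundance tables.
#'
#' @param n_features number of input features.
#' @param mtry_factor integer multiplier (>= 1).
#' @return integer mtry.
#' @export
derive_mtry <- function(n_features, mtry_factor) {
  stopifnot(n_features >= 1, mtry_factor >= 1)
  as.integer(min(floor(sqrt(n_features)) * mtry_factor, n_features))
}

#' Train a classification random forest
#'
#' Wraps a ranger ensemble: `n_trees` trees grown on bootstrap samples, with
#' `derive_mtry()` candidate features per split, Gini impurity, unlimited
#' depth and minimum node size 1. Out-of-bag (OOB) class predictions and the
#' OOB error are recorded; samples never out of bag (possible at very small
#' tree counts) get `NA` and are excluded from the OOB error with a warning.
#'
#' @param x a [feature_matrix()] or numeric matrix with sample rownames.
#' @param y response factor (levels `absent`, `present`), named by sample or
#'   aligned with `x` rows.
#' @param hp a [hyper_params()].
#' @param importance `"none"`, `"impurity"` or `"permutation"` (forwarded to
#'   ranger; used by the importance estimators).
#' @return an object of class `tnt_forest`.
#' @export
train_forest <- function(x, y, hp = hyper_params(), importance = "none") {
  x <- as_plain_matrix(x)
  y <- align_response(y, rownames(x))
  if (nlevels(droplevels(y)) < 2)
    stop("response has a single class; cannot train a classifier")
  if (any(is.na(x))) stop("missing values in features")
  df <- data.frame(x, check.names = FALSE)
  fit <- ranger::ranger(
    x = df, y = y,
    num.trees = hp$n_trees,
    mtry = derive_mtry(ncol(x), hp$mtry_factor),
    min.node.size = 1,
    importance = importance,
    seed = hp$seed,
    num.threads = 1,
    oob.error = TRUE,
    write.forest = TRUE)
  oob <- fit$predictions
  never_oob <- is.na(oob)
  if (any(never_oob))
    warning(sum(never_oob), " sample(s) never out of bag; excluded from ",
            "OOB error")
  oob_err <- mean(oob[!never_oob] != y[!never_oob])
  structure(list(fit = fit, hp = hp, feature_names = colnames(x),
                 levels = levels(y), y = stats::setNames(y, rownames(x)),
                 oob_predictions = stats::setNames(oob, rownames(x)),
                 oob_error = oob_err),
            class = "tnt_forest")
}

#' @export
print.tnt_forest <- function(x, ...) {
  cat(sprintf(paste0("<tnt_forest> %d trees, mtry %d (factor %d), ",
                     "%d features, OOB error %.3f\n"),
              x$hp$n_trees, derive_mtry(length(x$feature_names),
                                        x$hp$mtry_factor),
              x$hp$mtry_factor, length(x$feature_names), x$oob_error))
  invisible(x)
}

#' Predict classes by majority vote
#'
#' Per-sample majority-vote class over the trees plus the vote fraction for
#' each class. Exact vote ties are broken in favour of the class with the
#' larger training prevalence, then lexicographically.
#'
#' @param object a [train_forest()] model.
#' @param newdata feature matrix with the training feature columns.
#' @param ... unused.
#' @return data.frame: `sample_id`, `predicted`, one vote-fraction column per
#'   class.
#' @export
predict.tnt_forest <- function(object, newdata, ...) {
  x <- as_plain_matrix(newdata)
  if (!identical(colnames(x), object$feature_names)) {
    if (!all(object$feature_names %in% colnames(x)))
      stop("feature mismatch: newdata lacks training features")
    x <- x[, object$feature_names, drop = FALSE]
  }
  pr <- stats::predict(object$fit, data = data.frame(x, check.names = FALSE),
                       predict.all = TRUE, num.threads = 1)
  votes <- pr$predictions  # n x trees, integer codes into forest levels
  lev <- object$fit$forest$levels
  frac <- t(apply(votes, 1, function(v)
    tabulate(v, nbins = length(lev)) / length(v)))
  colnames(frac) <- lev
  frac <- frac[, object$levels, drop = FALSE]
  prev <- table(object$y)[object$levels]
  pred <- apply(frac, 1, function(f) {
    top <- which(f == max(f))
    if (length(top) > 1) {
      top <- top[order(-prev[top], object$levels[top])][1]
    }
    object$levels[top]
  })
  out <- data.frame(sample_id = rownames(x),
                    predicted = factor(pred, levels = object$levels),
                    frac, check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Forest proximity matrix
#'
#' Proximity between two samples is the fraction of trees in which they land
#' in the same terminal node: symmetric, unit diagonal, entries in [0, 1].
#'
#' @param model a [train_forest()] model.
#' @param x feature matrix of the samples to compare (training features).
#' @return n x n proximity matrix with sample ids as dimnames.
#' @export
proximity_matrix <- function(model, x) {
  x <- as_plain_matrix(x)[, model$feature_names, drop = FALSE]
  tn <- stats::predict(model$fit, data = data.frame(x, check.names = FALSE),
                       type = "terminalNodes", num.threads = 1)$predictions
  n <- nrow(tn); n_trees <- ncol(tn)
  P <- matrix(0, n, n)
  for (t in seq_len(n_trees)) {
    f <- factor(tn[, t])
    M <- matrix(0, n, nlevels(f))
    M[cbind(seq_len(n), as.integer(f))] <- 1
    P <- P + tcrossprod(M)
  }
  P <- P / n_trees
  dimnames(P) <- list(rownames(x), rownames(x))
  P
}

#' Unsupervised random forest via shuffled-column synthetic data
#'
#' Builds a synthetic copy of the data by independently permuting each
#' column (breaking all between-variable relationships while keeping every
#' marginal), labels rows `real`/`synthetic`, trains a forest to tell them
#' apart, and returns the proximity matrix restricted to the real samples.
#' High real-vs-real proximity then reflects intrinsic correlation structure.
#'
#' @param x feature matrix of the real samples.
#' @param hp a [hyper_params()]; `hp$seed` also seeds the column shuffles.
#' @return list with `model` (the discriminating [train_forest()] fit,
#'   OOB accuracy readable from it), `proximity` (real samples only) and
#'   `synthetic` (the shuffled copy).
#' @export
unsupervised_forest <- function(x, hp = hyper_params()) {
  x <- as_plain_matrix(x)
  if (nrow(x) < 2) stop("need at least 2 samples")
  rng <- local_rng(hp$seed)
  synth <- apply(x, 2, function(col) col[rng$sample(length(col))])
  rownames(synth) <- paste0(".synthetic_", seq_len(nrow(x)))
  both <- rbind(x, synth)
  y <- factor(rep(c("real", "synthetic"), each = nrow(x)))
  names(y) <- rownames(both)
  model <- train_forest(both, y, hp)
  prox <- proximity_matrix(model, both[seq_len(nrow(x)), , drop = FALSE])
  list(model = model, proximity = prox, synthetic = synth)
}

# --- internals ---------------------------------------------------------------

as_plain_matrix <- function(x) {
  if (inherits(x, "feature_matrix")) x <- fm_values(x)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(rownames(x))) rownames(x) <- paste0("s", seq_len(nrow(x)))
  x
}

align_response <- function(y, ids) {
  y <- as.factor(y)
  if (!is.null(names(y)) && all(ids %in% names(y))) y <- y[ids]
  if (length(y) != length(ids)) stop("response length does not match samples")
  y
}

# private RNG stream so package operations do not disturb the caller's RNG
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  with_state <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    expr
  }
  list(
    sample = function(...) with_state(sample(...)),
    runif = function(...) with_state(stats::runif(...)),
    rnorm = function(...) with_state(stats::rnorm(...)),
    rbinom = function(...) with_state(stats::rbinom(...)),
    rlnorm = function(...) with_state(stats::rlnorm(...)),
    rnbinom = function(...) with_state(stats::rnbinom(...)),
    rmultinom = function(...) with_state(stats::rmultinom(...)),
    int = function(n = 1) with_state(sample.int(.Machine$integer.max - 1, n))
  )
}
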