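#' Ordinate samples from a forest proximity matrix
#'
#' Proximity is a similarity; classical principal-coordinates analysis
#' (PCoA) is run on the complement `D = 1 - P`. If `D` is not Euclidean
#' (negative eigenvalues beyond numerical noise) the square-root corrected
#' dissimilarity `sqrt(D)` is used instead. Axes are ordered by eigenvalue;
#' each axis' explained fraction is its eigenvalue over the positive
#' eigenvalue sum. Axis signs are fixed so that the lexicographically
#' smallest sample id scores non-negatively, making plots reproducible.
#'
#' @param proximity symmetric proximity matrix (unit diagonal, \[0,1\]).
#' @param n_axes number of axes to return (default 2).
#' @return object of class `ordination_result`: `scores` (samples x axes),
#'   `explained` (fractions), `eigenvalues`, `sqrt_corrected` flag.
#' @export
ordinate_from_proximity <- function(proximity, n_axes = 2) {
  P <- as.matrix(proximity)
  if (nrow(P) != ncol(P) || max(abs(P - t(P))) > 1e-8)
    stop("proximity matrix must be square and symmetric")
  if (any(P < -1e-9) || any(P > 1 + 1e-9))
    stop("proximity entries must lie in [0, 1]")
  D <- 1 - P
  diag(D) <- 0
  dec <- pcoa_decompose(D)
  if (min(dec$eig) < -1e-8 * max(abs(dec$eig))) {
    dec <- pcoa_decompose(sqrt(D))
    sqrt_corrected <- TRUE
  } else sqrt_corrected <- FALSE
  pos <- dec$eig > 1e-12 * max(abs(dec$eig), 1e-300)
  rank <- sum(pos)
  k <- n_axes
  if (k > rank) {
    warning("requested ", n_axes, " axes but rank is ", rank,
            "; truncating")
    k <- max(rank, 1L)
  }
  scores <- dec$vectors[, seq_len(k), drop = FALSE]
  rownames(scores) <- rownames(P)
  colnames(scores) <- paste0("PC", seq_len(k))
  ref <- if (!is.null(rownames(P))) order(rownames(P))[1] else 1L
  flip <- scores[ref, ] < 0
  scores[, flip] <- -scores[, flip, drop = FALSE]
  explained <- dec$eig[seq_len(k)] / sum(dec$eig[pos])
  structure(list(scores = scores,
                 explained = pmax(explained, 0),
                 eigenvalues = dec$eig,
                 sqrt_corrected = sqrt_corrected),
            class = "ordination_result")
}

pcoa_decompose <- function(D) {
  n <- nrow(D)
  A <- -0.5 * D^2
  C <- diag(n) - matrix(1 / n, n, n)
  B <- C %*% A %*% C
  ed <- eigen((B + t(B)) / 2, symmetric = TRUE)
  vec <- ed$vectors
  lam <- ed$values
  keep <- lam > 1e-12 * max(abs(lam), 1e-300)
  vec_scaled <- vec
  vec_scaled[, keep] <- sweep(vec[, keep, drop = FALSE], 2,
                              sqrt(lam[keep]), "*")
  list(eig = lam, vectors = vec_scaled)
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf("<ordination_result> %d samples, %d axes; explained: %s%s\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", "),
              if (x$sqrt_corrected) " (sqrt-corrected)" else ""))
  invisible(x)
}

#' Fit environmental vectors onto an ordination
#'
#' Least-squares projection of each (numeric) environmental variable onto
#' the first two ordination axes, with squared multiple correlation R^2 and
#' a permutation p-value (variable rows permuted), via `vegan::envfit`.
#' Constant variables get R^2 = 0 and p = 1 with a warning.
#'
#' @param ordination an [ordinate_from_proximity()] result (>= 2 axes).
#' @param env numeric matrix/data.frame of environmental variables over the
#'   same samples.
#' @param n_perm number of permutations (default 9999).
#' @param seed integer seed for the permutations.
#' @return object of class `vector_fit`: data.frame `variable`, `axis1`,
#'   `axis2` (direction cosines), `r2`, `p_value`.
#' @export
fit_environment_vectors <- function(ordination, env, n_perm = 9999,
                                    seed = 1) {
  scores <- ordination$scores
  if (ncol(scores) < 2) stop("need at least 2 ordination axes")
  env <- as.matrix(env)
  storage.mode(env) <- "double"
  if (is.null(rownames(env))) stop("env needs sample rownames")
  if (!all(rownames(scores) %in% rownames(env)))
    stop("env does not cover the ordinated samples")
  env <- env[rownames(scores), , drop = FALSE]
  const <- apply(env, 2, function(v) stats::var(v) == 0)
  if (any(const))
    warning("constant variable(s) get R^2 = 0, p = 1: ",
            paste(colnames(env)[const], collapse = ", "))
  out <- data.frame(variable = colnames(env),
                    axis1 = 0, axis2 = 0, r2 = 0, p_value = 1,
                    stringsAsFactors = FALSE)
  use <- which(!const)
  if (length(use)) {
    set.seed(seed)
    ef <- vegan::envfit(scores[, 1:2], env[, use, drop = FALSE],
                        permutations = n_perm)
    out$axis1[use] <- ef$vectors$arrows[, 1]
    out$axis2[use] <- ef$vectors$arrows[, 2]
    out$r2[use] <- ef$vectors$r
    out$p_value[use] <- ef$vectors$pvals
  }
  rownames(out) <- NULL
  class(out) <- c("vector_fit", "data.frame")
  out
}

#' Filter fitted vectors by the display rule
#'
#' @param fit a [fit_environment_vectors()] result.
#' @param p_max strict upper bound on the permutation p-value
#'   (default 0.001).
#' @param r2_min strict lower bound on R^2 (default 0.3).
#' @return the filtered `vector_fit` rows.
#' @export
display_vectors <- function(fit, p_max = 0.001, r2_min = 0.3) {
  fit[fit$p_value < p_max & fit$r2 > r2_min, , drop = FALSE]
}

#' Spearman correlation structure of the sediment variables
#'
#' Pairwise Spearman rank correlations with p-values, hierarchically
#' ordered by average-linkage clustering on `1 - |rho|`, and flagged
#' significant at `p < p_flag`. Zero-variance columns yield `NA`
#' correlations and unflagged pairs.
#'
#' @param env numeric matrix/data.frame (>= 3 samples).
#' @param p_flag significance threshold (default 0.01).
#' @return object of class `spearman_cluster`: `rho`, `p_value`,
#'   `significant` matrices (variables ordered by the clustering) and the
#'   `hclust` tree.
#' @export
spearman_correlation_cluster <- function(env, p_flag = 0.01) {
  env <- as.matrix(env)
  if (nrow(env) < 3) stop("need at least 3 samples")
  p <- ncol(env)
  rho <- matrix(NA_real_, p, p, dimnames = list(colnames(env), colnames(env)))
  pv <- rho
  for (i in seq_len(p)) for (j in i:p) {
    vi <- env[, i]; vj <- env[, j]
    if (stats::var(vi) == 0 || stats::var(vj) == 0) next
    if (i == j) { rho[i, j] <- 1; pv[i, j] <- 0; next }
    ct <- suppressWarnings(stats::cor.test(vi, vj, method = "spearman",
                                           exact = FALSE))
    rho[i, j] <- rho[j, i] <- unname(ct$estimate)
    pv[i, j] <- pv[j, i] <- ct$p.value
  }
  d <- 1 - abs(rho)
  d[is.na(d)] <- 1
  diag(d) <- 0
  tree <- stats::hclust(stats::as.dist(d), method = "average")
  ord <- tree$order
  structure(list(rho = rho[ord, ord], p_value = pv[ord, ord],
                 significant = (pv < p_flag)[ord, ord],
                 tree = tree),
            class = "spearman_cluster")
}

#' @export
print.spearman_cluster <- function(x, ...) {
  cat(sprintf("<spearman_cluster> %d variables, %d significant pair(s)\n",
              nrow(x$rho),
              sum(x$significant[upper.tri(x$significant)], na.rm = TRUE)))
  invisible(x)
}
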