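test_that("mtry derivation follows the floor-sqrt-times-factor convention", {
  expect_identical(derive_mtry(542, 5), 115L)
  expect_identical(derive_mtry(41, 1), 6L)
  expect_identical(derive_mtry(9, 13), 9L)   # capped at feature count
  # factor 1 reproduces the floor-sqrt default across feature counts
  for (p in c(1, 2, 3, 7, 10, 99, 100, 101, 1024, 5000, 10000))
    expect_identical(derive_mtry(p, 1), as.integer(floor(sqrt(p))))
  expect_error(derive_mtry(0, 1))
})

test_that("training is seed-deterministic and learns separable data", {
  sep <- fixture_separable(n = 40, p = 5)
  f1 <- train_forest(sep$x, sep$y, hyper_params(300, 2, seed = 7))
  f2 <- train_forest(sep$x, sep$y, hyper_params(300, 2, seed = 7))
  expect_identical(f1$oob_predictions, f2$oob_predictions)
  expect_lt(f1$oob_error, 0.10)
  expect_error(train_forest(sep$x, factor(rep("absent", 40))),
               "single class")
})

test_that("label-shuffled data scores at chance OOB balanced accuracy", {
  sep <- fixture_separable(n = 80)
  set.seed(8)
  y_null <- sample(sep$y)
  names(y_null) <- names(sep$y)
  bas <- vapply(1:10, function(i) {
    f <- train_forest(sep$x, y_null, hyper_params(300, 1, seed = i))
    ok <- !is.na(f$oob_predictions)
    balanced_accuracy(y_null[ok], f$oob_predictions[ok])
  }, numeric(1))
  expect_lt(abs(mean(bas) - 0.5), 0.1)
})

test_that("majority-vote prediction returns coherent vote fractions", {
  sep <- fixture_separable()
  fit <- train_forest(sep$x, sep$y, hyper_params(100, 1, seed = 3))
  pr <- predict(fit, sep$x)
  expect_equal(rowSums(pr[, c("absent", "present")]), rep(1, 40),
               ignore_attr = TRUE)
  # resubstitution on separable data is near-perfect
  expect_lt(mean(pr$predicted != sep$y), 0.05)
  expect_error(predict(fit, sep$x[, 1:3]), "feature mismatch")
})

test_that("proximity matches brute-force tree-pair counting exactly", {
  sep <- fixture_separable(n = 30, p = 5, seed = 9)
  fit <- train_forest(sep$x, sep$y, hyper_params(50, 1, seed = 11))
  P <- proximity_matrix(fit, sep$x)
  expect_equal(diag(P), rep(1, 30), ignore_attr = TRUE)
  expect_equal(P, t(P))
  expect_true(all(P >= 0 & P <= 1))
  tn <- predict(fit$fit, data = data.frame(sep$x, check.names = FALSE),
                type = "terminalNodes", num.threads = 1)$predictions
  Pb <- matrix(0, 30, 30)
  for (i in 1:30) for (j in 1:30) Pb[i, j] <- mean(tn[i, ] == tn[j, ])
  expect_equal(unname(P), Pb)
})

test_that("unsupervised forest separates clustered data, not noise", {
  set.seed(21)
  n <- 30
  cl <- rep(c(0, 6), each = n / 2)
  x <- matrix(rnorm(n * 4), n, 4) + cl
  dimnames(x) <- list(sprintf("S%02d", 1:n), paste0("f", 1:4))
  u <- unsupervised_forest(x, hyper_params(200, 1, seed = 5))
  # synthetic copy permutes columns: marginals preserved
  P <- u$proximity
  within <- c(P[1:15, 1:15][upper.tri(P[1:15, 1:15])],
              P[16:30, 16:30][upper.tri(P[16:30, 16:30])])
  between <- P[1:15, 16:30]
  expect_gt(mean(within), mean(between))
  # clustered data is discriminated well above the iid-noise level ...
  expect_gt(1 - u$model$oob_error, 0.6)
  # ... while i.i.d. noise is not above chance (exact value twins in the
  # shuffled copy in fact pull iid-noise OOB accuracy below 0.5)
  xn <- matrix(rnorm(n * 4), n, 4,
               dimnames = list(sprintf("S%02d", 1:n), paste0("f", 1:4)))
  errs <- vapply(1:3, function(i)
    unsupervised_forest(xn, hyper_params(200, 1, seed = i))$model$oob_error,
    numeric(1))
  expect_lt(mean(1 - errs), 0.55)
})

test_that("shuffled-column synthetic data preserves per-column marginals", {
  sep <- fixture_separable(n = 20, p = 4)
  u <- unsupervised_forest(sep$x, hyper_params(30, 1, seed = 2))
  expect_equal(apply(u$synthetic, 2, sort), apply(sep$x, 2, sort))
  expect_false(identical(u$synthetic, sep$x))
  expect_equal(as.character(sort(unname(u$model$y))),
               rep(c("real", "synthetic"), each = 20))
})

test_that("corrected-impurity importance ranks a planted feature first", {
  set.seed(31)
  n <- 80
  y <- factor(rep(c("absent", "present"), each = n / 2))
  x <- matrix(rnorm(n * 160), n, 160,
              dimnames = list(sprintf("S%02d", 1:n), paste0("f", 1:160)))
  x[, 1] <- x[, 1] + ifelse(y == "present", 2.5, 0)
  names(y) <- rownames(x)
  imp <- importance_corrected_janitza(x, y, hyper_params(300, 2, seed = 4),
                                      m_models = 5)
  expect_equal(imp$feature[which.max(imp$importance)], "f1")
  expect_equal(imp$feature[which.min(imp$p_value)], "f1")
  expect_lt(imp$p_value[imp$feature == "f1"], 0.01)
  expect_true(all(imp$p_value > 0 & imp$p_value <= 1))
  # constant column: unsplittable, importance <= 0, p near 1
  xc <- cbind(x, const = 0)
  imp2 <- importance_corrected_janitza(xc, y, hyper_params(200, 2, seed = 5),
                                       m_models = 5)
  expect_lte(imp2$importance[imp2$feature == "const"], 0)
  expect_gt(imp2$p_value[imp2$feature == "const"], 0.5)
})

test_that("corrected impurity agrees with ranger's own corrected scheme", {
  # independent cross-check: ranger's Nembrini-style corrected impurity
  # should rank features similarly to the shadow-variable realization
  set.seed(33)
  n <- 100
  y <- factor(rep(c("absent", "present"), each = n / 2))
  x <- matrix(rnorm(n * 30), n, 30,
              dimnames = list(sprintf("S%03d", 1:n), paste0("f", 1:30)))
  x[, 1] <- x[, 1] + ifelse(y == "present", 2, 0)
  x[, 2] <- x[, 2] + ifelse(y == "present", 1, 0)
  x[, 3] <- x[, 3] + ifelse(y == "present", 0.5, 0)
  names(y) <- rownames(x)
  mine <- importance_corrected_janitza(x, y, hyper_params(500, 2, seed = 6),
                                       m_models = 5)
  rf <- ranger::ranger(x = data.frame(x), y = y, num.trees = 500,
                       importance = "impurity_corrected", seed = 6,
                       num.threads = 1)
  top3 <- function(v, nm) nm[order(-v)][1:3]
  expect_setequal(top3(mine$importance, mine$feature), c("f1", "f2", "f3"))
  expect_setequal(top3(rf$variable.importance,
                       names(rf$variable.importance)), c("f1", "f2", "f3"))
  expect_equal(mine$feature[which.max(mine$importance)],
               names(which.max(rf$variable.importance)))
})

test_that("permutation importance p-values follow the Altmann formula", {
  set.seed(41)
  n <- 40
  y <- factor(rep(c("absent", "present"), each = n / 2))
  x <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(sprintf("S%02d", 1:n), paste0("f", 1:4)))
  x[, 1] <- x[, 1] + ifelse(y == "present", 5, 0)  # dominates every null
  names(y) <- rownames(x)
  imp <- importance_permutation_altmann(x, y, hyper_params(60, 1, seed = 1),
                                        n_perm = 100)
  # observed exceeds all 100 permuted values: p = 1/101
  expect_equal(imp$p_value[imp$feature == "f1"], 1 / 101)
  # p can never be 0 nor exceed 1
  expect_true(all(imp$p_value >= 1 / 101 & imp$p_value <= 1))
})

test_that("top-feature selection applies strict cutoffs in order", {
  imp <- tntfinger:::importance_result(
    c("a", "b", "c", "d"), c(0.5, 0.25, 0.3, -0.1),
    c(0.001, 0.001, 0.5, 0.9), "corrected_impurity_janitza")
  expect_equal(select_top_features(imp, -Inf, 1.01), c("a", "c", "b", "d"))
  # importance exactly at the cutoff is excluded (strict >)
  expect_equal(select_top_features(imp, 0.25, 0.01), "a")
  expect_equal(select_top_features(imp, -Inf, 1.01, n_top = 2), c("a", "c"))
})
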