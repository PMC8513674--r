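test_that("consistency rates are per-sample OOB error frequencies", {
  sep <- fixture_separable(n = 30, p = 4)
  cons <- consistency_analysis(sep$x, sep$y, hyper_params(100, 1, seed = 2),
                               m_models = 20)
  expect_equal(nrow(cons), 30)
  expect_true(all(cons$misclassification_pct >= 0 &
                    cons$misclassification_pct <= 100))
  # separable samples are consistently correct (rounded to 0)
  expect_gt(sum(cons$misclassification_pct == 0), 20)
  # the rounding rule never touches rates inside [0.5, 99.5]
  inside <- cons$misclassification_pct > 0 & cons$misclassification_pct < 100
  expect_true(all(!cons$rounded[inside]))
  # rate arithmetic: 710 wrong out of 1000 models reads 71%
  expect_equal(100 * 710 / 1000, 71)
  # a rate of 0.3% rounds to 0: emulate via near-perfect sample
  expect_true(all(cons$misclassification_pct[cons$rounded] %in% c(0, 100)))
})

test_that("consistency rates stabilize as models accumulate", {
  set.seed(12)
  n <- 40
  y <- factor(rep(c("absent", "present"), each = n / 2))
  x <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(sprintf("S%02d", 1:n), paste0("f", 1:5)))
  x[, 1] <- x[, 1] + ifelse(y == "present", 1.5, 0)  # imperfect signal
  names(y) <- rownames(x)
  c1 <- consistency_analysis(x, y, hyper_params(200, 1, seed = 3),
                             m_models = 60)
  c2 <- consistency_analysis(x, y, hyper_params(200, 1, seed = 4),
                             m_models = 120)
  drift <- abs(c1$misclassification_pct - c2$misclassification_pct)
  expect_lt(stats::median(drift), 5)
})

test_that("false-positive resilience separates historical from clean samples", {
  ds <- generate_dataset(synth_config(n_samples = 100, n_taxa = 150,
                                      n_indicator_taxa = 15,
                                      indicator_effect = 3,
                                      historical_fraction = 0.15, seed = 31))
  pct <- to_relative_abundance(ds$community)
  x <- as_feature_matrix(filter_by_threshold(pct, 0.02))
  y <- binarize_response(ds$samples)
  cons <- consistency_analysis(x, y, hyper_params(300, 1, seed = 32),
                               m_models = 40)
  res <- false_positive_resilience(cons, ds$samples)
  parts <- res$partitions
  met <- parts[parts$partition == "metabolites_present", ]
  cln <- parts[parts$partition == "clean", ]
  expect_gt(met$n, 0)
  # historical (metabolite-bearing) absent samples are misclassified more
  rates <- cons$misclassification_pct
  names(rates) <- cons$sample_id
  hist_ids <- names(which(ds$truth$historical))
  clean_ids <- names(which(!ds$truth$historical & !ds$truth$tnt_present))
  expect_gt(mean(rates[hist_ids]), mean(rates[clean_ids]))
})

test_that("resilience bookkeeping handles empty and partitioned cases", {
  cons <- structure(data.frame(
    sample_id = paste0("S", 1:4),
    truth = factor(c("absent", "absent", "absent", "present"),
                   levels = c("absent", "present")),
    majority_predicted = factor(rep("absent", 4),
                                levels = c("absent", "present")),
    misclassification_pct = c(40, 10, 0, 5),
    rounded = FALSE), class = c("consistency_result", "data.frame"))
  df <- data.frame(sample_id = paste0("S", 1:4), tnt_pmol_g = c(0, 0, 0, 9),
                   adnt2_pmol_g = c(3, 0, 0, 1),
                   adnt4_pmol_g = 0,
                   replicate_group = paste0("S", 1:4))
  smp <- sample_table(df, metabolite_cols = c("adnt2_pmol_g", "adnt4_pmol_g"))
  res <- false_positive_resilience(cons, smp)
  # S1 (metabolites, 40%) and S2 (clean, 10%); S3 never misclassified
  expect_equal(res$n_false_positive, 2)
  parts <- res$partitions
  expect_equal(parts$mean_rate[parts$partition == "metabolites_present"], 40)
  expect_equal(parts$mean_rate[parts$partition == "clean"], 10)
  # no false positives at all -> empty summary
  cons0 <- cons; cons0$misclassification_pct <- c(0, 0, 0, 5)
  res0 <- false_positive_resilience(cons0, smp)
  expect_equal(res0$n_false_positive, 0)
})

test_that("the MLP learns separable data and stalls on shuffled labels", {
  set.seed(51)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  x <- matrix(rnorm(n * 5), n, 5)
  x[, 1] <- x[, 1] + y * 4
  x <- scale(x)
  fit <- mlp_fit(x, y, hidden = c(20, 10), seed = 1, epochs = 60,
                 x_val = x, y_val = y)
  expect_lt(mean((predict(fit, x) > 0.5) != y), 0.05)
  # determinism given the seed
  fit2 <- mlp_fit(x, y, hidden = c(20, 10), seed = 1, epochs = 60,
                  x_val = x, y_val = y)
  expect_identical(fit$W, fit2$W)
  # early stopping restores the best-validation weights
  expect_true(is.finite(fit$val_loss))
  expect_lte(fit$epochs_run, 60)
})

test_that("ANN cross-validation respects the fit counter and scaling contract", {
  set.seed(61)
  n <- 24
  y <- factor(rep(c("absent", "present"), each = n / 2))
  x <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(sprintf("S%02d", 1:n), paste0("f", 1:4)))
  x[, 1] <- x[, 1] + ifelse(y == "present", 5, 0)
  names(y) <- rownames(x)
  xz <- encode_and_scale(feature_matrix(x, origin = "environmental"))
  spec <- ann_spec(hidden = c(8, 6), learning_rate = 0.01)
  res <- ann_cross_validate(xz, y, spec, repeats = 4, folds = 3, seed = 7)
  expect_identical(attr(res, "n_fits"), 12L)     # repeats x folds
  expect_true(all(res$n_validations == 4))       # one validation per repeat
  # separable data: near-zero per-sample error
  expect_lt(mean(res$misclassification_pct), 15)
  # raw input violates the scaling contract
  expect_error(ann_cross_validate(feature_matrix(x, origin = "environmental"),
                                  y, spec, repeats = 1, seed = 1),
               "z-scored")
})

test_that("label-shuffled ANN cross-validation hovers near 50% error", {
  set.seed(62)
  n <- 24
  x <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(sprintf("S%02d", 1:n), paste0("f", 1:4)))
  y <- factor(sample(rep(c("absent", "present"), n / 2)))
  names(y) <- rownames(x)
  xz <- encode_and_scale(feature_matrix(x, origin = "environmental"))
  res <- ann_cross_validate(xz, y, ann_spec(hidden = c(8, 6), epochs = 10),
                            repeats = 6, folds = 3, seed = 8)
  expect_lt(abs(mean(res$misclassification_pct) - 50), 25)
})

test_that("cross-algorithm agreement tabulates co-misclassification", {
  rf <- structure(data.frame(
    sample_id = paste0("S", 1:4),
    truth = factor(rep("absent", 4), levels = c("absent", "present")),
    majority_predicted = factor(rep("absent", 4),
                                levels = c("absent", "present")),
    misclassification_pct = c(90, 10, 60, 0), rounded = FALSE),
    class = c("consistency_result", "data.frame"))
  ann <- data.frame(sample_id = paste0("S", 4:1),
                    misclassification_pct = c(0, 70, 5, 95))
  agr <- cross_algorithm_agreement(rf, ann)
  expect_equal(unname(agr$table["wrong", "wrong"]), 2)  # S1, S3
  expect_setequal(agr$samples$both_wrong, c("S1", "S3"))
  expect_equal(unname(agr$table["right", "right"]), 2)
  # identical rates -> perfect agreement
  ann2 <- rf[, c("sample_id", "misclassification_pct")]
  agr2 <- cross_algorithm_agreement(rf, ann2)
  expect_equal(unname(agr2$table["wrong", "right"]), 0)
  expect_equal(unname(agr2$table["right", "wrong"]), 0)
  expect_error(cross_algorithm_agreement(rf, data.frame(
    sample_id = "X", misclassification_pct = 1)), "differ")
})
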