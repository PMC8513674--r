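test_that("relative abundance converts counts to row-sum-100 percent", {
  counts <- matrix(c(2, 3, 5), 1, 3,
                   dimnames = list("S1", paste0("A", 1:3)))
  pct <- to_relative_abundance(community_table(counts))
  expect_equal(unname(pct$values[1, ]), c(20, 30, 50))
  single <- community_table(matrix(7, 1, 1, dimnames = list("S1", "A1")))
  expect_equal(unname(to_relative_abundance(single)$values[1, 1]), 100)
  # property: rows sum to 100 for random count matrices
  set.seed(1)
  for (i in 1:50) {
    m <- matrix(rpois(30, 5) + 1, 5, 6,
                dimnames = list(paste0("S", 1:5), paste0("A", 1:6)))
    expect_equal(unname(rowSums(to_relative_abundance(
      community_table(m))$values)), rep(100, 5))
  }
  zero <- community_table(matrix(c(1, 0), 2, 1,
                                 dimnames = list(c("S1", "S2"), "A1")))
  expect_error(to_relative_abundance(zero), "zero-sum")
})

test_that("threshold filtering is strict and monotone", {
  vals <- rbind(c(0.05, 0.2, 1.0), c(0.02, 0.1, 0.5))
  vals <- cbind(vals, 100 - rowSums(vals))
  dimnames(vals) <- list(c("S1", "S2"), paste0("A", 1:4))
  ct <- community_table(vals, unit = "percent")
  expect_equal(ncol(filter_by_threshold(ct, 0.1)$values), 3)  # A2, A3, A4
  # feature with max exactly at the threshold is removed
  expect_false("A1" %in% colnames(filter_by_threshold(ct, 0.05)$values))
  # threshold 0 keeps everything with any nonzero abundance
  expect_equal(ncol(filter_by_threshold(ct, 0)$values), 4)
  expect_error(filter_by_threshold(ct, -1), ">= 0")
  # monotone: larger threshold keeps a subset
  set.seed(2)
  m <- matrix(runif(60), 6, 10)
  m <- m / rowSums(m) * 100
  dimnames(m) <- list(paste0("S", 1:6), paste0("A", 1:10))
  cm <- community_table(m, unit = "percent")
  for (pair in list(c(0.5, 2), c(1, 5), c(2, 10))) {
    lo <- colnames(filter_by_threshold(cm, pair[1])$values)
    hi <- colnames(filter_by_threshold(cm, pair[2])$values)
    expect_true(all(hi %in% lo))
  }
})

test_that("agglomeration sums lineages and labels unclassified features", {
  vals <- matrix(c(1.2, 0.3, 2, 90, 6.5), 1, 5,
                 dimnames = list("S1", paste0("ASV", 1:5)))
  ct <- community_table(vals, unit = "percent")
  agg <- agglomerate_rank(ct, fixture_taxonomy(), "genus")
  # ASV1 + ASV2 share genus G1: 1.2 + 0.3 = 1.5
  expect_equal(unname(agg$values[1, "G1"]), 1.5)
  # ASV3 lacks a genus, family Gemmatimonadaceae
  expect_true("unclassified Gemmatimonadaceae" %in% colnames(agg$values))
  expect_equal(unname(agg$values[1, "unclassified Gemmatimonadaceae"]), 2)
  expect_equal(agg$rank, "genus")
  expect_error(agglomerate_rank(ct, fixture_taxonomy(), "species"),
               "unknown rank")
})

test_that("agglomeration conserves per-sample totals on random fixtures", {
  set.seed(3)
  ds <- generate_dataset(synth_config(n_samples = 12, n_taxa = 60,
                                      n_indicator_taxa = 5, seed = 5))
  pct <- to_relative_abundance(ds$community)
  for (rk in c("genus", "family", "phylum")) {
    agg <- agglomerate_rank(pct, ds$taxonomy, rk)
    expect_equal(rowSums(agg$values), rowSums(pct$values))
    expect_true(ncol(agg$values) <= ncol(pct$values))
  }
})

test_that("control-feature removal uses a strict read cutoff and exemptions", {
  counts <- rbind(S1 = c(100, 500, 10, 3), S2 = c(80, 400, 5, 2),
                  CTRL = c(40, 75, 35, 2))
  colnames(counts) <- paste0("ASV", 1:4)
  ct <- community_table(counts)
  out <- remove_control_features(ct, "CTRL")
  # 40 > 35 removed; 75 > 35 removed; 35 kept (strict >); controls dropped
  expect_equal(colnames(out$values), c("ASV3", "ASV4"))
  expect_equal(rownames(out$values), c("S1", "S2"))
  # exemption keeps the abundant-in-samples feature despite 75 control reads
  out2 <- remove_control_features(ct, "CTRL", exemptions = "ASV2")
  expect_true("ASV2" %in% colnames(out2$values))
  # empty control set only implies no removal
  out3 <- remove_control_features(ct, character())
  expect_equal(ncol(out3$values), 4)
})

test_that("feature combination preserves tags and refuses collisions", {
  tax <- feature_matrix(matrix(1:4, 2, 2, dimnames = list(c("S1", "S2"),
                                                          c("t1", "t2"))),
                        origin = "taxon")
  env <- feature_matrix(matrix(5:8, 2, 2, dimnames = list(c("S2", "S1"),
                                                          c("e1", "e2"))),
                        origin = "environmental")
  both <- combine_features(tax, env)
  expect_equal(ncol(both), 4)
  expect_equal(attr(both, "origin"),
               c("taxon", "taxon", "environmental", "environmental"))
  expect_equal(both["S1", "e1"], 6)  # row alignment by id
  # associative over disjoint feature sets
  env2 <- feature_matrix(matrix(1, 2, 1, dimnames = list(c("S1", "S2"), "e3")),
                         origin = "environmental")
  a <- combine_features(combine_features(tax, env), env2)
  b <- combine_features(tax, combine_features(env, env2))
  expect_equal(unclass(a), unclass(b))
  bad <- feature_matrix(matrix(0, 2, 1, dimnames = list(c("S1", "S2"), "t1")),
                        origin = "environmental")
  expect_error(combine_features(tax, bad), "collision")
  expect_error(combine_features(tax, env[1, , drop = FALSE]),
               "sample sets differ")
})

test_that("encoding and scaling give population z-scores and indicators", {
  m <- matrix(c(1, 2, 3), 3, 1, dimnames = list(paste0("S", 1:3), "v"))
  fm <- feature_matrix(m, origin = "environmental")
  z <- encode_and_scale(fm)
  expect_equal(unname(z[, "v"]), c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_equal(attr(z, "scaling"), "zscored")
  expect_equal(mean(z[, "v"]), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(z[, "v"]^2)), 1, tolerance = 1e-9)
  # categorical one-hot
  df <- data.frame(cat = c("A", "B", "A"), num = c(2, 4, 6),
                   row.names = paste0("S", 1:3))
  z2 <- encode_and_scale(df, categorical_columns = "cat")
  expect_true(all(c("cat=A", "cat=B", "num") %in% colnames(z2)))
  # indicators (1,0,1)/(0,1,0) before scaling: signs survive the z-score
  expect_equal(unname(sign(z2[, "cat=A"])), c(1, -1, 1))
  expect_equal(unname(sign(z2[, "cat=B"])), c(-1, 1, -1))
  # constant column warns and stays at zero
  df3 <- data.frame(const = c(1, 1, 1), num = c(1, 2, 3),
                    row.names = paste0("S", 1:3))
  expect_warning(z3 <- encode_and_scale(df3), "constant")
  expect_equal(unname(z3[, "const"]), c(0, 0, 0))
})

test_that("pipeline order is threshold at ASV rank, then agglomerate", {
  # thresholding after agglomeration would keep A1+A2 (same genus, joint
  # max 1.1%); the pipeline's ASV-first order drops both
  vals <- matrix(c(0.6, 0.5, 98.9), 1, 3,
                 dimnames = list("S1", paste0("ASV", 1:3)))
  ct <- community_table(vals, unit = "percent")
  tax <- taxonomy_table(data.frame(
    feature_id = paste0("ASV", 1:3), Kingdom = "B", Phylum = "P",
    Class = "C", Order = "O", Family = "F",
    Genus = c("G1", "G1", "G2"), stringsAsFactors = FALSE))
  asv_first <- agglomerate_rank(filter_by_threshold(ct, 0.8), tax, "genus")
  agg_first <- filter_by_threshold(agglomerate_rank(ct, tax, "genus"), 0.8)
  expect_false("G1" %in% colnames(asv_first$values))
  expect_true("G1" %in% colnames(agg_first$values))
  # run_pipeline applies the ASV-first order: with threshold 0.8% the genus
  # G1 must be absent from the modelled features
  counts <- rbind(S1 = c(6, 5, 989), S2 = c(5, 6, 989))
  colnames(counts) <- paste0("ASV", 1:3)
  filt <- filter_by_threshold(to_relative_abundance(community_table(counts)),
                              0.8)
  agg <- agglomerate_rank(filt, tax, "genus")
  expect_false("G1" %in% colnames(agg$values))
})
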