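# small fixtures built in code, shared across test files

fixture_community <- function(counts = NULL, unit = "counts", rank = "asv") {
  if (is.null(counts)) {
    counts <- matrix(c(10, 20, 30, 40, 0,
                       5, 5, 10, 60, 20,
                       1, 9, 40, 30, 20),
                     nrow = 3, byrow = TRUE,
                     dimnames = list(paste0("S", 1:3), paste0("ASV", 1:5)))
  }
  community_table(counts, unit = unit, rank = rank)
}

fixture_taxonomy <- function() {
  taxonomy_table(data.frame(
    feature_id = paste0("ASV", 1:5),
    Kingdom = "Bacteria",
    Phylum = c("P1", "P1", "P1", "P2", "P2"),
    Class = c("C1", "C1", "C1", "C2", "C2"),
    Order = c("O1", "O1", "O2", "O3", "O3"),
    Family = c("F1", "F1", "Gemmatimonadaceae", "F3", "F3"),
    Genus = c("G1", "G1", "", "G3", ""),
    stringsAsFactors = FALSE))
}

fixture_samples <- function(n = 3, tnt = c(0, 0.05, 12)) {
  df <- data.frame(
    sample_id = paste0("S", seq_len(n)),
    tnt_pmol_g = rep_len(tnt, n),
    adnt2_pmol_g = 0, adnt4_pmol_g = 0,
    mud_pct = seq_len(n) * 10,
    cruise = "c1", experiment = "e1", area = "a1",
    lat = 54.5, lon = 10.2, date = "2018-06-01",
    replicate_group = paste0("S", seq_len(n)),
    stringsAsFactors = FALSE)
  sample_table(df, env_cols = "mud_pct",
               metabolite_cols = c("adnt2_pmol_g", "adnt4_pmol_g"))
}

# tiny well-separated two-class learning problem
fixture_separable <- function(n = 40, p = 6, seed = 42) {
  set.seed(seed)
  y <- factor(rep(c("absent", "present"), each = n / 2))
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("S%02d", 1:n), paste0("f", 1:p)))
  x[, 1] <- x[, 1] + ifelse(y == "present", 6, 0)
  names(y) <- rownames(x)
  list(x = x, y = y)
}
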