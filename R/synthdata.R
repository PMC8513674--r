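#' Configuration of the synthetic sediment-community generator
#'
#' The generator emulates the statistical structure the analysis assumes:
#' sparse compositional 16S counts dominated by a latent grain-size-like
#' gradient, a weak planted set of contamination-indicative taxa, correlated
#' environmental covariates (including grain-size fractions summing to
#' 100%), binary TNT status at ~45% prevalence, and "historical" samples
#' whose community carries the contamination signal and whose metabolites
#' are positive although TNT itself is below the detection limit.
#'
#' @param n_samples number of sediments (default 150).
#' @param n_taxa number of taxa (default 600).
#' @param n_indicator_taxa planted TNT-indicative taxa (default 25).
#' @param tnt_prevalence fraction of TNT-present samples (default 0.45).
#' @param indicator_effect multiplicative abundance shift of indicator taxa
#'   in TNT-present (and historical) samples (default 2; 1 = no signal).
#' @param gradient_strength fraction of taxa responding to the latent
#'   gradient (default 0.6).
#' @param n_env number of environmental variables (default 41; the first 4
#'   are grain-size fractions summing to 100%).
#' @param historical_fraction fraction of TNT-absent samples flagged as
#'   historically contaminated (default 0.1).
#' @param depth_mean,depth_dispersion negative-binomial library depth
#'   (defaults 80000 and 10).
#' @param detection_limit_pmol_g TNT detection limit (default 0.044).
#' @param seed integer seed.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_samples = 150, n_taxa = 600,
                         n_indicator_taxa = 25, tnt_prevalence = 0.45,
                         indicator_effect = 2, gradient_strength = 0.6,
                         n_env = 41, historical_fraction = 0.1,
                         depth_mean = 80000, depth_dispersion = 10,
                         detection_limit_pmol_g = 0.044, seed = 1) {
  stopifnot(tnt_prevalence > 0, tnt_prevalence < 1, indicator_effect > 0,
            gradient_strength >= 0, gradient_strength <= 1,
            historical_fraction >= 0, historical_fraction <= 1,
            n_env >= 4)
  if (n_indicator_taxa > n_taxa)
    stop("more indicator taxa than taxa; infeasible configuration")
  structure(as.list(environment()), class = "synth_config")
}

#' Generate a fully labeled synthetic dataset
#'
#' Model: a latent gradient `g ~ U(0,1)` per sample; per-taxon log-normal
#' baseline abundances; a gradient-responsive taxon subset with linear
#' log-abundance response to `g`; indicator taxa (drawn from the
#' non-responsive pool) gain `log(indicator_effect)` in TNT-present and
#' historical samples; per-cell log-normal noise; compositional closure and
#' a multinomial read draw at a negative-binomial library depth.
#' Environmental variables are noisy monotone functions of `g` (first four
#' are softmax grain-size fractions summing to 100%) plus independent noise
#' variables. TNT concentrations are drawn above the detection limit for
#' present samples and 0 otherwise; metabolites are positive for present
#' samples with probability 0.9 and for all historical samples.
#'
#' @param config a [synth_config()].
#' @return object of class `synthetic_dataset`: `community` (counts),
#'   `taxonomy`, `samples`, and `truth` (indicator ids, gradient,
#'   `tnt_present`, `historical` flags).
#' @export
generate_dataset <- function(config = synth_config()) {
  cf <- config
  rng <- local_rng(cf$seed)
  n <- cf$n_samples; p <- cf$n_taxa
  ids <- sprintf("S%03d", seq_len(n))
  taxa <- sprintf("ASV%05d", seq_len(p))

  g <- rng$runif(n)
  n_resp <- round(cf$gradient_strength * p)
  responsive <- rng$sample(p, n_resp)
  non_responsive <- setdiff(seq_len(p), responsive)
  base <- rng$rnorm(p, 0, 2)
  # indicator taxa must be observable: planted among the non-responsive
  # taxa of above-median baseline abundance, as a fingerprint taxon below
  # the detection/threshold scale could not indicate anything
  candidates <- non_responsive[base[non_responsive] >
    stats::quantile(base, 0.6)]
  if (length(candidates) < cf$n_indicator_taxa)
    stop("gradient_strength leaves too few abundant non-responsive taxa ",
         "for the indicator set")
  indicators <- sort(candidates[rng$sample(length(candidates),
                                           cf$n_indicator_taxa)])

  tnt_present <- rng$rbinom(n, 1, cf$tnt_prevalence) == 1
  absent_idx <- which(!tnt_present)
  n_hist <- round(cf$historical_fraction * length(absent_idx))
  historical <- rep(FALSE, n)
  if (n_hist > 0)
    historical[absent_idx[rng$sample(length(absent_idx), n_hist)]] <- TRUE

  slope <- rep(0, p)
  slope[responsive] <- rng$rnorm(n_resp, 0, 1.5)
  shift <- tnt_present | historical

  logab <- matrix(rng$rnorm(n * p, 0, 0.5), n, p)         # per-cell noise
  logab <- sweep(logab, 2, base, "+")
  logab <- logab + outer(g, slope)
  logab[shift, indicators] <- logab[shift, indicators] +
    log(cf$indicator_effect)
  prob <- exp(logab)
  prob <- prob / rowSums(prob)

  depth <- pmax(rng$rnbinom(n, mu = cf$depth_mean,
                            size = cf$depth_dispersion), 1000)
  counts <- t(vapply(seq_len(n),
                     function(i) rng$rmultinom(1, depth[i], prob[i, ])[, 1],
                     numeric(p)))
  dimnames(counts) <- list(ids, taxa)

  taxonomy <- synth_taxonomy(taxa, rng)
  samples <- synth_samples(ids, g, tnt_present, historical, cf, rng)

  structure(list(
    community = community_table(counts, unit = "counts", rank = "asv"),
    taxonomy = taxonomy,
    samples = samples,
    truth = list(indicator_taxa = taxa[indicators],
                 gradient = stats::setNames(g, ids),
                 responsive_taxa = taxa[sort(responsive)],
                 tnt_present = stats::setNames(tnt_present, ids),
                 historical = stats::setNames(historical, ids))),
    class = "synthetic_dataset")
}

synth_taxonomy <- function(taxa, rng) {
  p <- length(taxa)
  n_phy <- 15; n_cls <- 40; n_ord <- 80; n_fam <- 150; n_gen <- 300
  phy <- sprintf("Phylum%02d", rng$sample(n_phy, p, replace = TRUE))
  cls <- sprintf("Class%02d", rng$sample(n_cls, p, replace = TRUE))
  ord <- sprintf("Order%02d", rng$sample(n_ord, p, replace = TRUE))
  fam <- sprintf("Family%03d", rng$sample(n_fam, p, replace = TRUE))
  gen <- sprintf("Genus%03d", rng$sample(n_gen, p, replace = TRUE))
  # ~10% of taxa lack a genus annotation, a few lack family too
  gen[rng$runif(p) < 0.10] <- ""
  fam[rng$runif(p) < 0.02] <- ""
  fam[gen == "" & fam == ""] <- ""  # keep consistent missingness
  taxonomy_table(data.frame(
    feature_id = taxa, Kingdom = "Bacteria", Phylum = phy, Class = cls,
    Order = ord, Family = fam, Genus = gen, stringsAsFactors = FALSE))
}

synth_samples <- function(ids, g, tnt_present, historical, cf, rng) {
  n <- length(ids)
  # 4 grain-size fractions: softmax over monotone transforms of g
  gs_raw <- cbind(3 * (1 - g), 1.5 * (1 - g), 1.5 * g, 3 * g) +
    matrix(rng$rnorm(4 * n, 0, 0.3), n, 4)
  gs <- exp(gs_raw) / rowSums(exp(gs_raw)) * 100
  colnames(gs) <- c("grain_lt63um_pct", "grain_63_125um_pct",
                    "grain_125_250um_pct", "grain_gt250um_pct")
  n_grad_env <- max(0, floor((cf$n_env - 4) / 2))
  n_noise_env <- cf$n_env - 4 - n_grad_env
  grad_env <- matrix(0, n, n_grad_env)
  for (j in seq_len(n_grad_env)) {
    a <- rng$rnorm(1, 0, 2)
    grad_env[, j] <- a * g + rng$rnorm(n, 0, 0.5)
  }
  if (n_grad_env) colnames(grad_env) <- sprintf("env_grad_%02d",
                                                seq_len(n_grad_env))
  noise_env <- matrix(rng$rnorm(n * n_noise_env), n, n_noise_env)
  if (n_noise_env) colnames(noise_env) <- sprintf("env_noise_%02d",
                                                  seq_len(n_noise_env))
  env <- cbind(gs, grad_env, noise_env)

  tnt <- rep(0, n)
  tnt[tnt_present] <- cf$detection_limit_pmol_g +
    rng$rlnorm(sum(tnt_present), log(10), 1.5)
  met_cols <- c("adnt2_pmol_g", "adnt4_pmol_g", "dant24_pmol_g",
                "dant26_pmol_g")
  met <- matrix(0, n, 4, dimnames = list(ids, met_cols))
  src <- tnt_present | historical
  for (k in 1:4) {
    has <- src & (rng$runif(n) < ifelse(historical, 1, 0.9))
    met[has, k] <- rng$rlnorm(sum(has), log(2), 1)
  }
  # every historical sample carries at least one metabolite
  none <- historical & rowSums(met) == 0
  met[none, 1] <- rng$rlnorm(sum(none), log(2), 1)

  df <- data.frame(
    sample_id = ids,
    tnt_pmol_g = tnt,
    met,
    env,
    cruise = sprintf("cruise%d", 1 + (seq_len(n) - 1) %/% 50),
    experiment = "multicorer",
    area = ifelse(g < 0.5, "west", "east"),
    lat = 54.5 + g * 0.01 + rng$rnorm(n, 0, 0.001),
    lon = 10.2 + rng$rnorm(n, 0, 0.01),
    date = as.character(as.Date("2018-06-01") + rng$sample(300, n,
                                                           replace = TRUE)),
    replicate_group = ids,
    stringsAsFactors = FALSE, check.names = FALSE)
  sample_table(df, env_cols = colnames(env), metabolite_cols = met_cols)
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_dataset> %d samples x %d taxa; %d TNT-",
                     "present, %d historical; %d planted indicator taxa\n"),
              nrow(x$community$values), ncol(x$community$values),
              sum(x$truth$tnt_present), sum(x$truth$historical),
              length(x$truth$indicator_taxa)))
  invisible(x)
}

#' Recovery metrics for a feature selection against the planted truth
#'
#' @param selected_features character vector of selected feature ids (at
#'   the rank the truth is stated: ASVs).
#' @param dataset a [generate_dataset()] result.
#' @return list with `precision`, `recall`, `n_selected`, `n_planted`,
#'   `recovered` ids.
#' @export
truth_eval <- function(selected_features, dataset) {
  planted <- dataset$truth$indicator_taxa
  hit <- intersect(selected_features, planted)
  list(precision = if (length(selected_features))
         length(hit) / length(selected_features) else NA_real_,
       recall = length(hit) / length(planted),
       n_selected = length(selected_features),
       n_planted = length(planted),
       recovered = hit)
}
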