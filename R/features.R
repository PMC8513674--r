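#' Construct a feature matrix
#'
#' The numeric samples x features matrix handed to the learners, carrying a
#' per-feature origin tag (`taxon` or `environmental`), the taxonomic rank of
#' the taxon features, and its scaling state.
#'
#' @param values numeric matrix with sample rownames and feature colnames.
#' @param origin character vector (length = n features) of
#'   `"taxon"`/`"environmental"` tags, or a single tag recycled.
#' @param rank taxonomic rank tag for taxon features.
#' @param scaling `"raw"` or `"zscored"`.
#' @return an object of class `feature_matrix` (a numeric matrix with
#'   attributes).
#' @export
feature_matrix <- function(values, origin = "taxon", rank = NA_character_,
                           scaling = c("raw", "zscored")) {
  scaling <- match.arg(scaling)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("feature matrix needs sample rownames and feature colnames")
  if (any(!is.finite(values))) stop("feature matrix must be finite")
  origin <- rep_len(origin, ncol(values))
  if (!all(origin %in% c("taxon", "environmental")))
    stop("origin tags must be 'taxon' or 'environmental'")
  structure(values, origin = origin, rank = rank, scaling = scaling,
            class = c("feature_matrix", "matrix", "array"))
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "<feature_matrix> %d samples x %d features (%d taxon, %d environmental) [%s]\n",
    nrow(x), ncol(x), sum(attr(x, "origin") == "taxon"),
    sum(attr(x, "origin") == "environmental"), attr(x, "scaling")))
  invisible(x)
}

feature_origin <- function(x) attr(x, "origin")

# strip feature_matrix attributes, keep a plain matrix
fm_values <- function(x) {
  y <- unclass(x)
  attr(y, "origin") <- NULL; attr(y, "rank") <- NULL
  attr(y, "scaling") <- NULL
  y
}

#' Convert counts to relative abundance
#'
#' @param community a [community_table()] in counts; every sample must have a
#'   positive total.
#' @return a [community_table()] in percent: `100 * count / sample total`.
#' @export
to_relative_abundance <- function(community) {
  if (community$unit != "counts")
    stop("to_relative_abundance expects a counts table")
  totals <- rowSums(community$values)
  if (any(totals == 0))
    stop("zero-sum sample(s): ",
         paste(sample_ids(community)[totals == 0], collapse = ", "))
  community_table(sweep(community$values, 1, totals, "/") * 100,
                  unit = "percent", rank = community$rank)
}

#' Filter features by a relative-abundance threshold
#'
#' A feature is kept iff it is strictly more abundant than `threshold_pct`
#' in at least one sample; kept features are left unchanged.
#'
#' @param community a [community_table()] in percent.
#' @param threshold_pct threshold in percent (>= 0).
#' @return the filtered [community_table()].
#' @export
filter_by_threshold <- function(community, threshold_pct) {
  if (community$unit != "percent")
    stop("filter_by_threshold expects a percent table")
  if (threshold_pct < 0) stop("threshold must be >= 0")
  keep <- apply(community$values, 2, max) > threshold_pct
  out <- community$values[, keep, drop = FALSE]
  structure(list(values = out, unit = "percent", rank = community$rank),
            class = "community_table")
}

#' The relative-abundance threshold grid
#'
#' Default grid of thresholds (percent) screened during hyperparameter
#' search.
#' @return numeric vector of thresholds.
#' @export
default_thresholds <- function() {
  c(0.02, 0.04, 0.06, 0.08, 0.1, 0.2, 0.4, 0.6, 0.8, 1)
}

#' Agglomerate ASV abundances to a broader taxonomic rank
#'
#' Abundances are summed over features whose lineage is identical down to
#' `rank`. Features unannotated at `rank` are grouped under
#' `"unclassified <deepest annotated parent>"` (distinct parents give
#' distinct groups). Per-sample total abundance is conserved.
#'
#' @param community a [community_table()] in percent at ASV rank.
#' @param taxonomy a [taxonomy_table()] covering the features.
#' @param rank target rank: `"genus"`, `"family"`, `"order"`, `"class"` or
#'   `"phylum"`.
#' @return a [community_table()] at the requested rank.
#' @export
agglomerate_rank <- function(community, taxonomy, rank) {
  rank_col <- c(genus = "Genus", family = "Family", order = "Order",
                class = "Class", phylum = "Phylum")[rank]
  if (is.na(rank_col)) stop("unknown rank: ", rank)
  if (community$rank != "asv")
    stop("agglomerate_rank expects an ASV-rank table")
  feats <- feature_ids(community)
  missing <- setdiff(feats, taxonomy$feature_id)
  if (length(missing))
    stop("taxonomy lacks feature(s): ", paste(missing, collapse = ", "))
  lev <- tax_ranks()
  upto <- seq_len(match(rank_col, lev))
  lin <- as.matrix(taxonomy[feats, lev[upto], drop = FALSE])
  labels <- apply(lin, 1, function(path) {
    if (nzchar(path[length(path)])) {
      # full lineage prefix keys the group; display label is the rank name
      paste(path, collapse = ";")
    } else {
      ann <- which(nzchar(path))
      parent <- if (length(ann)) path[max(ann)] else "Unknown"
      paste0("unclassified ", parent)
    }
  })
  display <- ifelse(grepl(";", labels, fixed = TRUE),
                    vapply(strsplit(labels, ";", fixed = TRUE),
                           function(p) p[length(p)], character(1)),
                    labels)
  # identical display names from different lineages stay separate via the key
  key <- labels
  agg <- t(rowsum(t(community$values), group = key, reorder = TRUE))
  disp <- display[match(colnames(agg), key)]
  # disambiguate any display-name clash deterministically
  if (anyDuplicated(disp)) disp <- make.unique(disp, sep = " #")
  colnames(agg) <- disp
  structure(list(values = agg, unit = "percent", rank = rank),
            class = "community_table")
}

#' Remove features abundant in negative controls
#'
#' Features with more than `max_control_reads` reads in any control sample
#' are removed (strict >), unless exempted; control samples themselves are
#' dropped from the output.
#'
#' @param community a [community_table()] in counts containing the control
#'   samples.
#' @param control_sample_ids ids of the control samples.
#' @param max_control_reads read-count cutoff (default 35).
#' @param exemptions feature ids excluded from the rule (e.g. features far
#'   more abundant in real samples than in controls).
#' @return a [community_table()] without controls and contaminant features.
#' @export
remove_control_features <- function(community, control_sample_ids,
                                    max_control_reads = 35,
                                    exemptions = character()) {
  if (community$unit != "counts")
    stop("remove_control_features expects a counts table")
  ids <- sample_ids(community)
  missing <- setdiff(control_sample_ids, ids)
  if (length(missing))
    stop("control sample(s) not in table: ", paste(missing, collapse = ", "))
  ctrl <- community$values[control_sample_ids, , drop = FALSE]
  flagged <- if (length(control_sample_ids))
    apply(ctrl, 2, max) > max_control_reads else rep(FALSE, ncol(ctrl))
  flagged[colnames(community$values) %in% exemptions] <- FALSE
  out <- community$values[setdiff(ids, control_sample_ids),
                          !flagged, drop = FALSE]
  community_table(out, unit = "counts", rank = community$rank)
}

#' Combine taxon and environmental feature matrices
#'
#' Column-concatenates two feature matrices over an identical sample set,
#' preserving per-feature origin tags. Feature-name collisions are rejected.
#'
#' @param community a [feature_matrix()] of taxon features.
#' @param environment a [feature_matrix()] of environmental features.
#' @return the combined [feature_matrix()].
#' @export
combine_features <- function(community, environment) {
  if (ncol(environment) == 0 && nrow(environment) == 0) return(community)
  if (!identical(sort(rownames(community)), sort(rownames(environment))))
    stop("sample sets differ between the two matrices")
  if (ncol(environment) == 0) return(community)
  env <- environment[rownames(community), , drop = FALSE]
  clash <- intersect(colnames(community), colnames(env))
  if (length(clash))
    stop("feature name collision: ", paste(clash, collapse = ", "))
  if (!identical(attr(community, "scaling"), attr(environment, "scaling")))
    stop("scaling states differ")
  feature_matrix(cbind(fm_values(community), fm_values(env)),
                 origin = c(feature_origin(community),
                            feature_origin(environment)),
                 rank = attr(community, "rank"),
                 scaling = attr(community, "scaling"))
}

#' One-hot encode and z-score a feature matrix
#'
#' Declared categorical columns become 0/1 indicator columns (one per
#' level, named `<column>=<level>`); numeric columns are centred and divided
#' by the population (divide-by-n) standard deviation. Constant numeric
#' columns cannot be scaled and are set to 0 with a warning.
#'
#' @param features a [feature_matrix()] or data.frame.
#' @param categorical_columns names of columns to one-hot encode.
#' @return a z-scored [feature_matrix()] (`scaling = "zscored"`).
#' @export
encode_and_scale <- function(features, categorical_columns = character()) {
  df <- as.data.frame(unclass(features), check.names = FALSE,
                      stringsAsFactors = FALSE)
  if (is.null(rownames(df))) stop("features need sample rownames")
  origin <- if (inherits(features, "feature_matrix"))
    stats::setNames(feature_origin(features), colnames(features))
  else stats::setNames(rep("environmental", ncol(df)), names(df))

  cols <- list(); tags <- character()
  for (nm in names(df)) {
    v <- df[[nm]]
    if (nm %in% categorical_columns) {
      lv <- sort(unique(as.character(v)))
      for (l in lv) {
        cols[[paste0(nm, "=", l)]] <- as.numeric(as.character(v) == l)
        tags <- c(tags, origin[[nm]])
      }
    } else {
      if (!is.numeric(v)) stop("column ", nm, " is not numeric and not ",
                               "declared categorical")
      cols[[nm]] <- v
      tags <- c(tags, origin[[nm]])
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- rownames(df)
  n <- nrow(m)
  mu <- colMeans(m)
  sd_pop <- sqrt(colMeans(sweep(m, 2, mu)^2))
  const <- sd_pop == 0
  if (any(const))
    warning("constant column(s) left at 0: ",
            paste(colnames(m)[const], collapse = ", "))
  scaled <- sweep(m, 2, mu)
  scaled[, !const] <- sweep(scaled[, !const, drop = FALSE], 2,
                            sd_pop[!const], "/")
  scaled[, const] <- 0
  feature_matrix(scaled, origin = tags, rank = attr(features, "rank"),
                 scaling = "zscored")
}

#' Turn a community table into a taxon feature matrix
#'
#' @param community a [community_table()] (percent for model input).
#' @return a [feature_matrix()] with origin `"taxon"`.
#' @export
as_feature_matrix <- function(community) {
  feature_matrix(community$values, origin = "taxon", rank = community$rank,
                 scaling = "raw")
}

#' Turn sample-table environmental columns into a feature matrix
#'
#' @param samples a [sample_table()] with declared environmental columns.
#' @return a [feature_matrix()] with origin `"environmental"`.
#' @export
env_feature_matrix <- function(samples) {
  cols <- env_columns(samples)
  if (!length(cols)) stop("no environmental columns declared")
  m <- as.matrix(samples[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- samples$sample_id
  feature_matrix(m, origin = "environmental", scaling = "raw")
}
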