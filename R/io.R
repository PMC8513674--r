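#' Construct a community table
#'
#' A community table holds a samples x features abundance matrix together with
#' its unit (raw read counts or relative abundance in percent) and the
#' taxonomic rank of its features (ASVs or an agglomerated rank).
#'
#' @param values numeric matrix, samples in rows (rownames = sample ids),
#'   features in columns (colnames = feature ids). No negative entries.
#' @param unit `"counts"` or `"percent"`. Percent rows must sum to 100.
#' @param rank taxonomic rank of the features, one of
#'   `"asv"`, `"genus"`, `"family"`, `"order"`, `"class"`, `"phylum"`.
#' @return an object of class `community_table`.
#' @export
community_table <- function(values, unit = c("counts", "percent"),
                            rank = "asv") {
  unit <- match.arg(unit)
  rank <- match.arg(rank, c("asv", "genus", "family", "order", "class",
                            "phylum"))
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("community table needs sample ids (rownames) and feature ids ",
         "(colnames)")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids in community table")
  if (anyDuplicated(colnames(values)))
    stop("duplicate feature ids in community table")
  if (any(!is.finite(values)) || any(values < 0))
    stop("community table entries must be finite and non-negative")
  if (unit == "percent") {
    rs <- rowSums(values)
    bad <- abs(rs - 100) > 1e-6 & rs > 0
    if (any(bad))
      stop("percent rows must sum to 100: ",
           paste(rownames(values)[bad][seq_len(min(3, sum(bad)))],
                 collapse = ", "))
  }
  structure(list(values = values, unit = unit, rank = rank),
            class = "community_table")
}

#' @export
print.community_table <- function(x, ...) {
  cat(sprintf("<community_table> %d samples x %d features [%s, rank %s]\n",
              nrow(x$values), ncol(x$values), x$unit, x$rank))
  invisible(x)
}

#' @export
dim.community_table <- function(x) dim(x$values)

sample_ids <- function(ct) rownames(ct$values)
feature_ids <- function(ct) colnames(ct$values)

#' Construct a taxonomy table
#'
#' Maps each feature id to an ordered lineage Kingdom..Genus. Missing rank
#' labels are encoded as empty strings and rendered downstream as
#' "unclassified <deepest annotated parent>".
#'
#' @param df data.frame with a `feature_id` column plus the columns
#'   `Kingdom`, `Phylum`, `Class`, `Order`, `Family`, `Genus` (character;
#'   `NA` or `""` mean unannotated).
#' @return an object of class `taxonomy_table`.
#' @export
taxonomy_table <- function(df) {
  needed <- c("feature_id", tax_ranks())
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("taxonomy table lacks columns: ", paste(missing, collapse = ", "))
  df <- df[, needed, drop = FALSE]
  for (r in tax_ranks()) {
    df[[r]] <- as.character(df[[r]])
    df[[r]][is.na(df[[r]])] <- ""
  }
  df$feature_id <- as.character(df$feature_id)
  if (anyDuplicated(df$feature_id))
    stop("duplicate feature ids in taxonomy table")
  rownames(df) <- df$feature_id
  class(df) <- c("taxonomy_table", "data.frame")
  df
}

tax_ranks <- function() {
  c("Kingdom", "Phylum", "Class", "Order", "Family", "Genus")
}

#' Construct a sample metadata table
#'
#' Per-sample metadata: TNT concentration, metabolite concentrations,
#' environmental covariates, grouping fields and coordinates.
#'
#' @param df data.frame with columns `sample_id`, `tnt_pmol_g`, grouping
#'   fields (`cruise`, `experiment`, `area`, `replicate_group`), coordinates
#'   (`lat`, `lon`), a `date`, plus metabolite and environmental columns.
#' @param env_cols names of the numeric environmental covariate columns.
#' @param metabolite_cols names of the munition-metabolite concentration
#'   columns (e.g. ADNT/DANT compounds, pmol per g wet sediment).
#' @return an object of class `sample_table`.
#' @export
sample_table <- function(df, env_cols = character(),
                         metabolite_cols = character()) {
  if (!"sample_id" %in% names(df)) stop("sample table needs 'sample_id'")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids")
  if ("tnt_pmol_g" %in% names(df) && any(df$tnt_pmol_g < 0, na.rm = TRUE))
    stop("negative TNT concentration")
  for (cc in metabolite_cols)
    if (any(df[[cc]] < 0, na.rm = TRUE)) stop("negative concentration in ", cc)
  if ("lat" %in% names(df) &&
      any(abs(df$lat) > 90, na.rm = TRUE)) stop("latitude outside [-90, 90]")
  if ("lon" %in% names(df) &&
      any(abs(df$lon) > 180, na.rm = TRUE)) stop("longitude outside [-180, 180]")
  missing <- setdiff(c(env_cols, metabolite_cols), names(df))
  if (length(missing))
    stop("declared columns absent from table: ", paste(missing, collapse = ", "))
  rownames(df) <- df$sample_id
  attr(df, "env_cols") <- env_cols
  attr(df, "metabolite_cols") <- metabolite_cols
  class(df) <- c("sample_table", "data.frame")
  df
}

env_columns <- function(st) attr(st, "env_cols")
metabolite_columns <- function(st) attr(st, "metabolite_cols")

#' Load the three canonical input tables
#'
#' Reads the community table (TSV: first column sample id, remaining columns
#' features; or BIOM 2.1 JSON), the taxonomy table and the sample metadata
#' table, validates identifiers and aligns everything by sample/feature id.
#' Features absent from the taxonomy receive an all-missing lineage with a
#' warning. Tables are returned canonically sorted by id so that loading is
#' insensitive to input row order.
#'
#' @param community_path path to the community table.
#' @param taxonomy_path path to the taxonomy TSV.
#' @param samples_path path to the sample metadata TSV.
#' @param format `"tsv"` or `"biom"` (community table only).
#' @param unit unit of the community values.
#' @param rank feature rank of the community table.
#' @param env_cols,metabolite_cols forwarded to [sample_table()].
#' @return list with elements `community`, `taxonomy`, `samples`.
#' @export
load_dataset <- function(community_path, taxonomy_path, samples_path,
                         format = c("tsv", "biom"),
                         unit = "counts", rank = "asv",
                         env_cols = character(),
                         metabolite_cols = character()) {
  format <- match.arg(format)
  for (p in c(community_path, taxonomy_path, samples_path))
    if (!file.exists(p)) stop("file not found: ", p)

  mat <- if (format == "tsv") read_community_tsv(community_path)
         else read_community_biom(community_path)

  tax_df <- read_tsv_checked(taxonomy_path)
  smp_df <- read_tsv_checked(samples_path)
  samples <- sample_table(smp_df, env_cols = env_cols,
                          metabolite_cols = metabolite_cols)

  extra <- setdiff(rownames(mat), samples$sample_id)
  if (length(extra))
    stop("community samples missing from metadata: ",
         paste(extra, collapse = ", "))

  missing_tax <- setdiff(colnames(mat), tax_df$feature_id)
  if (length(missing_tax)) {
    warning(length(missing_tax),
            " feature(s) absent from taxonomy; assigned all-missing lineage")
    blank <- data.frame(feature_id = missing_tax, Kingdom = "", Phylum = "",
                        Class = "", Order = "", Family = "", Genus = "",
                        stringsAsFactors = FALSE)
    keep <- intersect(names(tax_df), names(blank))
    tax_df <- rbind(tax_df[, keep, drop = FALSE], blank[, keep, drop = FALSE])
  }
  taxonomy <- taxonomy_table(tax_df)

  # canonical order: sort by id
  mat <- mat[order(rownames(mat)), order(colnames(mat)), drop = FALSE]
  taxonomy <- taxonomy[order(taxonomy$feature_id), , drop = FALSE]
  samples <- samples[order(samples$sample_id), , drop = FALSE]
  taxonomy <- taxonomy[taxonomy$feature_id %in% colnames(mat), , drop = FALSE]

  list(community = community_table(mat, unit = unit, rank = rank),
       taxonomy = taxonomy,
       samples = samples)
}

read_tsv_checked <- function(path) {
  out <- tryCatch(
    utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE, dec = "."),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  out
}

read_community_tsv <- function(path) {
  df <- read_tsv_checked(path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate sample ids in ", path)
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) stop("parse error in ", path,
                             ": non-numeric abundance values")
  rownames(mat) <- ids
  mat
}

read_community_biom <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("reading BIOM requires the 'biomformat' package")
  b <- biomformat::read_biom(path)
  m <- as.matrix(biomformat::biom_data(b))  # features x samples
  t(m)
}

#' Write a community table to BIOM (JSON dialect)
#'
#' @param community a [community_table()].
#' @param path output path.
#' @export
write_community_biom <- function(community, path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("writing BIOM requires the 'biomformat' package")
  b <- biomformat::make_biom(t(community$values))
  biomformat::write_biom(b, path)
  invisible(path)
}

#' Export a result artifact
#'
#' Serializes any of the package's tabular result artifacts (importance
#' tables, grid results, curation reports, consistency tables, ...) with
#' deterministic column/key ordering. TSV for rectangular artifacts, JSON
#' (with a `schema_version` key) for nested ones. Round-tripping preserves
#' integers bitwise and floats to 1e-12.
#'
#' @param artifact a data.frame-like result or a list.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @export
export_results <- function(artifact, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- as.data.frame(artifact)
    df <- df[, sort(names(df)), drop = FALSE]
    ok <- tryCatch({
      utils::write.table(df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop("cannot write to ", path)
  } else {
    payload <- list(schema_version = "1.0", data = artifact)
    ok <- tryCatch({
      jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop("cannot write to ", path)
  }
  invisible(path)
}

#' Read back an exported artifact
#'
#' @param path file written by [export_results()].
#' @param format `"tsv"` or `"json"`.
#' @export
read_results <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") read_tsv_checked(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)$data
}

#' Write a community table as TSV
#'
#' First column `sample_id`, remaining columns the features.
#' @param community a [community_table()].
#' @param path output path.
#' @export
write_community_tsv <- function(community, path) {
  df <- data.frame(sample_id = rownames(community$values),
                   community$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
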