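#' Guideline parameters for sample exclusion
#'
#' Contextual subsets of samples (same cruise, experiment and area, taken
#' within a short horizontal distance) that carry only one TNT class -- or a
#' strongly imbalanced pair of classes -- risk teaching a classifier the
#' sampling context instead of the contamination. Such subsets are thinned to
#' a fixed number of representatives before model training.
#'
#' @param distance_threshold_m pairwise horizontal distance (meters) below
#'   which samples count as co-located. Default 20.
#' @param imbalance_rule maximum minority-class count that still counts as
#'   "strong imbalance" (default 1, i.e. a 20-vs-1 style subset is flagged).
#' @param retain_per_subset representatives kept per flagged subset
#'   (default 1; the lowest sample id is kept).
#' @return an object of class `guideline_params`.
#' @export
guideline_params <- function(distance_threshold_m = 20,
                             imbalance_rule = 1,
                             retain_per_subset = 1) {
  stopifnot(distance_threshold_m > 0, retain_per_subset >= 1,
            imbalance_rule >= 0)
  structure(list(distance_threshold_m = distance_threshold_m,
                 imbalance_rule = imbalance_rule,
                 retain_per_subset = retain_per_subset),
            class = "guideline_params")
}

#' Average technical replicates to one community per sediment
#'
#' Each library is first converted to relative abundance (percent) so that
#' unequal sequencing depths do not weight the mean, then libraries sharing a
#' `replicate_group` are averaged arithmetically. Output rows sum to 100%.
#'
#' @param community a [community_table()] in counts.
#' @param samples a [sample_table()] with a `replicate_group` column covering
#'   every community sample.
#' @return a [community_table()] in percent with one row per replicate group,
#'   rows named by the group identifier.
#' @export
average_replicates <- function(community, samples) {
  if (community$unit != "counts")
    stop("average_replicates expects a counts table")
  if (!"replicate_group" %in% names(samples))
    stop("samples need a 'replicate_group' column")
  ids <- sample_ids(community)
  grp <- samples[ids, "replicate_group"]
  if (any(is.na(grp)))
    stop("replicate_group undefined for: ",
         paste(ids[is.na(grp)], collapse = ", "))
  totals <- rowSums(community$values)
  if (any(totals == 0)) {
    zero_groups <- unique(grp[totals == 0])
    stop("zero total reads in group(s): ",
         paste(zero_groups, collapse = ", "))
  }
  pct <- sweep(community$values, 1, totals, "/") * 100
  out <- rowsum(pct, group = grp, reorder = TRUE) /
    as.vector(table(grp)[sort(unique(grp))])
  community_table(out, unit = "percent", rank = community$rank)
}

#' Apply the sample-exclusion guideline
#'
#' Flags every maximal group of samples that share cruise, experiment and
#' area, lie pairwise closer than the distance threshold (haversine on a
#' 6371 km sphere), and either carry a single response class or a strongly
#' imbalanced pair. From each flagged group all but `retain_per_subset`
#' samples are removed; the retained representatives are the lowest sample
#' ids (deterministic).
#'
#' @param samples a [sample_table()] with `cruise`, `experiment`, `area`,
#'   `lat`, `lon`.
#' @param response a [binarize_response()] result covering the samples.
#' @param params a [guideline_params()].
#' @return an object of class `curation_report`: list with `kept_ids`,
#'   `removed_ids`, and a `subsets` data.frame recording the rationale per
#'   contextual subset.
#' @export
apply_exclusion_guideline <- function(samples, response,
                                      params = guideline_params()) {
  need <- c("cruise", "experiment", "area", "lat", "lon")
  missing <- setdiff(need, names(samples))
  if (length(missing))
    stop("samples lack columns: ", paste(missing, collapse = ", "))
  ids <- samples$sample_id
  cls <- response[ids]
  if (any(is.na(cls))) stop("response missing for some samples")

  no_coord <- is.na(samples$lat) | is.na(samples$lon)
  if (any(no_coord))
    warning("samples without coordinates excluded from distance grouping: ",
            paste(ids[no_coord], collapse = ", "))

  ctx <- interaction(samples$cruise, samples$experiment, samples$area,
                     drop = TRUE)
  removed <- character()
  recs <- list()
  for (cx in levels(ctx)) {
    in_ctx <- which(ctx == cx & !no_coord)
    if (length(in_ctx) < 2) next
    # partition the context into co-located components: pairwise < threshold
    coords <- cbind(samples$lon[in_ctx], samples$lat[in_ctx])
    d <- geosphere::distm(coords, fun = geosphere::distHaversine) /
      6378137 * 6371000
    close <- d < params$distance_threshold_m
    comp <- connected_components(close)
    for (k in unique(comp)) {
      member <- in_ctx[comp == k]
      if (length(member) < 2) next
      # the guideline requires ALL pairs within the subset to be co-located
      sub_d <- d[comp == k, comp == k, drop = FALSE]
      if (any(sub_d >= params$distance_threshold_m)) next
      tab <- table(factor(cls[member], levels = c("absent", "present")))
      single_class <- sum(tab > 0) == 1
      imbalanced <- min(tab) <= params$imbalance_rule && all(tab >= 0) &&
        sum(tab > 0) == 2
      flagged <- single_class || imbalanced
      sub_ids <- sort(ids[member])
      drop_ids <- if (flagged && length(sub_ids) > params$retain_per_subset)
        sub_ids[-seq_len(params$retain_per_subset)] else character()
      removed <- c(removed, drop_ids)
      recs[[length(recs) + 1]] <- data.frame(
        cruise = samples$cruise[member[1]],
        experiment = samples$experiment[member[1]],
        area = samples$area[member[1]],
        n_samples = length(sub_ids),
        max_distance_m = max(sub_d),
        n_absent = as.integer(tab["absent"]),
        n_present = as.integer(tab["present"]),
        flagged = flagged,
        n_removed = length(drop_ids),
        stringsAsFactors = FALSE)
    }
  }
  kept <- setdiff(ids, removed)
  structure(list(kept_ids = sort(kept), removed_ids = sort(removed),
                 subsets = if (length(recs)) do.call(rbind, recs)
                           else data.frame()),
            class = "curation_report")
}

#' @export
print.curation_report <- function(x, ...) {
  cat(sprintf("<curation_report> kept %d, removed %d sample(s)\n",
              length(x$kept_ids), length(x$removed_ids)))
  invisible(x)
}

# components of an undirected adjacency matrix (logical), simple BFS
connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Binarize the TNT response
#'
#' Samples with a TNT concentration strictly below the detection limit are
#' classed `absent`; all others (including exactly at the limit) `present`.
#' The default limit is 0.01 ng per g wet sediment expressed as
#' 0.044 pmol per g.
#'
#' @param samples a [sample_table()] with `tnt_pmol_g`.
#' @param detection_limit_pmol_g detection limit, pmol per g wet sediment.
#' @return named factor (levels `absent`, `present`) with the underlying
#'   concentrations retained in attribute `concentration`.
#' @export
binarize_response <- function(samples, detection_limit_pmol_g = 0.044) {
  conc <- samples$tnt_pmol_g
  if (is.null(conc)) stop("samples lack 'tnt_pmol_g'")
  if (any(conc < 0, na.rm = TRUE)) stop("negative TNT concentration")
  cls <- factor(ifelse(conc < detection_limit_pmol_g, "absent", "present"),
                levels = c("absent", "present"))
  names(cls) <- samples$sample_id
  attr(cls, "concentration") <- stats::setNames(conc, samples$sample_id)
  attr(cls, "detection_limit_pmol_g") <- detection_limit_pmol_g
  cls
}

#' Convert ng per g to pmol per g
#'
#' @param value_ng_g concentration in ng per g.
#' @param molar_mass_g_mol molar mass in g per mol (TNT: 227.13).
#' @return concentration in pmol per g.
#' @export
ng_per_g_to_pmol_per_g <- function(value_ng_g, molar_mass_g_mol) {
  if (any(molar_mass_g_mol <= 0)) stop("molar mass must be positive")
  value_ng_g / molar_mass_g_mol * 1000
}
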