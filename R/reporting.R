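#' Rank regions by fold-averaged kernel weight
#'
#' Averages the simplex kernel weights across cross-validation folds,
#' renormalises the averages to sum to 100 (a no-op unless regions were
#' dropped in some folds), and ranks regions in descending order with a
#' deterministic tie-break by region id. Selection frequency — the
#' fraction of folds in which a region received nonzero weight — is an
#' added stability diagnostic.
#'
#' @param fold_weights matrix `folds x regions` of kernel weights
#'   (columns named by region id), e.g. `cv_report$fold_weights`, or a
#'   list of `mkl_model`s over identical region sets.
#' @return data frame (class `region_ranking`) sorted by rank:
#'   `region_id`, `mean_pct`, `rank`, `selection_freq`.
#' @export
rank_regions <- function(fold_weights) {
  if (is.list(fold_weights) && !is.matrix(fold_weights)) {
    ids <- lapply(fold_weights, function(m) m$region_ids)
    if (length(unique(vapply(ids, paste, "", collapse = ","))) != 1L)
      stop("fold models have inconsistent region sets", call. = FALSE)
    fold_weights <- do.call(rbind, lapply(fold_weights, function(m) m$d))
  }
  stopifnot(is.matrix(fold_weights), nrow(fold_weights) >= 1L)
  ids <- as.integer(colnames(fold_weights))
  mean_d <- colMeans(fold_weights)
  pct <- 100 * mean_d / sum(mean_d)
  ord <- order(-pct, ids)
  out <- data.frame(region_id = ids[ord], mean_pct = pct[ord],
                    rank = seq_along(ids),
                    selection_freq = colMeans(fold_weights > 0)[ord],
                    row.names = NULL)
  class(out) <- c("region_ranking", "data.frame")
  out
}

#' Sum region weight percentages per cerebral lobe
#'
#' @param ranking a `region_ranking` from [rank_regions()].
#' @param region_table atlas region table (`region_id`, `region_name`,
#'   `lobe_group`); every ranked region must be mapped.
#' @return data frame with `lobe_group` and `total_pct`, sorted
#'   descending; totals sum to the ranking's grand total.
#' @export
summarize_by_lobe <- function(ranking, region_table) {
  m <- match(ranking$region_id, region_table$region_id)
  if (anyNA(m))
    stop(sprintf("regions missing from the region table: %s",
                 paste(ranking$region_id[is.na(m)], collapse = ", ")),
         call. = FALSE)
  lobe <- region_table$lobe_group[m]
  agg <- stats::aggregate(list(total_pct = ranking$mean_pct),
                          by = list(lobe_group = lobe), FUN = sum)
  agg[order(-agg$total_pct), , drop = FALSE]
}

#' Export weight maps and the ranking table
#'
#' Writes a region-level volume (every voxel carries its region's weight
#' percentage), the voxel-level weight volume, and a CSV ranking table.
#'
#' @param weight_map a `weight_map` from [extract_weights()].
#' @param atlas the `atlas_parcellation` the model was built on.
#' @param dir output directory (created if needed).
#' @param ranking optional `region_ranking` to store alongside; defaults
#'   to a single-model ranking from the weight map itself.
#' @return named character vector of the written paths, invisibly.
#' @export
export_weight_maps <- function(weight_map, atlas, dir, ranking = NULL) {
  validate_atlas(atlas)
  if (!identical(dim(weight_map$voxel_weights),
                 dim(atlas$label_volume)))
    stop_mismatch("weight map and atlas")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  region_vol <- array(0, dim(atlas$label_volume))
  for (i in seq_along(weight_map$region_ids)) {
    rid <- weight_map$region_ids[i]
    region_vol[atlas$label_volume == rid] <- weight_map$region_pct[i]
  }
  p_region <- file.path(dir, "region_weights.nii.gz")
  p_voxel <- file.path(dir, "voxel_weights.nii.gz")
  for (pp in list(list(p_region, region_vol),
                  list(p_voxel, weight_map$voxel_weights))) {
    img <- RNifti::asNifti(pp[[2]])
    img <- RNifti::`pixdim<-`(img, atlas$voxel_size)
    RNifti::writeNifti(img, pp[[1]])
  }

  if (is.null(ranking)) {
    w <- matrix(weight_map$d, nrow = 1,
                dimnames = list(NULL, as.character(weight_map$region_ids)))
    ranking <- rank_regions(w)
  }
  tab <- merge(ranking, atlas$region_table, by = "region_id", sort = FALSE)
  tab <- tab[order(tab$rank),
             c("region_id", "region_name", "lobe_group", "mean_pct",
               "rank", "selection_freq")]
  p_csv <- file.path(dir, "region_ranking.csv")
  utils::write.csv(tab, p_csv, row.names = FALSE)

  invisible(c(region_map = p_region, voxel_map = p_voxel,
              ranking = p_csv))
}
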