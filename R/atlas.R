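#' Generate a synthetic brain parcellation
#'
#' Builds a brain-like ellipsoidal mask inside a rectangular voxel grid and
#' tiles it with `n_regions` spatially contiguous regions (Voronoi cells of
#' randomly placed seed voxels). This is a synthetic stand-in for an
#' anatomical parcellation such as a 120-region whole-brain atlas: the
#' decoding pipeline consumes any integer-labelled volume, and tests use
#' this generator so no external atlas file is required.
#'
#' Region ids are contiguous from 1, every region has at least one voxel
#' (each seed voxel belongs to its own cell), and each region is assigned
#' to one of six lobe groups round-robin.
#'
#' @param grid_shape integer vector of length 3, voxels per axis.
#' @param n_regions number of regions (>= 2).
#' @param seed integer seed; the atlas is deterministic given the seed.
#' @param voxel_size mm per axis (length 1 or 3).
#' @param lobe_groups character vector of lobe labels cycled over regions.
#' @return an object of class `atlas_parcellation`: a list with
#'   `label_volume` (3-D integer array, 0 = background), `region_table`
#'   (data frame with `region_id`, `region_name`, `lobe_group`) and
#'   `voxel_size`.
#' @examples
#' atl <- make_synthetic_atlas(c(16, 16, 16), n_regions = 8, seed = 1)
#' table(atl$label_volume[atl$label_volume > 0])
#' @export
make_synthetic_atlas <- function(grid_shape, n_regions, seed = 1L,
                                 voxel_size = c(3, 3, 3),
                                 lobe_groups = c("frontal", "occipital",
                                                 "temporal", "parietal",
                                                 "limbic", "cerebellum")) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop("grid_shape must be three positive integers", call. = FALSE)
  n_regions <- as.integer(n_regions)
  if (n_regions < 2L) stop("n_regions must be >= 2", call. = FALSE)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3)

  ctr <- (grid_shape + 1) / 2
  rad <- pmax(grid_shape * 0.45, 0.5)
  ax <- lapply(1:3, function(a)
    ((seq_len(grid_shape[a]) - ctr[a]) / rad[a])^2)
  d2 <- outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
  mask <- d2 <= 1
  n_in <- sum(mask)
  if (n_in < n_regions)
    stop(sprintf(paste0("grid too small: the brain mask holds %d voxels ",
                        "but %d regions were requested"), n_in, n_regions),
         call. = FALSE)

  idx_in <- which(mask)
  coords <- arrayInd(idx_in, grid_shape)
  seed_rows <- with_seed(derive_seed(seed, 11L), sample.int(n_in, n_regions))
  sc <- coords[seed_rows, , drop = FALSE]

  dmat <- matrix(0, n_in, n_regions)
  for (r in seq_len(n_regions)) {
    dmat[, r] <- (coords[, 1] - sc[r, 1])^2 +
      (coords[, 2] - sc[r, 2])^2 + (coords[, 3] - sc[r, 3])^2
  }
  lab <- max.col(-dmat, ties.method = "first")

  label_volume <- array(0L, grid_shape)
  label_volume[idx_in] <- lab
  lobes <- lobe_groups[((seq_len(n_regions) - 1L) %% length(lobe_groups)) + 1L]
  region_table <- data.frame(
    region_id = seq_len(n_regions),
    region_name = sprintf("%s_%02d", lobes, seq_len(n_regions)),
    lobe_group = lobes,
    stringsAsFactors = FALSE)

  atlas <- structure(list(label_volume = label_volume,
                          region_table = region_table,
                          voxel_size = as.numeric(voxel_size)),
                     class = "atlas_parcellation")
  validate_atlas(atlas)
  atlas
}

#' Validate an atlas parcellation
#'
#' Checks the structural invariants: ids contiguous from 1, the set of ids
#' in the label volume equals the set in the region table, and every
#' region owns at least one voxel.
#'
#' @param atlas an `atlas_parcellation`.
#' @return the atlas, invisibly; errors on violation.
#' @export
validate_atlas <- function(atlas) {
  stopifnot(inherits(atlas, "atlas_parcellation"))
  ids <- atlas$region_table$region_id
  if (!identical(as.integer(ids), seq_along(ids)))
    stop("region ids must be contiguous from 1", call. = FALSE)
  present <- sort(unique(as.integer(atlas$label_volume)))
  present <- present[present > 0L]
  if (!identical(present, as.integer(ids)))
    stop("region table and label volume disagree on region ids",
         call. = FALSE)
  invisible(atlas)
}

#' @export
print.atlas_parcellation <- function(x, ...) {
  cat(sprintf("atlas_parcellation: %d regions, grid %s, %d foreground voxels\n",
              nrow(x$region_table),
              paste(dim(x$label_volume), collapse = "x"),
              sum(x$label_volume > 0)))
  invisible(x)
}

atlas_mask <- function(atlas) atlas$label_volume > 0L

#' Write / read an atlas as NIfTI plus a region table CSV
#'
#' @param atlas an `atlas_parcellation`.
#' @param nifti_path output `.nii` / `.nii.gz` path for the label volume.
#' @param table_path output CSV path for the region table.
#' @return `write_atlas` returns the paths invisibly; `read_atlas` returns
#'   an `atlas_parcellation`.
#' @export
write_atlas <- function(atlas, nifti_path, table_path) {
  validate_atlas(atlas)
  img <- RNifti::asNifti(atlas$label_volume)
  img <- RNifti::`pixdim<-`(img, atlas$voxel_size)
  RNifti::writeNifti(img, nifti_path)
  tab <- atlas$region_table
  tab$voxel_size_mm <- paste(atlas$voxel_size, collapse = ";")
  utils::write.csv(tab, table_path, row.names = FALSE)
  invisible(c(nifti = nifti_path, table = table_path))
}

#' @rdname write_atlas
#' @export
read_atlas <- function(nifti_path, table_path) {
  img <- RNifti::readNifti(nifti_path)
  tab <- utils::read.csv(table_path, stringsAsFactors = FALSE)
  vs <- if ("voxel_size_mm" %in% names(tab))
    as.numeric(strsplit(tab$voxel_size_mm[1], ";")[[1]])
  else RNifti::pixdim(img)[1:3]
  lab <- array(as.integer(round(as.array(img))), dim = dim(img)[1:3])
  atlas <- structure(list(
    label_volume = lab,
    region_table = tab[, c("region_id", "region_name", "lobe_group")],
    voxel_size = vs), class = "atlas_parcellation")
  validate_atlas(atlas)
  atlas
}
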