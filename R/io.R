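#' Write a contrast dataset to disk
#'
#' One 3-D NIfTI per subject and condition
#' (`sub-XX_<condition>_gtbaseline.nii.gz`), the atlas, a sample manifest
#' and the ratings table as CSV.
#'
#' @param dataset a `contrast_dataset`.
#' @param dir output directory.
#' @return the manifest path, invisibly.
#' @export
write_contrast_images <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  info <- dataset$info
  paths <- character(nrow(info))
  for (k in seq_len(nrow(info))) {
    fn <- sprintf("sub-%02d_%s_gtbaseline.nii.gz",
                  info$subject_id[k], info$condition[k])
    img <- RNifti::asNifti(dataset$images[, , , k])
    img <- RNifti::`pixdim<-`(img, dataset$atlas$voxel_size)
    RNifti::writeNifti(img, file.path(dir, fn))
    paths[k] <- fn
  }
  manifest <- cbind(info, path = paths)
  utils::write.csv(manifest, file.path(dir, "samples.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$ratings, file.path(dir, "ratings.csv"),
                   row.names = FALSE)
  write_atlas(dataset$atlas, file.path(dir, "atlas.nii.gz"),
              file.path(dir, "atlas_regions.csv"))
  invisible(file.path(dir, "samples.csv"))
}

#' Read a contrast dataset written by [write_contrast_images()]
#'
#' @param dir directory holding `samples.csv`, `ratings.csv`, the atlas
#'   pair, and the per-sample NIfTI images.
#' @return a `contrast_dataset` (without generating design/effect
#'   metadata).
#' @export
read_contrast_images <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "samples.csv"),
                              stringsAsFactors = FALSE)
  atlas <- read_atlas(file.path(dir, "atlas.nii.gz"),
                      file.path(dir, "atlas_regions.csv"))
  dm <- dim(atlas$label_volume)
  images <- array(NA_real_, c(dm, nrow(manifest)))
  for (k in seq_len(nrow(manifest))) {
    img <- as.array(RNifti::readNifti(file.path(dir, manifest$path[k])))
    if (!identical(dim(img)[1:3], dm)) stop_mismatch("images and atlas")
    images[, , , k] <- img
  }
  ratings <- utils::read.csv(file.path(dir, "ratings.csv"),
                             stringsAsFactors = FALSE)
  info <- manifest[, setdiff(names(manifest), "path"), drop = FALSE]
  structure(list(images = images, info = info, ratings = ratings,
                 atlas = atlas),
            class = "contrast_dataset")
}

#' Write / read a synthetic scenario definition as YAML
#'
#' A scenario bundles the study design, the effect specification, the
#' synthetic atlas parameters and a seed — everything needed to
#' regenerate a dataset deterministically.
#'
#' @param design a [study_design()].
#' @param effect an [effect_spec()].
#' @param atlas_spec list with `grid_shape` and `n_regions`.
#' @param seed integer seed.
#' @param path YAML file path.
#' @return `write_scenario` returns `path` invisibly; `read_scenario`
#'   returns a list with `design`, `effect`, `atlas_spec`, `seed`.
#' @export
write_scenario <- function(design, effect, atlas_spec, seed, path) {
  yaml::write_yaml(list(
    design = unclass(design), effect = unclass(effect),
    atlas = atlas_spec, seed = seed), path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  sc <- yaml::read_yaml(path)
  design <- do.call(study_design, sc$design)
  effect <- do.call(effect_spec, sc$effect)
  list(design = design, effect = effect, atlas_spec = sc$atlas,
       seed = sc$seed)
}
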