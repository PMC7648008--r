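#' Split masked contrast images into per-region feature blocks
#'
#' For every atlas region with at least one voxel surviving the common
#' mask, extracts the `n_samples x n_voxels` matrix of contrast values.
#' Regions emptied by the mask are dropped with a warning naming them.
#'
#' @param images 4-D array (x, y, z, sample) or list of 3-D images sharing
#'   one grid with the atlas and mask.
#' @param atlas an `atlas_parcellation`.
#' @param mask logical 3-D array (e.g. from [build_common_mask()]);
#'   defaults to the atlas foreground.
#' @return named list (by region id) of `region_block` objects: lists with
#'   `region_id`, `X` (samples x voxels) and `voxel_index` (linear indices
#'   into the grid); the grid dimension is attached as attribute
#'   `grid_dim`.
#' @export
parcellate <- function(images, atlas, mask = NULL) {
  validate_atlas(atlas)
  if (is.list(images) && !is.array(images)) {
    check_same_grid(images, "images")
    images <- array(unlist(images, use.names = FALSE),
                    c(dim(images[[1]]), length(images)))
  }
  dm <- dim(images)[1:3]
  if (!identical(dm, dim(atlas$label_volume)))
    stop_mismatch("images and atlas")
  if (is.null(mask)) mask <- atlas_mask(atlas)
  if (!identical(dim(mask), dm)) stop_mismatch("mask and images")

  n_samp <- dim(images)[4]
  flat <- matrix(images, prod(dm), n_samp)
  lab <- as.integer(atlas$label_volume)
  keep <- as.logical(mask) & lab > 0L
  if (any(!is.finite(flat[keep, ])))
    stop("images contain non-finite values inside the mask", call. = FALSE)

  ids <- atlas$region_table$region_id
  blocks <- list()
  dropped <- integer(0)
  for (rid in ids) {
    vox <- which(keep & lab == rid)
    if (length(vox) == 0L) {
      dropped <- c(dropped, rid)
      next
    }
    blocks[[as.character(rid)]] <- structure(
      list(region_id = rid,
           X = t(flat[vox, , drop = FALSE]),
           voxel_index = vox),
      class = "region_block")
  }
  if (length(blocks) == 0L)
    stop("no region survives the mask", call. = FALSE)
  if (length(dropped) > 0L)
    warning(sprintf("regions removed entirely by the mask: %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
  attr(blocks, "grid_dim") <- dm
  blocks
}

#' Linear kernel of a region feature block
#'
#' `K[i, j]` is the inner product of samples i and j over the region's
#' voxels.
#'
#' @param block a `region_block` (or any samples-by-features matrix).
#' @return symmetric `n x n` matrix.
#' @export
linear_kernel <- function(block) {
  X <- if (inherits(block, "region_block")) block$X else as.matrix(block)
  if (nrow(X) < 1L || ncol(X) < 1L)
    stop("empty feature block", call. = FALSE)
  tcrossprod(X)
}

#' Build the raw kernel set from region blocks
#'
#' One linear kernel per region, sharing the sample ordering of the
#' blocks. Kernels are neither centered nor normalised; per-fold
#' statistics are applied later by [prepare_kernels()] so no test
#' information leaks into training statistics.
#'
#' @param blocks output of [parcellate()].
#' @param sample_info optional data frame describing the shared sample
#'   order (used for the provenance hash).
#' @return object of class `kernel_set`.
#' @export
build_kernel_set <- function(blocks, sample_info = NULL) {
  kernels <- lapply(blocks, linear_kernel)
  structure(list(kernels = kernels,
                 region_ids = as.integer(names(blocks)),
                 normalized = FALSE, centered = FALSE,
                 training_rows = NULL, scales = NULL,
                 sample_info = sample_info,
                 sample_hash = obj_hash(sample_info)),
            class = "kernel_set")
}

#' @export
print.kernel_set <- function(x, ...) {
  cat(sprintf("kernel_set: %d region kernels, %d samples (centered=%s, normalized=%s)\n",
              length(x$kernels), nrow(x$kernels[[1]]),
              x$centered, x$normalized))
  invisible(x)
}

#' Mean-center a kernel in feature space using training rows only
#'
#' Subtracts the feature-space mean of the training samples:
#' `K' = K - 1 m' - m 1' + mean(K_tt)` with `m_i = mean_t K[i, t]`. The
#' training submatrix of `K'` has rows and columns summing to zero; test
#' rows are transformed with the same training statistics.
#'
#' @param K `n x n` kernel.
#' @param training_rows integer indices of the training samples (>= 2).
#' @return centered kernel of the same size.
#' @export
center_kernel <- function(K, training_rows = seq_len(nrow(K))) {
  K <- as.matrix(K)
  tr <- as.integer(training_rows)
  if (length(tr) < 2L)
    stop("kernel centering needs at least 2 training rows", call. = FALSE)
  m <- rowMeans(K[, tr, drop = FALSE])
  mt <- mean(K[tr, tr])
  K - outer(m, rep(1, ncol(K))) - outer(rep(1, nrow(K)), m) + mt
}

#' Trace-normalise a kernel using training rows only
#'
#' Rescales so the training submatrix has trace equal to the number of
#' training samples: `K' = K * n_train / trace(K_train)`. This compensates
#' for region size (voxel count) differences. The same factor is applied
#' to test rows.
#'
#' @param K `n x n` kernel.
#' @param training_rows integer indices of the training samples.
#' @return list with `K` (rescaled kernel) and `scale` (the factor), or
#'   `NULL` if the training trace is not positive (degenerate region).
#' @export
normalize_kernel <- function(K, training_rows = seq_len(nrow(K))) {
  K <- as.matrix(K)
  tr <- as.integer(training_rows)
  tra <- sum(diag(K)[tr])
  if (!is.finite(tra) || tra <= .Machine$double.eps * length(tr))
    return(NULL)
  s <- length(tr) / tra
  list(K = K * s, scale = s)
}

#' Center then normalise every kernel of a set for one train/test split
#'
#' Applies [center_kernel()] then [normalize_kernel()] (statistics from
#' the training rows only) to every region kernel. Regions whose centered
#' training kernel has zero trace (no variance across training samples)
#' are dropped with a warning.
#'
#' @param kset a raw `kernel_set`.
#' @param training_rows indices of the training samples.
#' @param warn warn about dropped regions.
#' @return a prepared `kernel_set` with `centered`, `normalized`,
#'   `training_rows` and per-region `scales` recorded.
#' @export
prepare_kernels <- function(kset, training_rows, warn = TRUE) {
  stopifnot(inherits(kset, "kernel_set"))
  if (isTRUE(kset$centered) || isTRUE(kset$normalized))
    stop("kernel set is already prepared", call. = FALSE)
  kept <- list()
  scales <- numeric(0)
  dropped <- integer(0)
  for (i in seq_along(kset$kernels)) {
    Kc <- center_kernel(kset$kernels[[i]], training_rows)
    nk <- normalize_kernel(Kc, training_rows)
    rid <- as.character(kset$region_ids[i])
    if (is.null(nk)) {
      dropped <- c(dropped, kset$region_ids[i])
      next
    }
    kept[[rid]] <- nk$K
    scales[rid] <- nk$scale
  }
  if (length(kept) == 0L)
    stop("all regions degenerate on the training rows", call. = FALSE)
  if (warn && length(dropped) > 0L)
    warning(sprintf("zero-variance regions dropped: %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
  structure(list(kernels = kept,
                 region_ids = as.integer(names(kept)),
                 normalized = TRUE, centered = TRUE,
                 training_rows = as.integer(training_rows),
                 scales = scales,
                 sample_info = kset$sample_info,
                 sample_hash = kset$sample_hash),
            class = "kernel_set")
}
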