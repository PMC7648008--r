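#' Discrete cosine drift basis
#'
#' High-pass drift model: the `k = 1..K` non-constant discrete cosine
#' transform basis functions whose periods `2 N tr / k` are at least the
#' cut-off period, i.e. `K = floor(2 N tr / cutoff)`.
#'
#' @param n_scans number of volumes.
#' @param tr repetition time (s).
#' @param cutoff_s high-pass cut-off period (s).
#' @return matrix `n_scans x K` (0 columns if the run is too short);
#'   columns are mutually orthogonal.
#' @export
dct_drift_basis <- function(n_scans, tr, cutoff_s = 128) {
  if (cutoff_s < 2 * tr)
    stop("drift cut-off period must be at least 2 * tr", call. = FALSE)
  K <- floor(2 * n_scans * tr / cutoff_s)
  t <- seq_len(n_scans) - 1L
  X <- sapply(seq_len(K), function(k)
    sqrt(2 / n_scans) * cos(pi * (2 * t + 1) * k / (2 * n_scans)))
  if (K == 0) X <- matrix(0, n_scans, 0)
  if (K == 1) X <- matrix(X, ncol = 1)
  colnames(X) <- if (K > 0) paste0("drift_", seq_len(K))
  X
}

#' Build a first-level design matrix for one run
#'
#' One boxcar-convolved-with-HRF column per condition (regressors of
#' interest), a discrete cosine drift basis with the given cut-off,
#' optional nuisance covariates (e.g. motion parameters), and a constant
#' column.
#'
#' @param events data frame with `onset_s`, `duration_s`, `condition`
#'   (onsets relative to the first modelled volume).
#' @param n_scans number of volumes in the run.
#' @param tr repetition time (s).
#' @param hp_cutoff_s drift cut-off period (s).
#' @param nuisance optional data frame / matrix of nuisance series
#'   (`n_scans` rows).
#' @param hrf an [hrf_spec()].
#' @param conditions optional character vector fixing the order (and full
#'   set) of condition columns; defaults to the sorted conditions present.
#' @return object of class `design_matrix`: list with `X`, `names`,
#'   `interest`, `nuisance` (column index vectors), `tr`, `n_scans`.
#' @export
build_design_matrix <- function(events, n_scans, tr, hp_cutoff_s = 128,
                                nuisance = NULL, hrf = hrf_spec(),
                                conditions = NULL) {
  stopifnot(all(c("onset_s", "duration_s", "condition") %in% names(events)))
  if (nrow(events) > 0 &&
      (any(events$onset_s < 0) ||
       any(events$onset_s + events$duration_s > n_scans * tr)))
    stop("events fall outside the scan window", call. = FALSE)
  if (is.null(conditions))
    conditions <- sort(unique(events$condition))
  Xc <- sapply(conditions, function(cc) {
    ev <- events[events$condition == cc, , drop = FALSE]
    if (nrow(ev) == 0) return(rep(0, n_scans))
    condition_regressor(ev$onset_s, ev$duration_s, n_scans, tr, hrf)
  })
  if (length(conditions) == 0) Xc <- matrix(0, n_scans, 0)
  if (length(conditions) == 1) Xc <- matrix(Xc, ncol = 1)
  colnames(Xc) <- conditions

  Xd <- dct_drift_basis(n_scans, tr, hp_cutoff_s)
  Xn <- if (!is.null(nuisance)) {
    Xn <- as.matrix(nuisance)
    if (nrow(Xn) != n_scans)
      stop("nuisance table must have one row per scan", call. = FALSE)
    if (is.null(colnames(Xn)))
      colnames(Xn) <- paste0("nuisance_", seq_len(ncol(Xn)))
    Xn
  } else matrix(0, n_scans, 0)

  X <- cbind(Xc, Xd, Xn, constant = 1)
  structure(list(
    X = X, names = colnames(X),
    interest = seq_len(ncol(Xc)),
    nuisance = if (ncol(Xn) > 0)
      ncol(Xc) + ncol(Xd) + seq_len(ncol(Xn)) else integer(0),
    tr = tr, n_scans = n_scans), class = "design_matrix")
}

# single-run voxelwise OLS; returns coefficient array [voxels x p]
glm_fit_run <- function(series, design) {
  X <- design$X
  dm <- dim(series)
  if (length(dm) != 4L || dm[4] != nrow(X))
    stop("series must be 4-D with one volume per design row", call. = FALSE)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop(sprintf("design matrix is rank deficient; collinear columns: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  Y <- t(matrix(series, prod(dm[1:3]), dm[4]))
  qr.coef(qx, Y)
}

#' Fit a voxelwise GLM and form a contrast image
#'
#' Ordinary least squares at every voxel. With a single run, returns the
#' 3-D image of `contrast' beta`. With a list of runs (and a matching list
#' of designs), each run is modelled independently and the per-run
#' contrast estimates are averaged, so units do not depend on the number
#' of runs.
#'
#' @param series 4-D array (x, y, z, t) or list of such arrays.
#' @param design a `design_matrix` or list of them (one per run).
#' @param contrast numeric contrast vector (length = columns of the
#'   design), or a condition name, resolved per run to an indicator of
#'   that column.
#' @return 3-D contrast image.
#' @export
fit_glm_and_contrast <- function(series, design, contrast) {
  if (!is.list(series) || is.array(series)) {
    series <- list(series)
    design <- list(design)
  }
  stopifnot(length(series) == length(design))
  acc <- NULL
  for (r in seq_along(series)) {
    X <- design[[r]]$X
    cvec <- if (is.character(contrast)) {
      if (!contrast %in% colnames(X))
        stop(sprintf("condition '%s' not in design", contrast),
             call. = FALSE)
      as.numeric(colnames(X) == contrast)
    } else {
      if (length(contrast) != ncol(X))
        stop("contrast length must match design columns", call. = FALSE)
      contrast
    }
    beta <- glm_fit_run(series[[r]], design[[r]])
    con <- drop(crossprod(beta, cvec))
    acc <- if (is.null(acc)) con else acc + con
  }
  array(acc / length(series), dim(series[[1]])[1:3])
}

#' First-level analysis of a synthetic BOLD session
#'
#' Drops the initial volumes of each run, shifts event onsets accordingly,
#' builds one design matrix per run (conditions + drift + motion +
#' constant), fits the GLM run-wise and averages each condition's
#' contrast-versus-baseline estimate across runs. Baseline is the
#' unmodelled fixation interval, so the contrast vector simply selects the
#' condition column.
#'
#' @param session output of [make_bold_session()].
#' @param drop_volumes initial volumes removed per run.
#' @param hp_cutoff_s drift cut-off period (s).
#' @param use_motion include the motion covariates.
#' @param hrf an [hrf_spec()].
#' @return named list of 3-D contrast images, one per condition.
#' @export
run_first_level <- function(session, drop_volumes = 3L, hp_cutoff_s = 128,
                            use_motion = TRUE, hrf = session$hrf %||% hrf_spec()) {
  tr <- session$tr_seconds
  conds <- session$design$conditions
  series <- list()
  designs <- list()
  for (r in seq_along(session$runs)) {
    run <- session$runs[[r]]
    nt <- dim(run)[4]
    keep <- (drop_volumes + 1L):nt
    ev <- session$events[session$events$run == r, , drop = FALSE]
    ev$onset_s <- ev$onset_s - drop_volumes * tr
    if (any(ev$onset_s < 0))
      stop("dropping volumes would truncate an event", call. = FALSE)
    nuis <- if (use_motion && !is.null(session$motion))
      session$motion[[r]][keep, , drop = FALSE] else NULL
    series[[r]] <- run[, , , keep, drop = FALSE]
    designs[[r]] <- build_design_matrix(ev, length(keep), tr,
                                        hp_cutoff_s = hp_cutoff_s,
                                        nuisance = nuis, hrf = hrf,
                                        conditions = conds)
  }
  out <- lapply(conds, function(cc)
    fit_glm_and_contrast(series, designs, cc))
  names(out) <- conds
  out
}

#' Separable Gaussian spatial smoothing
#'
#' Smooths a 3-D volume with a separable Gaussian of the given full width
#' at half maximum, axis by axis, with kernel weights renormalised at the
#' edges so constant volumes are preserved exactly.
#'
#' @param volume 3-D numeric array.
#' @param fwhm_mm full width at half maximum in mm (>= 0; 0 = identity).
#' @param voxel_size mm per axis (length 1 or 3).
#' @return smoothed array of the same dimensions.
#' @export
gaussian_smooth <- function(volume, fwhm_mm, voxel_size = c(1, 1, 1)) {
  if (fwhm_mm < 0) stop("fwhm must be nonnegative", call. = FALSE)
  if (fwhm_mm == 0) return(volume)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3)
  dm <- dim(volume)
  stopifnot(length(dm) == 3L)
  sd_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size
  out <- volume
  for (axis in 1:3) {
    s <- sd_vox[axis]
    if (s <= 0) next
    r <- max(1L, ceiling(4 * s))
    w <- stats::dnorm(-r:r, sd = s)
    n <- dm[axis]
    # banded smoothing operator with edge renormalisation
    B <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- max(1L, i - r):min(n, i + r)
      wj <- w[j - i + r + 1L]
      B[i, j] <- wj / sum(wj)
    }
    perm <- c(axis, setdiff(1:3, axis))
    a <- aperm(out, perm)
    da <- dim(a)
    a <- B %*% matrix(a, da[1], da[2] * da[3])
    dim(a) <- da
    out <- aperm(a, order(perm))
  }
  out
}

#' Common finite-value mask across contrast images
#'
#' A voxel is kept iff it is finite in every supplied image, across all
#' subjects and conditions; a single subject's NaN therefore removes the
#' voxel for everyone. Adding images can only shrink the mask.
#'
#' @param images list of 3-D arrays, or a 4-D array (last axis = image).
#' @return logical 3-D array.
#' @export
build_common_mask <- function(images) {
  if (is.array(images) && length(dim(images)) == 4L)
    images <- lapply(seq_len(dim(images)[4]), function(k)
      images[, , , k])
  if (length(images) < 1L) stop("need at least one image", call. = FALSE)
  check_same_grid(images, "contrast images")
  Reduce(`&`, lapply(images, is.finite))
}
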