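#' Sample subject threat-evaluation ratings
#'
#' Each subject rates four threat dimensions (threat magnitude, proximity,
#' inescapability, impossibility of hiding) on a 1-9 Likert scale; the
#' threat-perception index is their exact sum (range 4-36). Ratings are
#' drawn independently from a discretised truncated normal (mean 3, sd 2,
#' support 1..9), which puts the index mean near the published
#' towards-context value of about 12.4.
#'
#' @param n_subjects number of subjects.
#' @param seed integer seed.
#' @param mean,sd parameters of the underlying normal before truncation.
#' @return data frame with `subject_id`, the four ratings and
#'   `threat_perception_index`.
#' @export
sample_ratings <- function(n_subjects, seed = 1L, mean = 3, sd = 2) {
  ks <- 1:9
  pk <- stats::pnorm(ks + 0.5, mean, sd) - stats::pnorm(ks - 0.5, mean, sd)
  pk <- pk / sum(pk)
  r <- with_seed(derive_seed(seed, 23L), {
    matrix(sample(ks, 4L * n_subjects, replace = TRUE, prob = pk),
           nrow = n_subjects, ncol = 4L)
  })
  out <- data.frame(
    subject_id = seq_len(n_subjects),
    rating_threat_magnitude = r[, 1], rating_proximity = r[, 2],
    rating_inescapability = r[, 3], rating_hiding = r[, 4])
  out$threat_perception_index <- as.integer(rowSums(r))
  out
}

# mask voxels with at least one background 6-neighbour
border_voxels <- function(mask) {
  dm <- dim(mask)
  pad <- array(FALSE, dm + 2L)
  pad[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)] <- mask
  inner <- pad[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)]
  nb <- pad[1:dm[1], 2:(dm[2] + 1), 2:(dm[3] + 1)] &
    pad[3:(dm[1] + 2), 2:(dm[2] + 1), 2:(dm[3] + 1)] &
    pad[2:(dm[1] + 1), 1:dm[2], 2:(dm[3] + 1)] &
    pad[2:(dm[1] + 1), 3:(dm[2] + 2), 2:(dm[3] + 1)] &
    pad[2:(dm[1] + 1), 2:(dm[2] + 1), 1:dm[3]] &
    pad[2:(dm[1] + 1), 2:(dm[2] + 1), 3:(dm[3] + 2)]
  inner & !nb
}

#' Generate a synthetic contrast-image dataset
#'
#' Emulates the per-subject, per-condition GLM contrast images the decoding
#' analysis consumes. Threat-condition images receive a mean effect of
#' `delta + gamma * z(index)` in the voxels of the informative regions
#' (`z` is the across-subject standardised threat-perception index);
#' neutral conditions have zero mean effect. A per-subject scalar offset
#' and iid Gaussian noise are added to every voxel inside the atlas mask.
#' Sample order follows the contract shared by all kernels: subjects sorted
#' by id, conditions in the declared order.
#'
#' @param design a [study_design()].
#' @param atlas an `atlas_parcellation`.
#' @param effect an [effect_spec()].
#' @param seed integer seed; output is deterministic given the seed.
#' @return an object of class `contrast_dataset`: list with `images`
#'   (4-D array, last axis = sample), `info` (one row per sample:
#'   `sample`, `subject_id`, `condition`, `is_threat`, `index`),
#'   `ratings`, and the generating `design`, `effect`, `atlas`.
#' @export
make_contrast_dataset <- function(design = study_design(), atlas,
                                  effect = effect_spec(), seed = 1L) {
  validate_design(design)
  validate_atlas(atlas)
  check_effect_atlas(effect, atlas)

  n_sub <- design$n_subjects
  conds <- design$conditions
  dm <- dim(atlas$label_volume)
  mask <- atlas_mask(atlas)
  informative <- array(atlas$label_volume %in% effect$informative_region_ids,
                       dm) & mask
  ratings <- sample_ratings(n_sub, seed = derive_seed(seed, 1L))
  idx <- ratings$threat_perception_index
  z <- if (stats::sd(idx) > 0) (idx - mean(idx)) / stats::sd(idx)
       else rep(0, n_sub)

  n_samp <- n_sub * length(conds)
  images <- array(NA_real_, c(dm, n_samp))
  info <- data.frame(sample = seq_len(n_samp),
                     subject_id = rep(seq_len(n_sub), each = length(conds)),
                     condition = rep(conds, times = n_sub),
                     stringsAsFactors = FALSE)
  info$is_threat <- startsWith(info$condition, "threat")
  info$index <- idx[info$subject_id]

  offs <- with_seed(derive_seed(seed, 2L),
                    stats::rnorm(n_sub, 0, effect$subject_offset_sd))
  bord <- if (effect$nan_injection) which(border_voxels(mask)) else integer(0)

  for (s in seq_len(n_sub)) {
    nan_here <- if (effect$nan_injection) {
      with_seed(derive_seed(seed, 1000L + s),
                bord[stats::runif(length(bord)) < 0.01])
    } else integer(0)
    for (ci in seq_along(conds)) {
      k <- (s - 1L) * length(conds) + ci
      vol <- array(0, dm)
      if (startsWith(conds[ci], "threat"))
        vol[informative] <- effect$delta + effect$gamma * z[s]
      noise <- with_seed(derive_seed(seed, 10L + k),
                         stats::rnorm(sum(mask), 0, effect$noise_sd))
      vol[mask] <- vol[mask] + offs[s] + noise
      if (effect$smoothness_fwhm_mm > 0)
        vol <- gaussian_smooth(vol, effect$smoothness_fwhm_mm,
                               atlas$voxel_size)
      vol[!mask] <- 0
      vol[nan_here] <- NaN
      images[, , , k] <- vol
    }
  }

  structure(list(images = images, info = info, ratings = ratings,
                 design = design, effect = effect, atlas = atlas,
                 seed = seed),
            class = "contrast_dataset")
}

#' @export
print.contrast_dataset <- function(x, ...) {
  cat(sprintf("contrast_dataset: %d subjects x %d conditions, grid %s\n",
              x$design$n_subjects, length(x$design$conditions),
              paste(dim(x$images)[1:3], collapse = "x")))
  invisible(x)
}

#' Per-run block schedule for a session
#'
#' Lays out the session's blocks: each run holds an equal share of the 56
#' blocks, conditions are distributed so that every condition appears in
#' every run and totals per condition match the design, block order within
#' a run is shuffled by the seed, and blocks are separated by the baseline
#' interval. Onsets are relative to the first acquired volume of the run;
#' the first block starts after the three volumes that are later dropped
#' from modelling.
#'
#' @param design a [study_design()].
#' @param seed integer seed.
#' @return data frame with `run`, `onset_s`, `duration_s`, `condition`.
#' @export
make_event_table <- function(design = study_design(), seed = 1L) {
  validate_design(design)
  counts <- condition_run_counts(design)
  cycle <- design$block_duration_s + design$baseline_duration_s
  settle <- 3 * design$tr_seconds
  ev <- list()
  for (r in seq_len(design$n_runs)) {
    conds <- rep(colnames(counts), counts[r, ])
    conds <- with_seed(derive_seed(seed, 100L + r), sample(conds))
    ev[[r]] <- data.frame(
      run = r,
      onset_s = settle + (seq_along(conds) - 1L) * cycle,
      duration_s = design$block_duration_s,
      condition = conds, stringsAsFactors = FALSE)
  }
  do.call(rbind, ev)
}

#' Generate a synthetic single-subject BOLD session
#'
#' Produces, per run, a 4-D time series built as baseline + sum over
#' conditions of amplitude x (boxcar convolved with the canonical HRF)
#' restricted to the informative regions, plus a slow cosine drift and
#' AR(1) Gaussian noise; together with the event table and six smooth
#' motion-like nuisance series. Used to exercise the GLM stage end-to-end.
#'
#' @param design a [study_design()].
#' @param atlas an `atlas_parcellation`.
#' @param effect an [effect_spec()]; threat conditions get amplitude
#'   `delta + gamma * z_index`, neutral conditions 0, unless `amplitudes`
#'   overrides this.
#' @param seed integer seed.
#' @param amplitudes optional named vector of per-condition response
#'   amplitudes (signal units).
#' @param z_index standardised threat-perception index of this subject.
#' @param baseline constant signal level.
#' @param drift_amplitude amplitude of the slow cosine drift (0 = none).
#' @param ar1 AR(1) coefficient of the noise process.
#' @param hrf an [hrf_spec()].
#' @return list with `runs` (list of 4-D arrays), `events`, `motion`,
#'   `amplitudes`, `design`, `atlas`, `tr_seconds`.
#' @export
make_bold_session <- function(design = study_design(), atlas,
                              effect = effect_spec(), seed = 1L,
                              amplitudes = NULL, z_index = 0,
                              baseline = 100, drift_amplitude = 0.5,
                              ar1 = 0.3, hrf = hrf_spec()) {
  validate_design(design)
  validate_atlas(atlas)
  check_effect_atlas(effect, atlas)
  conds <- design$conditions
  if (is.null(amplitudes)) {
    amplitudes <- ifelse(startsWith(conds, "threat"),
                         effect$delta + effect$gamma * z_index, 0)
    names(amplitudes) <- conds
  }
  if (!all(conds %in% names(amplitudes)))
    stop("amplitudes must name every condition", call. = FALSE)

  events <- make_event_table(design, seed = seed)
  dm <- dim(atlas$label_volume)
  mask <- atlas_mask(atlas)
  informative <- array(atlas$label_volume %in% effect$informative_region_ids,
                       dm) & mask
  nt <- design$volumes_per_run
  tr <- design$tr_seconds
  nv <- prod(dm)

  runs <- vector("list", design$n_runs)
  motion <- list()
  for (r in seq_len(design$n_runs)) {
    ev_r <- events[events$run == r, , drop = FALSE]
    sig <- rep(0, nt)
    for (cc in conds) {
      ev_c <- ev_r[ev_r$condition == cc, , drop = FALSE]
      if (nrow(ev_c) > 0)
        sig <- sig + amplitudes[[cc]] *
          condition_regressor(ev_c$onset_s, ev_c$duration_s, nt, tr, hrf)
    }
    tt <- (seq_len(nt) - 1) * tr
    drift <- drift_amplitude * cos(2 * pi * tt / (nt * tr) * 0.75)

    series <- array(baseline, c(dm, nt))
    flat <- matrix(series, nv, nt)
    inf_idx <- which(informative)
    flat[inf_idx, ] <- flat[inf_idx, ] +
      matrix(sig, length(inf_idx), nt, byrow = TRUE)
    mask_idx <- which(mask)
    flat[mask_idx, ] <- flat[mask_idx, ] +
      matrix(drift, length(mask_idx), nt, byrow = TRUE)
    if (effect$noise_sd > 0) {
      eps <- with_seed(derive_seed(seed, 200L + r), {
        e <- matrix(stats::rnorm(length(mask_idx) * nt, 0,
                                 effect$noise_sd), length(mask_idx), nt)
        if (ar1 != 0 && nt > 1)
          for (t in 2:nt) e[, t] <- ar1 * e[, t - 1] +
              sqrt(1 - ar1^2) * e[, t]
        e
      })
      flat[mask_idx, ] <- flat[mask_idx, ] + eps
    }
    runs[[r]] <- array(flat, c(dm, nt))

    mo <- with_seed(derive_seed(seed, 300L + r), {
      tt_n <- tt / max(tt)
      sapply(1:6, function(j)
        0.1 * sin(2 * pi * tt_n * stats::runif(1, 0.5, 2) +
                    stats::runif(1, 0, 2 * pi)) +
          cumsum(stats::rnorm(nt, 0, 0.002)))
    })
    colnames(mo) <- paste0("motion_", 1:6)
    motion[[r]] <- as.data.frame(mo)
  }

  list(runs = runs, events = events, motion = motion,
       amplitudes = amplitudes, design = design, atlas = atlas,
       tr_seconds = tr, hrf = hrf)
}

#' Generate an analytic test picture
#'
#' RGB images whose pixel statistics are known in closed form, used to
#' validate the stimulus picture metrics.
#'
#' @param kind one of `"uniform"`, `"vertical_gradient"`, `"checkerboard"`.
#' @param width,height image size in pixels.
#' @param value grey level for `"uniform"` (0-255).
#' @param period full period of the checkerboard in pixels (even).
#' @param seed unused; kept for generator API uniformity.
#' @return numeric array `height x width x 3` with values in 0-255.
#' @export
make_stimulus_image <- function(kind = c("uniform", "vertical_gradient",
                                         "checkerboard"),
                                width = 64L, height = 64L, value = 128,
                                period = 8L, seed = NULL) {
  kind <- match.arg(kind)
  g <- switch(kind,
    uniform = matrix(value, height, width),
    vertical_gradient = matrix(rep(seq(0, 255, length.out = width),
                                   each = height), height, width),
    checkerboard = {
      if (period %% 2 != 0) stop("checkerboard period must be even",
                                 call. = FALSE)
      half <- period / 2
      ri <- floor((seq_len(height) - 1) / half)
      ci <- floor((seq_len(width) - 1) / half)
      255 * outer(ri, ci, function(a, b) (a + b) %% 2)
    })
  array(rep(g, 3L), c(height, width, 3L))
}
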