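#' Blocked threat-perception study design
#'
#' Encodes the acquisition and task structure the synthetic generators
#' emulate: 38 subjects view threat and neutral pictures, each either
#' directed towards or away from the viewer (4 conditions), in 4 runs of
#' 198 volumes at TR = 2 s. The session holds 56 blocks of 15 s (14 per
#' condition) separated by 12 s of fixation baseline, and every condition
#' appears in every run.
#'
#' @param n_subjects number of subjects.
#' @param conditions condition labels in their declared order; the first
#'   `threat_` prefix marks the positive class for classification.
#' @param n_runs,volumes_per_run,tr_seconds acquisition geometry.
#' @param block_duration_s,baseline_duration_s,blocks_per_condition task
#'   block structure (per session).
#' @return an object of class `study_design`.
#' @export
study_design <- function(n_subjects = 38L,
                         conditions = c("threat_towards", "threat_away",
                                        "neutral_towards", "neutral_away"),
                         n_runs = 4L, volumes_per_run = 198L,
                         tr_seconds = 2.0, block_duration_s = 15,
                         baseline_duration_s = 12,
                         blocks_per_condition = 14L) {
  d <- structure(list(n_subjects = as.integer(n_subjects),
                      conditions = conditions,
                      n_runs = as.integer(n_runs),
                      volumes_per_run = as.integer(volumes_per_run),
                      tr_seconds = tr_seconds,
                      block_duration_s = block_duration_s,
                      baseline_duration_s = baseline_duration_s,
                      blocks_per_condition = as.integer(blocks_per_condition)),
                 class = "study_design")
  validate_design(d)
  d
}

validate_design <- function(design) {
  stopifnot(inherits(design, "study_design"))
  n_cond <- length(design$conditions)
  total_blocks <- design$blocks_per_condition * n_cond
  if (total_blocks %% design$n_runs != 0L)
    stop("total block count must divide evenly across runs", call. = FALSE)
  blocks_per_run <- total_blocks / design$n_runs
  cycle <- design$block_duration_s + design$baseline_duration_s
  run_s <- design$volumes_per_run * design$tr_seconds
  # blocks start after an initial settle period of one baseline... they must
  # fit: settle (3 volumes) + blocks
  need <- 3 * design$tr_seconds + blocks_per_run * cycle
  if (need > run_s + design$baseline_duration_s)
    stop(sprintf("block schedule (%g s) does not fit in a %g s run",
                 need, run_s), call. = FALSE)
  if (design$blocks_per_condition < design$n_runs)
    stop("each condition must appear in every run", call. = FALSE)
  invisible(design)
}

# Per-run condition block counts: rows = runs, cols = conditions; every
# condition appears in every run and column sums equal blocks_per_condition.
condition_run_counts <- function(design) {
  n_cond <- length(design$conditions)
  n_runs <- design$n_runs
  base <- design$blocks_per_condition %/% n_runs
  extra <- design$blocks_per_condition %% n_runs
  m <- matrix(base, n_runs, n_cond,
              dimnames = list(NULL, design$conditions))
  if (extra > 0) {
    # distribute the remainder so each run still has equal total blocks:
    # condition c gets its extra blocks in runs (c, c+1, ...) cyclically
    for (cc in seq_len(n_cond)) {
      runs <- ((cc - 1L + seq_len(extra) - 1L) %% n_runs) + 1L
      m[runs, cc] <- m[runs, cc] + 1L
    }
  }
  m
}

#' Effect specification for the synthetic generators
#'
#' Encodes the generative assumptions the decoding analysis is tested
#' against: a condition effect of size `delta` added to threat-condition
#' voxels inside the informative regions, a per-subject amplitude
#' modulation `gamma` per unit of standardised threat-perception index,
#' iid Gaussian voxel noise, a per-subject global offset, optional Gaussian
#' smoothing and optional NaN injection at mask border voxels (off by
#' default; it exists to exercise the common-mask rule).
#'
#' @param informative_region_ids atlas region ids carrying the effect.
#' @param delta class effect size (signal units) for threat conditions.
#' @param gamma index loading: amplitude added per unit of standardised
#'   threat-perception index in threat conditions.
#' @param noise_sd iid Gaussian noise SD.
#' @param subject_offset_sd SD of the per-subject scalar offset added to
#'   every mask voxel.
#' @param smoothness_fwhm_mm optional Gaussian smoothing FWHM (0 = none).
#' @param nan_injection logical; inject NaN at ~1 percent of each
#'   subject's mask border voxels.
#' @return an object of class `effect_spec`.
#' @export
effect_spec <- function(informative_region_ids = 1L, delta = 1,
                        gamma = 1, noise_sd = 0.5,
                        subject_offset_sd = 0.2,
                        smoothness_fwhm_mm = 0,
                        nan_injection = FALSE) {
  if (delta < 0 || noise_sd < 0 || subject_offset_sd < 0 ||
      smoothness_fwhm_mm < 0)
    stop("delta, noise_sd, subject_offset_sd and smoothness must be >= 0",
         call. = FALSE)
  structure(list(informative_region_ids = as.integer(informative_region_ids),
                 delta = delta, gamma = gamma, noise_sd = noise_sd,
                 subject_offset_sd = subject_offset_sd,
                 smoothness_fwhm_mm = smoothness_fwhm_mm,
                 nan_injection = isTRUE(nan_injection)),
            class = "effect_spec")
}

check_effect_atlas <- function(effect, atlas) {
  ids <- atlas$region_table$region_id
  if (!all(effect$informative_region_ids %in% ids))
    stop("informative_region_ids must be a subset of the atlas region ids",
         call. = FALSE)
  invisible(TRUE)
}
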