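#' Canonical double-gamma HRF specification
#'
#' The conventional parameterisation: a response gamma density (delay 6 s,
#' dispersion 1) minus an undershoot gamma density (delay 16 s, dispersion
#' 1) scaled by 1/ratio, supported on 32 s. All parameters are
#' configurable.
#'
#' @param peak_delay,peak_dispersion response gamma delay and dispersion
#'   (seconds; the gamma has shape `delay/dispersion` and scale
#'   `dispersion`).
#' @param undershoot_delay,undershoot_dispersion undershoot gamma
#'   parameters.
#' @param ratio peak:undershoot amplitude ratio (larger = weaker
#'   undershoot; `Inf` removes it).
#' @param length_s kernel support in seconds (>= 24).
#' @return an object of class `hrf_spec`.
#' @export
hrf_spec <- function(peak_delay = 6, peak_dispersion = 1,
                     undershoot_delay = 16, undershoot_dispersion = 1,
                     ratio = 6, length_s = 32) {
  if (length_s < 24) stop("HRF support must be at least 24 s", call. = FALSE)
  if (ratio <= 0) stop("ratio must be positive", call. = FALSE)
  structure(list(peak_delay = peak_delay,
                 peak_dispersion = peak_dispersion,
                 undershoot_delay = undershoot_delay,
                 undershoot_dispersion = undershoot_dispersion,
                 ratio = ratio, length_s = length_s),
            class = "hrf_spec")
}

# raw double-gamma evaluated at arbitrary times (seconds)
hrf_values <- function(t, spec) {
  h <- stats::dgamma(t, shape = spec$peak_delay / spec$peak_dispersion,
                     scale = spec$peak_dispersion)
  if (is.finite(spec$ratio))
    h <- h - stats::dgamma(t,
                           shape = spec$undershoot_delay /
                             spec$undershoot_dispersion,
                           scale = spec$undershoot_dispersion) / spec$ratio
  h
}

#' Sample the canonical HRF at the repetition time
#'
#' @param tr repetition time in seconds (> 0).
#' @param spec an [hrf_spec()].
#' @return numeric kernel of length `ceiling(length_s / tr)`, sampled at
#'   `0, tr, 2 tr, ...`.
#' @examples
#' length(canonical_hrf(2))  # 16 samples over the default 32-s support
#' @export
canonical_hrf <- function(tr, spec = hrf_spec()) {
  if (!is.numeric(tr) || tr <= 0) stop("tr must be positive", call. = FALSE)
  n <- ceiling(spec$length_s / tr)
  t <- (seq_len(n) - 1) * tr
  h <- hrf_values(t, spec)
  if (sum(h) * tr <= 0)
    stop("HRF kernel must integrate to a positive value", call. = FALSE)
  h
}

#' Condition regressor: boxcar convolved with the canonical HRF
#'
#' Builds the boxcar on an oversampled time grid (`tr/oversample`),
#' convolves with the HRF normalised to unit integral (so a long block
#' plateaus at 1 and GLM betas are in the signal's amplitude units), and
#' samples at scan times. The synthetic BOLD generator and the design
#' matrix builder share this routine, so injected amplitudes are
#' recoverable exactly on noiseless data.
#'
#' @param onsets,durations block onsets/durations in seconds, relative to
#'   the first volume.
#' @param n_scans number of volumes.
#' @param tr repetition time in seconds.
#' @param hrf an [hrf_spec()].
#' @param oversample microtime resolution per TR.
#' @return numeric vector of length `n_scans`.
#' @export
condition_regressor <- function(onsets, durations, n_scans, tr,
                                hrf = hrf_spec(), oversample = 16L) {
  if (any(onsets < 0) || any(onsets + durations > n_scans * tr))
    stop("events fall outside the scan window", call. = FALSE)
  dt <- tr / oversample
  n_fine <- n_scans * oversample
  u <- rep(0, n_fine)
  for (k in seq_along(onsets)) {
    i0 <- floor(onsets[k] / dt) + 1L
    i1 <- min(n_fine, ceiling((onsets[k] + durations[k]) / dt))
    if (i0 <= n_fine) u[i0:i1] <- 1
  }
  th <- seq(0, hrf$length_s, by = dt)
  h <- hrf_values(th, hrf)
  h <- h / (sum(h) * dt)
  conv <- stats::convolve(u, rev(h), type = "open")[seq_len(n_fine)] * dt
  conv[seq(1L, n_fine, by = oversample)]
}
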