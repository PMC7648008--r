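# Stimulus picture standardisation metrics. Pictures are numeric arrays
# height x width x 3 with channel values on 0-255 (see read_stimulus()).

pixel_mean_rgb <- function(image) {
  if (!(is.array(image) && length(dim(image)) == 3L && dim(image)[3] == 3L))
    stop("image must be a height x width x 3 RGB array", call. = FALSE)
  if (any(dim(image)[1:2] == 0L)) stop("empty image", call. = FALSE)
  matrix((image[, , 1] + image[, , 2] + image[, , 3]) / 3,
         dim(image)[1], dim(image)[2])
}

#' Picture brightness
#'
#' The mean RGB value of each pixel (mean of the three channels),
#' averaged across all pixels.
#'
#' @param image `height x width x 3` numeric array, values 0-255.
#' @return scalar in 0-255.
#' @export
stim_brightness <- function(image) {
  mean(pixel_mean_rgb(image))
}

#' Picture contrast
#'
#' The standard deviation, across image columns, of each column's mean
#' RGB value.
#'
#' @inheritParams stim_brightness
#' @return nonnegative scalar (SD units).
#' @export
stim_contrast <- function(image) {
  g <- pixel_mean_rgb(image)
  if (ncol(g) < 2L) stop("contrast needs at least 2 columns", call. = FALSE)
  stats::sd(colMeans(g))
}

#' Picture spatial frequency
#'
#' The median discrete Fourier power spectrum computed for each row and
#' each column of the pixel-mean image and then averaged: per line the
#' median of `|FFT|^2` excluding the zero-frequency term (so the metric is
#' invariant to constant offsets), averaged over rows and over columns,
#' and the two averages are themselves averaged.
#'
#' @inheritParams stim_brightness
#' @return nonnegative scalar (arbitrary power units).
#' @export
stim_spatial_frequency <- function(image) {
  g <- pixel_mean_rgb(image)
  if (nrow(g) < 2L || ncol(g) < 2L)
    stop("spatial frequency needs at least 2 rows and 2 columns",
         call. = FALSE)
  line_med <- function(v) stats::median(Mod(stats::fft(v))[-1]^2)
  row_med <- apply(g, 1, line_med)
  col_med <- apply(g, 2, line_med)
  mean(c(mean(row_med), mean(col_med)))
}

#' Threat-perception index
#'
#' The exact sum of the four 1-9 threat-evaluation ratings (threat
#' magnitude, proximity, inescapability, impossibility of hiding); range
#' 4-36.
#'
#' @param ratings numeric vector of four ratings, each in `[1, 9]`.
#' @return the summed index.
#' @export
threat_perception_index <- function(ratings) {
  ratings <- as.numeric(ratings)
  if (length(ratings) != 4L)
    stop("expected four rating dimensions", call. = FALSE)
  if (any(ratings < 1 | ratings > 9))
    stop("ratings must lie in [1, 9]", call. = FALSE)
  sum(ratings)
}

#' Compute the metric table for a set of pictures
#'
#' @param images named list of RGB arrays (0-255).
#' @return data frame with `image_id`, `brightness`, `contrast`,
#'   `spatial_frequency`.
#' @export
stimulus_metrics_table <- function(images) {
  ids <- names(images) %||% as.character(seq_along(images))
  data.frame(
    image_id = ids,
    brightness = vapply(images, stim_brightness, numeric(1)),
    contrast = vapply(images, stim_contrast, numeric(1)),
    spatial_frequency = vapply(images, stim_spatial_frequency, numeric(1)),
    row.names = NULL)
}

#' Read / write a stimulus picture as PNG
#'
#' Values are scaled to the 0-255 range used by the metrics.
#'
#' @param path PNG file path.
#' @param image RGB array on 0-255.
#' @export
read_stimulus <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), c(dim(a), 3L))
  a[, , 1:3, drop = FALSE] * 255
}

#' @rdname read_stimulus
#' @export
write_stimulus <- function(image, path) {
  png::writePNG(pmin(pmax(image / 255, 0), 1), path)
  invisible(path)
}
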