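## Background normalization and adaptive local thresholding: turns the green
## channel into the binary retinal image from which large vessels and
## residual fragments are taken.

#' Estimate the slowly varying background
#'
#' Median-filters the gray image with an odd square window (default 25 x 25),
#' reflect-padded at the borders.  Vessels are narrow relative to the window,
#' so the median passes the background through while removing them.
#'
#' @param gray A [gray_image()] or numeric matrix.
#' @param window Odd window size in pixels, >= 3.
#' @return A [gray_image()] of the same shape with the FOV propagated.
#' @export
estimate_background <- function(gray, window = 25L) {
  gray <- as_gray(gray)
  window <- as.integer(window)
  if (window %% 2L != 1L || window < 3L)
    stop("window must be odd and >= 3, got ", window)
  gray_image(cpp_median_filter(gray$values, window), fov = gray$fov)
}

#' Normalize away the illumination background
#'
#' Subtracts the gray image from its background estimate
#' (`background - gray`).  The sign is chosen so that vessels -- dark in the
#' green channel -- come out *bright* (positive) in the normalized image.
#' Values may be negative; the FOV is propagated.
#'
#' @param gray A [gray_image()] or matrix.
#' @param background Background estimate of identical shape, e.g. from
#'   [estimate_background()].
#' @return A [gray_image()] of normalized values.
#' @export
normalize_image <- function(gray, background) {
  gray <- as_gray(gray)
  background <- as_gray(background)
  if (!identical(dim(gray$values), dim(background$values)))
    stop("gray and background shapes differ")
  gray_image(background$values - gray$values, fov = gray$fov)
}

#' Adaptive local thresholding
#'
#' A pixel is set when its normalized value exceeds the local mean over an
#' odd square window by more than `offset`.  Pixels outside the FOV are
#' always `FALSE`.  Raising `offset` can only switch pixels off, never on.
#'
#' @param norm Normalized image ([gray_image()] or matrix), vessels bright.
#' @param window Odd window size in pixels.
#' @param offset Scalar threshold offset on the \[0,1\] intensity scale.
#' @return Logical matrix (binary retinal image).
#' @export
adaptive_threshold <- function(norm, window = 25L, offset = 0.022) {
  norm <- as_gray(norm)
  window <- as.integer(window)
  if (window %% 2L != 1L || window < 3L)
    stop("window must be odd and >= 3, got ", window)
  if (!is.finite(offset)) stop("offset must be finite")
  local_mean <- box_mean(norm$values, window)
  out <- norm$values > local_mean + offset
  out & fov_or_true(norm)
}
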