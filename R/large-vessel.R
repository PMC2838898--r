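## Large-vessel extraction: area filtering of the binary image, erasure of
## optic-disc rim edges, and refinement by gradient extremum pairs.
##
## The key geometric fact: a dark vessel crossed by a horizontal or vertical
## profile produces a *pair* of gradient extrema -- a local minimum where the
## intensity drops into the vessel followed by a local maximum where it
## climbs out -- separated by at most the vessel width.  The optic-disc rim
## is a one-sided step and produces a single extremum, never a close pair.

#' Keep large connected components
#'
#' Retains exactly the 8-connected components of the binary image whose
#' pixel count is strictly greater than the minimum grain size `T`.
#'
#' @param binary Logical matrix.
#' @param T Minimum grain size in pixels (components with area `> T` are
#'   kept; default 100).
#' @return Logical matrix containing only the surviving components.
#' @export
filter_components <- function(binary, T = 100L) {
  assert_binary_map(binary)
  T <- as.integer(T)
  if (T < 1L) stop("T must be >= 1")
  lab <- cpp_label_components(binary)
  if (max(lab) == 0L) return(binary & FALSE)
  areas <- tabulate(lab, nbins = max(lab))
  keep <- which(areas > T)
  matrix(lab %in% keep, nrow(binary), ncol(binary))
}

#' Sobel gradients
#'
#' Convolves the image with the standard 3 x 3 Sobel kernels, reflect-padded.
#' `gx` responds to intensity increasing with column (horizontal direction),
#' `gy` to intensity increasing with row.
#'
#' @param gray A [gray_image()] or matrix, at least 3 x 3.
#' @return An object of class `gradient_field` with matrices `gx`, `gy`.
#' @export
sobel_gradients <- function(gray) {
  gray <- as_gray(gray)
  v <- gray$values
  if (nrow(v) < 3L || ncol(v) < 3L) stop("image must be at least 3 x 3")
  smooth <- c(1, 2, 1)
  diffk <- c(-1, 0, 1)
  gx <- filter1(filter1(v, smooth, 2L, margin = 1L), diffk, 2L, margin = 2L)
  gy <- filter1(filter1(v, smooth, 2L, margin = 2L), diffk, 2L, margin = 1L)
  structure(list(gx = gx, gy = gy), class = "gradient_field")
}

#' Locate the optic disc
#'
#' The optic disc is the brightest region of the fundus.  The image is
#' Gaussian-smoothed (sigma 8 px) and the disc center is the
#' intensity-weighted centroid of the top 1 percent brightest FOV pixels of
#' the smoothed copy.  The radius is a configured constant (40 px at DRIVE
#' width, rescaled to the image width) -- localization only, not
#' segmentation.
#'
#' @param gray A [gray_image()] or matrix.
#' @param radius Disc radius in px; `NULL` uses `40/565 * ncol`.
#' @param smooth_sigma Smoothing scale in px.
#' @return An object of class `optic_disc`: list with `center` (row, col)
#'   and `radius`.
#' @export
locate_optic_disc <- function(gray, radius = NULL, smooth_sigma = 8) {
  gray <- as_gray(gray)
  fov <- fov_or_true(gray)
  if (!any(fov)) stop("degenerate FOV: no pixels inside")
  sm <- gaussian_filter(gray$values, smooth_sigma)
  vals <- sm[fov]
  thr <- stats::quantile(vals, 0.99, names = FALSE)
  sel <- fov & sm >= thr
  w <- sm[sel]
  if (all(w <= 0)) w <- rep(1, length(w))  # degenerate all-dark image
  idx <- which(sel, arr.ind = TRUE)
  center <- c(sum(idx[, 1L] * w), sum(idx[, 2L] * w)) / sum(w)
  if (is.null(radius)) radius <- 40 / 565 * ncol(gray$values)
  structure(list(center = center, radius = radius), class = "optic_disc")
}

## ---- gradient extremum pairs -------------------------------------------

# Strict local extrema of a 1-D profile (indices 2..n-1).
local_extrema <- function(v) {
  n <- length(v)
  if (n < 3L) return(list(minima = integer(0), maxima = integer(0)))
  i <- 2:(n - 1L)
  list(minima = i[v[i] < v[i - 1L] & v[i] < v[i + 1L]],
       maxima = i[v[i] > v[i - 1L] & v[i] > v[i + 1L]])
}

# Mark the runs of a 1-D gradient profile bounded by a local minimum
# followed by a local maximum within max_width, provided the run overlaps
# a candidate pixel.  (Dark bar on bright background: the scan gradient
# dips entering the bar and peaks leaving it; a bright structure gives the
# opposite order and is never marked.)
mark_pair_runs <- function(grad_profile, cand_profile, max_width) {
  out <- logical(length(grad_profile))
  ex <- local_extrema(grad_profile)
  if (!length(ex$minima) || !length(ex$maxima)) return(out)
  pos <- sort(c(ex$minima, ex$maxima))
  type <- ifelse(pos %in% ex$minima, "min", "max")
  for (t in seq_len(length(pos) - 1L)) {
    if (type[t] == "min" && type[t + 1L] == "max") {
      i <- pos[t]; j <- pos[t + 1L]
      if (j - i <= max_width && any(cand_profile[i:j])) out[i:j] <- TRUE
    }
  }
  out
}

# Row-wise and column-wise pair-run marks over the whole image.  Profiles
# are the gradient component along the scan direction, smoothed (sigma 2)
# along that direction: wide vessels have a near-flat gradient plateau
# between their edge extrema, and weaker smoothing lets noise spawn
# spurious extrema there that break the min/max pairing.
pair_run_marks <- function(candidates, grad, max_width) {
  k <- gaussian_kernel(2)
  gxs <- filter1(grad$gx, k, (length(k) + 1L) %/% 2L, margin = 2L)
  gys <- filter1(grad$gy, k, (length(k) + 1L) %/% 2L, margin = 1L)
  rows <- matrix(FALSE, nrow(gxs), ncol(gxs))
  cols <- rows
  for (i in seq_len(nrow(gxs)))
    rows[i, ] <- mark_pair_runs(gxs[i, ], candidates[i, ], max_width)
  for (j in seq_len(ncol(gys)))
    cols[, j] <- mark_pair_runs(gys[, j], candidates[, j], max_width)
  list(rows = rows, cols = cols)
}

#' Erase optic-disc rim edges from the candidate map
#'
#' Inside the disc neighborhood (a square of side four disc radii), a
#' candidate pixel survives only if a horizontal or vertical gradient
#' profile through it places it between a local gradient minimum and the
#' following local maximum within the maximum vessel width -- the two-sided
#' signature of a dark vessel.  One-sided rim edges fail this test.  All
#' surviving components touching the neighborhood with area below `T/2` are
#' then removed.  Pixels outside the neighborhood are untouched.
#'
#' @param candidates Logical matrix of large-vessel candidates.
#' @param grad [sobel_gradients()] of the gray image.
#' @param disc [locate_optic_disc()] result.
#' @param T Minimum grain size (the small-object cutoff is `T/2`).
#' @param max_width Maximum vessel width in px.
#' @return Logical matrix.
#' @export
erase_disc_edges <- function(candidates, grad, disc, T = 100L, max_width = 18L) {
  assert_binary_map(candidates)
  nr <- nrow(candidates); nc <- ncol(candidates)
  r0 <- max(1L, floor(disc$center[1L] - 2 * disc$radius))
  r1 <- min(nr, ceiling(disc$center[1L] + 2 * disc$radius))
  c0 <- max(1L, floor(disc$center[2L] - 2 * disc$radius))
  c1 <- min(nc, ceiling(disc$center[2L] + 2 * disc$radius))
  inside <- matrix(FALSE, nr, nc)
  inside[r0:r1, c0:c1] <- TRUE
  if (!any(candidates & inside)) return(candidates)
  marks <- pair_run_marks(candidates, grad, max_width)
  out <- candidates
  out[inside] <- candidates[inside] & (marks$rows | marks$cols)[inside]
  # remove small surviving objects near the disc
  lab <- cpp_label_components(out)
  if (max(lab) > 0L) {
    areas <- tabulate(lab, nbins = max(lab))
    near <- unique(lab[inside & lab > 0L])
    drop <- near[areas[near] < T / 2]
    if (length(drop)) out[lab %in% drop] <- FALSE
  }
  out
}

#' Refine large vessels by gradient extremum pairs
#'
#' For every row and every column, the gradient profile is scanned for a
#' local minimum followed by a local maximum within `max_width` pixels,
#' the two-sided signature of a dark vessel; the pixel run between such a
#' pair is kept and filled whenever it overlaps a candidate pixel, which
#' fills interior holes the threshold missed.  Pixels outside every
#' extremum pair are excluded.  The result is the union of the row-wise
#' and column-wise runs; every kept pixel lies in a run shared with a
#' candidate pixel, hence within `max_width` of one.
#'
#' @param candidates Logical matrix of large-vessel candidates.
#' @param grad [sobel_gradients()] of the gray image.
#' @param max_width Maximum vessel width in px (>= 2).
#' @return Logical matrix: the refined large-vessel mask.
#' @export
refine_by_gradient_pairs <- function(candidates, grad, max_width = 18L) {
  assert_binary_map(candidates)
  if (max_width < 2L) stop("max_width must be >= 2")
  if (!any(candidates)) return(candidates)
  marks <- pair_run_marks(candidates, grad, max_width)
  marks$rows | marks$cols
}

#' Residual fragments
#'
#' Binary-image pixels not claimed by the large-vessel mask: thin-vessel
#' segments mixed with noise, to be separated by the classifier.
#'
#' @param binary Binary retinal image (logical matrix).
#' @param large Large-vessel mask of the same shape.
#' @return Logical matrix `binary & !large`.
#' @export
residual_fragments <- function(binary, large) {
  assert_binary_map(binary)
  assert_binary_map(large)
  if (!identical(dim(binary), dim(large))) stop("shape mismatch")
  binary & !large
}
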