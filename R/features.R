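## Per-pixel features for residual-fragment classification: oriented line
## detectors applied to the gray image and to two edge-modulus images
## (undecimated Haar wavelet, curvelet-style FFT wedge bank), yielding a
## 12-dimensional vector per pixel, min-max scaled to [-1, 1].

#' Build an oriented line-detector bank
#'
#' Constructs `n` symmetric digital lines of odd length `l` through the
#' origin at equally spaced angles `k * 180 / n` degrees (the default 8
#' orientations give 22.5 degree angular resolution).  Each line is sampled
#' at `l` integer offsets by stepping along its dominant axis and rounding
#' the other coordinate, so every detector contains the center pixel.
#'
#' @param l Odd line length in pixels, >= 3.
#' @param n Number of orientations, >= 2.
#' @return Object of class `line_detector_bank`: list with `length_l`, `n`,
#'   `offsets` (list of `l` x 2 integer matrices of (dr, dc) offsets) and
#'   `directions` (`n` x 2 matrix of unit (dr, dc) vectors).
#' @export
build_line_detectors <- function(l = 15L, n = 8L) {
  l <- as.integer(l); n <- as.integer(n)
  if (l %% 2L != 1L || l < 3L) stop("l must be odd and >= 3")
  if (n < 2L) stop("n must be >= 2")
  h <- (l - 1L) %/% 2L
  rnd <- function(x) as.integer(trunc(x + 0.5 * sign(x)))  # half away from 0
  offsets <- vector("list", n)
  directions <- matrix(0, n, 2L)
  for (k in seq_len(n)) {
    theta <- (k - 1L) * pi / n
    dr_unit <- sin(theta); dc_unit <- cos(theta)
    directions[k, ] <- c(dr_unit, dc_unit)
    t <- (-h):h
    if (abs(dc_unit) >= abs(dr_unit)) {   # shallow: step along columns
      dc <- t
      dr <- rnd(t * dr_unit / dc_unit)
    } else {                              # steep: step along rows
      dr <- t
      dc <- rnd(t * dc_unit / dr_unit)
    }
    offsets[[k]] <- cbind(dr = dr, dc = dc)
  }
  structure(list(length_l = l, n = n, offsets = offsets,
                 directions = directions),
            class = "line_detector_bank")
}

# Mean and population SD along every detector line for a batch of pixels.
# Off-image samples are reflect-padded.  Returns N x n matrices.
line_stats <- function(values, pixels, bank) {
  pixels <- matrix(as.integer(pixels), ncol = 2L)
  nr <- nrow(values); nc <- ncol(values)
  if (any(pixels[, 1L] < 1L | pixels[, 1L] > nr |
          pixels[, 2L] < 1L | pixels[, 2L] > nc))
    stop("pixel outside image")
  np <- nrow(pixels); n <- bank$n; l <- bank$length_l
  means <- matrix(0, np, n); sds <- matrix(0, np, n)
  for (k in seq_len(n)) {
    off <- bank$offsets[[k]]
    s <- numeric(np); s2 <- numeric(np)
    for (t in seq_len(l)) {
      rr <- reflect_index(pixels[, 1L] + off[t, 1L], nr)
      cc <- reflect_index(pixels[, 2L] + off[t, 2L], nc)
      v <- values[cbind(rr, cc)]
      s <- s + v; s2 <- s2 + v * v
    }
    m <- s / l
    means[, k] <- m
    sds[, k] <- sqrt(pmax(0, s2 / l - m * m))
  }
  list(means = means, sds = sds)
}

#' Orientation statistics at a pixel
#'
#' Evaluates the mean and population standard deviation of intensity along
#' each detector line through the pixel.  The best-aligned direction `D1`
#' is the one with the smallest mean (a dark vessel along the line keeps
#' the profile uniformly dark); `D2` has the largest mean.  Ties go to the
#' lower orientation index.
#'
#' @param img A [gray_image()] or matrix.
#' @param pixel Integer (row, col), inside the image; off-image line
#'   samples are reflect-padded.
#' @param bank A [build_line_detectors()] bank.
#' @return Object of class `orientation_stats`: list with `means`, `sds`
#'   (length-`n` vectors), `d1_index`, `d2_index`.
#' @export
orientation_stats <- function(img, pixel, bank) {
  img <- as_gray(img)
  st <- line_stats(img$values, matrix(pixel, 1L), bank)
  means <- st$means[1L, ]; sds <- st$sds[1L, ]
  structure(list(means = means, sds = sds,
                 d1_index = which.min(means),
                 d2_index = which.max(means)),
            class = "orientation_stats")
}

#' Undecimated Haar wavelet modulus
#'
#' One-level undecimated (a-trous) Haar decomposition: the horizontal and
#' vertical detail sub-images are computed by the 2-tap difference filter
#' `(x[i+1] - x[i]) / 2` along one axis combined with the 2-tap average
#' along the other, reflect-padded, with no downsampling so the sub-images
#' keep the input shape.  The modulus is `sqrt(Wh^2 + Wv^2)` pixelwise;
#' it is large along edges, e.g. vessel boundaries.
#'
#' @param gray A [gray_image()] or matrix.
#' @return A [gray_image()] holding the modulus.
#' @export
wavelet_modulus <- function(gray) {
  gray <- as_gray(gray)
  v <- gray$values
  lo <- c(0.5, 0.5); hi <- c(-0.5, 0.5)  # taps at offsets 0, +1
  wv <- filter1(filter1(v, hi, 1L, margin = 2L), lo, 1L, margin = 1L)
  wh <- filter1(filter1(v, hi, 1L, margin = 1L), lo, 1L, margin = 2L)
  gray_image(sqrt(wh^2 + wv^2), fov = gray$fov)
}

## ---- curvelet-style FFT wedge bank -------------------------------------

# Frequency coordinates of an n-point FFT, as fractions of the sampling
# rate, in FFT order.
fft_freqs <- function(n) {
  f <- 0:(n - 1L)
  f[f > n / 2] <- f[f > n / 2] - n
  f / n
}

# Smooth frequency-domain windows: one coarse radial window plus n_angles
# overlapping angular wedges on the detail band, forming a partition of
# unity (coarse + sum of wedges == 1 at every frequency).
curvelet_windows <- function(nr, nc, n_angles = 8L) {
  fr <- matrix(fft_freqs(nr), nr, nc)
  fc <- matrix(fft_freqs(nc), nr, nc, byrow = TRUE)
  rho <- sqrt(fr^2 + fc^2)
  # radial split: detail band ramps on over [1/16, 1/8] of the sampling rate
  s <- pmin(pmax((rho - 1 / 16) / (1 / 8 - 1 / 16), 0), 1)
  detail <- sin(pi / 2 * s)^2
  phi <- atan2(fr, fc) %% pi       # orientation is defined modulo 180 deg
  delta <- pi / n_angles
  wedges <- vector("list", n_angles)
  for (i in seq_len(n_angles)) {
    theta_i <- (i - 1L) * delta
    d <- abs((phi - theta_i + pi / 2) %% pi - pi / 2)  # circular distance
    a <- ifelse(d < delta, 0.5 * (1 + cos(pi * d / delta)), 0)
    wedges[[i]] <- detail * a
  }
  list(coarse = 1 - detail, wedges = wedges)
}

#' Curvelet-style decomposition into coarse and directional detail blocks
#'
#' Decomposes the image in the FFT domain at two scales -- one coarse
#' (low-pass) subband and one detail scale split into eight overlapping
#' angular wedges -- and reconstructs one image per detail block.  The
#' windows form a partition of unity, so the coarse reconstruction plus the
#' eight detail reconstructions reproduce the input.  Images smaller than
#' 32 x 32 are reflect-padded to that working size and the reconstructions
#' cropped back.
#'
#' @param gray A [gray_image()] or matrix.
#' @param n_angles Number of angular wedges at the detail scale.
#' @return List with `coarse` (matrix) and `details` (list of `n_angles`
#'   matrices), all of the input shape.
#' @export
curvelet_decompose <- function(gray, n_angles = 8L) {
  gray <- as_gray(gray)
  v <- gray$values
  nr0 <- nrow(v); nc0 <- ncol(v)
  # reflect-pad small images to the minimum working size
  pad_to <- function(m, n) {
    while (nrow(m) < n) {
      add <- min(nrow(m), n - nrow(m))
      m <- rbind(m, m[nrow(m):(nrow(m) - add + 1L), , drop = FALSE])
    }
    while (ncol(m) < n) {
      add <- min(ncol(m), n - ncol(m))
      m <- cbind(m, m[, ncol(m):(ncol(m) - add + 1L), drop = FALSE])
    }
    m
  }
  v <- pad_to(v, 32L)
  nr <- nrow(v); nc <- ncol(v)
  win <- curvelet_windows(nr, nc, n_angles)
  f <- stats::fft(v)
  inv <- function(fm) Re(stats::fft(fm, inverse = TRUE)) / (nr * nc)
  coarse <- inv(f * win$coarse)[seq_len(nr0), seq_len(nc0), drop = FALSE]
  details <- lapply(win$wedges, function(w)
    inv(f * w)[seq_len(nr0), seq_len(nc0), drop = FALSE])
  list(coarse = coarse, details = details)
}

#' Curvelet modulus image
#'
#' Root-sum-square over the eight directional detail reconstructions of
#' [curvelet_decompose()].  Like the wavelet modulus it peaks along edges,
#' but with directional frequency resolution that favors elongated
#' (curvilinear) structures.
#'
#' @param gray A [gray_image()] or matrix.
#' @param n_angles Number of angular wedges.
#' @return A [gray_image()] holding the modulus.
#' @export
curvelet_modulus <- function(gray, n_angles = 8L) {
  gray <- as_gray(gray)
  dec <- curvelet_decompose(gray, n_angles)
  m <- Reduce(`+`, lapply(dec$details, function(d) d^2))
  gray_image(sqrt(m), fov = gray$fov)
}

## ---- the 12-dimensional feature vector ---------------------------------

feature_names <- c("Mg1", "SDg1", "Dm_g", "Dsd_g",
                   "MW1", "SDW1", "Dm_W", "Dsd_W",
                   "MC1", "SDC1", "Dm_C", "Dsd_C")

#' Per-pixel feature matrix for a batch of pixels
#'
#' For each pixel, the aligned direction `D1` (minimum line mean) and the
#' orthogonal-most direction `D2` (maximum line mean) are determined once on
#' the gray image and reused on the wavelet and curvelet modulus images.
#' The 12 features are, for each of the three images: the mean and SD along
#' `D1` and the absolute differences of mean and SD between `D2` and `D1`.
#' For a thin-vessel pixel the along-vessel line is uniform while the
#' across-vessel line mixes vessel and background, so the difference
#' features are large; for noise they are small.
#'
#' @param gray,mw,mc Aligned [gray_image()]s (gray, wavelet modulus,
#'   curvelet modulus).
#' @param pixels Integer matrix (N x 2) of (row, col) pixel coordinates.
#' @param bank A [build_line_detectors()] bank.
#' @return Numeric `N x 12` matrix with columns
#'   `Mg1, SDg1, Dm_g, Dsd_g, MW1, SDW1, Dm_W, Dsd_W, MC1, SDC1, Dm_C,
#'   Dsd_C`.
#' @export
pixel_features_matrix <- function(gray, mw, mc, pixels, bank) {
  gray <- as_gray(gray); mw <- as_gray(mw); mc <- as_gray(mc)
  stopifnot(identical(dim(gray$values), dim(mw$values)),
            identical(dim(gray$values), dim(mc$values)))
  pixels <- matrix(as.integer(pixels), ncol = 2L)
  np <- nrow(pixels)
  gs <- line_stats(gray$values, pixels, bank)
  ws <- line_stats(mw$values, pixels, bank)
  cs <- line_stats(mc$values, pixels, bank)
  d1 <- max.col(-gs$means, ties.method = "first")
  d2 <- max.col(gs$means, ties.method = "first")
  i1 <- cbind(seq_len(np), d1); i2 <- cbind(seq_len(np), d2)
  out <- cbind(
    gs$means[i1], gs$sds[i1],
    abs(gs$means[i2] - gs$means[i1]), abs(gs$sds[i2] - gs$sds[i1]),
    ws$means[i1], ws$sds[i1],
    abs(ws$means[i2] - ws$means[i1]), abs(ws$sds[i2] - ws$sds[i1]),
    cs$means[i1], cs$sds[i1],
    abs(cs$means[i2] - cs$means[i1]), abs(cs$sds[i2] - cs$sds[i1]))
  colnames(out) <- feature_names
  out
}

#' Feature vector of a single residual pixel
#'
#' @inheritParams pixel_features_matrix
#' @param pixel Integer (row, col).
#' @return Named numeric vector of length 12.
#' @export
pixel_features <- function(gray, mw, mc, pixel, bank) {
  drop(pixel_features_matrix(gray, mw, mc, matrix(pixel, 1L), bank))
}

#' Fit the min-max feature scaler
#'
#' Stores per-feature training minima and maxima.  A constant feature
#' (max == min) is flagged degenerate and maps to 0 for every input.
#'
#' @param features Numeric matrix of training feature rows (>= 2 rows).
#' @return Object of class `feature_scaler`.
#' @export
fit_scaler <- function(features) {
  features <- as.matrix(features)
  if (nrow(features) < 2L) stop("need at least 2 training rows")
  structure(list(mins = apply(features, 2L, min),
                 maxs = apply(features, 2L, max)),
            class = "feature_scaler")
}

#' Apply the min-max scaler
#'
#' Maps each feature linearly so the training extrema land on -1 and +1:
#' `x = 2 * (x_ori - x_min) / (x_max - x_min) - 1`.  Unseen rows may fall
#' outside `[-1, 1]` and are clipped to `[-1.5, 1.5]`; degenerate features
#' map to 0.
#'
#' @param scaler A [fit_scaler()] result.
#' @param features Numeric matrix (or single row vector) of raw features.
#' @return Scaled matrix (or vector) of the input shape.
#' @export
apply_scaler <- function(scaler, features) {
  stopifnot(inherits(scaler, "feature_scaler"))
  vec <- is.null(dim(features))
  x <- if (vec) matrix(features, 1L) else as.matrix(features)
  rng <- scaler$maxs - scaler$mins
  out <- matrix(0, nrow(x), ncol(x), dimnames = dimnames(x))
  for (j in seq_len(ncol(x))) {
    if (rng[j] > 0)
      out[, j] <- 2 * (x[, j] - scaler$mins[j]) / rng[j] - 1
  }
  out <- pmin(pmax(out, -1.5), 1.5)
  if (vec) drop(out) else out
}
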