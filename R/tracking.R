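## Tracking growth of thin vessels: classified segments are extended from
## their endpoints, stepping along a blend of the line-detector direction
## D1 and the Hessian ridge direction, while the Hessian eigenvalues keep
## certifying "this still looks like a dark vessel".

#' Gaussian-derivative Hessian field
#'
#' Computes the second-derivative matrix entries `f_xx`, `f_xy`, `f_yy` of
#' the gray image by convolution with second-order Gaussian derivative
#' kernels at scale `sigma_h`, then the per-pixel eigen-decomposition of
#' the symmetric 2 x 2 Hessian with `lambda1 >= lambda2`.  On an image
#' where vessels are darker than the background, a vessel pixel has
#' `lambda1 >> 0` (strong upward curvature across the vessel) and
#' `lambda2 ~ 0` (flat along it); the `lambda1` eigenvector points across
#' the vessel.
#'
#' @param gray A [gray_image()] or matrix (green channel: vessels dark).
#' @param sigma_h Gaussian scale in px, > 0.
#' @return Object of class `hessian_field`: matrices `lambda1`, `lambda2`,
#'   `ev1r`, `ev1c` (unit eigenvector of `lambda1`, (row, col) components)
#'   and `sigma_h`.
#' @export
hessian_field <- function(gray, sigma_h = 1.5) {
  gray <- as_gray(gray)
  if (sigma_h <= 0) stop("sigma_h must be > 0")
  v <- gray$values
  # x = column axis, y = row axis
  fxx <- gaussian_filter(v, sigma_h, order = c(0L, 2L))
  fyy <- gaussian_filter(v, sigma_h, order = c(2L, 0L))
  fxy <- gaussian_filter(v, sigma_h, order = c(1L, 1L))
  tr <- fxx + fyy
  disc <- sqrt(pmax(0, (fxx - fyy)^2 + 4 * fxy^2))
  l1 <- (tr + disc) / 2
  l2 <- (tr - disc) / 2
  # eigenvector for lambda1: (H - l2 I) column of larger norm, in (x, y)
  vx1 <- fxy;        vy1 <- l1 - fxx
  vx2 <- l1 - fyy;   vy2 <- fxy
  use2 <- (vx2^2 + vy2^2) > (vx1^2 + vy1^2)
  vx <- ifelse(use2, vx2, vx1)
  vy <- ifelse(use2, vy2, vy1)
  nrm <- sqrt(vx^2 + vy^2)
  degen <- nrm < 1e-12          # isotropic point: pick an arbitrary axis
  vx <- ifelse(degen, 1, vx / pmax(nrm, 1e-12))
  vy <- ifelse(degen, 0, vy / pmax(nrm, 1e-12))
  structure(list(lambda1 = l1, lambda2 = l2, ev1r = vy, ev1c = vx,
                 sigma_h = sigma_h),
            class = "hessian_field")
}

# Bilinear interpolation of a matrix at continuous 1-based (row, col).
bilinear_at <- function(m, p) {
  r <- p[1L]; c <- p[2L]
  r0 <- floor(r); c0 <- floor(c)
  r0 <- min(max(r0, 1), nrow(m) - 1L); c0 <- min(max(c0, 1), ncol(m) - 1L)
  fr <- r - r0; fc <- c - c0
  m[r0, c0] * (1 - fr) * (1 - fc) + m[r0 + 1L, c0] * fr * (1 - fc) +
    m[r0, c0 + 1L] * (1 - fr) * fc + m[r0 + 1L, c0 + 1L] * fr * fc
}

#' Hessian vesselness gate
#'
#' `TRUE` iff `lambda1(p) > lambda1_min` and `|lambda2(p)| < lambda2_max`,
#' with bilinear interpolation at non-integer positions.  A point outside
#' the image is `FALSE` (growth stops there; it is not an error).
#'
#' @param h A [hessian_field()].
#' @param p Continuous (row, col) position, 1-based.
#' @param lambda1_min,lambda2_max Eigenvalue gates.
#' @return Logical scalar.
#' @export
is_vessel_point <- function(h, p, lambda1_min, lambda2_max) {
  stopifnot(inherits(h, "hessian_field"))
  if (p[1L] < 1 || p[2L] < 1 ||
      p[1L] > nrow(h$lambda1) || p[2L] > ncol(h$lambda1)) return(FALSE)
  l1 <- bilinear_at(h$lambda1, p)
  l2 <- bilinear_at(h$lambda2, p)
  isTRUE(l1 > lambda1_min && abs(l2) < lambda2_max)
}

# 8-neighbor count of set pixels, per pixel (zero-padded at borders).
neighbor_count <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  padded <- matrix(0L, nr + 2L, nc + 2L)
  padded[2:(nr + 1L), 2:(nc + 1L)] <- mask * 1L
  cnt <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    cnt <- cnt + padded[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
  }
  cnt
}

#' Find segment endpoints and their outgoing directions
#'
#' Endpoints are segment pixels with exactly one 8-neighbor in the segment;
#' an isolated pixel yields two endpoint records with opposite directions.
#' The outgoing direction is the line-detector `D1` direction at the pixel
#' (evaluated on the gray image), with its sign chosen to point away from
#' the segment body.
#'
#' @param segments Logical matrix of thin-vessel segments.
#' @param gray A [gray_image()] or matrix used to evaluate `D1`.
#' @param bank A [build_line_detectors()] bank.
#' @return List of endpoint records, each a list with `position` (row, col)
#'   and `direction` (unit (dr, dc)).
#' @export
find_endpoints <- function(segments, gray, bank = build_line_detectors()) {
  assert_binary_map(segments)
  gray <- as_gray(gray)
  cnt <- neighbor_count(segments)
  out <- list()
  add <- function(pos, dir) {
    out[[length(out) + 1L]] <<- list(position = pos, direction = dir)
  }
  ends <- which(segments & (cnt == 1L | cnt == 0L), arr.ind = TRUE)
  if (nrow(ends) == 0L) return(out)
  st <- line_stats(gray$values, ends, bank)
  d1 <- max.col(-st$means, ties.method = "first")
  nr <- nrow(segments); nc <- ncol(segments)
  for (k in seq_len(nrow(ends))) {
    pos <- as.numeric(ends[k, ])
    u <- bank$directions[d1[k], ]
    if (cnt[ends[k, 1L], ends[k, 2L]] == 0L) {
      add(pos, u); add(pos, -u)
    } else {
      # the single neighbor marks the body side
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        r <- ends[k, 1L] + dr; c <- ends[k, 2L] + dc
        if (r >= 1L && c >= 1L && r <= nr && c <= nc && segments[r, c]) {
          away <- c(-dr, -dc)
          s <- sum(u * away)
          add(pos, if (s >= 0) u else -u)
        }
      }
    }
  }
  out
}

#' Grow a path from one endpoint
#'
#' Repeatedly steps from the current position along the unit average of the
#' local `D1` direction (re-evaluated at the nearest pixel, sign-aligned
#' with the travel direction) and the Hessian ridge direction (the
#' `lambda2` eigenvector, i.e. along the vessel, likewise sign-aligned).
#' Each candidate point is re-centered onto the ridge -- shifted along the
#' across-vessel eigenvector to the position of maximal interpolated
#' `lambda1` -- before the [is_vessel_point()] gate is tested; without this
#' a one-pixel step on a one-to-two-pixel-wide faint ridge drifts off the
#' centerline and the gate fails prematurely.  Accepted points are
#' rasterized with their local cross-section: the two neighbors one pixel
#' across the vessel are included when they pass the gate themselves, so a
#' grown path covers the width of the vessel, not just its centerline.
#' Growth stops when the (re-centered) candidate fails the gate, after
#' `max_steps` steps, or when the path would revisit a pixel.
#'
#' @param start Endpoint record (list with `position`, `direction`).
#' @param gray A [gray_image()] or matrix.
#' @param h A [hessian_field()] of that image.
#' @param bank Line-detector bank.
#' @param step Step length in px, > 0.
#' @param max_steps Maximum number of growth steps.
#' @param lambda1_min,lambda2_max Vesselness gates.
#' @param direction_weight Weight of `D1` in the direction blend (in
#'   \[0, 1\]; the Hessian ridge direction gets the complement).
#' @return Integer matrix (n x 2) of visited (row, col) pixels; zero rows
#'   when the first candidate already fails the gate.
#' @export
grow_from_endpoint <- function(start, gray, h, bank = build_line_detectors(),
                               step = 1, max_steps = 200L,
                               lambda1_min, lambda2_max,
                               direction_weight = 0.5) {
  gray <- as_gray(gray)
  if (step <= 0) stop("step must be > 0")
  nr <- nrow(gray$values); nc <- ncol(gray$values)
  inside <- function(rc) rc[1L] >= 1L && rc[2L] >= 1L && rc[1L] <= nr && rc[2L] <= nc
  pos <- as.numeric(start$position)
  travel <- as.numeric(start$direction)
  visited <- matrix(integer(0), 0L, 2L)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  key <- function(rc) paste(rc[1L], rc[2L])
  assign(key(round(pos)), TRUE, envir = seen)
  steps <- 0L
  while (steps < max_steps) {
    px <- pmin(pmax(round(pos), 1L), c(nr, nc))
    st <- line_stats(gray$values, matrix(px, 1L), bank)
    u <- bank$directions[which.min(st$means[1L, ]), ]
    if (sum(u * travel) < 0) u <- -u
    ridge <- c(-h$ev1c[px[1L], px[2L]], h$ev1r[px[1L], px[2L]])  # along vessel
    if (sum(ridge * travel) < 0) ridge <- -ridge
    d <- direction_weight * u + (1 - direction_weight) * ridge
    nd <- sqrt(sum(d^2))
    if (nd < 1e-9) d <- travel else d <- d / nd
    nxt <- pos + step * d
    # re-center across the vessel onto the lambda1 ridge crest
    ev <- c(h$ev1r[px[1L], px[2L]], h$ev1c[px[1L], px[2L]])
    cand <- lapply(c(0, -0.5, 0.5, -1, 1), function(dl) nxt + dl * ev)
    cand <- Filter(function(p) p[1L] >= 1 && p[2L] >= 1 &&
                     p[1L] <= nr && p[2L] <= nc, cand)
    if (!length(cand)) break
    l1s <- vapply(cand, function(p) bilinear_at(h$lambda1, p), numeric(1L))
    nxt <- cand[[which.max(l1s)]]
    if (!is_vessel_point(h, nxt, lambda1_min, lambda2_max)) break
    rc <- as.integer(round(nxt))
    if (!inside(rc)) break
    k <- key(rc)
    if (!is.null(seen[[k]])) break
    assign(k, TRUE, envir = seen)
    visited <- rbind(visited, rc)
    # cross-section rasterization: include gate-passing across neighbors
    ev_rc <- c(h$ev1r[rc[1L], rc[2L]], h$ev1c[rc[1L], rc[2L]])
    for (dl in c(-1, 1)) {
      q <- nxt + dl * ev_rc
      if (is_vessel_point(h, q, lambda1_min, lambda2_max)) {
        qc <- as.integer(round(q))
        if (inside(qc) && is.null(seen[[key(qc)]])) {
          assign(key(qc), TRUE, envir = seen)
          visited <- rbind(visited, qc)
        }
      }
    }
    travel <- (nxt - pos) / sqrt(sum((nxt - pos)^2))
    pos <- nxt
    steps <- steps + 1L
  }
  visited
}

#' Track-grow all thin-vessel segments
#'
#' Unions the classified segments with the paths grown from every segment
#' endpoint.  The eigenvalue gates default to segment-adaptive values:
#' `lambda1_min` is 15 percent of the 99th percentile of `lambda1` over the
#' segment pixels and `lambda2_max` is twice `lambda1_min`.  Tying the
#' gates to the segments' own eigenvalue distribution keeps them on the
#' image's contrast scale; the fractions are deliberately permissive
#' because growth exists to follow vessels *fainter* than the classified
#' segments, while the `lambda1` floor still rejects flat background.
#'
#' @param segments Logical matrix of classified thin-vessel segments.
#' @param gray A [gray_image()] or matrix (green channel).
#' @param cfg A [pipeline_config()].
#' @return Logical matrix: segments plus grown pixels (always a superset of
#'   `segments`).
#' @export
track_all <- function(segments, gray, cfg = pipeline_config()) {
  assert_binary_map(segments)
  gray <- as_gray(gray)
  if (!any(segments)) return(segments)
  h <- hessian_field(gray, cfg$hessian_sigma)
  l1seg <- h$lambda1[segments]
  lambda1_min <- if (!is.null(cfg$lambda1_min)) cfg$lambda1_min else
    0.15 * stats::quantile(l1seg, 0.99, names = FALSE)
  lambda2_max <- if (!is.null(cfg$lambda2_max)) cfg$lambda2_max else
    2 * lambda1_min
  bank <- build_line_detectors(cfg$line_length_l, cfg$n_orientations)
  out <- segments
  for (ep in find_endpoints(segments, gray, bank)) {
    path <- grow_from_endpoint(ep, gray, h, bank,
                               step = cfg$step, max_steps = cfg$max_steps,
                               lambda1_min = lambda1_min,
                               lambda2_max = lambda2_max,
                               direction_weight = cfg$direction_weight)
    if (nrow(path)) out[path] <- TRUE
  }
  out
}
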