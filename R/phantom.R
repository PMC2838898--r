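## Synthetic fundus phantom generator.  Emulates the image features every
## pipeline stage relies on -- dark curvilinear vessels of two width classes
## rooted at a bright optic disc, radial illumination falloff, additive
## noise, a circular FOV -- with exact per-pixel ground truth, so the whole
## pipeline is testable without external image databases.

#' Phantom specification
#'
#' @param shape Integer (rows, cols) of the generated image.
#' @param n_large,n_thin Numbers of large and thin vessels.
#' @param width_large,width_thin Width ranges in px (large vessels default
#'   4--12 px; thin vessels 1--3 px, the class the classifier targets).
#' @param vessel_contrast Peak darkening of a vessel below its local
#'   background, on the \[0,1\] scale.
#' @param disc_center Optional (row, col) of the optic disc; `NULL` places
#'   it at a random angle just over half-way to the FOV rim.
#' @param disc_radius Optic-disc radius in px; `NULL` uses 7\% of the image
#'   width.
#' @param illum_falloff Relative brightness loss from image center to FOV
#'   rim (radial illumination model).
#' @param noise_sd Standard deviation of the additive Gaussian noise on the
#'   green channel (red/blue receive twice as much).
#' @param seed Integer seed; the phantom is a deterministic function of its
#'   spec.
#' @return List of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(192L, 192L),
                         n_large = 2L, n_thin = 8L,
                         width_large = c(4, 12), width_thin = c(1, 3),
                         vessel_contrast = 0.32,
                         disc_center = NULL, disc_radius = NULL,
                         illum_falloff = 0.3,
                         noise_sd = 0.015,
                         seed = 1L) {
  stopifnot(length(shape) == 2L, all(shape >= 48L),
            all(width_large > 0), all(width_thin > 0),
            max(width_thin) <= 3, noise_sd >= 0,
            vessel_contrast > 0, vessel_contrast < 1)
  structure(list(shape = as.integer(shape),
                 n_large = as.integer(n_large), n_thin = as.integer(n_thin),
                 width_large = width_large, width_thin = width_thin,
                 vessel_contrast = vessel_contrast,
                 disc_center = disc_center, disc_radius = disc_radius,
                 illum_falloff = illum_falloff, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Run body with the RNG seeded to `seed`, restoring the caller's RNG state.
with_seed <- function(seed, body) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  body()
}

# Smooth random-walk centerline: unit steps whose heading performs a
# bounded random walk (curvature-limited), stopped at the FOV margin.
walk_centerline <- function(start, angle0, n_steps, center, r_max,
                            turn_sd = 0.06, max_turn = 0.9) {
  pts <- matrix(0, n_steps + 1L, 2L)
  pts[1L, ] <- start
  ang <- angle0
  drift <- 0
  for (t in seq_len(n_steps)) {
    drift <- max(-max_turn, min(max_turn, drift + stats::rnorm(1L, 0, turn_sd)))
    ang_t <- angle0 + drift
    nxt <- pts[t, ] + c(sin(ang_t), cos(ang_t))
    if (sqrt(sum((nxt - center)^2)) > r_max) return(pts[seq_len(t), , drop = FALSE])
    pts[t + 1L, ] <- nxt
    angle0 <- angle0 + 0.02 * drift   # slow mean heading drift: gentle curves
  }
  pts
}

# Stamp a polyline with a circular brush into logical mask and intensity
# layer (layer keeps the per-pixel max of depth).  `width` may be a scalar
# or per-point vector, allowing vessels to narrow towards their tail.
stamp_vessel <- function(mask, layer, pts, width, depth) {
  nr <- nrow(mask); nc <- ncol(mask)
  width <- rep_len(width, nrow(pts))
  for (t in seq_len(nrow(pts))) {
    r_brush <- width[t] / 2
    ro <- (-ceiling(r_brush)):ceiling(r_brush)
    off <- expand.grid(dr = ro, dc = ro)
    off <- off[off$dr^2 + off$dc^2 <= r_brush^2, , drop = FALSE]
    rr <- round(pts[t, 1L]) + off$dr
    cc <- round(pts[t, 2L]) + off$dc
    ok <- rr >= 1L & cc >= 1L & rr <= nr & cc <= nc
    idx <- cbind(rr[ok], cc[ok])
    mask[idx] <- TRUE
    layer[idx] <- pmax(layer[idx], depth[t])
  }
  list(mask = mask, layer = layer)
}

#' Generate a synthetic fundus phantom
#'
#' Builds a deterministic (per seed) fundus-like image: a radially falling
#' background, a bright Gaussian optic-disc blob, large and thin vessels as
#' smooth random-walk polylines rooted at the disc and rasterized at their
#' widths, darker than the background by `vessel_contrast` and tapering
#' with distance from the disc (thin-vessel tails fade towards the noise
#' floor, which is what makes adaptive thresholding lose them and tracking
#' growth worthwhile), plus additive Gaussian noise and a circular FOV.
#' The red and blue channels carry an attenuated copy of the green signal
#' with extra noise.
#'
#' @param spec A [phantom_spec()].
#' @return Object of class `phantom`: list with `image` ([retinal_image()]
#'   with FOV attached), `truth`, `truth_large`, `truth_thin`, `fov`,
#'   `spec`.  `truth = truth_large | truth_thin` and the two are disjoint.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, function() {
    nr <- spec$shape[1L]; nc <- spec$shape[2L]
    center <- c((nr + 1) / 2, (nc + 1) / 2)
    r_fov <- 0.47 * min(nr, nc)
    rows <- matrix(seq_len(nr), nr, nc)
    cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    d2 <- ((rows - center[1L])^2 + (cols - center[2L])^2) / r_fov^2
    fov <- d2 <= 1
    bg <- 0.55 * (1 - spec$illum_falloff * pmin(d2, 1))
    # optic disc: bright Gaussian blob, vessels originate there
    disc_radius <- if (!is.null(spec$disc_radius)) spec$disc_radius else 0.07 * nc
    if (!is.null(spec$disc_center)) {
      disc_center <- spec$disc_center
    } else {
      ang <- stats::runif(1L, 0, 2 * pi)
      disc_center <- center + 0.55 * r_fov * c(sin(ang), cos(ang))
    }
    dd2 <- (rows - disc_center[1L])^2 + (cols - disc_center[2L])^2
    bump <- 0.30 * exp(-dd2 / (2 * (0.6 * disc_radius)^2))

    mask_large <- matrix(FALSE, nr, nc)
    mask_thin <- matrix(FALSE, nr, nc)
    layer <- matrix(0, nr, nc)
    large_lines <- list()
    n_steps_large <- round(2.2 * r_fov)
    # heading from the disc through the image center so large vessels cross
    # the whole FOV, fanned out per vessel
    ang_center <- atan2(center[1L] - disc_center[1L],
                        center[2L] - disc_center[2L])
    # widths stratified across the configured range (plus jitter) so every
    # phantom exercises both narrow and wide vessels of each class
    w_large <- sample(seq(spec$width_large[1L], spec$width_large[2L],
                          length.out = max(1L, spec$n_large))) +
      stats::runif(spec$n_large, -0.5, 0.5)
    w_thin <- sample(seq(spec$width_thin[1L], spec$width_thin[2L],
                         length.out = max(1L, spec$n_thin))) +
      stats::runif(spec$n_thin, -0.25, 0.25)
    for (i in seq_len(spec$n_large)) {
      fan <- (i - (spec$n_large + 1) / 2) * (1.6 / max(1L, spec$n_large))
      ang <- ang_center + fan + stats::runif(1L, -0.25, 0.25)
      # emerge from the disc rim, fanned, so vessels stay individually
      # resolvable near the disc instead of piling into one blob
      start <- disc_center + 0.8 * disc_radius * c(sin(ang), cos(ang))
      pts <- walk_centerline(start, ang, n_steps_large, center, r_fov - 2)
      if (nrow(pts) < 10L) next
      w <- max(spec$width_large[1L], w_large[i])
      # large vessels narrow and fade towards their distal end, as real
      # arterioles/venules do
      w <- w * seq(1, 0.6, length.out = nrow(pts))
      depth <- spec$vessel_contrast *
        seq(1, 0.65, length.out = nrow(pts))
      st <- stamp_vessel(mask_large, layer, pts, w, depth)
      mask_large <- st$mask; layer <- st$layer
      large_lines[[length(large_lines) + 1L]] <- pts
    }
    placed_thin <- 0L
    for (i in seq_len(spec$n_thin)) {
      if (length(large_lines)) {
        parent <- large_lines[[sample.int(length(large_lines), 1L)]]
        t0 <- max(2L, round(stats::runif(1L, 0.15, 0.7) * nrow(parent)))
        pang <- atan2(parent[t0, 1L] - parent[t0 - 1L, 1L],
                      parent[t0, 2L] - parent[t0 - 1L, 2L])
        ang <- pang + sample(c(-1, 1), 1L) * stats::runif(1L, 0.5, 1.1)
        # the junction itself is below vessel contrast in real fundus
        # images; start past the parent's edge so the faint branch does not
        # merge with the parent's binary component
        parent_w <- w_large[[min(i %% max(1L, length(w_large)) + 1L,
                                 length(w_large))]]
        start <- parent[t0, ] + (parent_w / 2 + 2) * c(sin(ang), cos(ang))
      } else {
        start <- disc_center
        ang <- stats::runif(1L, 0, 2 * pi)
      }
      n_steps <- round(stats::runif(1L, 0.35, 0.65) * r_fov)
      pts <- walk_centerline(start, ang, n_steps, center, r_fov - 2)
      if (nrow(pts) < 8L) next
      w <- min(max(spec$width_thin[1L], w_thin[i]), 3)
      # thin vessels have genuinely bad contrast: above the threshold floor
      # near the root, fading towards the noise floor at the tail, so the
      # binary image only catches fragments of them (each well below the
      # large-vessel grain size)
      depth <- spec$vessel_contrast * seq(0.40, 0.08, length.out = nrow(pts))
      st <- stamp_vessel(mask_thin, layer, pts, w, depth)
      mask_thin <- st$mask; layer <- st$layer
      placed_thin <- placed_thin + 1L
    }
    if (placed_thin < spec$n_thin)
      warning("phantom seed ", spec$seed, ": placed only ", placed_thin,
              " of ", spec$n_thin, " thin vessels")
    layer <- gaussian_filter(layer, 0.5)  # soft vessel cross-profile
    green_clean <- pmin(pmax(bg + bump - layer, 0.02), 0.98)
    green_clean[!fov] <- 0.03
    clip01 <- function(x) pmin(pmax(x, 0), 1)
    green <- clip01(green_clean +
                      matrix(stats::rnorm(nr * nc, 0, spec$noise_sd), nr, nc))
    red <- clip01(0.6 * green_clean + 0.25 +
                    matrix(stats::rnorm(nr * nc, 0, 2 * spec$noise_sd), nr, nc))
    blue <- clip01(0.3 * green_clean + 0.15 +
                     matrix(stats::rnorm(nr * nc, 0, 2 * spec$noise_sd), nr, nc))
    truth_large <- mask_large & fov
    truth_thin <- mask_thin & !mask_large & fov
    img <- retinal_image(red, green, blue, fov = fov,
                         id = sprintf("phantom_%d", spec$seed))
    structure(list(image = img,
                   truth = truth_large | truth_thin,
                   truth_large = truth_large,
                   truth_thin = truth_thin,
                   fov = fov, spec = spec),
              class = "phantom")
  })
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf(paste0("<phantom seed %d: %d x %d, vessel fraction %.1f%%",
                     " (thin %.1f%%)>\n"),
              x$spec$seed, nrow(x$fov), ncol(x$fov),
              100 * sum(x$truth) / sum(x$fov),
              100 * sum(x$truth_thin) / sum(x$fov)))
  invisible(x)
}

#' Generate a suite of phantoms with jittered specs
#'
#' Produces `n_images` phantoms whose specs are jittered around the
#' defaults (thin-vessel count, contrast), deterministic given `seed`.  The
#' default of 20 images mirrors the 20-image residual training set the
#' classifier is built from.
#'
#' @param seed Integer master seed.
#' @param n_images Number of phantoms, >= 1.
#' @param shape Image shape passed to every spec.
#' @return List of [generate_phantom()] objects.
#' @export
make_fixture_suite <- function(seed = 42L, n_images = 20L,
                               shape = c(192L, 192L)) {
  stopifnot(n_images >= 1L)
  with_seed(seed, function() {
    specs <- lapply(seq_len(n_images), function(i) {
      phantom_spec(shape = shape,
                   n_thin = sample(7:9, 1L),
                   vessel_contrast = 0.32 * stats::runif(1L, 0.9, 1.1),
                   seed = sample.int(2147483646L, 1L))
    })
    lapply(specs, generate_phantom)
  })
}
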