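## End-to-end pipeline: preprocessing and large-vessel stages shared by
## training and segmentation, classifier training on a phantom (or image)
## set, and full-image segmentation.

# Run the deterministic front half of the pipeline on one image:
# green channel -> background -> normalized -> binary -> large -> residual.
pipeline_stages <- function(img, cfg = pipeline_config()) {
  green <- if (inherits(img, "retinal_image")) extract_green(img) else as_gray(img)
  bg <- estimate_background(green, cfg$median_window)
  norm <- normalize_image(green, bg)
  binary <- adaptive_threshold(norm, cfg$thresh_window, cfg$thresh_offset)
  cand <- filter_components(binary, cfg$grain_size_T)
  grad <- sobel_gradients(green)
  disc <- locate_optic_disc(green, cfg$disc_radius)
  cand <- erase_disc_edges(cand, grad, disc, cfg$grain_size_T,
                           cfg$max_vessel_width)
  large <- refine_by_gradient_pairs(cand, grad, cfg$max_vessel_width)
  large <- large & fov_or_true(green)
  residual <- residual_fragments(binary, large)
  list(green = green, normalized = norm, binary = binary, grad = grad,
       disc = disc, large = large, residual = residual)
}

#' Train the thin-vessel classifier on a phantom suite
#'
#' Runs the preprocessing and large-vessel stages on every phantom, samples
#' a balanced training set from the residual fragments against the
#' thin-vessel ground truth, and fits the asymmetric-cost RBF SVM from the
#' configuration.
#'
#' @param phantoms List of [generate_phantom()] objects (or any list whose
#'   elements have `$image` and `$truth_thin`).
#' @param cfg A [pipeline_config()].
#' @param per_image Training pixels per image (default 100: 50 thin-vessel,
#'   50 noise).
#' @return A [train_svm()] model.
#' @export
train_vessel_classifier <- function(phantoms, cfg = pipeline_config(),
                                    per_image = 100L) {
  stopifnot(length(phantoms) >= 1L)
  stages <- lapply(phantoms, function(ph) pipeline_stages(ph$image, cfg))
  ts <- sample_training_set(
    residuals = lapply(stages, `[[`, "residual"),
    truths = lapply(phantoms, `[[`, "truth_thin"),
    grays = lapply(stages, `[[`, "green"),
    per_image = per_image,
    seed = cfg$seed,
    bank = build_line_detectors(cfg$line_length_l, cfg$n_orientations))
  train_svm(ts, sigma = cfg$svm_sigma, C1 = cfg$svm_C1, C2 = cfg$svm_C2)
}

#' Segment the blood vessels of one fundus image
#'
#' Full pipeline: adaptive thresholding of the normalized green channel,
#' large-vessel extraction (area filter, optic-disc edge erasure, gradient
#' extremum-pair refinement), residual-fragment classification by the
#' trained SVM with score pruning to the per-image cap, Hessian-gated
#' tracking growth of the classified thin segments, and the union of large
#' and thin vessels as the final mask.
#'
#' @param img A [retinal_image()] (or a gray matrix, taken as the green
#'   channel).
#' @param model A [train_svm()] / [train_vessel_classifier()] model.
#' @param cfg A [pipeline_config()].
#' @return Object of class `vessel_segmentation`: list with `mask` (final
#'   vessel map), `large`, `thin_segments` (classified, pre-growth),
#'   `thin` (post-growth), `binary`, `residual`, `green`, `disc`, `cfg`.
#' @export
segment_vessels <- function(img, model, cfg = pipeline_config()) {
  stopifnot(inherits(model, "svm_vessel_model"))
  st <- pipeline_stages(img, cfg)
  bank <- build_line_detectors(cfg$line_length_l, cfg$n_orientations)
  coords <- raster_coords(st$residual)
  thin_segments <- if (nrow(coords)) {
    mw <- wavelet_modulus(st$green)
    mc <- curvelet_modulus(st$green)
    feats <- pixel_features_matrix(st$green, mw, mc, coords, bank)
    iterative_prune(model, feats, coords, cfg$prune_cap, dim(st$residual))
  } else {
    st$residual
  }
  thin <- track_all(thin_segments, st$green, cfg)
  thin <- thin & fov_or_true(st$green)
  structure(list(mask = st$large | thin,
                 large = st$large,
                 thin_segments = thin_segments,
                 thin = thin,
                 binary = st$binary,
                 residual = st$residual,
                 green = st$green,
                 disc = st$disc,
                 cfg = cfg),
            class = "vessel_segmentation")
}

#' @export
print.vessel_segmentation <- function(x, ...) {
  n_fov <- sum(fov_or_true(x$green))
  cat(sprintf(paste0("<vessel_segmentation: %.1f%% of FOV vessel ",
                     "(%d large px, %d thin px, %d thin-segment px)>\n"),
              100 * sum(x$mask) / n_fov, sum(x$large), sum(x$thin),
              sum(x$thin_segments)))
  invisible(x)
}

#' Plot a segmentation overlay
#'
#' Shows the green channel in gray with the final vessel mask overlaid in
#' red (large vessels) and yellow (tracked thin vessels).
#'
#' @param x A `vessel_segmentation`.
#' @param ... Unused.
#' @export
plot.vessel_segmentation <- function(x, ...) {
  g <- pmin(pmax(x$green$values, 0), 1)
  a <- array(rep(g, 3L), dim = c(dim(g), 3L))
  a[, , 1L][x$mask] <- 1
  a[, , 2L][x$large] <- 0
  a[, , 3L][x$mask] <- 0
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::plot.window(c(0, 1), c(0, 1), asp = nrow(g) / ncol(g))
  graphics::rasterImage(a, 0, 0, 1, 1)
  invisible(x)
}
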