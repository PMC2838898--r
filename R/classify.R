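## Thin-vessel/noise classification of residual pixels: balanced
## proportional-spacing sampling, an RBF support vector machine with
## asymmetric class costs, and score-threshold pruning down to a per-image
## pixel cap.

#' @importFrom e1071 svm
NULL

# Residual-pixel coordinates in raster order (row-major: by row, then col).
raster_coords <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(idx)
  idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}

# k indices evenly strided over 1..m ("proportional spacing"); fewer when
# m < k.
stride_indices <- function(m, k) {
  if (m == 0L || k == 0L) return(integer(0))
  k <- min(k, m)
  unique(round(seq(1, m, length.out = k)))
}

#' Sample a balanced training set from residual images
#'
#' From each residual image, `per_image` pixels are taken at proportional
#' (evenly strided) spacing along the raster order of its residual pixels,
#' balanced half thin-vessel (`+1`, residual pixels on the thin-vessel
#' truth) and half noise (`-1`, residual pixels off the vessel truth).
#' When one class of an image cannot supply its share, the shortfall is
#' filled from the pooled remaining pixels of that class in the other
#' images, with a warning.  The defaults -- 20 images at 100 pixels each --
#' give 2000 rows, 1000 of them thin-vessel.
#'
#' @param residuals List of residual binary maps (logical matrices).
#' @param truths List of thin-vessel truth maps aligned with `residuals`.
#' @param grays List of gray images the features are computed on.
#' @param per_image Even number of pixels to draw per image.
#' @param seed Integer seed (the draw is deterministic; the seed guards any
#'   downstream stochastic consumer and is recorded in the provenance).
#' @param bank Line-detector bank for feature extraction.
#' @param mws,mcs Optional precomputed wavelet/curvelet modulus images;
#'   computed from `grays` when `NULL`.
#' @return Object of class `training_set`: list with `features` (N x 12),
#'   `labels` (+1/-1), `provenance` (data.frame image/row/col), `seed`.
#' @export
sample_training_set <- function(residuals, truths, grays, per_image = 100L,
                                seed = 1L, bank = build_line_detectors(),
                                mws = NULL, mcs = NULL) {
  stopifnot(length(residuals) == length(truths),
            length(residuals) == length(grays), per_image >= 2L)
  n_img <- length(residuals)
  half <- per_image %/% 2L
  pos_pool <- vector("list", n_img)
  neg_pool <- vector("list", n_img)
  take_pos <- vector("list", n_img)
  take_neg <- vector("list", n_img)
  for (i in seq_len(n_img)) {
    res <- residuals[[i]]; tru <- truths[[i]]
    stopifnot(identical(dim(res), dim(tru)))
    coords <- raster_coords(res)
    lab_pos <- tru[coords]
    pos_pool[[i]] <- coords[lab_pos, , drop = FALSE]
    neg_pool[[i]] <- coords[!lab_pos, , drop = FALSE]
    take_pos[[i]] <- stride_indices(nrow(pos_pool[[i]]), half)
    take_neg[[i]] <- stride_indices(nrow(neg_pool[[i]]), half)
  }
  # fill per-image shortfalls from the pooled leftovers of the same class
  fill_short <- function(pools, takes, want_total, class_name) {
    short <- want_total - sum(lengths(takes))
    if (short > 0L) {
      leftovers <- do.call(rbind, lapply(seq_along(pools), function(i) {
        left <- setdiff(seq_len(nrow(pools[[i]])), takes[[i]])
        if (!length(left)) return(NULL)
        cbind(img = i, idx = left)
      }))
      if (is.null(leftovers) || nrow(leftovers) < short)
        stop("not enough ", class_name, " residual pixels to fill the training set")
      warning("class '", class_name, "' underfilled in some images; ",
              short, " pixels drawn from other images")
      extra <- leftovers[stride_indices(nrow(leftovers), short), , drop = FALSE]
      for (r in seq_len(nrow(extra))) {
        i <- extra[r, 1L]
        takes[[i]] <- c(takes[[i]], extra[r, 2L])
      }
    }
    takes
  }
  take_pos <- fill_short(pos_pool, take_pos, half * n_img, "thin-vessel")
  take_neg <- fill_short(neg_pool, take_neg, half * n_img, "noise")
  feats <- vector("list", n_img)
  labs <- vector("list", n_img)
  prov <- vector("list", n_img)
  for (i in seq_len(n_img)) {
    px <- rbind(pos_pool[[i]][take_pos[[i]], , drop = FALSE],
                neg_pool[[i]][take_neg[[i]], , drop = FALSE])
    y <- c(rep(1L, length(take_pos[[i]])), rep(-1L, length(take_neg[[i]])))
    if (!nrow(px)) next
    g <- as_gray(grays[[i]])
    mw <- if (is.null(mws)) wavelet_modulus(g) else as_gray(mws[[i]])
    mc <- if (is.null(mcs)) curvelet_modulus(g) else as_gray(mcs[[i]])
    feats[[i]] <- pixel_features_matrix(g, mw, mc, px, bank)
    labs[[i]] <- y
    prov[[i]] <- data.frame(image = i, row = px[, 1L], col = px[, 2L])
  }
  structure(list(features = do.call(rbind, feats),
                 labels = unlist(labs),
                 provenance = do.call(rbind, prov),
                 seed = as.integer(seed)),
            class = "training_set")
}

#' Construct a training set directly
#'
#' Mostly useful for experimentation and testing; [sample_training_set()]
#' is the standard route.
#'
#' @param features Numeric N x p matrix.
#' @param labels Integer vector of +1/-1, length N.
#' @param provenance Optional data.frame of per-row origin info.
#' @param seed Integer seed recorded with the set.
#' @return Object of class `training_set`.
#' @export
training_set <- function(features, labels, provenance = NULL, seed = 1L) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  stopifnot(nrow(features) == length(labels), nrow(features) > 0,
            all(labels %in% c(-1L, 1L)), all(is.finite(features)))
  structure(list(features = features, labels = labels,
                 provenance = provenance, seed = as.integer(seed)),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("<training_set: %d rows (%d thin-vessel, %d noise)>\n",
              length(x$labels), sum(x$labels == 1L), sum(x$labels == -1L)))
  invisible(x)
}

#' Gaussian RBF kernel
#'
#' `K(a, b) = exp(-||a - b||^2 / (2 sigma^2))`, the kernel used by the
#' thin-vessel classifier.
#'
#' @param a,b Numeric vectors of equal length.
#' @param sigma Kernel width, > 0.
#' @return Scalar in (0, 1].
#' @export
rbf_kernel <- function(a, b, sigma) {
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0")
  exp(-sum((a - b)^2) / (2 * sigma^2))
}

# Median pairwise Euclidean distance between (scaled) feature rows; rows
# are subsampled deterministically for very large sets.
median_heuristic_sigma <- function(x, max_rows = 1000L) {
  if (nrow(x) > max_rows)
    x <- x[stride_indices(nrow(x), max_rows), , drop = FALSE]
  stats::median(stats::dist(x))
}

#' Train the thin-vessel RBF support vector machine
#'
#' Fits a soft-margin SVM with the Gaussian RBF kernel and *asymmetric*
#' class costs: slack on thin-vessel rows (+1) is charged `C1`, slack on
#' noise rows (-1) is charged `C2`.  A small `C1` with a large `C2`
#' tolerates missed vessel pixels (tracking growth can recover a vessel
#' from any one of its pixels) while penalizing false vessels, which would
#' seed noise growth.  The min-max feature scaler is fitted on the training
#' rows and stored in the model.
#'
#' @param ts A [sample_training_set()] result (both classes present).
#' @param sigma RBF width; `NULL` uses the median pairwise distance of the
#'   scaled training rows.
#' @param C1,C2 Positive class costs for the +1 and -1 classes.
#' @return Object of class `svm_vessel_model`.
#' @export
train_svm <- function(ts, sigma = NULL, C1 = 1, C2 = 10) {
  stopifnot(inherits(ts, "training_set"))
  if (length(unique(ts$labels)) < 2L)
    stop("training set must contain both classes")
  if (C1 <= 0 || C2 <= 0) stop("C1 and C2 must be > 0")
  scaler <- fit_scaler(ts$features)
  x <- apply_scaler(scaler, ts$features)
  if (is.null(sigma)) sigma <- median_heuristic_sigma(x)
  if (sigma <= 0) stop("sigma must be > 0")
  y <- factor(ts$labels, levels = c(-1L, 1L))
  # tight convergence tolerance makes the fitted decision function
  # independent of training-row order to ~1e-9
  fit <- e1071::svm(x = x, y = y, scale = FALSE, kernel = "radial",
                    gamma = 1 / (2 * sigma^2), cost = 1,
                    class.weights = c("1" = C1, "-1" = C2),
                    tolerance = 1e-9)
  # orient decision values so positive score means thin-vessel (+1)
  dv <- attr(stats::predict(fit, x[1:2, , drop = FALSE],
                            decision.values = TRUE), "decision.values")
  flip <- if (startsWith(colnames(dv)[1L], "-1")) -1 else 1
  structure(list(fit = fit, scaler = scaler, sigma = sigma,
                 C1 = C1, C2 = C2, flip = flip),
            class = "svm_vessel_model")
}

#' @export
print.svm_vessel_model <- function(x, ...) {
  cat(sprintf(paste0("<svm_vessel_model: RBF sigma=%.4g, C1=%.3g, C2=%.3g, ",
                     "%d support vectors>\n"),
              x$sigma, x$C1, x$C2, x$fit$tot.nSV))
  invisible(x)
}

#' Save / load a trained vessel classifier
#'
#' Serializes the full model -- support vectors, coefficients, bias, kernel
#' width, class costs, the fitted feature scaler and a format version --
#' into a single file.
#'
#' @param model A [train_svm()] model.
#' @param path Destination / source file path.
#' @return `load_model` returns the `svm_vessel_model`; `save_model` returns
#'   `NULL` invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "svm_vessel_model"))
  payload <- unclass(model)
  payload$format_version <- 1L
  saveRDS(payload, path)
  invisible(NULL)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- readRDS(path)
  if (is.null(payload$format_version) || payload$format_version != 1L)
    stop("unsupported model format in ", path)
  payload$format_version <- NULL
  structure(payload, class = "svm_vessel_model")
}

#' Classify residual pixels
#'
#' Scales the features with the model's stored scaler and returns signed
#' decision values (positive = thin-vessel side) plus hard labels
#' `sign(score - bias_shift)`.
#'
#' @param model A [train_svm()] model.
#' @param features Numeric N x 12 matrix of raw (unscaled) features.
#' @param bias_shift Decision threshold shift (default 0).
#' @return List with `labels` (+1/-1) and `scores`.
#' @export
classify_pixels <- function(model, features, bias_shift = 0) {
  stopifnot(inherits(model, "svm_vessel_model"))
  features <- as.matrix(features)
  if (ncol(features) != length(model$scaler$mins))
    stop("feature width ", ncol(features), " != ",
         length(model$scaler$mins))
  x <- apply_scaler(model$scaler, features)
  dv <- attr(stats::predict(model$fit, x, decision.values = TRUE),
             "decision.values")
  scores <- model$flip * as.numeric(dv)
  list(labels = ifelse(scores > bias_shift, 1L, -1L), scores = scores)
}

#' Prune classified pixels to a per-image cap
#'
#' Classifies the residual pixels and, when more than `cap` come out
#' positive, raises the decision threshold to the smallest value leaving at
#' most `cap` positives -- equivalently keeps the `cap` highest-scoring
#' pixels.  Exact score ties at the cut are kept together, so the result
#' may exceed `cap` only on ties (a warning is issued then).  This realizes
#' the design rule that at most about a thousand of the most vessel-like
#' residual pixels per image should survive, which keeps noise specificity
#' high.
#'
#' @param model A [train_svm()] model.
#' @param features N x 12 raw feature matrix of the residual pixels.
#' @param coords Integer N x 2 matrix of their (row, col) coordinates.
#' @param cap Maximum positives to keep (>= 1).
#' @param shape Integer (rows, cols) of the output map.
#' @return Logical matrix: the thin-vessel segment map.
#' @export
iterative_prune <- function(model, features, coords, cap = 1000L, shape) {
  coords <- matrix(as.integer(coords), ncol = 2L)
  cap <- as.integer(cap)
  if (cap < 1L) stop("cap must be >= 1")
  out <- matrix(FALSE, shape[1L], shape[2L])
  if (nrow(coords) == 0L) return(out)
  cl <- classify_pixels(model, features)
  pos <- cl$labels == 1L
  if (sum(pos) > cap) {
    s <- cl$scores[pos]
    thr <- sort(s, decreasing = TRUE)[cap]
    keep <- pos & cl$scores >= thr
    if (sum(keep) > cap)
      warning("score ties at the cap: keeping ", sum(keep), " > ", cap,
              " pixels")
    pos <- keep
  }
  out[coords[pos, , drop = FALSE]] <- TRUE
  out
}
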