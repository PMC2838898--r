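## Pipeline configuration: one flat list of every tunable parameter, with
## validation.  All intensity-scale parameters are on the [0,1] scale.

#' Pipeline configuration
#'
#' Collects every tunable parameter of the segmentation pipeline.  Defaults
#' are sized for fundus images a few hundred pixels across (DRIVE-scale
#' parameters such as the optic-disc radius are rescaled to the image width
#' at run time).
#'
#' @param median_window Odd window (px) of the background median filter.
#' @param thresh_window Odd window (px) of the adaptive local-mean threshold.
#' @param thresh_offset Offset added to the local mean before thresholding,
#'   on the \[0,1\] intensity scale.  The default passes roughly 12--15\% of
#'   FOV pixels on the bundled phantoms, the fraction human experts mark as
#'   vessel.
#' @param grain_size_T Minimum grain size (px^2): connected components of
#'   the binary image with area strictly greater than `T` count as
#'   large-vessel candidates.
#' @param line_length_l Odd length (px) of the oriented line detectors.
#' @param n_orientations Number of line-detector orientations (8 gives the
#'   classical 22.5 degree angular resolution).
#' @param max_vessel_width Maximum span (px) of a gradient extremum pair.
#'   A vessel of width w crossed diagonally by a horizontal or vertical
#'   profile spans up to `sqrt(2) * w` pixels, so the cap exceeds the
#'   largest expected vessel width by that factor.
#' @param svm_sigma RBF kernel width; `NULL` selects the median pairwise
#'   distance of the scaled training features (median heuristic).
#' @param svm_C1,svm_C2 Soft-margin costs for the thin-vessel (+1) and
#'   noise (-1) classes; `C2 > C1` penalizes false vessels harder.
#' @param prune_cap Maximum number of thin-segment pixels kept per image
#'   after classification.
#' @param hessian_sigma Gaussian-derivative scale (px) of the Hessian used
#'   to gate tracking growth.
#' @param lambda1_min,lambda2_max Hessian eigenvalue gates; `NULL` derives
#'   them from the eigenvalue distribution over the classified segments.
#' @param disc_radius Optic-disc radius (px); `NULL` scales 40 px at DRIVE
#'   width (565 px) to the image width.
#' @param step Tracking step length (px).
#' @param max_steps Maximum growth steps per endpoint.
#' @param direction_weight Weight of the line-detector direction when
#'   averaged with the Hessian ridge direction during growth (in \[0,1\]).
#' @param seed Integer seed for the stochastic stages.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(median_window = 25L,
                            thresh_window = 25L,
                            thresh_offset = 0.022,
                            grain_size_T = 100L,
                            line_length_l = 15L,
                            n_orientations = 8L,
                            max_vessel_width = 18L,
                            svm_sigma = NULL,
                            svm_C1 = 1,
                            svm_C2 = 10,
                            prune_cap = 1000L,
                            hessian_sigma = 1.5,
                            lambda1_min = NULL,
                            lambda2_max = NULL,
                            disc_radius = NULL,
                            step = 1,
                            max_steps = 200L,
                            direction_weight = 0.5,
                            seed = 42L) {
  cfg <- structure(list(
    median_window = as.integer(median_window),
    thresh_window = as.integer(thresh_window),
    thresh_offset = thresh_offset,
    grain_size_T = as.integer(grain_size_T),
    line_length_l = as.integer(line_length_l),
    n_orientations = as.integer(n_orientations),
    max_vessel_width = as.integer(max_vessel_width),
    svm_sigma = svm_sigma,
    svm_C1 = svm_C1,
    svm_C2 = svm_C2,
    prune_cap = as.integer(prune_cap),
    hessian_sigma = hessian_sigma,
    lambda1_min = lambda1_min,
    lambda2_max = lambda2_max,
    disc_radius = disc_radius,
    step = step,
    max_steps = as.integer(max_steps),
    direction_weight = direction_weight,
    seed = as.integer(seed)
  ), class = "pipeline_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  odd <- function(w) w %% 2L == 1L && w >= 3L
  if (!odd(cfg$median_window)) stop("median_window must be odd and >= 3")
  if (!odd(cfg$thresh_window)) stop("thresh_window must be odd and >= 3")
  if (!odd(cfg$line_length_l)) stop("line_length_l must be odd and >= 3")
  if (!is.finite(cfg$thresh_offset)) stop("thresh_offset must be finite")
  if (cfg$grain_size_T < 1L) stop("grain_size_T must be >= 1")
  if (cfg$n_orientations < 2L) stop("n_orientations must be >= 2")
  if (cfg$prune_cap < 1L) stop("prune_cap must be >= 1")
  if (cfg$max_vessel_width < 2L) stop("max_vessel_width must be >= 2")
  if (cfg$hessian_sigma <= 0) stop("hessian_sigma must be > 0")
  if (!is.null(cfg$svm_sigma) && cfg$svm_sigma <= 0) stop("svm_sigma must be > 0")
  if (cfg$svm_C1 <= 0 || cfg$svm_C2 <= 0) stop("svm_C1 and svm_C2 must be > 0")
  if (cfg$step <= 0) stop("step must be > 0")
  if (cfg$max_steps < 0L) stop("max_steps must be >= 0")
  if (cfg$direction_weight < 0 || cfg$direction_weight > 1)
    stop("direction_weight must lie in [0, 1]")
  invisible(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-18s %s\n", nm, if (is.null(v)) "auto" else format(v)))
  }
  invisible(x)
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys present in the file override the corresponding [pipeline_config()]
#' defaults; unknown keys are an error.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}
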