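## Shared low-level image numerics: border reflection, separable filtering,
## Gaussian (derivative) kernels, box means.  All filters use symmetric
## border reflection with the edge sample repeated (… b a | a b c … | c b …),
## the same convention as the compiled median filter.

#' @useDynLib retiseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Map integer indices (possibly outside 1..n) back into 1..n by symmetric
# reflection with edge repetition.  Vectorized.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  j <- (i - 1L) %% (2L * n)
  j <- ifelse(j < 0L, j + 2L * n, j)
  as.integer(ifelse(j < n, j + 1L, 2L * n - j))
}

# Apply a 1-D kernel along one margin of a matrix (margin 1 = down columns,
# i.e. the kernel slides over rows; margin 2 = across rows).  `center` is the
# 1-based kernel tap aligned with the output pixel.
filter1 <- function(x, kernel, center, margin = 1L) {
  n <- if (margin == 1L) nrow(x) else ncol(x)
  out <- matrix(0, nrow(x), ncol(x))
  for (t in seq_along(kernel)) {
    if (kernel[t] == 0) next
    idx <- reflect_index(seq_len(n) + (t - center), n)
    out <- out + kernel[t] * (if (margin == 1L) x[idx, , drop = FALSE]
                              else x[, idx, drop = FALSE])
  }
  out
}

# Separable filtering with the same kernel (or two kernels) along both axes.
sep_filter <- function(x, krow, kcol = krow,
                       center_row = (length(krow) + 1L) %/% 2L,
                       center_col = (length(kcol) + 1L) %/% 2L) {
  filter1(filter1(x, krow, center_row, margin = 1L), kcol, center_col, margin = 2L)
}

# Sampled Gaussian kernel and its first/second analytic derivatives.
# order 0 is normalized to unit sum; derivatives inherit that normalization.
gaussian_kernel <- function(sigma, order = 0L) {
  stopifnot(sigma > 0)
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  t <- (-r):r
  g <- exp(-t^2 / (2 * sigma^2))
  g <- g / sum(g)
  switch(as.character(order),
         "0" = g,
         "1" = -t / sigma^2 * g,            # antisymmetric: zero-sum exactly
         "2" = {
           k <- (t^2 - sigma^2) / sigma^4 * g
           k - mean(k)                      # flat fields must map to zero
         },
         stop("unsupported derivative order: ", order))
}

# Isotropic Gaussian smoothing (order 0) or a Gaussian-derivative filter with
# per-axis derivative orders (order = c(row_order, col_order)).
gaussian_filter <- function(x, sigma, order = c(0L, 0L)) {
  order <- rep_len(order, 2L)
  sep_filter(x,
             krow = gaussian_kernel(sigma, order[1L]),
             kcol = gaussian_kernel(sigma, order[2L]))
}

# Local mean over an odd square window, reflect-padded.
box_mean <- function(x, window) {
  stopifnot(window %% 2L == 1L, window >= 3L)
  k <- rep(1 / window, window)
  sep_filter(x, k)
}
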