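## Image containers and file I/O.
##
## Conventions used throughout the package:
##   * images are R matrices indexed [row, col], row 1 at the top;
##   * intensities live in [0, 1] from the moment a file is read;
##   * binary maps are plain logical matrices aligned with their image;
##   * a missing field-of-view (FOV) mask means "everything is inside".

#' Retinal RGB image
#'
#' Container for a three-channel fundus photograph with an optional binary
#' field-of-view mask.  All channels are matrices in `[0, 1]` sharing one
#' shape; the FOV, when present, is a logical matrix of that same shape.
#'
#' @param red,green,blue Numeric matrices in `[0, 1]`, same dimensions.
#' @param fov Optional logical matrix (`TRUE` = inside the field of view).
#' @param id Character label, typically the file name stem.
#' @return An object of class `retinal_image`.
#' @export
retinal_image <- function(red, green, blue, fov = NULL, id = "") {
  stopifnot(is.matrix(red), is.matrix(green), is.matrix(blue),
            identical(dim(red), dim(green)), identical(dim(red), dim(blue)))
  if (!is.null(fov)) {
    stopifnot(is.logical(fov), identical(dim(fov), dim(green)))
  }
  structure(list(red = red, green = green, blue = blue, fov = fov,
                 id = as.character(id)),
            class = "retinal_image")
}

#' @export
print.retinal_image <- function(x, ...) {
  cat(sprintf("<retinal_image '%s' %d x %d%s>\n", x$id, nrow(x$green),
              ncol(x$green), if (is.null(x$fov)) "" else ", with FOV"))
  invisible(x)
}

#' Grayscale image
#'
#' A single-channel intensity grid with an optional FOV mask.  This is the
#' working representation at every pipeline stage after green-channel
#' extraction.
#'
#' @param values Numeric matrix of finite intensities.
#' @param fov Optional logical matrix matching `values` in shape.
#' @return An object of class `gray_image`.
#' @export
gray_image <- function(values, fov = NULL) {
  stopifnot(is.matrix(values), all(is.finite(values)))
  if (!is.null(fov)) stopifnot(is.logical(fov), identical(dim(fov), dim(values)))
  structure(list(values = values, fov = fov), class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d%s>\n", nrow(x$values), ncol(x$values),
              if (is.null(x$fov)) "" else ", with FOV"))
  invisible(x)
}

# Accept either a gray_image or a bare matrix wherever a gray image is
# expected; returns a gray_image.
as_gray <- function(x) {
  if (inherits(x, "gray_image")) return(x)
  if (is.matrix(x) && is.numeric(x)) return(gray_image(x))
  stop("expected a gray_image or a numeric matrix")
}

# FOV as a logical matrix, defaulting to all-TRUE when absent.
fov_or_true <- function(gray) {
  if (!is.null(gray$fov)) gray$fov else
    matrix(TRUE, nrow(gray$values), ncol(gray$values))
}

assert_binary_map <- function(m, name = deparse(substitute(m))) {
  if (!is.matrix(m) || !is.logical(m))
    stop(name, " must be a logical matrix (binary map)")
  invisible(m)
}

## ---- file readers -------------------------------------------------------

# Minimal PNM reader (P2/P3 ASCII, P5/P6 binary); returns [0,1] array
# (rows x cols x channels for P3/P6, rows x cols for P2/P5).
read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # token reader that skips whitespace and '#' comments
  next_token <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L || ch == "") stop("unexpected end of PNM header")
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || ch == "" || ch == "\n") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (nzchar(tok)) return(tok) else next
      }
      tok <- paste0(tok, ch)
    }
  }
  magic <- next_token()
  if (!magic %in% c("P2", "P3", "P5", "P6"))
    stop("unsupported PNM magic: ", magic)
  w <- as.integer(next_token())
  h <- as.integer(next_token())
  maxval <- as.integer(next_token())
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- w * h * nch
  vals <- if (magic %in% c("P5", "P6")) {
    if (maxval > 255L)
      readBin(con, "integer", n = n, size = 2L, signed = FALSE, endian = "big")
    else
      as.integer(readBin(con, "raw", n = n))
  } else {
    scan(con, what = integer(), n = n, quiet = TRUE)
  }
  if (length(vals) < n) stop("truncated PNM payload in ", path)
  # PNM stores row-major, channels interleaved
  if (nch == 3L) {
    a <- array(0, dim = c(h, w, 3L))
    for (k in 1:3)
      a[, , k] <- matrix(vals[seq(k, n, by = 3L)], nrow = h, byrow = TRUE)
  } else {
    a <- matrix(vals, nrow = h, byrow = TRUE)
  }
  a / maxval
}

# Read any supported raster file into a numeric array in [0,1]
# (matrix for single channel, rows x cols x ch otherwise).
read_raster <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
              png  = png::readPNG(path),
              tif  = ,
              tiff = tiff::readTIFF(path),
              ppm  = ,
              pgm  = ,
              pnm  = read_pnm(path),
              stop("unsupported image format '.", ext,
                   "' (supported: png, tif/tiff, ppm/pgm)"))
  a
}

#' Read a fundus photograph
#'
#' Reads a 3-channel PNG/TIFF/PPM image, scales intensities to `[0, 1]` and
#' labels it with the file name stem.  An alpha channel, if present, is
#' dropped.
#'
#' @param path Path to an RGB image file.
#' @param fov Optional path to a binary FOV mask image (thresholded at 0.5).
#' @return A [retinal_image()].
#' @export
read_image <- function(path, fov = NULL) {
  a <- read_raster(path)
  nch <- if (length(dim(a)) == 3L) dim(a)[3L] else 1L
  if (nch == 4L) a <- a[, , 1:3, drop = FALSE]  # drop alpha
  if (nch < 3L)
    stop("expected 3 channels, got ", nch, " in ", path)
  fov_mask <- if (!is.null(fov)) read_mask(fov) else NULL
  ch <- function(k) matrix(a[, , k], dim(a)[1L], dim(a)[2L])
  retinal_image(ch(1L), ch(2L), ch(3L), fov = fov_mask,
                id = tools::file_path_sans_ext(basename(path)))
}

#' Read a binary mask
#'
#' Reads a mask image and binarizes it at 0.5 (multi-channel masks use the
#' first channel).
#'
#' @param path Path to the mask image.
#' @return Logical matrix, `TRUE` where the mask is set.
#' @export
read_mask <- function(path) {
  a <- read_raster(path)
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  a >= 0.5
}

#' Write a binary mask as PNG
#'
#' Writes `TRUE` as 255 and `FALSE` as 0; `read_mask()` inverts the
#' operation exactly.
#'
#' @param path Destination path (parent directory must exist).
#' @param mask Logical matrix.
#' @export
write_mask <- function(path, mask) {
  assert_binary_map(mask)
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(NULL)
}

#' Write a retinal image as PNG
#'
#' @param path Destination path.
#' @param img A [retinal_image()].
#' @export
write_image <- function(path, img) {
  stopifnot(inherits(img, "retinal_image"))
  a <- array(0, dim = c(dim(img$green), 3L))
  a[, , 1L] <- pmin(pmax(img$red, 0), 1)
  a[, , 2L] <- pmin(pmax(img$green, 0), 1)
  a[, , 3L] <- pmin(pmax(img$blue, 0), 1)
  png::writePNG(a, path)
  invisible(NULL)
}

#' Extract the green channel
#'
#' The green channel of a fundus photograph carries the best vessel/background
#' contrast (vessels appear dark in it); all downstream stages work on it.
#'
#' @param img A [retinal_image()].
#' @return A [gray_image()] whose values are the green channel, with the FOV
#'   propagated unchanged.
#' @export
extract_green <- function(img) {
  stopifnot(inherits(img, "retinal_image"))
  gray_image(img$green, fov = img$fov)
}

## ---- DRIVE layout -------------------------------------------------------

# Locate <stem>.<ext> in dir for any supported extension; error otherwise,
# naming the expected relative path.  GIF files (the format DRIVE ships its
# masks in) cannot be decoded by this package; they are reported explicitly
# so users can convert them.
find_case_file <- function(root, subdir, stems) {
  exts <- c("png", "tif", "tiff", "ppm", "pgm")
  for (stem in stems) {
    for (ext in exts) {
      p <- file.path(root, subdir, paste0(stem, ".", ext))
      if (file.exists(p)) return(p)
    }
  }
  gifs <- file.path(root, subdir, paste0(stems, ".gif"))
  if (any(file.exists(gifs)))
    stop("found only a GIF for '", file.path(subdir, stems[1L]),
         "'; convert it to PNG/TIFF first (GIF decoding is unsupported)")
  stop("missing DRIVE file: expected '",
       file.path(subdir, paste0(stems[1L], ".{png|tif|tiff|ppm}")),
       "' under ", root)
}

#' Load one case from a DRIVE-style directory layout
#'
#' Expects the DRIVE convention `images/<id>_test.tif`,
#' `mask/<id>_test_mask.gif`, `1st_manual/<id>_manual1.gif` and optionally
#' `2nd_manual/<id>_manual2.gif` under `root` (`_training` stems are also
#' accepted, as are PNG/TIFF/PPM versions of each file).  Manual masks are
#' binarized at 0.5.
#'
#' @param root Root directory of the layout.
#' @param case_id Case identifier, e.g. `"21"`.
#' @return A list with elements `image` ([retinal_image()] with the FOV
#'   attached), `fov`, `manual1` and `manual2` (logical matrices; `manual2`
#'   is `NULL` when absent).
#' @export
load_drive_case <- function(root, case_id) {
  if (!dir.exists(root)) stop("DRIVE root does not exist: ", root)
  id <- as.character(case_id)
  img_path <- find_case_file(root, "images",
                             paste0(id, c("_test", "_training")))
  fov_path <- find_case_file(root, "mask",
                             paste0(id, c("_test_mask", "_training_mask")))
  man1_path <- find_case_file(root, "1st_manual", paste0(id, "_manual1"))
  man2_path <- tryCatch(find_case_file(root, "2nd_manual",
                                       paste0(id, "_manual2")),
                        error = function(e) NULL)
  img <- read_image(img_path)
  fov <- read_mask(fov_path)
  manual1 <- read_mask(man1_path)
  manual2 <- if (!is.null(man2_path)) read_mask(man2_path) else NULL
  shapes <- list(dim(img$green), dim(fov), dim(manual1))
  if (!is.null(manual2)) shapes <- c(shapes, list(dim(manual2)))
  if (length(unique(lapply(shapes, paste, collapse = "x"))) != 1L)
    stop("DRIVE case ", id, ": image and mask shapes disagree")
  img$fov <- fov
  list(image = img, fov = fov, manual1 = manual1, manual2 = manual2)
}
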