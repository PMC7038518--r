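# Image containers and low-level raster utilities.
#
# Images are plain numeric arrays in [0, 1]: H x W matrices for single-band
# data, H x W x 3 arrays for RGB. Pixel centres sit at integer coordinates
# (row, col), 1-based, row 1 at the top.

#' Validate an image array
#'
#' Checks that `x` is a numeric H x W matrix (single band) or H x W x 3 array
#' (RGB) and returns it unchanged.
#'
#' @param x Candidate image.
#' @param arg Name used in error messages.
#' @return `x`, invisibly validated.
#' @export
as_image <- function(x, arg = "x") {
  if (!is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric array, not %s.", arg, class(x)[1]))
  }
  d <- dim(x)
  if (is.null(d) || !(length(d) == 2L || (length(d) == 3L && d[3] == 3L))) {
    abort(sprintf(
      "`%s` must be an H x W matrix or H x W x 3 array (got dim %s).",
      arg, paste(d, collapse = " x ")
    ))
  }
  if (any(d[1:2] < 1L)) abort(sprintf("`%s` has a zero-sized dimension.", arg))
  x
}

#' Number of channels of an image
#' @param img Image array.
#' @return 1 for a matrix, 3 for an RGB array.
#' @export
n_channels <- function(img) if (length(dim(img)) == 2L) 1L else dim(img)[3]

#' Clamp pixel values to the unit interval
#' @param x Numeric array.
#' @return `x` with values clipped to `[0, 1]`.
#' @export
clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Quantize an image to 8-bit intensity steps
#'
#' Rounds values to multiples of 1/255, emulating the 8-bit storage used for
#' snap files while keeping the array numeric.
#'
#' @param img Image array in `[0, 1]`.
#' @return Quantized image.
#' @export
quantize8 <- function(img) round(clamp01(img) * 255) / 255

#' Luminance of an image
#'
#' Rec. 601 luma weighting (0.299 R + 0.587 G + 0.114 B) for RGB images;
#' single-band images are returned as-is.
#'
#' @param img Image array.
#' @return H x W matrix of luminance values.
#' @export
luminance <- function(img) {
  img <- as_image(img, "img")
  if (n_channels(img) == 1L) return(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# Bilinear interpolation of one band at fractional (row, col) positions.
# Sampling positions are clamped to the frame unless fill is given, in which
# case positions more than half a pixel outside get the fill value.
bilinear_band <- function(band, row, col, fill = NULL) {
  h <- nrow(band); w <- ncol(band)
  outside <- NULL
  if (!is.null(fill)) {
    outside <- row < 0.5 | row > h + 0.5 | col < 0.5 | col > w + 0.5
  }
  r <- pmin(pmax(row, 1), h)
  c <- pmin(pmax(col, 1), w)
  r0 <- pmin(floor(r), h - 1L); r0[h == 1L] <- 1L
  c0 <- pmin(floor(c), w - 1L); c0[w == 1L] <- 1L
  r1 <- pmin(r0 + 1L, h); c1 <- pmin(c0 + 1L, w)
  fr <- r - r0; fc <- c - c0
  v <- band[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    band[cbind(r1, c0)] * fr * (1 - fc) +
    band[cbind(r0, c1)] * (1 - fr) * fc +
    band[cbind(r1, c1)] * fr * fc
  if (!is.null(outside) && any(outside)) v[outside] <- fill
  v
}

#' Bilinearly sample an image at fractional pixel positions
#'
#' @param img Image array.
#' @param row,col Numeric vectors (recycled to common length) of sampling
#'   positions in pixel coordinates (1-based centres).
#' @param fill Value for positions outside the frame; `NULL` clamps to the
#'   nearest edge pixel instead.
#' @return For a matrix input, a numeric vector; for RGB, an n x 3 matrix.
#' @export
bilinear_sample <- function(img, row, col, fill = NULL) {
  img <- as_image(img, "img")
  n <- max(length(row), length(col))
  row <- rep_len(row, n); col <- rep_len(col, n)
  if (n_channels(img) == 1L) {
    bilinear_band(img, row, col, fill)
  } else {
    vapply(1:3, function(ch) bilinear_band(img[, , ch], row, col, fill),
           numeric(n))
  }
}

# Resample an image onto an out_h x out_w grid whose pixel (i, j) maps to the
# source position given by coordinate matrices src_row, src_col (out_h x out_w).
resample_grid <- function(img, src_row, src_col, fill = NULL) {
  out_h <- nrow(src_row); out_w <- ncol(src_row)
  if (n_channels(img) == 1L) {
    matrix(bilinear_band(img, as.vector(src_row), as.vector(src_col), fill),
           out_h, out_w)
  } else {
    out <- array(0, c(out_h, out_w, 3L))
    for (ch in 1:3) {
      out[, , ch] <- matrix(
        bilinear_band(img[, , ch], as.vector(src_row), as.vector(src_col), fill),
        out_h, out_w
      )
    }
    out
  }
}

#' Read an image file
#'
#' PNG and TIFF files are supported; pixel values are returned in `[0, 1]`.
#' An alpha channel, if present, is dropped.
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @return Image array.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    abort(sprintf("Unsupported image extension '%s' (use png/tif/tiff).", ext))
  )
  d <- dim(img)
  if (length(d) == 3L && d[3] == 2L) img <- img[, , 1]        # gray + alpha
  if (length(d) == 3L && d[3] == 4L) img <- img[, , 1:3]      # rgb + alpha
  as_image(img, "image file")
}

#' Write an image file
#'
#' @param img Image array in `[0, 1]`.
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @param bits Bit depth, 8 (default) or 16.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, bits = 8L) {
  img <- clamp01(as_image(img, "img"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path, dpi = NULL),
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = as.integer(bits)),
    abort(sprintf("Unsupported image extension '%s' (use png/tif/tiff).", ext))
  )
  invisible(path)
}

#' Normalized cross-correlation of two images
#'
#' Pearson correlation of luminance values over the common support; the
#' standard similarity score for registration and round-trip checks.
#'
#' @param a,b Images of identical size.
#' @return Correlation in `[-1, 1]`; 0 if either image has zero variance.
#' @export
ncc <- function(a, b) {
  la <- as.vector(luminance(a)); lb <- as.vector(luminance(b))
  if (length(la) != length(lb)) abort("`a` and `b` must have the same size.")
  if (sd(la) == 0 || sd(lb) == 0) return(0)
  cor(la, lb)
}
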