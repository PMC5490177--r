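#' Grayscale image container
#'
#' Images are plain numeric matrices `m[row, col]` with intensities on the
#' 8-bit scale `[0, 255]` (stored as doubles). A pixel at matrix position
#' `[r, c]` sits at coordinates `x = c - 1`, `y = r - 1`: 0-based, `x` along
#' columns, `y` along rows, pixel centers at integer coordinates.
#'
#' @param pixels numeric matrix of intensities in `[0, 255]`.
#' @return the validated matrix, invisibly classed as used throughout.
#' @export
gray_image <- function(pixels) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    abort("pixels must be a numeric matrix")
  }
  if (anyNA(pixels) || any(!is.finite(pixels))) abort("pixels must be finite")
  if (min(pixels) < 0 || max(pixels) > 255) {
    abort("intensities must lie in [0, 255]")
  }
  storage.mode(pixels) <- "double"
  pixels
}

img_width <- function(img) ncol(img)
img_height <- function(img) nrow(img)

#' Read / write 8-bit grayscale images
#'
#' PNG and TIFF are supported; color inputs are converted to grayscale by
#' Rec. 601 luminance.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @return `read_gray_image()` returns an intensity matrix in `[0, 255]`.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) abort(paste0("image file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    abort(paste0("unsupported image format: .", ext))
  )
  if (length(dim(a)) == 3) {
    ch <- dim(a)[3]
    a <- if (ch >= 3) {
      0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
    } else {
      a[, , 1]
    }
  }
  gray_image(pmin(pmax(a * 255, 0), 255))
}

#' @rdname read_gray_image
#' @param img intensity matrix in `[0, 255]`.
#' @export
write_gray_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  a <- pmin(pmax(img / 255, 0), 1)
  switch(ext,
    png = png::writePNG(a, path),
    tif = ,
    tiff = tiff::writeTIFF(a, path, bits.per.sample = 8L),
    abort(paste0("unsupported image format: .", ext))
  )
  invisible(path)
}

# Bilinear interpolation at real-valued (x, y), border-replicate.
# Returns intensities; coordinates outside [0, W-1] x [0, H-1] are clamped.
bilinear_sample <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  x <- pmin(pmax(x, 0), w - 1)
  y <- pmin(pmax(y, 0), h - 1)
  x0 <- floor(x); y0 <- floor(y)
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  fx <- x - x0; fy <- y - y0
  # matrix is [row = y + 1, col = x + 1]; linear index = row + (col - 1) * h
  i00 <- (y0 + 1) + x0 * h
  i10 <- (y0 + 1) + x1 * h
  i01 <- (y1 + 1) + x0 * h
  i11 <- (y1 + 1) + x1 * h
  (1 - fy) * ((1 - fx) * img[i00] + fx * img[i10]) +
    fy * ((1 - fx) * img[i01] + fx * img[i11])
}

# TRUE for samples whose (x, y) fell outside the image domain.
out_of_domain <- function(img, x, y) {
  x < 0 | x > ncol(img) - 1 | y < 0 | y > nrow(img) - 1
}

# EBImage bridge: EBImage stores images as [x, y]; we store [y, x].
as_ebimage <- function(img) EBImage::as.Image(t(img))
from_ebimage <- function(e) t(EBImage::imageData(e))

# Linear rescale of an arbitrary numeric matrix to [0, 255]; constant input
# maps to all-zeros.
rescale_255 <- function(m) {
  lo <- min(m); hi <- max(m)
  if (hi - lo <= .Machine$double.eps * max(1, abs(hi))) {
    return(matrix(0, nrow(m), ncol(m)))
  }
  pmin(pmax((m - lo) * (255 / (hi - lo)), 0), 255)
}
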