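#' Blur and invert
#'
#' First stage of the gradient-image construction: a Gaussian blur followed
#' by intensity inversion, so the dark vein pixels of the photograph become
#' bright.
#'
#' @param img intensity matrix in `[0, 255]`.
#' @param sigma Gaussian standard deviation in pixels (> 0).
#' @return intensity matrix `255 - blur(img)`.
#' @export
blur_invert <- function(img, sigma = 2) {
  if (sigma <= 0) abort("sigma must be > 0")
  b <- from_ebimage(EBImage::gblur(as_ebimage(img), sigma = sigma,
                                   boundary = "replicate"))
  255 - b
}

#' Edge map of the blurred image
#'
#' Sobel gradient magnitude thresholded by Otsu's method. A flat image
#' yields an empty edge set with a warning.
#'
#' @param blurred intensity matrix (typically the Gaussian-blurred input,
#'   before inversion).
#' @return logical matrix, `TRUE` on edge pixels.
#' @export
edge_binary <- function(blurred) {
  if (max(blurred) - min(blurred) <= 1e-9) {
    warn("flat image: empty edge set")
    return(matrix(FALSE, nrow(blurred), ncol(blurred)))
  }
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)  # d/dx, x = columns
  ky <- t(kx)                                          # d/dy, y = rows
  e <- as_ebimage(blurred)
  gx <- from_ebimage(EBImage::filter2(e, t(kx), boundary = "replicate"))
  gy <- from_ebimage(EBImage::filter2(e, t(ky), boundary = "replicate"))
  mag <- sqrt(gx^2 + gy^2)
  mag01 <- mag / max(mag)
  thr <- EBImage::otsu(as_ebimage(mag01), range = c(0, 1))
  mag01 > thr
}

#' Dilate the edge map and invert
#'
#' Morphological dilation with a disc brush thickens the detected vein
#' edges; the complement then marks everything away from veins as
#' foreground, ready for the distance transform.
#'
#' @param binary logical matrix (edge map).
#' @param r disc radius in pixels.
#' @return logical matrix, the complement of the dilated input.
#' @export
dilate_invert <- function(binary, r = 2) {
  if (!any(binary)) return(matrix(TRUE, nrow(binary), ncol(binary)))
  brush <- EBImage::makeBrush(2 * r + 1, shape = "disc")
  d <- from_ebimage(EBImage::dilate(as_ebimage(binary * 1), brush))
  !(d > 0.5)
}

#' Distance field from the veins, inverted
#'
#' Exact Euclidean distance of every pixel to the nearest vein (zero) pixel
#' of the mask, linearly rescaled to `[0, 255]` and inverted, so pixels on
#' veins are bright with a smooth downward gradient away from them.
#'
#' @param binary logical matrix with `FALSE` (zero) on the thickened veins
#'   (the output of [dilate_invert()]).
#' @return intensity matrix in `[0, 255]`.
#' @export
distance_field_invert <- function(binary) {
  if (all(binary)) abort("no vein support")
  d <- from_ebimage(EBImage::distmap(as_ebimage(binary * 1),
                                     metric = "euclidean"))
  255 - rescale_255(d)
}

#' Build the active-contour gradient image
#'
#' Runs the full preprocessing chain: blur + invert; Sobel edges of the
#' blurred image, Otsu threshold; disc dilation and complement; Euclidean
#' distance transform, rescale and invert; then the pixel-wise sum of the
#' blurred-inverted image and the inverted distance field, linearly rescaled
#' to `[0, 255]`. The result is bright on vein centrelines and decays
#' smoothly away from them, which is what guides the snake.
#'
#' @param img intensity matrix in `[0, 255]`.
#' @param sigma Gaussian blur standard deviation (px).
#' @param r dilation disc radius (px).
#' @return intensity matrix in `[0, 255]` with attribute `params`.
#' @export
build_gradient_image <- function(img, sigma = 2, r = 2) {
  blurred <- 255 - blur_invert(img, sigma)   # the blurred, un-inverted image
  bi <- 255 - blurred
  edges <- edge_binary(blurred)
  mask <- dilate_invert(edges, r)
  df <- distance_field_invert(mask)
  P <- rescale_255(bi + df)
  attr(P, "params") <- list(sigma = sigma, r = r)
  P
}
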