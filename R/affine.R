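#' Affine alignment from the three anchor points
#'
#' Each exemplar is aligned to the query by the unique affine transform that
#' maps its anchors `a`, `h`, `k` onto the user-clicked anchors of the query.
#' The correspondence is label-wise, never order-wise. With three point pairs
#' the 6 unknowns of the 2x3 matrix are determined exactly.
#'
#' @param src,dst key point tibbles each containing labels `a`, `h`, `k`.
#' @return a 2x3 matrix `T = [A | t]` of class `affine_transform`, mapping
#'   `(x, y) -> A %*% c(x, y) + t`.
#' @export
fit_affine <- function(src, dst) {
  s <- kp_matrix(src, anchor_labels())
  d <- kp_matrix(dst, anchor_labels())
  # degenerate when the source triangle collapses
  area <- abs((s[2, 1] - s[1, 1]) * (s[3, 2] - s[1, 2]) -
              (s[3, 1] - s[1, 1]) * (s[2, 2] - s[1, 2])) / 2
  if (!is.finite(area) || area <= 1e-6) abort("degenerate anchors")
  M <- cbind(s, 1)                       # 3 x 3: [x y 1]
  beta <- solve(M, d)                    # 3 x 2: columns (x', y')
  T <- t(beta)                           # 2 x 3: [A | t] with t last column
  T <- T[, c(1, 2, 3), drop = FALSE]
  structure(T, class = "affine_transform")
}

#' Apply an affine transform to points
#'
#' @param T 2x3 `affine_transform`.
#' @param pts `n x 2` matrix (or length-2 vector) of `(x, y)` coordinates.
#' @return `n x 2` matrix of transformed coordinates.
#' @export
apply_affine <- function(T, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  out <- sweep(pts %*% t(T[, 1:2, drop = FALSE]), 2, T[, 3], "+")
  dimnames(out) <- NULL
  out
}

#' @rdname apply_affine
#' @return `invert_affine()` returns the inverse transform.
#' @export
invert_affine <- function(T) {
  A <- T[, 1:2, drop = FALSE]
  if (abs(det(A)) < 1e-12) abort("affine transform is singular")
  Ai <- solve(A)
  structure(cbind(Ai, -Ai %*% T[, 3]), class = "affine_transform")
}

#' Map an exemplar's annotated key point into the query frame
#'
#' Fits the anchor affine from the exemplar to the query and maps the
#' exemplar's annotated location of `label` through it. The exemplar image is
#' never warped wholesale; only points (and, on demand, small patches via
#' [warp_patch()]) are transformed.
#'
#' @param wing fully annotated exemplar.
#' @param anchors_query key point tibble with the query's `a`, `h`, `k`.
#' @param label a non-anchor key point label.
#' @return length-2 `c(x, y)` in the query frame.
#' @export
map_exemplar_keypoint <- function(wing, anchors_query, label) {
  if (label %in% anchor_labels()) {
    abort("anchors are user-given, never predicted")
  }
  T <- fit_affine(wing$keypoints, anchors_query)
  drop(apply_affine(T, kp_xy(wing$keypoints, label)))
}

#' Warp a source patch into the destination frame
#'
#' Resamples a `(2 * half_size + 1)` square patch of the destination frame
#' centred at `center_dst`: each destination pixel is sampled from the source
#' image at `T^{-1}(p)` by bilinear interpolation with border replication.
#'
#' @param src source intensity matrix.
#' @param T `affine_transform` from source to destination frame.
#' @param center_dst length-2 destination centre `(x, y)`.
#' @param half_size patch half-size in pixels.
#' @return intensity matrix with attribute `oob_fraction`, the fraction of
#'   samples that fell outside the source; above 0.5 a warning flags the
#'   patch as low-confidence (attribute `low_confidence`).
#' @export
warp_patch <- function(src, T, center_dst, half_size) {
  Ti <- invert_affine(T)
  u <- seq(-half_size, half_size)
  gx <- center_dst[1] + rep(u, each = length(u))   # x varies over columns
  gy <- center_dst[2] + rep(u, times = length(u))  # y varies over rows
  sp <- apply_affine(Ti, cbind(gx, gy))
  oob <- mean(out_of_domain(src, sp[, 1], sp[, 2]))
  vals <- bilinear_sample(src, sp[, 1], sp[, 2])
  patch <- matrix(vals, nrow = length(u), ncol = length(u))
  attr(patch, "oob_fraction") <- oob
  if (oob > 0.5) {
    warn("more than half of the warped samples fall outside the source image")
    attr(patch, "low_confidence") <- TRUE
  }
  patch
}
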