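#' Wing centroid from the boundary octagon
#'
#' The wing centroid is the area-weighted centroid of the octagon with
#' vertices at key points `a, h, i, j, k, l, m, b` (in that fixed order).
#' It is computed by fan-triangulating the octagon from vertex `a` —
#' triangles (a,h,i), (a,i,j), (a,j,k), (a,k,l), (a,l,m), (a,m,b) — and
#' averaging the triangle centroids weighted by signed areas. For any simple
#' polygon this equals the closed-form (shoelace) polygon centroid, so the
#' result does not depend on the choice of triangulation.
#'
#' @param kps key point tibble containing the eight octagon labels.
#' @return list `(centroid = c(x, y), order, areas)`; a warning flags
#'   non-convex/self-intersecting octagons (the signed-area formula is still
#'   applied).
#' @export
wing_centroid <- function(kps) {
  ord <- c("a", "h", "i", "j", "k", "l", "m", "b")
  v <- kp_matrix(kps, ord)
  a <- v[1, ]
  tri_area <- numeric(6); tri_cx <- numeric(6); tri_cy <- numeric(6)
  for (t in 1:6) {
    p <- v[t + 1, ]; q <- v[t + 2, ]
    tri_area[t] <- ((p[1] - a[1]) * (q[2] - a[2]) -
                    (q[1] - a[1]) * (p[2] - a[2])) / 2
    tri_cx[t] <- (a[1] + p[1] + q[1]) / 3
    tri_cy[t] <- (a[2] + p[2] + q[2]) / 3
  }
  A <- sum(tri_area)
  if (abs(A) < 1e-9) abort("degenerate octagon: zero total area")
  if (any(sign(tri_area[tri_area != 0]) != sign(A))) {
    warn("octagon is non-convex or self-intersecting; signed areas used")
  }
  list(centroid = c(x = sum(tri_area * tri_cx) / A,
                    y = sum(tri_area * tri_cy) / A),
       order = ord, areas = tri_area)
}

#' Normalized centroid distances
#'
#' Euclidean distances from the wing centroid to the 13 key points, divided
#' by the wing length `|a - j|`. Scale-, rotation- and reflection-invariant.
#'
#' @param kps complete key point tibble.
#' @param centroid length-2 centroid; computed by [wing_centroid()] when
#'   `NULL`.
#' @return named numeric vector `d_a ... d_m`.
#' @export
normalized_distances <- function(kps, centroid = NULL) {
  if (!kp_complete(kps)) abort("complete 13-point set required")
  if (is.null(centroid)) centroid <- wing_centroid(kps)$centroid
  wl <- sqrt(sum((kp_xy(kps, "a") - kp_xy(kps, "j"))^2))
  if (wl <= 1e-12) abort("zero wing length")
  m <- kp_matrix(kps, keypoint_labels())
  d <- sqrt((m[, 1] - centroid[1])^2 + (m[, 2] - centroid[2])^2) / wl
  setNames(as.numeric(d), paste0("d_", keypoint_labels()))
}

#' Traditional wing indices
#'
#' `costal_index = lm / jl`, `c3_fringe = kl / jl`, `x5_index = gh / fg`,
#' computed from the five measured arc lengths. Invariant under uniform
#' scaling.
#'
#' @param arcs named numeric vector (or one-row data frame) of arc lengths
#'   with names from [arc_labels()], all > 0.
#' @return named numeric vector `(costal_index, c3_fringe, x5_index)`.
#' @export
wing_indices <- function(arcs) {
  arcs <- unlist(arcs)[arc_labels()]
  if (anyNA(arcs)) abort("all five arc lengths are required")
  for (nm in c("jl", "fg")) {
    if (arcs[[nm]] <= 0) abort(paste0("zero-length arc: ", nm))
  }
  c(costal_index = arcs[["lm"]] / arcs[["jl"]],
    c3_fringe = arcs[["kl"]] / arcs[["jl"]],
    x5_index = arcs[["gh"]] / arcs[["fg"]])
}

#' The 16-variable feature vector of one wing
#'
#' Thirteen normalized centroid distances plus the three wing indices, in
#' the canonical column order `d_a ... d_m, costal_index, c3_fringe,
#' x5_index`. Invariant under similarity transforms of the wing.
#'
#' @param kps complete key point tibble.
#' @param arcs named arc lengths (see [wing_indices()]).
#' @return one-row tibble with 16 named columns.
#' @export
feature_vector <- function(kps, arcs) {
  d <- normalized_distances(kps)
  idx <- wing_indices(arcs)
  tibble::as_tibble(as.list(c(d, idx)))
}

#' @rdname feature_vector
#' @return `feature_names()` gives the canonical 16 column names;
#'   `default_feature_subset()` the six variables used for the discriminant
#'   analysis by default (centroid distances of e, f, g, m plus the costal
#'   index and C3 fringe).
#' @export
feature_names <- function() {
  c(paste0("d_", keypoint_labels()), "costal_index", "c3_fringe", "x5_index")
}

#' @rdname feature_vector
#' @export
default_feature_subset <- function() {
  c("d_e", "d_f", "d_g", "d_m", "costal_index", "c3_fringe")
}
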