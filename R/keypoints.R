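#' Wing key point vocabulary
#'
#' The thirteen homologous wing landmarks are labelled `a` to `m`; most are
#' vein intersections, `k` is the boundary of the costal fringe. The three
#' anchors `a`, `h`, `k` are supplied by the user (clicked) and define the
#' affine alignment between a query wing and each exemplar; the remaining ten
#' are predicted by template matching.
#'
#' @return `keypoint_labels()` returns the 13 admissible labels;
#'   `anchor_labels()` the anchor subset `c("a", "h", "k")`;
#'   `arc_labels()` the five measured vein arcs.
#' @export
keypoint_labels <- function() {
  c("a", "b", "c", "d", "e", "f", "g", "h", "i", "j", "k", "l", "m")
}

#' @rdname keypoint_labels
#' @export
anchor_labels <- function() c("a", "h", "k")

#' @rdname keypoint_labels
#' @export
arc_labels <- function() c("fg", "gh", "jl", "kl", "lm")

#' Build a key point table
#'
#' Key point sets are plain tibbles with columns `label`, `x`, `y` (pixels,
#' 0-based, x = column, y = row). A set may be partial; a complete set has all
#' 13 labels exactly once.
#'
#' @param label character vector of labels from [keypoint_labels()].
#' @param x,y numeric coordinates in pixels.
#' @return A tibble with columns `label`, `x`, `y`.
#' @export
keypoints <- function(label, x, y) {
  stopifnot(length(label) == length(x), length(x) == length(y))
  bad <- setdiff(label, keypoint_labels())
  if (length(bad) > 0) {
    abort(paste0("unknown key point label(s): ", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(label)) abort("duplicate key point labels")
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort("key point coordinates must be finite")
  }
  tibble::tibble(label = as.character(label), x = as.numeric(x), y = as.numeric(y))
}

#' @rdname keypoints
#' @param kps a key point tibble.
#' @export
kp_complete <- function(kps) {
  setequal(kps$label, keypoint_labels()) && nrow(kps) == 13
}

#' Look up one key point as an `(x, y)` pair
#'
#' @param kps key point tibble.
#' @param label single label.
#' @return numeric length-2 vector `c(x, y)`.
#' @export
kp_xy <- function(kps, label) {
  i <- match(label, kps$label)
  if (is.na(i)) abort(paste0("key point '", label, "' not present"))
  c(kps$x[i], kps$y[i])
}

#' @rdname kp_xy
#' @param labels labels to extract, in order.
#' @return `kp_matrix()` returns an `n x 2` matrix with rows in `labels` order.
#' @export
kp_matrix <- function(kps, labels = kps$label) {
  i <- match(labels, kps$label)
  if (anyNA(i)) {
    abort(paste0("missing key point(s): ",
                 paste(labels[is.na(i)], collapse = ", ")))
  }
  m <- cbind(x = kps$x[i], y = kps$y[i])
  rownames(m) <- labels
  m
}
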