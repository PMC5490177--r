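#' Range-normalize a patch
#'
#' Linearly maps patch intensities so the minimum becomes 0 and the maximum
#' 255; a constant patch maps to all zeros. Applied to both template and
#' candidate patches before the Euclidean match score, making the matcher
#' insensitive to local brightness and contrast.
#'
#' @param p intensity matrix.
#' @return normalized matrix of the same shape.
#' @export
normalize_patch <- function(p) {
  lo <- min(p); hi <- max(p)
  if (hi - lo <= 1e-12) return(matrix(0, nrow(p), ncol(p)))
  (p - lo) * (255 / (hi - lo))
}

#' Extract a (possibly rotated) square patch
#'
#' Samples a `(2 * half_size + 1)` square grid centred at `(x, y)` and
#' rotated by `theta` degrees about the centre, by bilinear interpolation
#' with border replication.
#'
#' @param img intensity matrix.
#' @param x,y real-valued patch centre (0-based pixel coordinates).
#' @param theta rotation in degrees.
#' @param half_size patch half-size in pixels.
#' @return intensity matrix `[row = y-offset, col = x-offset]`.
#' @export
extract_rotated_patch <- function(img, x, y, theta, half_size) {
  if (out_of_domain(img, x, y)) abort("patch centre outside image")
  if (!is.finite(theta)) abort("theta must be finite")
  u <- seq(-half_size, half_size)
  gx <- rep(u, each = length(u))    # x offset, varies over columns
  gy <- rep(u, times = length(u))   # y offset, varies over rows
  th <- theta * pi / 180
  rx <- cos(th) * gx - sin(th) * gy
  ry <- sin(th) * gx + cos(th) * gy
  matrix(bilinear_sample(img, x + rx, y + ry),
         nrow = length(u), ncol = length(u))
}

#' Euclidean match score between a template and a shifted query window
#'
#' The score is the Euclidean norm of the pixel-wise difference between the
#' range-normalized template and the range-normalized query patch extracted
#' at the shifted centre `(x' - c_x, y' - c_y)` (unrotated). Normalization is
#' applied per candidate window, i.e. the query patch is re-extracted and
#' re-normalized at every shift. Zero iff the normalized patches coincide.
#' Minimizing this norm is equivalent to minimizing the summed squared
#' differences.
#'
#' @param template template patch (unnormalized is fine; normalized
#'   internally).
#' @param query_img query intensity matrix.
#' @param target_center length-2 mapped location `(x', y')`.
#' @param cx,cy integer shift of the window centre.
#' @return non-negative scalar score.
#' @export
match_score <- function(template, query_img, target_center, cx, cy) {
  half <- (nrow(template) - 1) / 2
  q <- extract_rotated_patch(query_img, target_center[1] - cx,
                             target_center[2] - cy, 0, half)
  if (!all(dim(q) == dim(template))) abort("patch size mismatch")
  sqrt(sum((normalize_patch(template) - normalize_patch(q))^2))
}

# Extract the query search region around a real-valued centre: a square of
# side 2 * (search + half) + 1 on the integer-offset grid anchored at the
# centre (border-replicate).
extract_region <- function(img, center, half, search) {
  extract_rotated_patch(img, center[1], center[2], 0, half + search)
}

# Build the n_theta rotated, range-normalized templates for one exemplar and
# label, sampled through the exemplar's alignment transform:
# template pixel at rotated offset (u, v) from the mapped centre samples the
# exemplar source at Q^{-1}(centre + R_theta (u, v)).
exemplar_templates <- function(wing, T, center, label, half, theta_set) {
  Ti <- invert_affine(T)
  u <- seq(-half, half)
  gx <- rep(u, each = length(u))
  gy <- rep(u, times = length(u))
  out <- matrix(0, length(gx), length(theta_set))
  for (k in seq_along(theta_set)) {
    th <- theta_set[k] * pi / 180
    rx <- cos(th) * gx - sin(th) * gy
    ry <- sin(th) * gx + cos(th) * gy
    sp <- apply_affine(Ti, cbind(center[1] + rx, center[2] + ry))
    vals <- exemplar_sample(wing, label, sp[, 1], sp[, 2])
    out[, k] <- as.vector(normalize_patch(
      matrix(vals, length(u), length(u))))
  }
  out
}

#' Detect one key point by exhaustive template matching
#'
#' For every exemplar the anchor affine maps its annotated location of
#' `label` into the query frame; five rotated templates (default
#' `theta = -10, -5, 0, 5, 10` degrees) are matched against query windows at
#' every integer shift within the search radius, and the global minimum of
#' the normalized Euclidean score over (shift, angle, exemplar) yields the
#' prediction `(x' - c_x*, y' - c_y*)`. Ties break lexicographically by
#' (exemplar, angle, shift) so runs are deterministic.
#'
#' @param image query intensity matrix.
#' @param anchors key point tibble with the user-clicked `a`, `h`, `k`.
#' @param library non-empty list of fully annotated exemplars.
#' @param label non-anchor key point label to predict.
#' @param template_half template half-size in pixels; default 24 at reference
#'   resolution, scaled by `scale`.
#' @param search shift search radius in pixels (`|c_x|, |c_y| <= search`);
#'   default 15 at reference resolution, scaled by `scale`.
#' @param theta_set template rotation angles in degrees.
#' @param scale query resolution relative to the reference resolution;
#'   pixel-unit defaults scale linearly with it.
#' @return a one-row tibble: `label, x, y, score, exemplar, theta, cx, cy`.
#' @export
detect_keypoint <- function(image, anchors, library, label,
                            template_half = NULL, search = NULL,
                            theta_set = c(-10, -5, 0, 5, 10), scale = 1) {
  if (length(library) == 0) abort("exemplar library is empty")
  transforms <- lapply(library, function(w) fit_affine(w$keypoints, anchors))
  detect_keypoint_impl(image, anchors, library, transforms, label,
                       template_half, search, theta_set, scale)
}

detect_keypoint_impl <- function(image, anchors, library, transforms, label,
                                 template_half, search, theta_set, scale) {
  if (label %in% anchor_labels()) {
    abort("anchors are user-given, never predicted")
  }
  if (is.null(template_half)) template_half <- max(3L, round(24 * scale))
  if (is.null(search)) search <- max(2L, round(15 * scale))
  theta_set <- sort(theta_set)
  best <- NULL
  n_usable <- 0
  for (m in seq_along(library)) {
    wing <- library[[m]]
    T <- transforms[[m]]
    center <- drop(apply_affine(T, kp_xy(wing$keypoints, label)))
    if (out_of_domain(image, center[1], center[2])) next
    n_usable <- n_usable + 1
    region <- extract_region(image, center, template_half, search)
    tmpl <- exemplar_templates(wing, T, center, label, template_half,
                               theta_set)
    r <- match_grid_cpp(region, tmpl, as.integer(template_half),
                        as.integer(search))
    if (is.null(best) || r[1] < best$score) {
      best <- list(score = r[1], cx = r[2], cy = r[3],
                   theta = theta_set[r[4]], m = m, center = center)
    }
  }
  if (n_usable == 0) abort("search region outside image")
  tibble::tibble(
    label = label,
    x = best$center[1] - best$cx,
    y = best$center[2] - best$cy,
    score = best$score,
    exemplar = library[[best$m]]$id,
    theta = best$theta,
    cx = best$cx, cy = best$cy
  )
}

#' Detect all ten non-anchor key points
#'
#' Runs [detect_keypoint()] independently for every non-anchor label and
#' returns the full 13-point set: the three user anchors plus ten
#' predictions, with the per-point match diagnostics retained.
#'
#' @inheritParams detect_keypoint
#' @return tibble with columns `label, x, y, source, score, exemplar, theta,
#'   cx, cy`; anchors carry `source = "anchor"` and `NA` diagnostics.
#' @export
detect_all_keypoints <- function(image, anchors, library,
                                 template_half = NULL, search = NULL,
                                 theta_set = c(-10, -5, 0, 5, 10),
                                 scale = 1) {
  if (length(library) == 0) abort("exemplar library is empty")
  transforms <- lapply(library, function(w) fit_affine(w$keypoints, anchors))
  labels <- setdiff(keypoint_labels(), anchor_labels())
  preds <- list()
  errors <- character()
  for (lab in labels) {
    res <- tryCatch(
      detect_keypoint_impl(image, anchors, library, transforms, lab,
                           template_half, search, theta_set, scale),
      error = function(e) conditionMessage(e)
    )
    if (is.character(res)) {
      errors[lab] <- res
    } else {
      preds[[lab]] <- res
    }
  }
  anchor_rows <- anchors |>
    dplyr::filter(.data$label %in% anchor_labels()) |>
    dplyr::transmute(.data$label, .data$x, .data$y, source = "anchor",
                     score = NA_real_, exemplar = NA_character_,
                     theta = NA_real_, cx = NA_real_, cy = NA_real_)
  pred_rows <- dplyr::bind_rows(preds)
  if (nrow(pred_rows) > 0) pred_rows$source <- "predicted"
  out <- dplyr::bind_rows(anchor_rows, pred_rows) |>
    dplyr::arrange(match(.data$label, keypoint_labels()))
  if (length(errors) > 0) attr(out, "errors") <- errors
  out
}
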