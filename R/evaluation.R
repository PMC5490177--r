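#' Inter-annotator covariance of one key point
#'
#' Sample covariance (n - 1 denominator) of k repeat annotations of the
#' same key point on the same image.
#'
#' @param points `k x 2` matrix or data frame of `(x, y)` annotations,
#'   k >= 2.
#' @return symmetric 2x2 covariance matrix (px^2).
#' @export
annotation_covariance <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2) abort("need at least 2 annotations")
  cov(points)
}

#' Average covariance across images
#'
#' Element-wise mean and standard deviation of per-image 2x2 covariance
#' matrices, the form in which multi-annotator spreads are reported.
#'
#' @param per_image non-empty list of 2x2 matrices.
#' @return list `(mean, sd)` of 2x2 matrices.
#' @export
average_covariance <- function(per_image) {
  if (length(per_image) == 0) abort("empty covariance list")
  arr <- simplify2array(per_image)
  m <- apply(arr, c(1, 2), mean)
  s <- if (length(per_image) == 1) {
    matrix(0, 2, 2)
  } else {
    apply(arr, c(1, 2), stats::sd)
  }
  list(mean = m, sd = s)
}

#' Reference annotator covariances
#'
#' Bundled per-key-point 2x2 covariance matrices (px^2 at the reference
#' image resolution) summarizing the spread of repeated manual annotations
#' of each landmark by multiple annotators. Landmarks `a`, `b`, `c`, `k`
#' and `m` show the largest spread — they are genuinely hard to place by
#' eye. These matrices are the default yardstick for the 2-standard-
#' deviation accuracy criterion and the default anchor-click jitter of the
#' synthetic generator.
#'
#' @param scale resolution ratio relative to the reference resolution;
#'   covariances scale with `scale^2`.
#' @return named list of 13 2x2 matrices.
#' @export
annotator_covariances <- function(scale = 1) {
  cov2 <- function(xx, xy, yy) matrix(c(xx, xy, xy, yy), 2, 2)
  base <- list(
    a = cov2(9.06, -0.127, 6.20),
    b = cov2(16.3, 5.22, 5.17),
    c = cov2(12.1, -2.50, 2.75),
    d = cov2(2.47, -0.0481, 1.40),
    e = cov2(1.99, 0.0319, 2.07),
    f = cov2(1.72, -0.0474, 1.38),
    g = cov2(2.35, 0.263, 2.21),
    h = cov2(2.43, 0.259, 2.06),
    i = cov2(2.22, -0.141, 1.35),
    j = cov2(2.41, 0.190, 1.81),
    k = cov2(12.3, 6.16, 8.91),
    l = cov2(5.21, -1.43, 1.97),
    m = cov2(13.5, -3.64, 9.09)
  )
  lapply(base, function(m) m * scale^2)
}

#' Two-standard-deviation accuracy criterion
#'
#' A prediction counts as accurate when its Euclidean distance to the
#' ground truth does not exceed two standard deviations derived from the
#' key point's annotator covariance. "Two standard deviations of a 2x2
#' covariance" is reduced to a scalar threshold by `sd_mode`:
#' `"max-eig"` (default, most conservative axis-aligned reading)
#' uses `2 * sqrt(lambda_max)`; `"mean-diag"` uses
#' `2 * sqrt(mean(diag))`; `"mahalanobis"` tests the Mahalanobis distance
#' of the deviation against 2.
#'
#' @param pred,truth length-2 points `(x, y)`.
#' @param cov 2x2 positive semi-definite covariance (px^2).
#' @param sd_mode threshold reading, see above.
#' @return logical.
#' @export
within_two_sd <- function(pred, truth, cov,
                          sd_mode = c("max-eig", "mean-diag",
                                      "mahalanobis")) {
  sd_mode <- match.arg(sd_mode)
  d <- pred - truth
  if (sd_mode == "mahalanobis") {
    z <- backsolve(chol(cov), d, transpose = TRUE)
    return(sqrt(sum(z^2)) <= 2)
  }
  s2 <- switch(sd_mode,
    "max-eig" = max(eigen(cov, symmetric = TRUE, only.values = TRUE)$values),
    "mean-diag" = mean(diag(cov))
  )
  sqrt(sum(d^2)) <= 2 * sqrt(s2)
}

#' Key point accuracy report
#'
#' Per-label percentage of predictions within the 2-standard-deviation
#' criterion plus the mean and standard deviation of the Euclidean pixel
#' deviation. The user-annotated anchors `a`, `h`, `k` are excluded.
#'
#' @param preds,truths tibbles with columns `wing_id` (optional), `label`,
#'   `x`, `y`, aligned by (wing, label).
#' @param covs named list of 2x2 covariances (defaults to
#'   [annotator_covariances()]).
#' @param sd_mode passed to [within_two_sd()].
#' @return tibble `label, n, pct_within_2sd, mean_dev, sd_dev`.
#' @export
accuracy_report <- function(preds, truths, covs = annotator_covariances(),
                            sd_mode = "max-eig") {
  if (nrow(preds) == 0) abort("empty predictions")
  if (!"wing_id" %in% names(preds)) preds$wing_id <- "w"
  if (!"wing_id" %in% names(truths)) truths$wing_id <- "w"
  joined <- dplyr::inner_join(
    preds |> dplyr::select("wing_id", "label", px = "x", py = "y"),
    truths |> dplyr::select("wing_id", "label", tx = "x", ty = "y"),
    by = c("wing_id", "label")
  ) |>
    dplyr::filter(!.data$label %in% anchor_labels())
  if (nrow(joined) == 0) abort("no non-anchor predictions to score")
  joined |>
    dplyr::mutate(
      dev = sqrt((.data$px - .data$tx)^2 + (.data$py - .data$ty)^2),
      within = purrr::pmap_lgl(
        list(.data$px, .data$py, .data$tx, .data$ty, .data$label),
        function(px, py, tx, ty, lab) {
          within_two_sd(c(px, py), c(tx, ty), covs[[lab]], sd_mode)
        })
    ) |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(
      n = dplyr::n(),
      pct_within_2sd = 100 * mean(.data$within),
      mean_dev = mean(.data$dev),
      sd_dev = stats::sd(.data$dev),
      .groups = "drop"
    )
}

#' Area-based arc error
#'
#' The error of a traced arc against its annotated ground truth is the
#' area enclosed between the two curves divided by the length of the
#' annotated arc (units: px). Both curves are resampled to a dense common
#' arc-length parameterization, joined into a closed loop (prediction
#' forward, truth reversed, endpoints bridged if they differ), and the
#' loop is split at its self-crossings so that lobes on opposite sides
#' accumulate rather than cancel.
#'
#' @param pred,truth polyline matrices (`k x 2`); truth must have positive
#'   length.
#' @param n_dense resampling density (points per curve).
#' @return list `(area, normalized, truth_length)`.
#' @export
arc_area_error <- function(pred, truth, n_dense = 512) {
  lt <- arc_length(truth)
  if (lt <= 1e-9) abort("degenerate ground-truth arc")
  p <- resample_polyline(pred, n_dense - 1)
  t <- resample_polyline(truth, n_dense - 1)
  loop <- rbind(p, t[rev(seq_len(nrow(t))), ])
  area <- polyline_loop_area(loop)
  list(area = area, normalized = area / lt, truth_length = lt)
}

# Total unsigned area of a closed polygonal loop, splitting at
# self-intersections so that crossing lobes add instead of cancelling.
polyline_loop_area <- function(loop) {
  # drop consecutive duplicates
  keep <- c(TRUE, rowSums(abs(diff(loop))) > 1e-12)
  loop <- loop[keep, , drop = FALSE]
  n <- nrow(loop)
  if (n < 3) return(0)
  # edges i: loop[i] -> loop[i+1], last edge closes the loop
  a <- loop
  b <- loop[c(2:n, 1), , drop = FALSE]
  pts <- split_at_crossings(a, b)
  decompose_loop_area(pts)
}

# Insert pairwise edge-intersection points into the vertex sequence.
split_at_crossings <- function(a, b) {
  n <- nrow(a)
  inserts <- vector("list", n)
  # bounding-box prefilter
  minx <- pmin(a[, 1], b[, 1]); maxx <- pmax(a[, 1], b[, 1])
  miny <- pmin(a[, 2], b[, 2]); maxy <- pmax(a[, 2], b[, 2])
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    js <- js[!(i == 1 & js == n)]  # skip edges adjacent through the closure
    if (length(js) == 0) next
    cand <- js[maxx[js] >= minx[i] & minx[js] <= maxx[i] &
               maxy[js] >= miny[i] & miny[js] <= maxy[i]]
    for (j in cand) {
      r <- b[i, ] - a[i, ]; s <- b[j, ] - a[j, ]
      denom <- r[1] * s[2] - r[2] * s[1]
      if (abs(denom) < 1e-12) next
      qp <- a[j, ] - a[i, ]
      t <- (qp[1] * s[2] - qp[2] * s[1]) / denom
      u <- (qp[1] * r[2] - qp[2] * r[1]) / denom
      if (t > 1e-9 && t < 1 - 1e-9 && u > 1e-9 && u < 1 - 1e-9) {
        pt <- a[i, ] + t * r
        inserts[[i]] <- rbind(inserts[[i]], c(t, pt))
        inserts[[j]] <- rbind(inserts[[j]], c(u, pt))
      }
    }
  }
  out <- list()
  for (i in seq_len(n)) {
    out[[length(out) + 1]] <- a[i, , drop = FALSE]
    ins <- inserts[[i]]
    if (!is.null(ins)) {
      ins <- ins[order(ins[, 1]), , drop = FALSE]
      out[[length(out) + 1]] <- ins[, 2:3, drop = FALSE]
    }
  }
  do.call(rbind, out)
}

# Walk the closed vertex sequence; whenever a vertex repeats a location
# already on the open path, pop that sub-loop and add its unsigned
# shoelace area.
decompose_loop_area <- function(pts) {
  key <- function(p) paste(round(p[1], 6), round(p[2], 6))
  shoelace <- function(v) {
    n <- nrow(v)
    if (n < 3) return(0)
    x <- v[, 1]; y <- v[, 2]
    xn <- x[c(2:n, 1)]; yn <- y[c(2:n, 1)]
    abs(sum(x * yn - xn * y)) / 2
  }
  path <- matrix(numeric(0), 0, 2)
  seen <- new.env(parent = emptyenv())
  total <- 0
  for (i in seq_len(nrow(pts))) {
    k <- key(pts[i, ])
    pos <- seen[[k]]
    if (!is.null(pos)) {
      sub <- path[pos:nrow(path), , drop = FALSE]
      total <- total + shoelace(sub)
      if (pos > 1) {
        drop_keys <- apply(path[(pos + 1):nrow(path), , drop = FALSE], 1, key)
        for (dk in drop_keys) rm(list = dk, envir = seen)
        path <- path[1:pos, , drop = FALSE]
      } else {
        for (dk in ls(seen)) rm(list = dk, envir = seen)
        path <- pts[i, , drop = FALSE]
        seen[[k]] <- 1
      }
    } else {
      path <- rbind(path, pts[i, ])
      seen[[k]] <- nrow(path)
    }
  }
  total + shoelace(path)
}
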