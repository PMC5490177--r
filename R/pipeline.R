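#' Run the full measurement pipeline on a set of query wings
#'
#' For each query: detect the ten non-anchor key points against the
#' exemplar library, build the gradient image, trace and measure the five
#' arcs, derive the 16-variable feature vector, and (when a fitted
#' discriminant is supplied) classify the wing. Failures are isolated per
#' wing: one corrupt query does not stop the batch.
#'
#' @param library exemplar library (list of [annotated_wing()]).
#' @param queries list of queries, each a list with fields `id`, `image`
#'   (intensity matrix) and `anchors` (key point tibble with `a`, `h`,
#'   `k`).
#' @param fit optional [fit_groups()] object for classification.
#' @param scale query resolution ratio (drives pixel-unit defaults).
#' @param cfg [snake_config()] for arc tracing.
#' @param overrides optional tibble of manual corrections, see
#'   [apply_overrides()].
#' @param significance chi-square rejection level.
#' @return list of tibbles: `points`, `arcs`, `features`, `calls`,
#'   `errors`.
#' @export
run_pipeline <- function(library, queries, fit = NULL, scale = 1,
                         cfg = snake_config(), overrides = NULL,
                         significance = 0.001) {
  tmpl <- wing_template(scale = scale)
  points <- list(); arcs <- list(); feats <- list(); errors <- list()
  for (q in queries) {
    res <- tryCatch({
      kps <- detect_all_keypoints(q$image, q$anchors, library, scale = scale)
      kps$wing_id <- q$id
      kps <- apply_point_overrides(kps, overrides, q$id)
      P <- build_gradient_image(q$image)
      ma <- measure_arcs(kps, P, tmpl = tmpl, cfg = cfg, scale = scale)
      at <- ma$arcs; at$wing_id <- q$id
      at <- apply_arc_overrides(at, overrides, q$id)
      fv <- feature_vector(kps, setNames(at$length_px, at$arc))
      fv$wing_id <- q$id
      list(points = kps, arcs = at, features = fv)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      errors[[q$id]] <- tibble::tibble(wing_id = q$id, error = res)
    } else {
      points[[q$id]] <- res$points
      arcs[[q$id]] <- res$arcs
      feats[[q$id]] <- res$features
    }
  }
  features <- dplyr::bind_rows(feats)
  calls <- NULL
  if (!is.null(fit) && nrow(features) > 0) {
    calls <- classify(features, fit, significance)
    calls$wing_id <- features$wing_id
  }
  list(points = dplyr::bind_rows(points), arcs = dplyr::bind_rows(arcs),
       features = features, calls = calls,
       errors = dplyr::bind_rows(errors))
}

#' Manual override of detected points or measured arcs
#'
#' The interactive correction affordance, realized as data: a tibble of
#' corrections with columns `wing_id`, `kind` (`"point"` or `"arc"`),
#' `target` (key point label or arc label) and the replacement values
#' (`x`, `y` for points; `length_px` for arcs). Downstream stages consume
#' the corrected values; corrected rows are marked `source = "manual"`.
#'
#' @param tbl a points or arcs tibble from the pipeline.
#' @param overrides the corrections tibble (or `NULL` for no-op).
#' @param wing_id which wing to apply corrections for.
#' @return the corrected tibble.
#' @export
apply_overrides <- function(tbl, overrides, wing_id) {
  if ("arc" %in% names(tbl)) {
    apply_arc_overrides(tbl, overrides, wing_id)
  } else {
    apply_point_overrides(tbl, overrides, wing_id)
  }
}

apply_point_overrides <- function(points, overrides, wing_id) {
  ov <- filter_overrides(overrides, wing_id, "point")
  if (is.null(ov) || nrow(ov) == 0) return(points)
  for (i in seq_len(nrow(ov))) {
    j <- match(ov$target[i], points$label)
    if (is.na(j)) abort(paste0("override for unknown key point '",
                               ov$target[i], "'"))
    points$x[j] <- ov$x[i]; points$y[j] <- ov$y[i]
    points$source[j] <- "manual"
  }
  points
}

apply_arc_overrides <- function(arcs, overrides, wing_id) {
  ov <- filter_overrides(overrides, wing_id, "arc")
  if (is.null(ov) || nrow(ov) == 0) return(arcs)
  if (!"source" %in% names(arcs)) arcs$source <- "traced"
  for (i in seq_len(nrow(ov))) {
    j <- match(ov$target[i], arcs$arc)
    if (is.na(j)) abort(paste0("override for unknown arc '",
                               ov$target[i], "'"))
    arcs$length_px[j] <- ov$length_px[i]
    arcs$source[j] <- "manual"
  }
  arcs
}

filter_overrides <- function(overrides, wing, kind) {
  if (is.null(overrides)) return(NULL)
  overrides[overrides$wing_id == wing & overrides$kind == kind, ,
            drop = FALSE]
}
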