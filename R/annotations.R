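#' Annotated exemplar wings
#'
#' An annotated wing bundles a complete 13-point annotation with its species
#' and sex labels and, optionally, the source image or a per-landmark patch
#' cache. Annotated wings form the exemplar library used for template
#' matching.
#'
#' @param id wing identifier (character).
#' @param species,sex text labels; `sex` one of `"female"`, `"male"`,
#'   `"unknown"`.
#' @param keypoints complete key point tibble (see [keypoints()]).
#' @param image optional intensity matrix.
#' @param patches optional patch cache built by [build_patch_cache()].
#' @param scale resolution of this wing relative to the reference resolution
#'   (1 = full resolution). Pixel-unit defaults elsewhere (template size,
#'   search radius, patch cache size) scale linearly with this ratio.
#' @return an object of class `annotated_wing`.
#' @export
annotated_wing <- function(id, species, sex = "unknown", keypoints,
                           image = NULL, patches = NULL, scale = 1) {
  if (!sex %in% c("female", "male", "unknown")) {
    abort("sex must be 'female', 'male' or 'unknown'")
  }
  if (!kp_complete(keypoints)) {
    abort(paste0("wing '", id, "': key point set incomplete"))
  }
  structure(
    list(id = as.character(id), species = as.character(species), sex = sex,
         keypoints = keypoints, image = image, patches = patches,
         scale = as.numeric(scale)),
    class = "annotated_wing"
  )
}

#' @export
print.annotated_wing <- function(x, ...) {
  cat("<annotated_wing>", x$id, "-", x$species, paste0("(", x$sex, ")"),
      "scale", x$scale,
      if (!is.null(x$image)) "[image]" else "",
      if (!is.null(x$patches)) "[patch cache]" else "", "\n")
  invisible(x)
}

#' Read and write wing annotations
#'
#' Annotations are stored as diff-able CSV, one row per key point, columns
#' `wing_id, species, sex, label, x, y, scale` (UTF-8, `.` decimal
#' separator). Records missing any of the 13 labels are excluded from the
#' returned library with a warning; a fully absent coordinate is a hard
#' error.
#'
#' @param path CSV file path.
#' @param image_dir optional directory of images named `<wing_id>.png`; when
#'   given, images are loaded eagerly and a missing file is an error naming
#'   the wing.
#' @return a list of [annotated_wing()] objects.
#' @export
read_annotations <- function(path, image_dir = NULL) {
  if (!file.exists(path)) abort(paste0("annotation file not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("wing_id", "species", "sex", "label", "x", "y")
  if (!all(need %in% names(df))) {
    abort(paste0("annotation CSV must have columns ",
                 paste(need, collapse = ", ")))
  }
  if (!"scale" %in% names(df)) df$scale <- 1
  wings <- df |>
    dplyr::group_by(.data$wing_id) |>
    dplyr::group_split()
  out <- list()
  for (g in wings) {
    id <- g$wing_id[1]
    if (!setequal(g$label, keypoint_labels()) || nrow(g) != 13) {
      warn(paste0("wing '", id, "' lacks a complete 13-point set; excluded"))
      next
    }
    img <- NULL
    if (!is.null(image_dir)) {
      f <- file.path(image_dir, paste0(id, ".png"))
      if (!file.exists(f)) {
        f2 <- file.path(image_dir, paste0(id, ".tif"))
        if (!file.exists(f2)) {
          abort(paste0("image file missing for wing '", id, "'"))
        }
        f <- f2
      }
      img <- read_gray_image(f)
    }
    out[[length(out) + 1]] <- annotated_wing(
      id = id, species = g$species[1], sex = g$sex[1],
      keypoints = keypoints(g$label, g$x, g$y),
      image = img, scale = g$scale[1]
    )
  }
  out
}

#' @rdname read_annotations
#' @param wings non-empty list of [annotated_wing()] objects.
#' @export
write_annotations <- function(wings, path) {
  if (length(wings) == 0) abort("no wings to write")
  rows <- purrr::map_dfr(wings, function(w) {
    if (nrow(w$keypoints) == 0) abort("wing with empty key point set")
    k <- dplyr::arrange(w$keypoints,
                        match(.data$label, keypoint_labels()))
    tibble::tibble(wing_id = w$id, species = w$species, sex = w$sex,
                   label = k$label, x = k$x, y = k$y, scale = w$scale)
  })
  readr::write_csv(rows, path, progress = FALSE)
  invisible(path)
}

#' Crop and cache landmark-centred patches
#'
#' Only pixels near the annotated key points are ever needed for template
#' matching, so exemplars can drop the full raster and keep one square patch
#' per landmark. Patches are clipped at image borders and their offset in the
#' source frame is recorded.
#'
#' @param wing an [annotated_wing()] with its image loaded.
#' @param half_size patch half-size in pixels; the cached patch spans
#'   `2 * half_size + 1` pixels per side before clipping. Must accommodate
#'   the template half-size plus the shift search radius plus rotation
#'   margin. Default 64 px at reference resolution, scaled by the wing's
#'   resolution ratio.
#' @return the wing with a `patches` field: per label a list
#'   `(pixels, x0, y0)` where `(x0, y0)` is the source coordinate of the
#'   patch's first pixel.
#' @export
build_patch_cache <- function(wing, half_size = NULL) {
  if (is.null(wing$image)) abort("wing image not loaded")
  if (is.null(half_size)) half_size <- max(8L, round(64 * wing$scale))
  img <- wing$image
  w <- ncol(img); h <- nrow(img)
  cache <- list()
  for (i in seq_len(nrow(wing$keypoints))) {
    lab <- wing$keypoints$label[i]
    cx <- wing$keypoints$x[i]; cy <- wing$keypoints$y[i]
    if (cx < 0 || cx > w - 1 || cy < 0 || cy > h - 1) {
      abort(paste0("key point '", lab, "' outside image bounds"))
    }
    x0 <- max(0L, floor(cx) - half_size)
    x1 <- min(w - 1L, floor(cx) + half_size)
    y0 <- max(0L, floor(cy) - half_size)
    y1 <- min(h - 1L, floor(cy) + half_size)
    cache[[lab]] <- list(
      pixels = img[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1), drop = FALSE],
      x0 = x0, y0 = y0
    )
  }
  wing$patches <- structure(cache, half_size = half_size,
                            src_width = w, src_height = h)
  wing
}

# Sample an exemplar at real-valued source coordinates, preferring the patch
# cache for `label` when the full image is absent. Border-replicate.
exemplar_sample <- function(wing, label, x, y) {
  if (!is.null(wing$image)) {
    return(bilinear_sample(wing$image, x, y))
  }
  p <- wing$patches[[label]]
  if (is.null(p)) abort(paste0("no image or cached patch for '", label, "'"))
  bilinear_sample(p$pixels, x - p$x0, y - p$y0)
}

#' Write / read a patch cache as plain files
#'
#' One directory per wing: `<label>.png` patches plus `offsets.json`.
#'
#' @param wing an [annotated_wing()] with `patches` built.
#' @param dir output directory (created).
#' @export
write_patch_cache <- function(wing, dir) {
  if (is.null(wing$patches)) abort("no patch cache to write")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  off <- list()
  for (lab in names(wing$patches)) {
    p <- wing$patches[[lab]]
    write_gray_image(p$pixels, file.path(dir, paste0(lab, ".png")))
    off[[lab]] <- list(x0 = p$x0, y0 = p$y0)
  }
  meta <- list(offsets = off,
               half_size = attr(wing$patches, "half_size"),
               src_width = attr(wing$patches, "src_width"),
               src_height = attr(wing$patches, "src_height"))
  jsonlite::write_json(meta, file.path(dir, "offsets.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_patch_cache
#' @export
read_patch_cache <- function(wing, dir) {
  meta <- jsonlite::read_json(file.path(dir, "offsets.json"),
                              simplifyVector = TRUE)
  cache <- list()
  for (lab in names(meta$offsets)) {
    cache[[lab]] <- list(
      pixels = read_gray_image(file.path(dir, paste0(lab, ".png"))),
      x0 = meta$offsets[[lab]]$x0, y0 = meta$offsets[[lab]]$y0
    )
  }
  wing$patches <- structure(cache, half_size = meta$half_size,
                            src_width = meta$src_width,
                            src_height = meta$src_height)
  wing
}
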