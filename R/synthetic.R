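# Canonical wing geometry, defined once at the reference resolution
# (1936 x 1288 frame). Key points sit at vein junctions; the costal margin
# runs b - m - l - k - j, the posterior margin a - h - i - j. Key point k is
# equidistant to j and l within 5% (template-choice rule for arc mapping).
canonical_keypoints <- function() {
  keypoints(
    label = c("a", "b", "c", "d", "e", "f", "g", "h", "i", "j", "k", "l", "m"),
    x = c(150, 350, 450, 850, 1250, 900, 950, 700, 1300, 1800, 1470, 1100, 700),
    y = c(600, 330, 430, 420, 480, 630, 830, 1000, 900, 520, 340, 210, 230)
  )
}

# Vein strokes as quadratic Bezier chains between key points. `bulge` is the
# perpendicular offset (px, reference scale) of the control point from the
# chord midpoint, along the left normal of (from -> to).
canonical_strokes <- function() {
  seg <- function(from, to, bulge) list(from = from, to = to, bulge = bulge)
  list(
    margin_top = list(seg("a", "b", 12), seg("b", "m", 25), seg("m", "l", 18),
                      seg("l", "k", 8), seg("k", "j", 12)),
    margin_bottom = list(seg("a", "h", -40), seg("h", "i", -30),
                         seg("i", "j", -35)),
    mid_vein = list(seg("a", "c", 8), seg("c", "d", -6), seg("d", "e", 8),
                    seg("e", "j", -10)),
    cross_cm = list(seg("c", "m", 10)),
    cross_dl = list(seg("d", "l", 8)),
    cross_ek = list(seg("e", "k", 6)),
    cross_fgh = list(seg("f", "g", 10), seg("g", "h", -8)),
    lower_vein = list(seg("a", "f", 12), seg("f", "i", -15))
  )
}

#' Synthetic wing genome
#'
#' The full parameter set of one synthetic wing image: canonical key point
#' geometry, per-segment Bezier curvature, vein rendering parameters,
#' background statistics, artefact model, pose and noise. The same genome
#' and seed always render the identical image.
#'
#' The defaults define the generator's study conditions: a bright mounting
#' background (mean 210, sd 8 grey levels) with dark smooth vein strokes
#' (intensity drop 120, width 6 px at reference resolution), a decoy vein
#' running parallel to and below the costal `lm` section (the documented
#' hazard for straight snake initialization), optional bright air-bubble
#' rings and dark dust specks placed above the wing (probability 0.2 each),
#' and anchor-click jitter drawn from the bundled annotator covariances.
#' The default working scale is 0.5 (canvas 968 x 644).
#'
#' @param scale rendering resolution relative to the reference frame.
#' @param keypoints optional key point tibble at reference scale (defaults
#'   to the canonical geometry).
#' @param vein_width full vein stroke width, px at reference scale.
#' @param vein_drop intensity drop of vein centrelines below background.
#' @param bg_mean,bg_sd background intensity mean and noise sd.
#' @param noise_sd additional pixel noise sd.
#' @param decoy_offset perpendicular distance of the decoy vein below the
#'   `lm` costal section, px at reference scale.
#' @param artefact_prob probability of a bubble (and, independently, of
#'   dust) appearing above the wing.
#' @param rotation,scale_jitter,translation pose: rotation in degrees about
#'   the wing centroid, isotropic scale factor, translation `(x, y)` px at
#'   rendering scale.
#' @param seed integer seed controlling all randomness of the render.
#' @return list of class `wing_genome`.
#' @export
wing_genome <- function(scale = 0.5, keypoints = canonical_keypoints(),
                        vein_width = 6, vein_drop = 120,
                        bg_mean = 210, bg_sd = 8, noise_sd = 3,
                        decoy_offset = 60, artefact_prob = 0.2,
                        rotation = 0, scale_jitter = 1,
                        translation = c(0, 0), seed = 1) {
  stopifnot(scale > 0, vein_width > 0, scale_jitter > 0)
  canvas <- c(width = round(1936 * scale), height = round(1288 * scale))
  structure(
    list(scale = scale, canvas = canvas, keypoints = keypoints,
         strokes = canonical_strokes(), vein_width = vein_width,
         vein_drop = vein_drop, bg_mean = bg_mean, bg_sd = bg_sd,
         noise_sd = noise_sd, decoy_offset = decoy_offset,
         artefact_prob = artefact_prob, rotation = rotation,
         scale_jitter = scale_jitter, translation = translation,
         seed = as.integer(seed)),
    class = "wing_genome"
  )
}

# Quadratic Bezier between p0 and p2 with control at chord midpoint +
# bulge * left-normal; densely sampled (spacing ~step px).
bezier_points <- function(p0, p2, bulge, step = 0.75) {
  chord <- p2 - p0
  len <- sqrt(sum(chord^2))
  nrm <- c(chord[2], -chord[1]) / max(len, 1e-9)
  p1 <- (p0 + p2) / 2 + bulge * nrm
  n <- max(8, ceiling(len / step))
  t <- seq(0, 1, length.out = n + 1)
  cbind((1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1],
        (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2])
}

# Pose transform of the genome, as an affine_transform in rendering pixels.
genome_pose <- function(g) {
  kp <- kp_matrix(g$keypoints)
  ctr <- colMeans(kp) * g$scale
  th <- g$rotation * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2) * g$scale_jitter
  t <- ctr - R %*% ctr + g$translation
  structure(cbind(R, t), class = "affine_transform")
}

# Ground-truth key points and arc polylines of a genome, in rendering
# coordinates (pose applied, scale applied).
wing_ground_truth <- function(g) {
  pose <- genome_pose(g)
  kp_ref <- g$keypoints
  to_render <- function(pts) apply_affine(pose, pts * g$scale)
  kpm <- to_render(kp_matrix(kp_ref))
  kps <- keypoints(kp_ref$label, kpm[, 1], kpm[, 2])
  seg_curve <- function(stroke_segments) {
    pts <- list()
    for (s in stroke_segments) {
      p0 <- kp_xy(kp_ref, s$from); p2 <- kp_xy(kp_ref, s$to)
      pts[[length(pts) + 1]] <- bezier_points(p0, p2, s$bulge,
                                              step = 0.75 / g$scale)
    }
    do.call(rbind, pts)
  }
  st <- g$strokes
  rev_poly <- function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]
  arcs_ref <- list(
    fg = bezier_points(kp_xy(kp_ref, "f"), kp_xy(kp_ref, "g"),
                       st$cross_fgh[[1]]$bulge, 0.75 / g$scale),
    gh = bezier_points(kp_xy(kp_ref, "g"), kp_xy(kp_ref, "h"),
                       st$cross_fgh[[2]]$bulge, 0.75 / g$scale),
    # jl runs along the costa from j through k to l
    jl = rbind(
      rev_poly(bezier_points(kp_xy(kp_ref, "k"), kp_xy(kp_ref, "j"),
                             st$margin_top[[5]]$bulge, 0.75 / g$scale)),
      rev_poly(bezier_points(kp_xy(kp_ref, "l"), kp_xy(kp_ref, "k"),
                             st$margin_top[[4]]$bulge, 0.75 / g$scale))
    ),
    # kl stored k -> l, lm stored l -> m (arc endpoint order)
    kl = rev_poly(bezier_points(kp_xy(kp_ref, "l"), kp_xy(kp_ref, "k"),
                                st$margin_top[[4]]$bulge, 0.75 / g$scale)),
    lm = rev_poly(bezier_points(kp_xy(kp_ref, "m"), kp_xy(kp_ref, "l"),
                                st$margin_top[[3]]$bulge, 0.75 / g$scale))
  )
  arcs <- lapply(arcs_ref, to_render)
  list(keypoints = kps, arcs = arcs, pose = pose)
}

# Decoy vein endpoints (reference scale): parallel to the m-l costal
# section, displaced into the wing blade (toward larger y).
decoy_endpoints <- function(g) {
  m <- kp_xy(g$keypoints, "m"); l <- kp_xy(g$keypoints, "l")
  chord <- l - m
  nrm <- c(chord[2], -chord[1]) / sqrt(sum(chord^2))
  if (nrm[2] < 0) nrm <- -nrm  # into the blade (downward)
  list(p0 = m + nrm * g$decoy_offset + 0.05 * chord,
       p1 = l + nrm * g$decoy_offset - 0.05 * chord)
}

#' Render a synthetic wing
#'
#' Rasterizes the genome: dark anti-aliased vein strokes (including the
#' decoy vein below the costal `lm` section) on a bright noisy background,
#' with optional bright bubble rings and dark dust specks above the wing.
#' Rendering is bit-reproducible for a given genome.
#'
#' @param g a [wing_genome()].
#' @return list `(image, keypoints, arcs, genome)` with exact ground-truth
#'   key points and densely sampled arc polylines in image coordinates.
#' @export
render_wing <- function(g) {
  withr::with_seed(g$seed, render_wing_impl(g))
}

render_wing_impl <- function(g) {
  W <- g$canvas[["width"]]; H <- g$canvas[["height"]]
  gt <- wing_ground_truth(g)
  pose <- gt$pose
  kpm <- kp_matrix(gt$keypoints)
  if (any(kpm[, 1] < 5) || any(kpm[, 1] > W - 6) ||
      any(kpm[, 2] < 5) || any(kpm[, 2] > H - 6)) {
    abort("pose pushes the wing out of frame")
  }
  to_render <- function(pts) apply_affine(pose, pts * g$scale)

  # dense centreline points of every stroke + decoy
  pts <- list()
  for (stroke in g$strokes) {
    for (s in stroke) {
      p0 <- kp_xy(g$keypoints, s$from); p2 <- kp_xy(g$keypoints, s$to)
      pts[[length(pts) + 1]] <-
        to_render(bezier_points(p0, p2, s$bulge, 0.75 / g$scale))
    }
  }
  dec <- decoy_endpoints(g)
  pts[[length(pts) + 1]] <-
    to_render(bezier_points(dec$p0, dec$p1, 10, 0.75 / g$scale))
  pts <- do.call(rbind, pts)

  # distance-to-centreline field via a binary mask + Euclidean distmap
  cx <- pmin(pmax(round(pts[, 1]), 0), W - 1)
  cy <- pmin(pmax(round(pts[, 2]), 0), H - 1)
  mask <- matrix(1, H, W)
  mask[cbind(cy + 1, cx + 1)] <- 0
  d <- from_ebimage(EBImage::distmap(as_ebimage(mask), metric = "euclidean"))

  sig <- (g$vein_width * g$scale) / 2
  img <- g$bg_mean - g$vein_drop * exp(-d^2 / (2 * sig^2))

  # artefacts: bright bubble rings and dark dust above the wing
  m_r <- kp_xy(gt$keypoints, "m"); l_r <- kp_xy(gt$keypoints, "l")
  up <- { ch <- l_r - m_r; n <- c(ch[2], -ch[1]) / sqrt(sum(ch^2))
          if (n[2] > 0) n <- -n; n }
  xg <- matrix(rep(0:(W - 1), each = H), H, W)
  yg <- matrix(rep(0:(H - 1), times = W), H, W)
  if (runif(1) < g$artefact_prob) {  # air bubble: bright ring
    t0 <- runif(1)
    ctr <- m_r + t0 * (l_r - m_r) + up * runif(1, 60, 140) * g$scale
    rad <- runif(1, 20, 45) * g$scale
    rd <- sqrt((xg - ctr[1])^2 + (yg - ctr[2])^2)
    img <- img + 35 * exp(-(rd - rad)^2 / (2 * (3 * g$scale)^2))
  }
  if (runif(1) < g$artefact_prob) {  # dust: small dark specks
    n_dust <- 1 + rpois(1, 2)
    for (q in seq_len(n_dust)) {
      t0 <- runif(1)
      ctr <- m_r + t0 * (l_r - m_r) + up * runif(1, 40, 150) * g$scale
      rd2 <- (xg - ctr[1])^2 + (yg - ctr[2])^2
      img <- img - 60 * exp(-rd2 / (2 * (2.5 * g$scale)^2))
    }
  }

  img <- img + rnorm(H * W, 0, g$bg_sd) + rnorm(H * W, 0, g$noise_sd)
  img <- pmin(pmax(img, 0), 255)
  list(image = img, keypoints = gt$keypoints, arcs = gt$arcs, genome = g)
}

#' Generate an exemplar library of synthetic wings
#'
#' Renders `n` wings with independent shape jitter (per-key-point Gaussian
#' perturbations at reference scale), pose jitter (rotation within
#' `rot_range` degrees, scale within `scale_range`, small translation) and
#' distinct seeds derived from the master seed; builds the per-landmark
#' patch cache and (by default) drops the full raster.
#'
#' @param n number of wings (>= 1).
#' @param seed master seed.
#' @param scale rendering scale (see [wing_genome()]).
#' @param shape_sd per-key-point jitter sd, px at reference scale.
#' @param rot_range,scale_range,trans_range pose jitter bounds.
#' @param species,sex labels recycled over wings.
#' @param keep_images keep full rasters alongside the patch cache.
#' @param artefact_prob forwarded to [wing_genome()].
#' @return list of [annotated_wing()] objects with patch caches.
#' @export
generate_library <- function(n, seed = 1, scale = 0.5, shape_sd = 2,
                             rot_range = c(-15, 15),
                             scale_range = c(0.9, 1.1),
                             trans_range = 10,
                             species = "synthetica", sex = "unknown",
                             keep_images = FALSE, artefact_prob = 0.2) {
  if (n < 1) abort("n must be >= 1")
  species <- rep_len(species, n); sex <- rep_len(sex, n)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    seed_i <- as.integer((as.numeric(seed) * 1009 + i * 7 + 13) %% 2147483647)
    g <- withr::with_seed(seed_i, jittered_genome(
      scale, shape_sd, rot_range, scale_range, trans_range, artefact_prob,
      seed_img = (seed_i + 500000011) %% 2147483647))
    r <- render_wing(g)
    w <- annotated_wing(id = sprintf("syn_%04d", i), species = species[i],
                        sex = sex[i], keypoints = r$keypoints,
                        image = r$image, scale = scale)
    w <- build_patch_cache(w)
    w$arcs <- r$arcs
    if (!keep_images) w$image <- NULL
    out[[i]] <- w
  }
  out
}

# One randomly jittered genome (RNG assumed seeded by the caller).
jittered_genome <- function(scale, shape_sd, rot_range, scale_range,
                            trans_range, artefact_prob, seed_img) {
  kp <- canonical_keypoints()
  kp$x <- kp$x + rnorm(13, 0, shape_sd)
  kp$y <- kp$y + rnorm(13, 0, shape_sd)
  wing_genome(
    scale = scale, keypoints = kp,
    rotation = runif(1, rot_range[1], rot_range[2]),
    scale_jitter = runif(1, scale_range[1], scale_range[2]),
    translation = runif(2, -trans_range, trans_range) * scale,
    artefact_prob = artefact_prob,
    seed = seed_img
  )
}

#' Jitter the anchor clicks
#'
#' Perturbs the anchors `a`, `h`, `k` by zero-mean Gaussian draws with the
#' given per-label covariances (defaults to the bundled annotator
#' covariances at reference scale), emulating the spread of manual clicks.
#' Other key points are untouched.
#'
#' @param kps key point tibble containing `a`, `h`, `k`.
#' @param covs named list of 2x2 covariance matrices.
#' @param seed integer seed.
#' @return the key point tibble with perturbed anchors.
#' @export
jitter_anchors <- function(kps, covs = annotator_covariances(), seed = 1) {
  withr::with_seed(seed, {
    for (lab in anchor_labels()) {
      C <- covs[[lab]]
      if (is.null(C)) abort(paste0("no covariance for anchor '", lab, "'"))
      if (max(abs(C)) == 0) next
      z <- drop(rnorm(2) %*% chol(C))
      i <- match(lab, kps$label)
      kps$x[i] <- kps$x[i] + z[1]
      kps$y[i] <- kps$y[i] + z[2]
    }
    kps
  })
}

#' Synthetic feature tables for the classifier
#'
#' Multivariate-normal feature draws per (species, sex) group, the
#' synthetic stand-in for a measured training table. Supports
#' planted-signal configurations in which only some coordinates carry
#' between-group differences.
#'
#' @param groups list of lists with fields `species`, `sex`, `mu` (named
#'   numeric), `sigma` (PSD matrix), `n`.
#' @param seed integer seed.
#' @return tibble with `species`, `sex` and one column per feature.
#' @export
generate_feature_table <- function(groups, seed = 1) {
  if (length(groups) == 0) {
    return(tibble::tibble(species = character(), sex = character()))
  }
  withr::with_seed(seed, {
    rows <- lapply(groups, function(g) {
      p <- length(g$mu)
      ev <- min(eigen(g$sigma, symmetric = TRUE, only.values = TRUE)$values)
      if (ev < -1e-8) abort("group covariance is not positive semi-definite")
      R <- chol(g$sigma + diag(1e-12, p))
      Z <- matrix(rnorm(g$n * p), g$n, p)
      X <- sweep(Z %*% R, 2, g$mu, "+")
      colnames(X) <- names(g$mu)
      dplyr::bind_cols(tibble::tibble(species = g$species, sex = g$sex),
                       tibble::as_tibble(X))
    })
    dplyr::bind_rows(rows)
  })
}
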