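# Shared fixtures, all generated in code.

# A smooth deterministic test image: gentle 2-D cosine field, values well
# inside [0, 255].
smooth_image <- function(h = 64, w = 64) {
  y <- matrix(rep(0:(h - 1), times = w), h, w)
  x <- matrix(rep(0:(w - 1), each = h), h, w)
  120 + 60 * cos(x / 9) * sin(y / 7)
}

# A linear intensity ramp a + b*x + c*y (exactly preserved by bilinear
# interpolation, so rotations have closed-form expectations).
ramp_image <- function(h = 41, w = 41, a = 100, b = 1.5, c = -0.8) {
  y <- matrix(rep(0:(h - 1), times = w), h, w)
  x <- matrix(rep(0:(w - 1), each = h), h, w)
  out <- a + b * x + c * y
  out - min(out)
}

# Quarter-scale synthetic wing: cheap enough for unit tests.
small_genome <- function(seed = 1, ...) {
  wing_genome(scale = 0.25, seed = seed, ...)
}

# One rendered quarter-scale wing, memoized across tests.
fixture_env <- new.env(parent = emptyenv())

small_wing <- function() {
  if (is.null(fixture_env$small_wing)) {
    fixture_env$small_wing <- render_wing(small_genome(seed = 4,
                                                       artefact_prob = 0))
  }
  fixture_env$small_wing
}

# A small half-scale exemplar library + query set, memoized (used by several
# detection tests).
small_library <- function(n = 8) {
  key <- paste0("lib", n)
  if (is.null(fixture_env[[key]])) {
    fixture_env[[key]] <- generate_library(n, seed = 21, scale = 0.5)
  }
  fixture_env[[key]]
}

half_scale_query <- function(seed = 5501) {
  g <- withr::with_seed(seed, wingmorph:::jittered_genome(
    0.5, 2, c(-15, 15), c(0.9, 1.1), 10, 0.2, seed + 17))
  render_wing(g)
}

# Feature-table groups for classifier tests: `k` well-separated groups in
# p dimensions.
separated_groups <- function(k = 2, p = 6, n = 50, spread = 10) {
  lapply(seq_len(k), function(i) {
    mu <- setNames(rep(0, p), paste0("v", seq_len(p)))
    mu[1] <- i * spread
    list(species = paste0("sp", i), sex = "female", mu = mu,
         sigma = diag(p), n = n)
  })
}

# Feature tables shaped like the study design: 15 named species x 2 sexes
# with two under-sampled female groups, on the default 6-variable subset.
study_like_groups <- function(p = 6) {
  species <- paste0("species_", sprintf("%02d", 1:15))
  groups <- list()
  set.seed(909)
  for (i in seq_along(species)) {
    for (sx in c("female", "male")) {
      n <- 20
      if (species[i] == "species_06" && sx == "female") n <- 11
      if (species[i] == "species_15" && sx == "female") n <- 5
      mu <- setNames(rnorm(p, 0, 4), default_feature_subset())
      groups[[length(groups) + 1]] <-
        list(species = species[i], sex = sx, mu = mu, sigma = diag(p),
             n = n)
    }
  }
  groups
}


# Brute-force R reference for the exhaustive template search, independent of
# the compiled path (used to validate the matcher).
brute_force_search <- function(img, wing, anchors, label, half, search,
                               theta_set = c(-10, -5, 0, 5, 10)) {
  T <- fit_affine(wing$keypoints, anchors)
  ctr <- drop(apply_affine(T, kp_xy(wing$keypoints, label)))
  Ti <- invert_affine(T)
  best <- NULL
  for (th in sort(theta_set)) {
    u <- seq(-half, half)
    gx <- rep(u, each = length(u)); gy <- rep(u, times = length(u))
    rad <- th * pi / 180
    rx <- cos(rad) * gx - sin(rad) * gy
    ry <- sin(rad) * gx + cos(rad) * gy
    sp <- apply_affine(Ti, cbind(ctr[1] + rx, ctr[2] + ry))
    tm <- matrix(wingmorph:::exemplar_sample(wing, label, sp[, 1], sp[, 2]),
                 length(u), length(u))
    for (cx in -search:search) {
      for (cy in -search:search) {
        s <- match_score(tm, img, ctr, cx, cy)
        if (is.null(best) || s < best$score) {
          best <- list(score = s, cx = cx, cy = cy, theta = th)
        }
      }
    }
  }
  best$loc <- c(ctr[1] - best$cx, ctr[2] - best$cy)
  best
}

# The full synthetic benchmark at the generator's study conditions:
# a 100-exemplar library (seed 1, generator defaults, scale 0.5) and 50
# held-out queries with jittered anchor clicks. Heavy; computed once and
# memoized for the blocks that consume it.
study_run <- function(n_lib = 100, n_query = 50) {
  if (!is.null(fixture_env$study)) return(fixture_env$study)
  lib <- generate_library(n_lib, seed = 1)
  covs <- annotator_covariances(0.5)
  preds <- list(); truths <- list(); arc_rows <- list()
  dev100 <- numeric(n_query); dev10 <- numeric(n_query)
  for (qi in seq_len(n_query)) {
    qseed <- 910000 + qi
    g <- withr::with_seed(qseed, wingmorph:::jittered_genome(
      0.5, 2, c(-15, 15), c(0.9, 1.1), 10, 0.2, qseed + 13))
    w <- render_wing(g)
    anchors <- jitter_anchors(w$keypoints, covs, seed = qseed + 29)
    det <- detect_all_keypoints(w$image, anchors, lib, scale = 0.5)
    det_small <- detect_all_keypoints(w$image, anchors, lib[1:10],
                                      scale = 0.5)
    id <- sprintf("q%03d", qi)
    det$wing_id <- id
    tr <- w$keypoints; tr$wing_id <- id
    preds[[qi]] <- det; truths[[qi]] <- tr
    tm <- kp_matrix(w$keypoints, det$label[det$source == "predicted"])
    p100 <- det[det$source == "predicted", ]
    p10 <- det_small[det_small$source == "predicted", ]
    dev100[qi] <- mean(sqrt((p100$x - tm[, 1])^2 + (p100$y - tm[, 2])^2))
    dev10[qi] <- mean(sqrt((p10$x - tm[, 1])^2 + (p10$y - tm[, 2])^2))
    P <- build_gradient_image(w$image)
    ma <- measure_arcs(det, P, scale = 0.5)
    for (a in arc_labels()) {
      err <- arc_area_error(ma$polylines[[a]], w$arcs[[a]])
      arc_rows[[length(arc_rows) + 1]] <-
        tibble::tibble(wing_id = id, arc = a,
                       normalized = err$normalized,
                       length_true = err$truth_length,
                       length_traced = ma$arcs$length_px[ma$arcs$arc == a])
    }
  }
  fixture_env$study <- list(
    preds = dplyr::bind_rows(preds),
    truths = dplyr::bind_rows(truths),
    covs = covs,
    arcs = dplyr::bind_rows(arc_rows),
    dev100 = dev100, dev10 = dev10
  )
  fixture_env$study
}
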