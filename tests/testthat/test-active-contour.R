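# A bright horizontal ridge at row y0 with smooth falloff: the snake's
# ideal playground.
ridge_image <- function(h = 60, w = 120, y0 = 30, sigma = 4,
                        floor_val = 20) {
  y <- matrix(rep(0:(h - 1), times = w), h, w)
  floor_val + (255 - floor_val) * exp(-(y - y0)^2 / (2 * sigma^2))
}

test_that("straight initialization spaces points evenly at equilibrium", {
  p <- init_straight(c(0, 0), c(10, 0), 5)
  expect_equal(p[, 1], c(0, 2, 4, 6, 8, 10))
  expect_equal(p[, 2], rep(0, 6))
  expect_equal(arc_length(p), 10)
  # internal energy exactly zero at equilibrium
  P <- matrix(100, 40, 40)
  cfg <- snake_config(n = 5, alpha = 0.3)
  f <- as.numeric(external_energy_f(p + 10, P, cfg$epsilon))
  expect_equal(objective_L(p + 10, P, cfg), f, tolerance = 1e-12)
  expect_error(init_straight(c(1, 1), c(1, 1), 4), "coincident")
  expect_error(init_straight(c(0, 0), c(1, 0), 1), ">= 2")
})

test_that("arc length matches closed forms and is isometry-invariant", {
  expect_equal(arc_length(init_straight(c(0, 0), c(10, 0), 7)), 10)
  t <- seq(0, pi, length.out = 65)
  semi <- cbind(cos(t), sin(t))
  expect_equal(arc_length(semi), pi, tolerance = pi * 1e-3)
  phi <- 0.73
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  expect_equal(arc_length(semi %*% t(R)), arc_length(semi),
               tolerance = 1e-9)
  # never shorter than the chord
  set.seed(2)
  for (r in 1:20) {
    poly <- cbind(cumsum(runif(8)), rnorm(8))
    expect_gte(arc_length(poly) + 1e-12,
               sqrt(sum((poly[1, ] - poly[8, ])^2)))
  }
})

test_that("image energy has the stated closed form on uniform fields", {
  P <- matrix(150, 50, 50)
  poly <- init_straight(c(5, 10), c(45, 30), 8)
  L <- arc_length(poly)
  f <- as.numeric(external_energy_f(poly, P, 1e-6))
  expect_equal(f, L * 150 / (150 + 1e-6), tolerance = 1e-9)
  # two-segment hand-computed value on a non-uniform field
  P2 <- matrix(0, 10, 10)
  P2[1, ] <- 0  # row y = 0
  P2[, 3] <- 40
  P2[5, 3] <- 80; P2[5, 6] <- 120; P2[5, 9] <- 200
  poly2 <- rbind(c(2, 4), c(5, 4), c(8, 4))
  eps <- 1e-6
  v <- c(P2[5, 3], P2[5, 6], P2[5, 9])
  pn <- (v[1] + v[3]) / 2
  expected <- (pn / 2) * (3 * (1 / (v[1] + eps) + 1 / (v[2] + eps)) +
                          3 * (1 / (v[2] + eps) + 1 / (v[3] + eps)))
  expect_equal(as.numeric(external_energy_f(poly2, P2, eps)), expected,
               tolerance = 1e-9)
})

test_that("image energy is invariant under intensity multiplication", {
  set.seed(4)
  P <- matrix(runif(50 * 80, 30, 220), 50, 80)
  poly <- init_straight(c(5, 5), c(70, 40), 16) +
    cbind(rep(0, 17), rnorm(17, 0, 2))
  poly[1, ] <- c(5, 5); poly[17, ] <- c(70, 40)
  f1 <- as.numeric(external_energy_f(poly, P, 1e-6))
  for (a in c(0.5, 2, 10)) {
    fa <- as.numeric(external_energy_f(poly, a * P, 1e-6))
    expect_lt(abs(fa - f1) / f1, 1e-4)
  }
})

test_that("objective reduces to f when alpha is zero and is locally tight", {
  P <- ridge_image()
  poly <- init_straight(c(10, 30), c(110, 30), 10)
  cfg0 <- snake_config(n = 10, alpha = 0)
  expect_equal(objective_L(poly, P, cfg0),
               as.numeric(external_energy_f(poly, P, cfg0$epsilon)),
               tolerance = 1e-12)
  # perturbing one interior point off the uniform bright ridge increases L
  cfg <- snake_config(n = 10, alpha = 0.05)
  L0 <- objective_L(poly, P, cfg)
  pert <- poly; pert[5, 2] <- pert[5, 2] + 3
  expect_gt(objective_L(pert, P, cfg), L0)
})

test_that("snakes settle onto a straight bright ridge and stay put", {
  P <- ridge_image()
  on_ridge <- init_straight(c(10, 30), c(110, 30), 16)
  ev <- evolve(on_ridge, P, snake_config(n = 16))
  expect_true(ev$converged)
  expect_lt(ev$iterations, 50)
  expect_lt(max(abs(ev$poly[, 2] - 30)), 0.5)
  # from a biased start the snake still finds the ridge
  off <- init_straight(c(10, 30), c(110, 30), 16)
  off[2:16, 2] <- off[2:16, 2] + 6
  ev2 <- evolve(off, P, snake_config(n = 16))
  expect_lt(max(abs(ev2$poly[2:16, 2] - 30)), 0.75)
  # endpoints are bit-identical through evolution
  expect_identical(ev2$poly[1, ], off[1, ])
  expect_identical(ev2$poly[17, ], off[17, ])
  # the objective did not increase
  cfg <- snake_config(n = 16)
  expect_lte(objective_L(ev2$poly, P, cfg), objective_L(off, P, cfg))
})

test_that("a curved synthetic vein is traced from a straight start", {
  g <- small_genome(seed = 7, artefact_prob = 0)
  w <- render_wing(g)
  P <- build_gradient_image(w$image)
  truth <- w$arcs$gh
  ends <- truth[c(1, nrow(truth)), ]
  init <- init_straight(ends[1, ], ends[2, ], 32)
  ev <- evolve(init, P, snake_config())
  # mean perpendicular deviation from the ground-truth curve
  dense <- wingmorph:::resample_polyline(truth, 400)
  devs <- vapply(seq(2, 32), function(i) {
    min(sqrt((dense[, 1] - ev$poly[i, 1])^2 +
             (dense[, 2] - ev$poly[i, 2])^2))
  }, numeric(1))
  expect_lt(mean(devs), 1.5)
})

test_that("two parallel veins capture a mis-initialized snake", {
  # the documented failure mode: init biased toward the wrong vein
  h <- 60; w <- 120
  y <- matrix(rep(0:(h - 1), times = w), h, w)
  two <- 20 + 235 * pmax(exp(-(y - 24)^2 / (2 * 2^2)),
                         exp(-(y - 36)^2 / (2 * 2^2)))
  init <- init_straight(c(10, 33), c(110, 33), 16)  # nearer the y=36 vein
  ev <- evolve(init, two, snake_config(n = 16))
  mid_y <- mean(ev$poly[2:16, 2])
  expect_gt(mid_y, 33)           # drifted to the wrong (lower) vein
  expect_lt(abs(mid_y - 36), 1)  # and locked onto it
})

test_that("epsilon keeps the objective finite on zero-intensity pixels", {
  P <- matrix(0, 30, 30)
  poly <- init_straight(c(2, 15), c(27, 15), 6)
  f <- as.numeric(external_energy_f(poly, P, 1e-6))
  expect_true(is.finite(f))
})

test_that("template arcs map through identity and scaling exactly", {
  tmpl <- wing_template(scale = 0.25)
  expect_true(kp_complete(tmpl$keypoints))
  # template-choice rule: k equidistant to j and l within 5%
  dkj <- sqrt(sum((kp_xy(tmpl$keypoints, "k") - kp_xy(tmpl$keypoints, "j"))^2))
  dkl <- sqrt(sum((kp_xy(tmpl$keypoints, "k") - kp_xy(tmpl$keypoints, "l"))^2))
  expect_lt(abs(dkj - dkl) / max(dkj, dkl), 0.05)
  # identity mapping: query = template
  init <- init_from_template(tmpl, tmpl$keypoints, "kl", 24)
  ref <- wingmorph:::resample_polyline(tmpl$arcs$kl, 24)
  expect_lt(max(abs(init - ref)), 1e-3)
  # 2x scaling maps arcs to scaled arcs
  kps2 <- tmpl$keypoints; kps2$x <- 2 * kps2$x; kps2$y <- 2 * kps2$y
  init2 <- init_from_template(tmpl, kps2, "fg", 24)
  ref2 <- 2 * wingmorph:::resample_polyline(tmpl$arcs$fg, 24)
  expect_lt(max(abs(init2 - ref2)), 1e-3)
  expect_error(init_from_template(tmpl, tmpl$keypoints[1:2, ], "fg", 8),
               "anchors")
})

test_that("the mapped lm initialization lies outside the wing blade", {
  tmpl <- wing_template(scale = 0.25)
  outside <- 0; total <- 0
  for (seed in 1:10) {
    g <- withr::with_seed(4000 + seed, wingmorph:::jittered_genome(
      0.25, 2, c(-10, 10), c(0.95, 1.05), 5, 0, 4000 + seed))
    w <- render_wing(g)
    init <- init_from_template(tmpl, w$keypoints, "lm", 32)
    # blade test: signed side of the costal margin l -> m; the blade
    # interior (centroid) defines the inside sign
    l <- kp_xy(w$keypoints, "l"); m <- kp_xy(w$keypoints, "m")
    ctr <- wing_centroid(w$keypoints)$centroid
    side <- function(p) sign((m[1] - l[1]) * (p[2] - l[2]) -
                             (m[2] - l[2]) * (p[1] - l[1]))
    inside_sign <- side(ctr)
    mid <- init[seq(8, 26), ]
    outside <- outside + sum(apply(mid, 1, side) != inside_sign)
    total <- total + nrow(mid)
  }
  expect_gt(outside / total, 0.95)
})

test_that("all five arcs are measured, with partial-failure isolation", {
  w <- small_wing()
  P <- build_gradient_image(w$image)
  ma <- measure_arcs(w$keypoints, P, cfg = snake_config(), scale = 0.25)
  expect_identical(sort(ma$arcs$arc), sort(arc_labels()))
  expect_true(all(is.na(ma$arcs$error)))
  # measured lengths within 3% of ground truth
  for (a in arc_labels()) {
    lt <- arc_length(w$arcs[[a]])
    lm_ <- ma$arcs$length_px[ma$arcs$arc == a]
    expect_lt(abs(lm_ - lt) / lt, 0.03)
  }
  # missing key point m: lm fails, the rest succeed
  kps_partial <- w$keypoints[w$keypoints$label != "m", ]
  ma2 <- measure_arcs(kps_partial, P, cfg = snake_config(), scale = 0.25)
  expect_true(is.na(ma2$arcs$length_px[ma2$arcs$arc == "lm"]))
  expect_false(anyNA(ma2$arcs$length_px[ma2$arcs$arc != "lm"]))
})
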