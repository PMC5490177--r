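#' Snake configuration
#'
#' Tunables of the fixed-endpoint active contour. `n` is the number of
#' straight segments (so `n - 1` interior points move); `alpha` weights the
#' internal energy that keeps segment lengths near their equilibrium
#' `l0 = |p_a - p_b| / n`; `epsilon` regularizes the image term so it stays
#' finite on zero-intensity pixels; `eta` is the gradient-descent step size;
#' evolution stops when the largest point displacement drops below `tol`
#' or after `max_iter` iterations.
#'
#' @param n segments (>= 2).
#' @param alpha internal-energy weight (>= 0).
#' @param epsilon image-term regularizer (0 < epsilon << 1).
#' @param eta step size (px per unit gradient).
#' @param max_iter iteration cap.
#' @param tol convergence threshold on the max point displacement (px).
#' @param fd_step finite-difference step for the energy gradient (px).
#' @return a list of class `snake_config`.
#' @export
snake_config <- function(n = 32, alpha = 0.05, epsilon = 1e-6, eta = 0.2,
                         max_iter = 800, tol = 1e-2, fd_step = 0.25) {
  stopifnot(n >= 2, alpha >= 0, epsilon > 0, eta > 0, max_iter >= 1,
            tol > 0, fd_step > 0)
  structure(list(n = as.integer(n), alpha = alpha, epsilon = epsilon,
                 eta = eta, max_iter = as.integer(max_iter), tol = tol,
                 fd_step = fd_step),
            class = "snake_config")
}

#' Straight-chord initialization
#'
#' Places `n - 1` intermediate points evenly on the chord from `p_a` to
#' `p_b`, so every segment has the equilibrium length and the internal
#' energy starts at zero. Works well for the relatively straight arcs
#' fg, gh, jl and kl.
#'
#' @param p_a,p_b length-2 endpoints `(x, y)`.
#' @param n number of segments (>= 2).
#' @return `(n + 1) x 2` matrix of polyline points.
#' @export
init_straight <- function(p_a, p_b, n = 32) {
  if (n < 2) abort("n must be >= 2")
  if (sqrt(sum((p_a - p_b)^2)) <= 1e-12) abort("coincident endpoints")
  t <- seq(0, 1, length.out = n + 1)
  cbind(p_a[1] + t * (p_b[1] - p_a[1]), p_a[2] + t * (p_b[2] - p_a[2]))
}

#' Arc length of a polyline
#'
#' Sum of the segment lengths; always at least the endpoint chord length.
#'
#' @param poly `(n + 1) x 2` matrix of points.
#' @return total length in pixels.
#' @export
arc_length <- function(poly) {
  d <- diff(poly)
  sum(sqrt(rowSums(d^2)))
}

# Segment lengths l_i, i = 1..n
segment_lengths <- function(poly) {
  d <- diff(poly)
  sqrt(rowSums(d^2))
}

#' Image (external) energy of a polyline
#'
#' `f = (<P>/2) * sum_i l_i * [1/(P_{i-1} + eps) + 1/(P_i + eps)]`, where
#' `P_i` is the gradient image sampled bilinearly at vertex i and
#' `<P> = (P(p_a) + P(p_b)) / 2` normalizes the intensity scale, making `f`
#' invariant under multiplying `P` by a constant (up to the epsilon
#' regularizer). Small along bright ridges. Points outside the image domain
#' are sampled at the clamped location and flagged via the `clamped`
#' attribute.
#'
#' @param poly `(n + 1) x 2` polyline.
#' @param P gradient image.
#' @param epsilon regularizer (> 0).
#' @param p_norm optional frozen normalization `<P>`; computed from the
#'   endpoints when `NULL`.
#' @return scalar energy.
#' @export
external_energy_f <- function(poly, P, epsilon = 1e-6, p_norm = NULL) {
  if (epsilon <= 0) abort("epsilon must be > 0")
  clamped <- any(out_of_domain(P, poly[, 1], poly[, 2]))
  v <- bilinear_sample(P, poly[, 1], poly[, 2])
  if (is.null(p_norm)) p_norm <- (v[1] + v[length(v)]) / 2
  l <- segment_lengths(poly)
  inv <- 1 / (v + epsilon)
  f <- (p_norm / 2) * sum(l * (inv[-length(inv)] + inv[-1]))
  attr(f, "clamped") <- clamped
  f
}

#' Full snake objective
#'
#' `L = f + alpha * sum_i (l_i - l0)^2` with `l0 = |p_a - p_b| / n`. The
#' internal term vanishes exactly when all segments share the equilibrium
#' length.
#'
#' @inheritParams external_energy_f
#' @param cfg a [snake_config()].
#' @param l0 optional equilibrium segment length; derived from the endpoints
#'   when `NULL`.
#' @return scalar objective value.
#' @export
objective_L <- function(poly, P, cfg = snake_config(), l0 = NULL,
                        p_norm = NULL) {
  n <- nrow(poly) - 1
  if (is.null(l0)) {
    l0 <- sqrt(sum((poly[1, ] - poly[n + 1, ])^2)) / n
  }
  f <- as.numeric(external_energy_f(poly, P, cfg$epsilon, p_norm))
  l <- segment_lengths(poly)
  f + cfg$alpha * sum((l - l0)^2)
}

# Energy terms local to each segment i = 1..n, given vertex intensities v
# (length n+1) and segment lengths l: used for the finite-difference
# gradient, where perturbing vertex k only touches segments k and k+1.
local_terms <- function(l, v, l0, alpha, epsilon, p_norm) {
  inv <- 1 / (v + epsilon)
  (p_norm / 2) * l * (inv[-length(inv)] + inv[-1]) + alpha * (l - l0)^2
}

#' Evolve a snake by gradient descent
#'
#' Interior points move down the finite-difference gradient of the
#' objective (central differences on the bilinearly interpolated field;
#' endpoints never move). The intensity normalization `<P>` is frozen at
#' initialization. If a step would increase the objective the step size is
#' halved for that step (up to 8 times), preserving the descent direction
#' while keeping the objective non-increasing. Stops when the largest point
#' displacement falls below `cfg$tol`.
#'
#' @inheritParams objective_L
#' @return list `(poly, iterations, converged, objective)`; on divergence
#'   (a coordinate leaving the image by more than the image diagonal / 2)
#'   the best polyline so far is returned with `converged = FALSE`.
#' @export
evolve <- function(poly, P, cfg = snake_config()) {
  n <- nrow(poly) - 1
  if (n < 2) abort("polyline needs at least 2 segments")
  l0 <- sqrt(sum((poly[1, ] - poly[n + 1, ])^2)) / n
  v0 <- bilinear_sample(P, c(poly[1, 1], poly[n + 1, 1]),
                        c(poly[1, 2], poly[n + 1, 2]))
  p_norm <- mean(v0)
  h <- cfg$fd_step
  margin <- max(nrow(P), ncol(P)) / 2

  energy <- function(pts) {
    l <- segment_lengths(pts)
    v <- bilinear_sample(P, pts[, 1], pts[, 2])
    sum(local_terms(l, v, l0, cfg$alpha, cfg$epsilon, p_norm))
  }

  L_cur <- energy(poly)
  best <- list(poly = poly, L = L_cur)
  converged <- FALSE
  iter <- 0
  idx <- 2:n  # interior vertices
  while (iter < cfg$max_iter) {
    iter <- iter + 1
    xs <- poly[, 1]; ys <- poly[, 2]
    v <- bilinear_sample(P, xs, ys)
    inv_pre <- v  # vertex intensities, reused below

    # Perturbing interior vertex k changes only segments k and k+1 and the
    # intensity sample at k; assemble those local terms vectorized over k.
    grad_dir <- function(dx, dy) {
      xk <- xs[idx] + dx; yk <- ys[idx] + dy
      vk <- bilinear_sample(P, xk, yk)
      l_in <- sqrt((xk - xs[idx - 1])^2 + (yk - ys[idx - 1])^2)
      l_out <- sqrt((xs[idx + 1] - xk)^2 + (ys[idx + 1] - yk)^2)
      inv_k <- 1 / (vk + cfg$epsilon)
      inv_prev <- 1 / (inv_pre[idx - 1] + cfg$epsilon)
      inv_next <- 1 / (inv_pre[idx + 1] + cfg$epsilon)
      (p_norm / 2) * (l_in * (inv_prev + inv_k) +
                      l_out * (inv_k + inv_next)) +
        cfg$alpha * ((l_in - l0)^2 + (l_out - l0)^2)
    }
    gx <- (grad_dir(h, 0) - grad_dir(-h, 0)) / (2 * h)
    gy <- (grad_dir(0, h) - grad_dir(0, -h)) / (2 * h)

    eta <- cfg$eta
    accepted <- FALSE
    for (try in 1:8) {
      cand <- poly
      cand[idx, 1] <- xs[idx] - eta * gx
      cand[idx, 2] <- ys[idx] - eta * gy
      L_new <- energy(cand)
      if (L_new <= L_cur) { accepted <- TRUE; break }
      eta <- eta / 2
    }
    if (!accepted) { converged <- TRUE; break }

    disp <- max(abs(cand[idx, ] - poly[idx, ]))
    poly <- cand
    L_cur <- L_new
    if (L_cur < best$L) best <- list(poly = poly, L = L_cur)

    # divergence guard
    if (any(cand[idx, 1] < -margin | cand[idx, 1] > ncol(P) - 1 + margin |
            cand[idx, 2] < -margin | cand[idx, 2] > nrow(P) - 1 + margin)) {
      warn("snake diverged; returning best configuration so far")
      return(list(poly = best$poly, iterations = iter, converged = FALSE,
                  objective = best$L))
    }
    if (disp < cfg$tol) { converged <- TRUE; break }
  }
  list(poly = poly, iterations = iter, converged = converged,
       objective = L_cur)
}

#' The packaged reference wing template
#'
#' A synthetic reference wing (generated from the canonical wing genome of
#' [wing_genome()]) supplying per-arc reference polylines for snake
#' initialization. Its key point `k` is equidistant to `j` and `l` within
#' 5%, and the reference `lm` polyline is stored displaced beyond the wing
#' margin so that, after mapping, the initial curve lies outside the wing
#' blade and approaches the costal vein from the artefact-free side (there
#' is another vein just below `lm` that a straight initialization tends to
#' capture).
#'
#' @param scale resolution of the template frame relative to the reference
#'   resolution.
#' @return list with `keypoints` (tibble) and `arcs` (named list of
#'   polyline matrices), class `wing_template`.
#' @export
wing_template <- function(scale = 1) {
  g <- wing_genome(scale = scale)
  gt <- wing_ground_truth(g)
  arcs <- gt$arcs
  # displace lm beyond the costal margin (outward = decreasing y here)
  lm <- arcs$lm
  p_l <- lm[1, ]; p_m <- lm[nrow(lm), ]
  chord <- p_m - p_l
  nrm <- c(chord[2], -chord[1])
  nrm <- nrm / sqrt(sum(nrm^2))
  if (nrm[2] > 0) nrm <- -nrm  # point away from the wing blade (up)
  bump <- 40 * g$scale
  t <- seq(0, 1, length.out = nrow(lm))
  offset <- bump * sin(pi * t)  # endpoints stay put
  arcs$lm <- lm + outer(offset, nrm)
  structure(list(keypoints = gt$keypoints, arcs = arcs, scale = g$scale),
            class = "wing_template")
}

#' Template-mapped initialization
#'
#' Maps a reference arc polyline of the wing template through the anchor
#' affine onto the query, resamples it to `n` segments, and snaps the
#' endpoints to the query's detected arc endpoints. Used for arc `lm`,
#' whose mapped curve lies outside the wing blade.
#'
#' @param tmpl a [wing_template()].
#' @param query_kps detected key point tibble of the query (needs `a`, `h`,
#'   `k` and the arc's endpoints).
#' @param arc one of [arc_labels()].
#' @param n number of segments.
#' @return `(n + 1) x 2` polyline matrix.
#' @export
init_from_template <- function(tmpl, query_kps, arc, n = 32) {
  if (!all(anchor_labels() %in% query_kps$label)) {
    abort("query key points must contain the anchors a, h, k")
  }
  if (!arc %in% arc_labels()) abort(paste0("unknown arc: ", arc))
  T <- fit_affine(tmpl$keypoints, query_kps)
  mapped <- apply_affine(T, tmpl$arcs[[arc]])
  mapped <- resample_polyline(mapped, n)
  ends <- arc_endpoints(arc)
  p_a <- kp_xy(query_kps, ends[1]); p_b <- kp_xy(query_kps, ends[2])
  # snap endpoints, distributing the correction linearly along the curve
  d_a <- p_a - mapped[1, ]; d_b <- p_b - mapped[n + 1, ]
  t <- seq(0, 1, length.out = n + 1)
  mapped + outer(1 - t, d_a) + outer(t, d_b)
}

# Arc label -> ordered endpoint labels. jl runs along the costa from j
# through k to l; its endpoints are j and l.
arc_endpoints <- function(arc) {
  switch(arc,
    fg = c("f", "g"), gh = c("g", "h"), jl = c("j", "l"),
    kl = c("k", "l"), lm = c("l", "m"),
    abort(paste0("unknown arc: ", arc)))
}

# Resample a polyline to n segments, uniformly in arc length.
resample_polyline <- function(poly, n) {
  d <- c(0, cumsum(segment_lengths(poly)))
  if (d[length(d)] <= 1e-12) abort("degenerate polyline")
  s <- seq(0, d[length(d)], length.out = n + 1)
  cbind(stats::approx(d, poly[, 1], xout = s, ties = "ordered")$y,
        stats::approx(d, poly[, 2], xout = s, ties = "ordered")$y)
}

#' Trace and measure the five vein arcs
#'
#' Initializes each arc (straight chords for fg, gh, jl, kl; the mapped
#' out-of-wing template curve for lm), evolves the snake on the gradient
#' image and reports the arc lengths. Per-arc failures are collected, not
#' fatal.
#'
#' @param query_kps complete detected key point tibble.
#' @param P gradient image from [build_gradient_image()].
#' @param tmpl a [wing_template()]; default built at `scale`.
#' @param cfg a [snake_config()].
#' @param scale query resolution ratio (used for the default template).
#' @return list with `arcs` (tibble `arc, length_px, converged, iterations,
#'   error`) and `polylines` (named list of final polylines).
#' @export
measure_arcs <- function(query_kps, P, tmpl = NULL, cfg = snake_config(),
                         scale = 1) {
  if (is.null(tmpl)) tmpl <- wing_template(scale = scale)
  rows <- list(); polys <- list()
  for (arc in arc_labels()) {
    res <- tryCatch({
      ends <- arc_endpoints(arc)
      p_a <- kp_xy(query_kps, ends[1]); p_b <- kp_xy(query_kps, ends[2])
      init <- if (arc == "lm") {
        init_from_template(tmpl, query_kps, arc, cfg$n)
      } else {
        init_straight(p_a, p_b, cfg$n)
      }
      ev <- evolve(init, P, cfg)
      polys[[arc]] <- ev$poly
      tibble::tibble(arc = arc, length_px = arc_length(ev$poly),
                     converged = ev$converged, iterations = ev$iterations,
                     error = NA_character_)
    }, error = function(e) {
      tibble::tibble(arc = arc, length_px = NA_real_, converged = FALSE,
                     iterations = 0L, error = conditionMessage(e))
    })
    rows[[arc]] <- res
  }
  list(arcs = dplyr::bind_rows(rows), polylines = polys)
}
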