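#' Fit per-(species, sex) Gaussian discriminant groups
#'
#' Computes the sample mean vector and sample covariance matrix (n - 1
#' denominator) of the selected feature subset for every (species, sex)
#' group with enough members. Groups below `min_group_size` (or with
#' `n <= p`, whose covariance is singular by construction) are excluded
#' with a logged reason.
#'
#' @param features tibble with columns `species`, `sex` and the feature
#'   columns.
#' @param subset character vector of feature column names (length >= 2).
#' @param min_group_size minimum group sample size retained (default 12).
#' @return object of class `wing_discriminant`: per-group stats, the
#'   subset, and an `excluded` tibble.
#' @export
fit_groups <- function(features, subset = default_feature_subset(),
                       min_group_size = 12) {
  p <- length(subset)
  if (p < 2) abort("subset must have at least 2 variables")
  missing_cols <- setdiff(c("species", "sex", subset), names(features))
  if (length(missing_cols) > 0) {
    abort(paste0("missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  split <- features |>
    dplyr::group_by(.data$species, .data$sex) |>
    dplyr::group_split()
  groups <- list(); excluded <- list()
  for (g in split) {
    sp <- g$species[1]; sx <- g$sex[1]; n <- nrow(g)
    if (n < min_group_size || n <= p) {
      reason <- if (n < min_group_size) {
        paste0("n = ", n, " < min_group_size = ", min_group_size)
      } else {
        paste0("n = ", n, " <= p = ", p, " (singular covariance)")
      }
      excluded[[length(excluded) + 1]] <-
        tibble::tibble(species = sp, sex = sx, n = n, reason = reason)
      next
    }
    X <- as.matrix(g[, subset])
    mu <- colMeans(X)
    S <- crossprod(sweep(X, 2, mu)) / (n - 1)
    ev <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
    if (!is.finite(ev) || ev <= 1e-10) {
      abort(paste0("singular covariance in group ", sp, "/", sx))
    }
    groups[[paste(sp, sx, sep = "/")]] <-
      list(species = sp, sex = sx, n = n, mu = mu, sigma = S)
  }
  if (length(groups) > 0) groups <- groups[order(names(groups))]
  structure(list(groups = groups, subset = subset,
                 min_group_size = min_group_size,
                 excluded = dplyr::bind_rows(excluded)),
            class = "wing_discriminant")
}

#' @export
print.wing_discriminant <- function(x, ...) {
  cat("<wing_discriminant>", length(x$groups), "groups on",
      length(x$subset), "variables:",
      paste(x$subset, collapse = ", "), "\n")
  if (nrow(x$excluded) > 0) {
    cat("  excluded:", paste0(x$excluded$species, "/", x$excluded$sex,
                              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Squared Mahalanobis distance to a group
#'
#' `D^2 = (x - mu)' S^{-1} (x - mu)`, computed through the Cholesky
#' factorization of `S` (triangular solve) rather than an explicit inverse;
#' the two agree to 1e-9.
#'
#' @param x numeric feature vector (subset order).
#' @param group a group entry of a [fit_groups()] object (fields `mu`,
#'   `sigma`).
#' @return non-negative scalar.
#' @export
mahalanobis_d2 <- function(x, group) {
  if (length(x) != length(group$mu)) abort("dimension mismatch")
  R <- chol(group$sigma)
  z <- backsolve(R, x - group$mu, transpose = TRUE)
  sum(z^2)
}

#' Classify wings by minimum Mahalanobis distance
#'
#' Each sample is assigned the group with the smallest `D^2` (ties broken
#' by lexicographic species/sex order). The goodness of fit of the best
#' group is judged by the chi-square distribution with `p` degrees of
#' freedom (`p` = number of variables): when the minimum `D^2` exceeds the
#' chi-square quantile at the `significance` level (default 0.1%), the
#' sample is labelled `"unknown"`.
#'
#' @param features tibble (or named vector for a single sample) holding the
#'   fitted subset columns.
#' @param fit a [fit_groups()] object.
#' @param significance rejection level (default 0.001).
#' @return tibble with one row per sample: `species, sex, d2, p_value,
#'   label` plus a list-column `d2_table` of per-group distances.
#' @export
classify <- function(features, fit, significance = 0.001) {
  if (length(fit$groups) == 0) abort("no fitted groups")
  if (!is.data.frame(features)) {
    features <- tibble::as_tibble(as.list(features))
  }
  X <- as.matrix(features[, fit$subset, drop = FALSE])
  p <- length(fit$subset)
  threshold <- qchisq(1 - significance, df = p)
  # pre-factor each group's covariance once
  facs <- lapply(fit$groups, function(g) chol(g$sigma))
  out <- vector("list", nrow(X))
  for (i in seq_len(nrow(X))) {
    d2 <- vapply(seq_along(fit$groups), function(k) {
      g <- fit$groups[[k]]
      z <- backsolve(facs[[k]], X[i, ] - g$mu, transpose = TRUE)
      sum(z^2)
    }, numeric(1))
    names(d2) <- names(fit$groups)
    best <- which.min(d2)  # group names sorted; first minimum = lexicographic
    g <- fit$groups[[best]]
    d2_best <- d2[[best]]
    out[[i]] <- tibble::tibble(
      species = g$species, sex = g$sex, d2 = d2_best,
      p_value = pchisq(d2_best, df = p, lower.tail = FALSE),
      label = if (d2_best > threshold) "unknown" else g$species,
      d2_table = list(d2)
    )
  }
  dplyr::bind_rows(out)
}

#' Leave-one-out identification accuracy
#'
#' For every wing, the group statistics are re-computed without it (by
#' rank-one downdating of the group mean and scatter, equivalent to a full
#' refit) and the wing is classified against the remaining groups. Species
#' accuracy counts a species match regardless of sex; species-and-sex
#' accuracy counts both, evaluated only over wings whose (species, sex)
#' group exists in the fit. A wing labelled `"unknown"` counts as incorrect.
#'
#' @inheritParams fit_groups
#' @param significance rejection level passed to the chi-square rule.
#' @return list `(accuracy_species, accuracy_species_sex, n, n_sexed,
#'   calls)`; accuracies are fractions in `[0, 1]`.
#' @export
loo_accuracy <- function(features, subset = default_feature_subset(),
                         min_group_size = 12, significance = 0.001) {
  if (nrow(features) < 2) abort("need at least 2 samples")
  fit <- fit_groups(features, subset, min_group_size)
  if (length(fit$groups) == 0) abort("no retainable groups")
  p <- length(subset)
  threshold <- qchisq(1 - significance, df = p)
  # per-group sufficient statistics for downdating
  stats <- lapply(fit$groups, function(g) {
    list(n = g$n, mu = g$mu, M = g$sigma * (g$n - 1))  # M = scatter matrix
  })
  X <- as.matrix(features[, subset, drop = FALSE])
  key <- paste(features$species, features$sex, sep = "/")
  n_total <- nrow(X)
  ok_species <- logical(n_total); ok_both <- logical(n_total)
  sexed <- key %in% names(fit$groups)
  pred_label <- character(n_total)
  for (i in seq_len(n_total)) {
    x <- X[i, ]
    d2 <- rep(Inf, length(fit$groups))
    for (k in seq_along(fit$groups)) {
      g <- fit$groups[[k]]; s <- stats[[k]]
      if (names(fit$groups)[k] == key[i]) {
        n <- s$n
        if (n - 1 <= p) next  # group unusable without this wing
        dev <- x - s$mu
        mu2 <- (n * s$mu - x) / (n - 1)
        M2 <- s$M - (n / (n - 1)) * tcrossprod(dev)
        S2 <- M2 / (n - 2)
        R <- tryCatch(chol(S2), error = function(e) NULL)
        if (is.null(R)) next
        z <- backsolve(R, x - mu2, transpose = TRUE)
      } else {
        R <- chol(g$sigma)
        z <- backsolve(R, x - g$mu, transpose = TRUE)
      }
      d2[k] <- sum(z^2)
    }
    if (all(!is.finite(d2))) next
    best <- which.min(d2)
    g <- fit$groups[[best]]
    lab <- if (d2[best] > threshold) "unknown" else g$species
    pred_label[i] <- lab
    ok_species[i] <- identical(lab, features$species[i])
    ok_both[i] <- ok_species[i] && identical(g$sex, features$sex[i])
  }
  list(
    accuracy_species = mean(ok_species),
    accuracy_species_sex = if (any(sexed)) mean(ok_both[sexed]) else NA_real_,
    n = n_total, n_sexed = sum(sexed),
    calls = tibble::tibble(species = features$species, sex = features$sex,
                           predicted = pred_label,
                           correct_species = ok_species)
  )
}

#' Enumerate feature subsets
#'
#' All subsets of the given variables with sizes in `sizes`. Over the 16
#' wing variables with sizes 2 to 16 there are exactly
#' `sum(choose(16, 2:16)) = 65519` candidates.
#'
#' @param vars character vector of variable names.
#' @param sizes integer vector of subset sizes.
#' @return list of character vectors.
#' @export
enumerate_feature_subsets <- function(vars = feature_names(),
                                      sizes = 2:length(vars)) {
  sizes <- sizes[sizes >= 1 & sizes <= length(vars)]
  out <- list()
  for (k in sort(sizes)) {
    cmb <- combn(vars, k, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

#' Exhaustive (or sampled) feature-subset search
#'
#' Evaluates leave-one-out identification accuracy for every candidate
#' subset and returns the ranking. The full enumeration over 16 variables
#' is 65519 leave-one-out runs; `n_sample` draws a random subset of
#' candidates for desk-scale runs.
#'
#' @inheritParams loo_accuracy
#' @param sizes subset sizes to consider (default 2:16 over the available
#'   features).
#' @param n_sample optionally evaluate only this many randomly chosen
#'   candidates.
#' @param seed RNG seed for sampling mode.
#' @return tibble `subset, size, accuracy_species, accuracy_species_sex`
#'   sorted by decreasing species accuracy.
#' @export
subset_search <- function(features, sizes = NULL,
                          min_group_size = 12, significance = 0.001,
                          n_sample = NULL, seed = 1) {
  meta <- c("species", "sex", "wing_id")
  vars <- setdiff(names(features), meta)
  vars <- vars[vapply(features[vars], is.numeric, logical(1))]
  if (length(vars) < 2) abort("need at least 2 feature columns")
  if (is.null(sizes)) sizes <- 2:length(vars)
  cands <- enumerate_feature_subsets(vars, sizes)
  if (!is.null(n_sample) && n_sample < length(cands)) {
    cands <- withr::with_seed(seed, sample(cands, n_sample))
  }
  rows <- purrr::map(cands, function(s) {
    acc <- tryCatch(
      loo_accuracy(features, s, min_group_size, significance),
      error = function(e) NULL
    )
    if (is.null(acc)) return(NULL)
    tibble::tibble(subset = paste(s, collapse = ","), size = length(s),
                   accuracy_species = acc$accuracy_species,
                   accuracy_species_sex = acc$accuracy_species_sex)
  })
  dplyr::bind_rows(rows) |>
    dplyr::arrange(dplyr::desc(.data$accuracy_species), .data$size,
                   .data$subset)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted discriminant
#'
#' @param x a `wing_discriminant`.
#' @param ... unused.
#' @return one row per group with `species, sex, n` and the group means.
#' @method tidy wing_discriminant
#' @export
tidy.wing_discriminant <- function(x, ...) {
  purrr::map_dfr(x$groups, function(g) {
    dplyr::bind_cols(
      tibble::tibble(species = g$species, sex = g$sex, n = g$n),
      tibble::as_tibble(as.list(g$mu))
    )
  })
}

#' @rdname tidy.wing_discriminant
#' @method glance wing_discriminant
#' @export
glance.wing_discriminant <- function(x, ...) {
  tibble::tibble(
    n_groups = length(x$groups),
    n_variables = length(x$subset),
    n_excluded = nrow(x$excluded),
    n_samples = sum(vapply(x$groups, function(g) g$n, numeric(1)))
  )
}

#' Persist a fitted discriminant as JSON
#'
#' @param fit a `wing_discriminant`.
#' @param path output JSON path.
#' @export
write_discriminant <- function(fit, path) {
  obj <- list(
    version = as.character(utils::packageVersion("wingmorph")),
    subset = fit$subset, min_group_size = fit$min_group_size,
    groups = lapply(fit$groups, function(g) {
      list(species = g$species, sex = g$sex, n = g$n,
           mu = as.numeric(g$mu), sigma = as.numeric(g$sigma))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_discriminant
#' @export
read_discriminant <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- length(obj$subset)
  groups <- list()
  for (key in names(obj$groups)) {
    e <- obj$groups[[key]]
    groups[[key]] <- list(species = e$species, sex = e$sex, n = e$n,
                          mu = setNames(as.numeric(e$mu), obj$subset),
                          sigma = matrix(as.numeric(e$sigma), p, p))
  }
  if (length(groups) > 0) groups <- groups[order(names(groups))]
  structure(list(groups = groups, subset = obj$subset,
                 min_group_size = obj$min_group_size,
                 excluded = tibble::tibble()),
            class = "wing_discriminant")
}
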