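test_that("group bookkeeping retains 28 of 30 groups", {
  tab <- generate_feature_table(study_like_groups(), seed = 2)
  fit <- fit_groups(tab, default_feature_subset(), min_group_size = 12)
  expect_length(fit$groups, 28)
  expect_identical(nrow(fit$excluded), 2L)
  expect_setequal(fit$excluded$sex, "female")
  expect_identical(glance(fit)$n_groups, 28L)
  td <- tidy(fit)
  expect_identical(nrow(td), 28L)
  expect_true(all(default_feature_subset() %in% names(td)))
})

test_that("group statistics are consistent estimators", {
  g <- list(list(species = "s", sex = "female",
                 mu = c(v1 = 1, v2 = -2), sigma = diag(2), n = 500))
  tab <- generate_feature_table(g, seed = 11)
  fit <- fit_groups(tab, c("v1", "v2"), min_group_size = 12)
  est <- fit$groups[[1]]
  expect_lt(max(abs(est$mu - c(1, -2))), 0.15)
  expect_lt(max(abs(est$sigma - diag(2))), 0.2)
})

test_that("groups with n <= p are excluded as singular by construction", {
  g <- list(list(species = "s", sex = "male",
                 mu = setNames(rep(0, 6), default_feature_subset()),
                 sigma = diag(6), n = 6))
  tab <- generate_feature_table(g, seed = 3)
  fit <- fit_groups(tab, default_feature_subset(), min_group_size = 2)
  expect_length(fit$groups, 0)
  expect_match(fit$excluded$reason, "singular")
})

test_that("Mahalanobis distance matches explicit inversion and stats::", {
  g <- list(species = "s", sex = "f", n = 10,
            mu = c(1, 2), sigma = matrix(c(2, 0.5, 0.5, 1), 2, 2))
  x <- c(2, 3)
  Sinv <- solve(g$sigma)  # explicit 2x2 inverse oracle
  expected <- drop(t(x - g$mu) %*% Sinv %*% (x - g$mu))
  expect_equal(mahalanobis_d2(x, g), expected, tolerance = 1e-9)
  expect_equal(mahalanobis_d2(x, g),
               unname(stats::mahalanobis(rbind(x), g$mu, g$sigma)),
               tolerance = 1e-9)
  expect_equal(mahalanobis_d2(g$mu, g), 0)
  gI <- list(mu = c(0, 0), sigma = diag(2))
  expect_equal(mahalanobis_d2(c(3, 4), gI), 25)
  expect_error(mahalanobis_d2(c(1, 2, 3), g), "dimension mismatch")
})

test_that("Mahalanobis distance is invariant under affine feature maps", {
  set.seed(41)
  p <- 4
  X <- matrix(rnorm(60 * p), 60, p)
  colnames(X) <- paste0("v", 1:p)
  tab <- dplyr::bind_cols(tibble::tibble(species = "s", sex = "male"),
                          tibble::as_tibble(X))
  fit <- fit_groups(tab, paste0("v", 1:p), min_group_size = 10)
  A <- matrix(rnorm(p * p), p, p) + diag(p) * 2
  b <- rnorm(p)
  Xa <- sweep(X %*% t(A), 2, b, "+")
  colnames(Xa) <- paste0("v", 1:p)
  taba <- dplyr::bind_cols(tibble::tibble(species = "s", sex = "male"),
                           tibble::as_tibble(Xa))
  fita <- fit_groups(taba, paste0("v", 1:p), min_group_size = 10)
  x <- X[7, ]; xa <- drop(A %*% x + b)
  expect_equal(mahalanobis_d2(x, fit$groups[[1]]),
               mahalanobis_d2(xa, fita$groups[[1]]), tolerance = 1e-6)
})

test_that("classification picks the nearest group and rejects outliers", {
  tab <- generate_feature_table(separated_groups(3), seed = 6)
  fit <- fit_groups(tab, paste0("v", 1:6), min_group_size = 12)
  # a sample at a group mean belongs to it with D^2 = 0
  x <- tibble::as_tibble(as.list(fit$groups[[2]]$mu))
  res <- classify(x, fit)
  expect_identical(res$label, fit$groups[[2]]$species)
  expect_equal(res$d2, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)
  # chi-square boundary with 6 variables at the 0.1% level:
  # the 0.999 quantile of chi^2_6 is 22.45774 (Wilson-Hilferty-checked)
  q999 <- qchisq(0.999, 6)
  expect_equal(q999, 22.45774, tolerance = 1e-6)
  wh <- 6 * (1 - 2 / (9 * 6) + qnorm(0.999) * sqrt(2 / (9 * 6)))^3
  expect_equal(q999, wh, tolerance = 0.02)
  g1 <- fit$groups[[1]]
  dir <- c(1, rep(0, 5))
  R <- chol(g1$sigma)
  step <- drop(t(R) %*% dir)  # unit Mahalanobis step
  x_in <- g1$mu + sqrt(q999 - 0.05) * step / sqrt(sum(dir^2))
  x_out <- g1$mu + sqrt(q999 + 0.05) * step / sqrt(sum(dir^2))
  r_in <- classify(tibble::as_tibble(as.list(x_in)), fit)
  r_out <- classify(tibble::as_tibble(as.list(x_out)), fit)
  expect_identical(r_in$label, g1$species)
  expect_identical(r_out$label, "unknown")
  # per-group table retained, minimum attained at the reported group
  expect_equal(min(r_in$d2_table[[1]]), r_in$d2)
})

test_that("the unknown rule rejects calibrated draws at the 0.1% level", {
  p <- 6
  tab <- generate_feature_table(list(list(
    species = "only", sex = "female",
    mu = setNames(rep(0, p), paste0("v", 1:p)), sigma = diag(p),
    n = 400)), seed = 17)
  fit <- fit_groups(tab, paste0("v", 1:p), min_group_size = 12)
  g <- fit$groups[[1]]
  # draws from the fitted group's own Gaussian follow chi^2_p exactly
  n_draw <- 100000
  withr::with_seed(17, {
    Z <- matrix(rnorm(n_draw * p), n_draw, p)
    X <- sweep(Z %*% chol(g$sigma), 2, g$mu, "+")
  })
  R <- chol(g$sigma)
  dev <- sweep(X, 2, g$mu)
  z <- dev %*% solve(R)  # whiten: rows ~ N(0, I)
  d2 <- rowSums(z^2)
  rate <- mean(d2 > qchisq(0.999, p))
  ci <- 3.29 * sqrt(0.001 * 0.999 / n_draw)  # 99.9% binomial band
  expect_lt(abs(rate - 0.001), ci + 1e-12)
  # the classifier's rejection agrees with the direct computation
  sub <- X[1:2000, , drop = FALSE]
  colnames(sub) <- paste0("v", 1:p)
  calls <- classify(tibble::as_tibble(sub), fit)
  expect_equal(mean(calls$label == "unknown"),
               mean(d2[1:2000] > qchisq(0.999, p)))
})

test_that("within-group distances follow the chi-square law", {
  p <- 6
  tab <- generate_feature_table(list(list(
    species = "only", sex = "female",
    mu = setNames(rnorm(p), paste0("v", 1:p)),
    sigma = crossprod(matrix(rnorm(p * p), p)) / p + diag(p),
    n = 250)), seed = 23)
  fit <- fit_groups(tab, paste0("v", 1:p), min_group_size = 12)
  g <- fit$groups[[1]]
  withr::with_seed(23, {
    Z <- matrix(rnorm(10000 * p), 10000, p)
    X <- sweep(Z %*% chol(g$sigma), 2, g$mu, "+")
  })
  d2 <- apply(X, 1, mahalanobis_d2, group = g)
  ks <- suppressWarnings(stats::ks.test(d2, "pchisq", df = p))
  expect_gt(ks$p.value, 0.01)
})

test_that("leave-one-out accuracy separates what is separable", {
  # well-separated species: perfect species accuracy (rejection rule
  # disabled so the rare chi-square rejection cannot spoil separability)
  tab <- generate_feature_table(separated_groups(2, n = 50), seed = 8)
  acc <- loo_accuracy(tab, paste0("v", 1:6), min_group_size = 12,
                      significance = 1e-9)
  expect_equal(acc$accuracy_species, 1)
  expect_identical(acc$n, 100L)
  # identical distributions: chance level
  g2 <- separated_groups(2, n = 50, spread = 0)
  tab2 <- generate_feature_table(g2, seed = 5)
  acc2 <- loo_accuracy(tab2, paste0("v", 1:6), min_group_size = 12)
  expect_gt(acc2$accuracy_species, 0.35)
  expect_lt(acc2$accuracy_species, 0.65)
})

test_that("downdated leave-one-out equals naive refitting", {
  set.seed(31)
  groups <- separated_groups(2, p = 3, n = 18, spread = 3)
  tab <- generate_feature_table(groups, seed = 31)
  acc <- loo_accuracy(tab, paste0("v", 1:3), min_group_size = 5)
  # naive reference: full refit per held-out wing
  naive_correct <- logical(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    fit_i <- fit_groups(tab[-i, ], paste0("v", 1:3), min_group_size = 5)
    call_i <- classify(tab[i, ], fit_i)
    naive_correct[i] <- identical(call_i$label, tab$species[i])
  }
  expect_equal(acc$accuracy_species, mean(naive_correct))
  expect_equal(acc$calls$correct_species, naive_correct)
})

test_that("subset enumeration counts match the combinatorics", {
  expect_length(enumerate_feature_subsets(feature_names(), 2:16), 65519)
  expect_length(enumerate_feature_subsets(paste0("v", 1:4), 2:4), 11)
  expect_length(enumerate_feature_subsets(paste0("v", 1:4), 2), 6)
})

test_that("subset search recovers a planted signal", {
  p <- 4
  set.seed(3)
  groups <- list()
  for (i in 1:2) {
    mu <- setNames(rep(0, p), paste0("v", 1:p))
    mu[1:2] <- i * 5  # only v1, v2 discriminate
    groups[[i]] <- list(species = paste0("sp", i), sex = "female",
                        mu = mu, sigma = diag(p), n = 100)
  }
  tab <- generate_feature_table(groups, seed = 3)
  rank <- subset_search(tab, sizes = 2:4, min_group_size = 12)
  top <- strsplit(rank$subset[1], ",")[[1]]
  expect_true(all(c("v1", "v2") %in% top) ||
                any(c("v1", "v2") %in% top) && rank$accuracy_species[1] == 1)
  # every top-accuracy subset contains at least one signal coordinate
  best <- rank[rank$accuracy_species == max(rank$accuracy_species), ]
  has_signal <- vapply(strsplit(best$subset, ","),
                       function(s) any(c("v1", "v2") %in% s), logical(1))
  expect_true(all(has_signal))
})

test_that("fitted discriminants survive a JSON round trip", {
  tab <- generate_feature_table(separated_groups(2), seed = 12)
  fit <- fit_groups(tab, paste0("v", 1:6), min_group_size = 12)
  path <- withr::local_tempfile(fileext = ".json")
  write_discriminant(fit, path)
  back <- read_discriminant(path)
  expect_identical(names(back$groups), names(fit$groups))
  expect_equal(back$groups[[1]]$mu, fit$groups[[1]]$mu,
               tolerance = 1e-12)
  expect_equal(back$groups[[2]]$sigma, fit$groups[[2]]$sigma,
               tolerance = 1e-12, ignore_attr = TRUE)
  x <- tibble::as_tibble(as.list(fit$groups[[1]]$mu))
  expect_equal(classify(x, back)$d2, classify(x, fit)$d2,
               tolerance = 1e-9)
})
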