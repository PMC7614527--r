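random_compositions <- function(n, K, seed = 1) {
  set.seed(seed)
  x <- matrix(rexp(n * K), n, K)
  x / rowSums(x)
}

test_that("the Helmert sub-basis is orthonormal with zero-sum rows", {
  for (K in c(2, 4, 6)) {
    H <- helmert_basis(K)
    expect_equal(H %*% t(H), diag(K - 1), tolerance = 1e-10)
    expect_lt(max(abs(H %*% rep(1, K))), 1e-12)
  }
})

test_that("alpha-transform maps the simplex center to zero and is injective", {
  for (alpha in c(0.5, 1, 2)) {
    z <- alpha_transform(rep(1 / 6, 6), alpha)
    expect_equal(drop(z), rep(0, 5), tolerance = 1e-12)
  }
  z2 <- alpha_transform(c(0.75, 0.25), alpha = 1)
  expect_equal(drop(z2), drop(helmert_basis(2) %*% c(0.5, -0.5)))
  expect_equal(drop(z2), 1 / sqrt(2), tolerance = 1e-12)
  x <- random_compositions(40, 5, seed = 2)
  z <- alpha_transform(x, 1)
  d <- as.matrix(dist(z))
  expect_gt(min(d[upper.tri(d)]), 0)   # distinct compositions stay distinct
  expect_error(alpha_transform(x, 0), "non-zero")
  expect_error(alpha_transform(matrix(c(0.7, 0.2), 1, 2), 1), "sum to 1")
})

test_that("PCA conserves variance and identifies rank-1 structure", {
  x <- random_compositions(100, 5, seed = 3)
  cp <- suppressWarnings(composition_pca(x))
  z <- alpha_transform(x, 1)
  expect_equal(sum(cp$eigenvalues), sum(apply(z, 2, var)), tolerance = 1e-10)
  # SVD cross-check of the leading eigenvalue
  zc <- scale(z, scale = FALSE)
  sv <- svd(zc)$d
  expect_equal(cp$eigenvalues, sv^2 / (nrow(x) - 1), tolerance = 1e-10)
  # compositions on a line through the simplex -> single component
  t_ <- seq(-0.05, 0.05, length.out = 30)
  line <- t(sapply(t_, function(s) rep(1 / 4, 4) + s * c(3, -1, -1, -1) / 4))
  cpl <- composition_pca(line)
  expect_equal(cpl$variance_explained[1], 1, tolerance = 1e-10)
  expect_equal(cpl$n_selected, 1L)
})

test_that("broken-stick values and selection match direct computation", {
  expect_equal(broken_stick_values(1), 1)
  b5 <- broken_stick_values(5)
  direct <- sapply(1:5, function(k) sum(1 / (k:5)) / 5)
  expect_equal(b5, direct, tolerance = 1e-12)
  expect_equal(b5, c(0.45667, 0.25667, 0.15667, 0.09, 0.04),
               tolerance = 1e-4)
  lam <- c(0.68, 0.12, 0.10, 0.06, 0.04)
  expect_equal(as.integer(broken_stick_select(lam)), 1L)
  # two leading components exceed their stick expectations
  lam2 <- c(0.50, 0.30, 0.10, 0.06, 0.04)
  expect_equal(as.integer(broken_stick_select(lam2)), 2L)
  expect_warning(sel <- broken_stick_select(rep(0.25, 4)), "retaining one")
  expect_equal(as.integer(sel), 1L)
  expect_true(attr(sel, "forced"))
})

test_that("varimax rotation is orthogonal and matches an angle-grid oracle", {
  set.seed(4)
  L <- qr.Q(qr(matrix(rnorm(36), 6, 6)))[, 1:2] %*% diag(c(2, 1))
  vm <- varimax(L, normalize = FALSE)
  R <- vm$rotmat
  expect_equal(t(R) %*% R, diag(2), tolerance = 1e-8)
  expect_gte(varimax_criterion(unclass(vm$loadings)),
             varimax_criterion(L) - 1e-12)
  thetas <- seq(0, pi / 2, length.out = 20001)
  crit <- vapply(thetas, function(th) varimax_criterion(rotate2(L, th)),
                 numeric(1))
  expect_equal(varimax_criterion(unclass(vm$loadings)), max(crit),
               tolerance = 1e-4)
  # a varimax-optimal matrix is a fixed point of the criterion
  vm2 <- varimax(unclass(vm$loadings), normalize = FALSE)
  expect_equal(varimax_criterion(unclass(vm2$loadings)),
               varimax_criterion(unclass(vm$loadings)), tolerance = 1e-10)
})

test_that("scores center at the training mean and compute linearly", {
  x <- random_compositions(60, 6, seed = 5)
  cp <- suppressWarnings(composition_pca(x))
  # mean composition in transform space scores 0
  zbar <- colMeans(alpha_transform(x, 1))
  # build a composition whose transform equals the training mean
  xc <- drop(t(helmert_basis(6)) %*% zbar + 1) / 6
  s0 <- predict(cp, matrix(xc, 1))
  expect_lt(max(abs(as.matrix(s0[, -1]))), 1e-10)
  # reflection through the training mean flips the score sign
  # (use a composition near the mean so the reflection stays on the simplex)
  x1 <- 0.9 * xc + 0.1 * x[1, ]
  z1 <- drop(alpha_transform(x1, 1))
  z_ref <- 2 * zbar - z1
  x_ref <- drop(t(helmert_basis(6)) %*% z_ref + 1) / 6
  expect_true(all(x_ref > 0))
  s1 <- as.matrix(predict(cp, matrix(x1, 1))[, -1])
  s_ref <- as.matrix(predict(cp, matrix(x_ref, 1))[, -1])
  expect_equal(s_ref, -s1, tolerance = 1e-10)
  # stepwise equals one-shot
  z_all <- alpha_transform(x, 1)
  manual <- sweep(z_all, 2, cp$center) %*% cp$loadings
  expect_equal(as.matrix(cp$scores[, -1]), manual, ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("state permutation of the occupancy columns permutes loadings", {
  x <- random_compositions(80, 5, seed = 6)
  perm <- c(3, 1, 5, 2, 4)
  cp1 <- suppressWarnings(composition_pca(x))
  cp2 <- suppressWarnings(composition_pca(x[, perm]))
  expect_equal(unname(cp2$state_loadings[, 1]),
               unname(cp1$state_loadings[perm, 1]), tolerance = 1e-8)
  expect_equal(cp2$eigenvalues, cp1$eigenvalues, tolerance = 1e-10)
})

test_that("a planted occupancy axis dominates the retained component", {
  # long scans shrink occupancy noise so the planted group axis dominates
  spec <- cohort_spec(group_sizes = c("non-carrier" = 25,
                                      "presymptomatic" = 0,
                                      "symptomatic" = 25),
                      n_converters = 0, n_channels = 3, t_per_scan = 4000,
                      seed = 17)
  sim <- simulate_cohort(spec)
  pm <- path_metrics(sim$true_paths, 6, repetition_times = 2)
  cp <- composition_pca(pm)
  expect_gt(cp$variance_explained[1], 0.6)
  expect_equal(cp$n_selected, 1L)
  # higher scores load on the target state with a positive sign
  expect_gt(cp$state_loadings[2, 1], 0)
})
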