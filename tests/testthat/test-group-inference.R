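fake_cohort <- function(n, effect = 0, site_levels = 3, seed = 1) {
  set.seed(seed)
  g <- rep(c("non-carrier", "symptomatic"), length.out = n)
  tibble::tibble(
    group = factor(g),
    age = rnorm(n, 55, 10),
    sex = sample(c("F", "M"), n, replace = TRUE),
    site = sample(paste0("site_", seq_len(site_levels)), n, replace = TRUE),
    metric = rnorm(n) + effect * (g == "symptomatic")
  )
}

test_that("the group test is null-calibrated and detects planted shifts", {
  set.seed(100)
  p_null <- replicate(200, {
    d <- fake_cohort(60, effect = 0, seed = sample.int(1e6, 1))
    fit_metric_model(d, "metric", method = "ancova")$p_value
  })
  # type I at .05 within the binomial 95% CI for 200 draws
  expect_gt(mean(p_null < 0.05), 0.05 - 1.96 * sqrt(0.05 * 0.95 / 200) - 0.001)
  expect_lt(mean(p_null < 0.05), 0.05 + 1.96 * sqrt(0.05 * 0.95 / 200) + 0.001)
  # and roughly uniform overall
  expect_gt(suppressWarnings(ks.test(p_null, "punif"))$p.value, 0.01)
  d_eff <- fake_cohort(100, effect = 1.2, seed = 7)
  expect_lt(fit_metric_model(d_eff, "metric", method = "ancova")$p_value,
            0.001)
})

test_that("mixed and fixed group tests agree when site variance is zero", {
  d <- fake_cohort(120, effect = 0.5, site_levels = 4, seed = 3)
  fixed <- fit_metric_model(d, "metric", method = "ancova")
  mixed <- suppressWarnings(suppressMessages(
    fit_metric_model(d, "metric", method = "mixed")))
  expect_equal(mixed$statistic, fixed$statistic, tolerance = 1e-4)
  one_site <- dplyr::mutate(d, site = "site_1")
  expect_warning(res <- fit_metric_model(one_site, "metric",
                                         method = "mixed"), "fewer than 2")
  expect_equal(res$statistic, fixed$statistic, tolerance = 1e-6)
})

test_that("age-model comparison favors the true generative degree", {
  set.seed(200)
  null_favor <- replicate(30, {
    n <- 120
    d <- tibble::tibble(age = runif(n, 30, 75),
                        sex = sample(c("F", "M"), n, TRUE),
                        site = "s1")
    d$metric <- 0.03 * d$age + rnorm(n)
    compare_age_models(d, "metric")$quadratic_favored
  })
  expect_lte(mean(null_favor), 0.2)
  quad_favor <- replicate(30, {
    n <- 120
    d <- tibble::tibble(age = runif(n, 30, 75),
                        sex = sample(c("F", "M"), n, TRUE),
                        site = "s1")
    d$metric <- 0.004 * (d$age - 52)^2 + rnorm(n)
    compare_age_models(d, "metric")$quadratic_favored
  })
  expect_gte(mean(quad_favor), 0.9)
})

test_that("group-by-age interaction is detected when planted and not otherwise", {
  set.seed(300)
  make_int <- function(beta_int, seed) {
    set.seed(seed)
    n <- 160
    g <- rep(c("non-carrier", "presymptomatic"), each = n / 2)
    age <- runif(n, 30, 75)
    tibble::tibble(
      group = factor(g), age = age,
      sex = sample(c("F", "M"), n, TRUE), site = "s1",
      metric = 0.01 * age + beta_int * (g == "presymptomatic") *
        pmax(age - 50, 0) + rnorm(n, 0, 0.5))
  }
  p_eff <- replicate(20, group_by_age_interaction(
    make_int(0.08, sample.int(1e6, 1)), "metric", degree = 2)$p_value)
  expect_gte(mean(p_eff < 0.05), 0.9)
  p_null <- replicate(30, group_by_age_interaction(
    make_int(0, sample.int(1e6, 1)), "metric", degree = 2)$p_value)
  rate <- mean(p_null < 0.05)
  expect_lte(rate, 0.2)
  # permuting group labels destroys a planted interaction
  d <- make_int(0.08, 11)
  d_perm <- dplyr::mutate(d, group = sample(group))
  p_perm <- replicate(10, group_by_age_interaction(
    dplyr::mutate(d, group = sample(group)), "metric", degree = 2)$p_value)
  expect_gt(mean(p_perm), 0.2)   # typically non-significant once shuffled
})

test_that("exact permutation p values match brute-force enumeration", {
  set.seed(400)
  K <- 2
  d <- null_transition_cohort(4, K, 60, 0.7)   # n = 8, 70 label splits
  res <- permutation_test_transitions(d, covariates = character(0),
                                      n_perm = 500, seed = 1)
  expect_true(res$exact)
  expect_equal(res$n_perm, 70)
  # independent brute force via lm on every split
  p_cols <- grep("^P_", names(d), value = TRUE)
  splits <- combn(8, 4)
  tmat <- apply(splits, 2, function(idx) {
    g <- rep(1, 8); g[idx] <- 0
    vapply(p_cols, function(cl)
      summary(lm(d[[cl]] ~ g))$coefficients["g", "t value"], numeric(1))
  })
  obs <- vapply(p_cols, function(cl)
    summary(lm(d[[cl]] ~ I(d$group == "b")))$coefficients[2, "t value"],
    numeric(1))
  max_t <- apply(abs(tmat), 2, max)
  p_exact <- vapply(abs(obs), function(t0) mean(max_t >= t0 - 1e-12),
                    numeric(1))
  expect_equal(res$cells$fwe_p, unname(p_exact), tolerance = 1e-12)
  expect_equal(abs(res$cells$t), unname(abs(obs)), tolerance = 1e-8)
})

test_that("permutation p values respect the smoothing floor and relabelling", {
  set.seed(500)
  d <- null_transition_cohort(12, 3, 80, 0.7)
  res <- permutation_test_transitions(d, n_perm = 200, seed = 2)
  expect_true(all(res$cells$fwe_p >= 1 / 201))
  expect_true(all(res$cells$fwe_p <= 1))
  # consistent state relabelling permutes cells but not the p-value multiset
  perm <- c(2, 3, 1)
  d2 <- d
  for (i in 1:3) for (j in 1:3)
    d2[[paste0("P_", i, "_", j)]] <- d[[paste0("P_", perm[i], "_", perm[j])]]
  res2 <- permutation_test_transitions(d2, n_perm = 200, seed = 2)
  expect_equal(sort(res2$cells$fwe_p), sort(res$cells$fwe_p),
               tolerance = 1e-12)
})

test_that("a planted persistence difference is localized by the test", {
  set.seed(600)
  K <- 3
  A0 <- matrix(0.15, K, K); diag(A0) <- 0.7
  A1 <- statedyn:::shift_transition(A0, 1, 0.15)
  mk <- function(A, n) {
    paths <- simulate_state_paths(A, 250, n_paths = n,
                                  init_probs = rep(1 / K, K))
    rows <- lapply(paths, function(path) {
      P <- subject_transition_matrix(hard_posterior(path, K), group_trans = A)
      out <- as.list(as.vector(t(P)))
      names(out) <- paste0("P_", rep(1:K, each = K), "_", rep(1:K, K))
      out
    })
    dplyr::bind_rows(rows)
  }
  d <- dplyr::bind_rows(mk(A0, 40), mk(A1, 40))
  d$group <- rep(c("a", "b"), each = 40)
  d$age <- rnorm(80, 50, 8)
  d$sex <- sample(c("F", "M"), 80, TRUE)
  res <- permutation_test_transitions(d, n_perm = 500, seed = 3)
  cell <- dplyr::filter(res$cells, from_state == 1, to_state == 1)
  expect_lt(cell$fwe_p, 0.05)
  expect_gt(cell$t, 0)
})

test_that("BH adjustment matches an independent step-up implementation", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(700)
  for (i in 1:1000) {
    p <- runif(sample(1:20, 1))
    expect_identical(fdr_adjust(p), bh_stepup(p))
  }
  p <- runif(50)
  adj <- fdr_adjust(p)
  expect_true(all(adj >= p))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the converter contrast detects an intermediate planted effect", {
  spec <- cohort_spec(group_sizes = c("non-carrier" = 0,
                                      "presymptomatic" = 120,
                                      "symptomatic" = 0),
                      n_converters = 40, n_channels = 3, t_per_scan = 600,
                      seed = 23)
  sim <- simulate_cohort(spec)
  d <- sim$cohort
  d$FO_2 <- d$true_target_occupancy
  res <- suppressWarnings(suppressMessages(converter_contrast(d, "FO_2")))
  expect_lt(res$p_value, 0.05)
  est <- mean(d$FO_2[d$converter]) - mean(d$FO_2[!d$converter])
  expect_gt(est, 0)
  d0 <- d[1:10, ]; d0$converter <- FALSE
  expect_error(converter_contrast(d0, "FO_2"), "converters")
})
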