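toy_visits <- function(n_subj, n_visits, slopes, intercepts, noise_sd,
                       seed = 1) {
  set.seed(seed)
  d <- tidyr::expand_grid(subject_id = sprintf("s%02d", seq_len(n_subj)),
                          years_from_baseline = seq_len(n_visits) - 1)
  i <- match(d$subject_id, sprintf("s%02d", seq_len(n_subj)))
  d$score <- intercepts[i] + slopes[i] * d$years_from_baseline +
    rnorm(nrow(d), 0, noise_sd)
  d
}

test_that("floor removal is outcome-local and based on baseline values", {
  v <- tidyr::expand_grid(subject_id = sprintf("s%02d", 1:10),
                          years_from_baseline = 0:2)
  v$mmse <- 25
  v$tmtb <- 100
  v$mmse[v$subject_id %in% c("s01", "s02", "s03") &
           v$years_from_baseline == 0] <- 0       # floored at baseline
  v$mmse[v$subject_id == "s04" & v$years_from_baseline == 2] <- 0  # later only
  v$tmtb[v$subject_id == "s05" & v$years_from_baseline == 0] <- 300 # ceiling
  res <- remove_floor(v, list(mmse = list(floor = 0),
                              tmtb = list(ceiling = 300)))
  expect_equal(res$report$n_removed[res$report$outcome == "mmse"], 3L)
  kept_mmse <- unique(res$visits$mmse$subject_id)
  expect_false(any(c("s01", "s02", "s03") %in% kept_mmse))
  expect_true("s04" %in% kept_mmse)   # floored later, not at baseline
  # outcome-local: s01 floored on mmse stays available for tmtb
  expect_true("s01" %in% unique(res$visits$tmtb$subject_id))
  expect_false("s05" %in% unique(res$visits$tmtb$subject_id))
  # no subject at floor -> identity
  res0 <- remove_floor(v, list(tmtb = list(floor = -1)))
  expect_equal(nrow(res0$visits$tmtb), nrow(v))
  expect_error(remove_floor(v, list(nope = list(floor = 0))), "unknown")
})

test_that("slopes are recovered from near-noise-free trajectories", {
  true_slopes <- seq(-2, 2, length.out = 15)
  v <- toy_visits(15, 6, true_slopes, rep(20, 15), noise_sd = 1e-4, seed = 2)
  sl <- suppressWarnings(suppressMessages(estimate_slopes(v, "score")))
  expect_lt(max(abs(sl$slope - true_slopes)), 0.05)
  expect_equal(sl$n_visits, rep(6L, 15))
})

test_that("single-visit subjects are shrunk toward the population slope", {
  set.seed(3)
  true_slopes <- rnorm(30, -1, 0.8)
  v <- toy_visits(30, 4, true_slopes, rnorm(30, 25, 2), noise_sd = 0.8,
                  seed = 4)
  # two added subjects share a trajectory far from the population slope:
  # s31 contributes its baseline point only, s32 the full trajectory
  traj <- 25 + 1.5 * (0:3)
  v1 <- tibble::tibble(subject_id = "s31", years_from_baseline = 0,
                       score = traj[1])
  v2 <- tibble::tibble(subject_id = "s32", years_from_baseline = 0:3,
                       score = traj)
  sl <- suppressWarnings(suppressMessages(
    estimate_slopes(dplyr::bind_rows(v, v1, v2), "score")))
  fixed <- attr(sl, "fixed_slope")
  dev_single <- abs(sl$slope[sl$subject_id == "s31"] - fixed)
  dev_multi <- abs(sl$slope[sl$subject_id == "s32"] - fixed)
  expect_lt(dev_single, dev_multi)
})

test_that("the population slope estimate covers the planted value", {
  covered <- replicate(20, {
    true_mean_slope <- -1.5
    sl_i <- rnorm(25, true_mean_slope, 0.4)
    v <- toy_visits(25, 4, sl_i, rnorm(25, 25, 1), noise_sd = 0.7,
                    seed = sample.int(1e6, 1))
    sl <- suppressWarnings(suppressMessages(estimate_slopes(v, "score")))
    est <- attr(sl, "fixed_slope")
    se <- attr(sl, "fixed_slope_se")
    abs(est - true_mean_slope) < 1.96 * (se + 0.4 / sqrt(25))
  })
  expect_gte(mean(covered), 0.9)
})

second_stage_data <- function(n, beta, seed, site_levels = 3,
                              site_conf = 0) {
  set.seed(seed)
  site <- sample(paste0("site_", seq_len(site_levels)), n, replace = TRUE)
  site_eff <- as.numeric(factor(site)) * site_conf
  comp <- rnorm(n) + site_eff
  slope <- -1 + beta * comp + site_eff + rnorm(n, 0, 0.5)
  list(
    slopes = tibble::tibble(subject_id = sprintf("s%03d", 1:n),
                            intercept = 25, slope = slope, slope_se = 0.1,
                            n_visits = 4L),
    scores = tibble::tibble(subject_id = sprintf("s%03d", 1:n),
                            comp_1 = comp),
    cohort = tibble::tibble(subject_id = sprintf("s%03d", 1:n),
                            age = rnorm(n, 55, 10),
                            sex = sample(c("F", "M"), n, TRUE),
                            site = site,
                            group = factor(rep(c("non-carrier",
                                                 "presymptomatic"),
                                               length.out = n)))
  )
}

test_that("second-stage regression recovers planted links and stays null-calibrated", {
  hits <- replicate(30, {
    d <- second_stage_data(60, beta = -0.5, seed = sample.int(1e6, 1))
    r <- predict_decline(d$slopes, d$scores, d$cohort, form = "comp")
    r$p_value < 0.05 && r$std_beta < 0
  })
  expect_gte(mean(hits), 0.9)
  p_null <- replicate(50, {
    d <- second_stage_data(60, beta = 0, seed = sample.int(1e6, 1))
    predict_decline(d$slopes, d$scores, d$cohort, form = "comp")$p_value
  })
  expect_gt(mean(p_null < 0.05), 0)   # sanity: p values vary
  expect_lt(mean(p_null < 0.05), 0.15)
})

test_that("standardized betas are invariant to outcome rescaling", {
  d <- second_stage_data(80, beta = -0.4, seed = 9)
  r1 <- predict_decline(d$slopes, d$scores, d$cohort, form = "comp")
  d$slopes$slope <- d$slopes$slope * 10
  r2 <- predict_decline(d$slopes, d$scores, d$cohort, form = "comp")
  expect_equal(r2$std_beta, r1$std_beta, tolerance = 1e-10)
  expect_equal(r2$statistic, r1$statistic, tolerance = 1e-10)
})

test_that("site enters as a fixed covariate and controls confounding", {
  d <- second_stage_data(200, beta = 0, seed = 10, site_conf = 1)
  with_site <- predict_decline(d$slopes, d$scores, d$cohort, form = "comp")
  no_site <- predict_decline(d$slopes, d$scores,
                             dplyr::mutate(d$cohort, site = "s1"),
                             form = "comp")
  expect_lt(abs(with_site$std_beta), abs(no_site$std_beta))
  # site label permutation leaves the estimate unchanged
  relab <- dplyr::mutate(d$cohort,
                         site = factor(site,
                                       levels = c("site_2", "site_3",
                                                  "site_1")))
  r_rel <- predict_decline(d$slopes, d$scores, relab, form = "comp")
  expect_equal(r_rel$std_beta, with_site$std_beta, tolerance = 1e-10)
})

test_that("interaction forms report the headline term", {
  d <- second_stage_data(120, beta = -0.3, seed = 11)
  r2 <- predict_decline(d$slopes, d$scores, d$cohort, form = "comp_age")
  expect_equal(r2$term, "comp_z:age_z")
  r3 <- predict_decline(d$slopes, d$scores, d$cohort,
                        form = "comp_age_group")
  expect_match(r3$term, "comp_z:age_z:group")
  expect_true(all(is.finite(c(r2$std_beta, r3$std_beta))))
})

test_that("two-step pipeline ties stages together with per-form FDR", {
  spec <- cohort_spec(group_sizes = c("non-carrier" = 0,
                                      "presymptomatic" = 0,
                                      "symptomatic" = 50),
                      n_converters = 0, n_channels = 3, t_per_scan = 400,
                      n_visits = 4, seed = 15)
  sim <- simulate_cohort(spec)
  pm <- path_metrics(sim$true_paths, 6, repetition_times = 2)
  cp <- suppressWarnings(composition_pca(pm))
  scores <- dplyr::mutate(cp$scores,
                          subject_id = sub("_scan_1", "", scan_id))
  res <- suppressWarnings(suppressMessages(two_step_prediction(
    sim$visits, scores[c("subject_id", "comp_1")], sim$cohort,
    outcomes = "cognition", forms = "comp")))
  expect_equal(nrow(res), 1)
  # the planted link is negative through the positive target-state loading
  expect_lt(res$std_beta * sign(cp$state_loadings[2, 1]), 0)
  expect_lt(res$p_value, 0.05)
})
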