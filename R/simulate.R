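#' Construct a K-state shared-covariance Gaussian HMM object
#'
#' Container for the model used throughout the package: initial state
#' probabilities, a row-stochastic transition matrix, per-state mean vectors
#' and one covariance matrix shared by all states.
#'
#' @param init_probs length-K probability vector (sums to 1).
#' @param trans K x K row-stochastic transition matrix.
#' @param means K x C matrix of state means (z-units).
#' @param sigma C x C symmetric positive-definite covariance shared by states.
#' @param diagnostics optional list of fit diagnostics (log-likelihood trace,
#'   iterations, restart seed, warnings).
#' @return An object of class `statedyn_hmm`.
#' @export
new_hmm <- function(init_probs, trans, means, sigma, diagnostics = NULL) {
  K <- length(init_probs)
  means <- as.matrix(means)
  trans <- as.matrix(trans)
  sigma <- as.matrix(sigma)
  stopifnot(nrow(trans) == K, ncol(trans) == K, nrow(means) == K,
            nrow(sigma) == ncol(sigma), ncol(means) == nrow(sigma))
  if (abs(sum(init_probs) - 1) > 1e-8)
    abort("`init_probs` must sum to 1.")
  if (max(abs(rowSums(trans) - 1)) > 1e-8)
    abort("rows of `trans` must sum to 1.")
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    abort("`sigma` must be positive-definite.")
  structure(
    list(init_probs = as.numeric(init_probs), trans = trans, means = means,
         sigma = sigma, K = K, C = ncol(means), diagnostics = diagnostics),
    class = "statedyn_hmm"
  )
}

#' @export
print.statedyn_hmm <- function(x, ...) {
  cat(sprintf("Gaussian HMM: %d states, %d channels, shared covariance\n",
              x$K, x$C))
  cat("Persistence probabilities:",
      paste(sprintf("%.3f", diag(x$trans)), collapse = " "), "\n")
  if (!is.null(x$diagnostics)) {
    d <- x$diagnostics
    cat(sprintf("Fit: logLik %.2f after %d EM iterations (%sconverged)\n",
                d$loglik, d$n_iter, if (isTRUE(d$converged)) "" else "not "))
  }
  invisible(x)
}

#' Stationary distribution of a transition matrix
#'
#' @param trans row-stochastic K x K matrix.
#' @return length-K stationary probability vector.
#' @export
stationary_distribution <- function(trans) {
  e <- eigen(t(trans))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

#' Sample a ground-truth HMM for simulation
#'
#' Builds a K-state model with a common persistence probability on the
#' diagonal and the remaining mass split evenly across other states. State
#' means are drawn from a standard Gaussian and, when needed, rescaled so the
#' minimum pairwise Euclidean separation is at least `mean_separation`
#' z-units; the shared covariance is a random correlation matrix (unit
#' diagonal, eigenvalues well away from zero), so channel noise has unit SD
#' and mean separations read directly in z-units.
#'
#' @param K number of states (>= 2).
#' @param C number of channels/components (C >= K recommended).
#' @param persistence diagonal transition probability, in (0, 1).
#' @param mean_separation minimum pairwise distance between state means.
#' @param seed integer seed; identical seeds yield identical models.
#' @return a `statedyn_hmm` with uniform initial probabilities.
#' @export
sample_ground_truth <- function(K, C, persistence, mean_separation = 1,
                                seed = 1L) {
  if (K < 2) abort("`K` must be at least 2.")
  if (!is.finite(persistence) || persistence <= 0 || persistence >= 1)
    abort("`persistence` must lie strictly inside (0, 1).")
  set.seed(seed)
  A <- matrix((1 - persistence) / (K - 1), K, K)
  diag(A) <- persistence

  M <- matrix(rnorm(K * C), K, C)
  d <- as.matrix(stats::dist(M))
  min_d <- min(d[upper.tri(d)])
  if (min_d < mean_separation) M <- M * (mean_separation / min_d)

  Q <- qr.Q(qr(matrix(rnorm(C * C), C, C)))
  lam <- runif(C, 0.5, 2)
  sigma <- Q %*% (lam * t(Q))
  sigma <- stats::cov2cor((sigma + t(sigma)) / 2)

  new_hmm(rep(1 / K, K), A, M, sigma)
}

#' Simulate one scan from an HMM
#'
#' Samples a hidden state path from the initial distribution and transition
#' matrix, then emits multivariate Gaussian observations with the state's mean
#' and the shared covariance. The returned time course is raw (not
#' standardized); standardization is an explicit downstream step.
#'
#' @param hmm a `statedyn_hmm`.
#' @param n_timepoints number of volumes T (>= 2).
#' @param seed integer seed.
#' @param repetition_time seconds per volume, attached as an attribute.
#' @return list with `state_path` (length-T integers in 1..K) and
#'   `timecourse` (T x C matrix, columns `comp_1..comp_C`).
#' @export
simulate_timecourse <- function(hmm, n_timepoints, seed = 1L,
                                repetition_time = 2.2) {
  stopifnot(inherits(hmm, "statedyn_hmm"))
  if (n_timepoints < 2) abort("`n_timepoints` must be >= 2.")
  set.seed(seed)
  sim <- simulate_timecourse_(hmm, n_timepoints, repetition_time)
  sim
}

# RNG-stream-internal version: draws from the current RNG state so a cohort
# simulation consumes one seed only.
simulate_timecourse_ <- function(hmm, n_timepoints, repetition_time) {
  u <- runif(n_timepoints)
  path <- .mc_sample_path(hmm$init_probs, hmm$trans, u)
  L <- chol(hmm$sigma)
  noise <- matrix(rnorm(n_timepoints * hmm$C), n_timepoints, hmm$C) %*% L
  x <- hmm$means[path, , drop = FALSE] + noise
  colnames(x) <- paste0("comp_", seq_len(hmm$C))
  attr(x, "repetition_time") <- repetition_time
  list(state_path = path, timecourse = x)
}

#' Specify a synthetic cohort
#'
#' Collects the generative conditions for [simulate_cohort()]: group sizes,
#' scan length, site repetition times, per-group age distributions, the
#' planted persistence shift on the target state for symptomatic subjects
#' (converters receive `converter_dose` of it), the planted link between
#' target-state occupancy and cognitive slope in symptomatic subjects, visit
#' schedule and noise levels.
#'
#' The default persistence of 0.55 gives mean state dwell times of ~2.2
#' volumes (about 5 s at TR 2.2 s), at the faster end of the range reported
#' for resting-state brain-state models; this keeps per-scan occupancy
#' estimates precise enough that the planted group effects are recoverable at
#' the study's group sizes. The default `effect_occupancy_shift` of 0.1752 raises
#' the target state's stationary occupancy by 0.08 above the uniform baseline
#' 1/K for a 6-state chain.
#'
#' @param group_sizes named integer vector over
#'   `c("non-carrier","presymptomatic","symptomatic")`.
#' @param n_converters number of presymptomatic subjects flagged as converters.
#' @param n_states,n_channels model order K and channel count C.
#' @param t_per_scan volumes per scan.
#' @param persistence baseline diagonal transition probability.
#' @param mean_separation minimum state-mean separation in z-units.
#' @param target_state state receiving the planted occupancy effect.
#' @param effect_occupancy_shift persistence increment for symptomatic subjects.
#' @param converter_dose fraction of the symptomatic shift given to converters.
#' @param repetition_times named numeric vector, seconds per site.
#' @param age_model list of `c(mean, sd)` per group, years.
#' @param n_visits annual visits per subject (>= 1).
#' @param base_slope named annual change per group for the cognitive outcome.
#' @param slope_link_beta change in annual slope per unit of true target-state
#'   occupancy deviation (symptomatic subjects only).
#' @param slope_sd between-subject SD of residual slopes.
#' @param noise_sd visit-level measurement noise SD.
#' @param frac_exceed_qc fraction of scans drawn to violate a motion bound.
#' @param seed integer seed.
#' @return a list of class `cohort_spec`.
#' @export
cohort_spec <- function(group_sizes = c("non-carrier" = 120,
                                        "presymptomatic" = 120,
                                        "symptomatic" = 60),
                        n_converters = 14,
                        n_states = 6, n_channels = 24,
                        t_per_scan = 300,
                        persistence = 0.55,
                        mean_separation = 2,
                        target_state = 2,
                        effect_occupancy_shift = 0.1752,
                        converter_dose = 0.5,
                        repetition_times = c(site_1 = 2.2, site_2 = 2.5,
                                             site_3 = 2.2, site_4 = 2.4,
                                             site_5 = 2.5),
                        age_model = list("non-carrier" = c(48, 13),
                                         "presymptomatic" = c(45, 12),
                                         "symptomatic" = c(63, 8.2)),
                        n_visits = 4,
                        base_slope = c("non-carrier" = -0.05,
                                       "presymptomatic" = -0.1,
                                       "symptomatic" = -1.5),
                        slope_link_beta = -12,
                        slope_sd = 0.5,
                        noise_sd = 1,
                        frac_exceed_qc = 0.1,
                        seed = 1L) {
  groups <- c("non-carrier", "presymptomatic", "symptomatic")
  if (!all(groups %in% names(group_sizes)))
    abort("`group_sizes` must name all three groups.")
  if (any(group_sizes < 0)) abort("`group_sizes` must be non-negative.")
  if (n_visits < 1) abort("`n_visits` must be >= 1.")
  p_shift <- persistence + effect_occupancy_shift
  if (p_shift >= 1 || p_shift < 0)
    abort("persistence after the occupancy shift must lie in [0, 1).")
  if (n_converters > group_sizes[["presymptomatic"]])
    abort("more converters than presymptomatic subjects.")
  structure(
    list(group_sizes = group_sizes[groups], n_converters = n_converters,
         n_states = n_states, n_channels = n_channels,
         t_per_scan = t_per_scan, persistence = persistence,
         mean_separation = mean_separation, target_state = target_state,
         effect_occupancy_shift = effect_occupancy_shift,
         converter_dose = converter_dose,
         repetition_times = repetition_times, age_model = age_model,
         n_visits = n_visits, base_slope = base_slope,
         slope_link_beta = slope_link_beta, slope_sd = slope_sd,
         noise_sd = noise_sd, frac_exceed_qc = frac_exceed_qc,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Subject-level transition matrix: persistence increment on the target state's
# diagonal, that row's off-diagonal mass re-split evenly.
shift_transition <- function(trans, target_state, delta) {
  K <- nrow(trans)
  p <- trans[target_state, target_state] + delta
  trans[target_state, ] <- (1 - p) / (K - 1)
  trans[target_state, target_state] <- p
  trans
}

#' Simulate a full synthetic cohort
#'
#' Generates, from one seed, a ground-truth HMM, per-subject state paths and
#' component time courses, a cohort metadata table with motion-QC indices, and
#' a longitudinal visits table. Symptomatic subjects (and converters, at a
#' fractional dose) receive a persistence increment on the target state,
#' raising its expected occupancy; the annual slope of the cognitive outcome
#' in symptomatic subjects is tied to each subject's true target-state
#' occupancy deviation through `slope_link_beta`.
#'
#' @param spec a [cohort_spec()].
#' @return list of class `statedyn_cohort` with elements `cohort` (tibble),
#'   `visits` (tibble), `timecourses` (named list of T x C matrices),
#'   `true_paths` (named list of integer vectors), `truth` (the
#'   `statedyn_hmm`), and `spec`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_total <- sum(spec$group_sizes)
  if (n_total == 0) abort("empty cohort: all group sizes are zero.")
  set.seed(spec$seed)

  truth <- with(spec, {
    A <- matrix((1 - persistence) / (n_states - 1), n_states, n_states)
    diag(A) <- persistence
    M <- matrix(rnorm(n_states * n_channels), n_states, n_channels)
    d <- as.matrix(stats::dist(M))
    min_d <- min(d[upper.tri(d)])
    if (min_d < mean_separation) M <- M * (mean_separation / min_d)
    Q <- qr.Q(qr(matrix(rnorm(n_channels^2), n_channels, n_channels)))
    lam <- runif(n_channels, 0.5, 2)
    S <- Q %*% (lam * t(Q))
    S <- stats::cov2cor((S + t(S)) / 2)
    new_hmm(rep(1 / n_states, n_states), A, M, S)
  })

  groups <- rep(names(spec$group_sizes), spec$group_sizes)
  n <- length(groups)
  ids <- sprintf("sub_%03d", seq_len(n))
  converter <- logical(n)
  psc_idx <- which(groups == "presymptomatic")
  if (spec$n_converters > 0)
    converter[sample(psc_idx, spec$n_converters)] <- TRUE

  sites <- sample(names(spec$repetition_times), n, replace = TRUE)
  tr <- spec$repetition_times[sites]
  sex <- sample(c("F", "M"), n, replace = TRUE)
  mut_pool <- c("C9orf72", "GRN", "MAPT", "TBK1")
  mut_prob <- c(0.37, 0.41, 0.19, 0.03)
  mutation <- ifelse(groups == "non-carrier", "none",
                     sample(mut_pool, n, replace = TRUE, prob = mut_prob))
  age <- vapply(groups, function(g) {
    m <- spec$age_model[[g]]
    max(18, rnorm(1, m[1], m[2]))
  }, numeric(1))

  # motion indices: lognormal bulk; a drawn fraction gets one index inflated
  # past the default bound for that index
  bounds <- qc_thresholds()
  motion <- tibble(
    max_spike_percentage = exp(rnorm(n, log(2), 0.5)),
    max_framewise_displacement = exp(rnorm(n, log(0.8), 0.5)),
    max_dvars = exp(rnorm(n, log(1.5), 0.4)),
    mean_framewise_displacement = exp(rnorm(n, log(0.15), 0.4))
  )
  fail <- runif(n) < spec$frac_exceed_qc
  which_idx <- sample(3, n, replace = TRUE)
  bound_vals <- c(bounds$max_spike_percentage,
                  bounds$max_framewise_displacement, bounds$max_dvars)
  for (i in which(fail)) {
    j <- which_idx[i]
    motion[[j]][i] <- bound_vals[j] * runif(1, 1.05, 2)
  }

  timecourses <- vector("list", n)
  true_paths <- vector("list", n)
  true_occ <- numeric(n)
  K <- spec$n_states
  for (i in seq_len(n)) {
    delta <- if (groups[i] == "symptomatic") spec$effect_occupancy_shift
             else if (converter[i]) spec$converter_dose * spec$effect_occupancy_shift
             else 0
    A_i <- if (delta > 0) shift_transition(truth$trans, spec$target_state, delta)
           else truth$trans
    hmm_i <- truth
    hmm_i$trans <- A_i
    hmm_i$init_probs <- stationary_distribution(A_i)
    sim <- simulate_timecourse_(hmm_i, spec$t_per_scan, tr[[i]])
    timecourses[[i]] <- sim$timecourse
    true_paths[[i]] <- sim$state_path
    true_occ[i] <- mean(sim$state_path == spec$target_state)
  }
  scan_ids <- paste0(ids, "_scan_1")
  names(timecourses) <- scan_ids
  names(true_paths) <- scan_ids

  cohort <- tibble(
    subject_id = ids, scan_id = scan_ids,
    group = factor(groups, levels = names(spec$group_sizes)),
    converter = converter, age = age, sex = sex, site = sites,
    mutation = mutation, repetition_time = unname(tr),
    n_timepoints = spec$t_per_scan
  )
  cohort <- dplyr::bind_cols(cohort, motion)
  cohort$true_target_occupancy <- true_occ

  occ_dev <- true_occ - 1 / K
  slope <- spec$base_slope[groups] + rnorm(n, 0, spec$slope_sd) +
    ifelse(groups == "symptomatic", spec$slope_link_beta * occ_dev, 0)
  intercept <- ifelse(groups == "symptomatic", 22, 29) + rnorm(n, 0, 1)
  visits <- tidyr::expand_grid(subject_id = ids,
                               years_from_baseline = seq_len(spec$n_visits) - 1)
  idx <- match(visits$subject_id, ids)
  visits$cognition <- intercept[idx] + slope[idx] * visits$years_from_baseline +
    rnorm(nrow(visits), 0, spec$noise_sd)
  visits <- as_tibble(visits)

  structure(
    list(cohort = cohort, visits = visits, timecourses = timecourses,
         true_paths = true_paths, truth = truth, spec = spec),
    class = "statedyn_cohort"
  )
}

#' @export
print.statedyn_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects (%s), %d states, T = %d\n",
              nrow(x$cohort),
              paste(sprintf("%s %d", names(x$spec$group_sizes),
                            x$spec$group_sizes), collapse = ", "),
              x$spec$n_states, x$spec$t_per_scan))
  invisible(x)
}

#' Sample hidden state paths from a transition matrix
#'
#' Draws one or more Markov state paths using the current RNG stream (no
#' internal seeding), so batches of subjects drawn in a loop remain mutually
#' independent under one `set.seed()` call.
#'
#' @param trans K x K row-stochastic transition matrix.
#' @param n_timepoints path length.
#' @param n_paths number of independent paths.
#' @param init_probs initial state distribution; default the stationary
#'   distribution of `trans`.
#' @return integer vector (one path) or a list of integer vectors.
#' @export
simulate_state_paths <- function(trans, n_timepoints, n_paths = 1,
                                 init_probs = NULL) {
  if (is.null(init_probs)) init_probs <- stationary_distribution(trans)
  if (max(abs(rowSums(trans) - 1)) > 1e-8)
    abort("rows of `trans` must sum to 1.")
  paths <- lapply(seq_len(n_paths), function(i)
    .mc_sample_path(init_probs, trans, runif(n_timepoints)))
  if (n_paths == 1) paths[[1]] else paths
}
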