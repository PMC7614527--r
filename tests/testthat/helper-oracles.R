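# Independent oracles used across the suite. These deliberately use naive
# implementations (path enumeration, direct summation, grid search) so they
# share no code with the package internals they check.

# Log-likelihood of a scan by exhaustive enumeration over all K^T state paths.
brute_force_loglik <- function(model, scan) {
  K <- model$K
  T_ <- nrow(scan)
  logB <- matrix(NA_real_, T_, K)
  for (k in seq_len(K)) {
    for (t in seq_len(T_)) {
      d <- scan[t, ] - model$means[k, ]
      logB[t, k] <- -0.5 * (model$C * log(2 * pi) +
                              determinant(model$sigma)$modulus[1] +
                              drop(d %*% solve(model$sigma, d)))
    }
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  logp <- log(model$init_probs[paths[, 1]]) + logB[1, ][paths[, 1]]
  if (T_ > 1) {
    for (t in 2:T_) {
      logp <- logp + log(model$trans[cbind(paths[, t - 1], paths[, t])]) +
        logB[t, ][paths[, t]]
    }
  }
  m <- max(logp)
  m + log(sum(exp(logp - m)))
}

# Benjamini-Hochberg step-up, written directly from the definition:
# adj_(i) = min(1, min_{j >= i} (m/j) p_(j)) over the sorted p values.
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    best <- 1
    for (j in i:m) best <- min(best, m / j * ps[j])
    adj[i] <- best
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Raw varimax criterion: sum over columns of the variance of squared loadings.
varimax_criterion <- function(L) {
  sum(apply(L^2, 2, function(v) mean(v^2) - mean(v)^2))
}

# Rotation of a 2-column loading matrix by angle theta.
rotate2 <- function(L, theta) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  L %*% R
}

# A small ground-truth model plus simulated standardized scans.
make_sim_scans <- function(n_scans, T_, K, C, persistence, seed,
                           mean_separation = 2) {
  hmm <- sample_ground_truth(K, C, persistence,
                             mean_separation = mean_separation, seed = seed)
  scans <- list()
  paths <- list()
  for (i in seq_len(n_scans)) {
    sim <- simulate_timecourse(hmm, T_, seed = seed + i)
    scans[[i]] <- sim$timecourse
    paths[[i]] <- sim$state_path
  }
  list(hmm = hmm, scans = scans, paths = paths)
}

# Per-subject flattened transition matrices from null Markov chains, as a
# data frame ready for the permutation test.
null_transition_cohort <- function(n_per_group, K, T_, persistence) {
  A <- matrix((1 - persistence) / (K - 1), K, K)
  diag(A) <- persistence
  pi0 <- rep(1 / K, K)
  n <- 2 * n_per_group
  paths <- simulate_state_paths(A, T_, n_paths = n, init_probs = pi0)
  rows <- lapply(paths, function(path) {
    P <- subject_transition_matrix(hard_posterior(path, K), group_trans = A)
    out <- as.list(as.vector(t(P)))
    names(out) <- paste0("P_", rep(1:K, each = K), "_", rep(1:K, K))
    out
  })
  d <- dplyr::bind_rows(rows)
  d$group <- rep(c("a", "b"), each = n_per_group)
  d$age <- rnorm(n, 50, 10)
  d$sex <- sample(c("F", "M"), n, replace = TRUE)
  d
}
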