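#' Standardize a component time course
#'
#' Centers and scales each component (column) to mean 0 and SD 1 within the
#' scan, as required before group-level HMM estimation.
#'
#' @param x T x C numeric matrix (T >= 2).
#' @return matrix of the same shape and attributes with unit-variance columns.
#' @export
standardize_timecourse <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) abort("time course needs at least 2 timepoints.")
  s <- apply(x, 2, sd)
  if (any(s == 0)) {
    bad <- colnames(x)[s == 0] %||% which(s == 0)
    abort(paste("constant component column(s):", paste(bad, collapse = ", ")))
  }
  out <- scale(x)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  attr(out, "repetition_time") <- attr(x, "repetition_time")
  out
}

#' Temporally concatenate scans
#'
#' Stacks scans row-wise and records scan boundaries so that the
#' forward-backward recursions restart at each scan: no state transitions are
#' modelled across subjects.
#'
#' @param scans list of T_i x C matrices sharing the same column count.
#' @return list with `data` (sum(T_i) x C matrix) and `boundaries`
#'   (integer vector `c(0, cumsum(T_i))`).
#' @export
concatenate_scans <- function(scans) {
  if (length(scans) == 0) abort("no scans supplied.")
  ncols <- vapply(scans, ncol, integer(1))
  if (length(unique(ncols)) != 1)
    abort("all scans must share the same number of components.")
  list(data = do.call(rbind, scans),
       boundaries = c(0L, cumsum(vapply(scans, nrow, integer(1)))))
}

# Per-state Gaussian log-densities under the shared covariance: T x K matrix.
emission_logdens <- function(x, means, sigma) {
  U <- tryCatch(chol(sigma), error = function(e)
    abort("shared covariance is singular; increase the ridge regularization."))
  logdet <- 2 * sum(log(diag(U)))
  C <- ncol(x)
  K <- nrow(means)
  const <- -0.5 * (C * log(2 * pi) + logdet)
  out <- matrix(0, nrow(x), K)
  for (k in seq_len(K)) {
    delta <- t(x) - means[k, ]
    z <- backsolve(U, delta, transpose = TRUE)
    out[, k] <- const - 0.5 * colSums(z^2)
  }
  out
}

#' Forward-backward state inference for one scan
#'
#' Computes the per-timepoint posterior state probabilities gamma, the
#' expected transition-count matrix xi (summed over the scan), and the scan
#' log-likelihood, using scaled recursions that are safe for long scans.
#'
#' @param model a `statedyn_hmm`.
#' @param scan standardized T x C matrix.
#' @return list of class `state_posterior` with `gamma` (T x K, rows on the
#'   simplex), `xi` (K x K, entries sum to T-1) and `loglik`.
#' @export
forward_backward <- function(model, scan) {
  stopifnot(inherits(model, "statedyn_hmm"))
  scan <- as.matrix(scan)
  if (ncol(scan) != model$C)
    abort("scan channel count does not match the model.")
  logB <- emission_logdens(scan, model$means, model$sigma)
  res <- .fb_core(logB, model$init_probs, model$trans)
  structure(list(gamma = res$gamma, xi = res$xi, loglik = res$loglik),
            class = "state_posterior")
}

hmm_init <- function(x, K, restart_seed) {
  set.seed(restart_seed)
  km <- suppressWarnings(kmeans(x, centers = K, nstart = 1, iter.max = 30))
  A <- matrix(0.1 / max(1, K - 1), K, K)
  diag(A) <- if (K > 1) 0.9 else 1
  sigma <- cov(x)
  sigma <- sigma + diag(1e-6 * sum(diag(sigma)) / ncol(x), ncol(x))
  new_hmm(rep(1 / K, K), A, km$centers, sigma)
}

em_run <- function(x, boundaries, K, max_iter, tol, restart_seed) {
  n_scan <- length(boundaries) - 1
  T_total <- nrow(x)
  C <- ncol(x)
  model <- hmm_init(x, K, restart_seed)
  trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  empty_state <- FALSE
  gamma <- NULL
  for (iter in seq_len(max_iter)) {
    logB <- emission_logdens(x, model$means, model$sigma)
    gamma <- matrix(0, T_total, K)
    xi <- matrix(0, K, K)
    pi_acc <- numeric(K)
    ll <- 0
    for (s in seq_len(n_scan)) {
      idx <- (boundaries[s] + 1):boundaries[s + 1]
      res <- .fb_core(logB[idx, , drop = FALSE], model$init_probs, model$trans)
      gamma[idx, ] <- res$gamma
      xi <- xi + res$xi
      pi_acc <- pi_acc + res$gamma[1, ]
      ll <- ll + res$loglik
    }
    trace <- c(trace, ll)
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol * abs(ll_prev)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll

    n_k <- colSums(gamma)
    if (any(n_k < 1)) empty_state <- TRUE
    model$init_probs <- pi_acc / sum(pi_acc)
    A <- xi / pmax(rowSums(xi), .Machine$double.eps)
    means <- (t(gamma) %*% x) / pmax(n_k, .Machine$double.eps)
    sigma <- (crossprod(x) - t(means) %*% (n_k * means)) / T_total
    sigma <- (sigma + t(sigma)) / 2
    sigma <- sigma + diag(1e-6 * sum(diag(sigma)) / C, C)
    model$trans <- A
    model$means <- means
    model$sigma <- sigma
  }
  list(model = model, loglik = trace[length(trace)], trace = trace,
       n_iter = length(trace), converged = converged,
       empty_state = empty_state, restart_seed = restart_seed)
}

#' Fit a shared-covariance Gaussian HMM by EM
#'
#' Baum-Welch estimation of a K-state multivariate Gaussian HMM in which all
#' states share one covariance matrix, fitted to temporally concatenated
#' standardized scans (forward-backward restarts at scan boundaries). The
#' M-step pools the covariance across states:
#' `Sigma = (1/T) * sum_t sum_k gamma_tk (x_t - mu_k)(x_t - mu_k)'`,
#' with a small ridge (1e-6 * trace/C) added to the diagonal each iteration.
#' Initialization is k-means for the means, diagonal-0.9 transitions, uniform
#' initial probabilities and the pooled sample covariance. The best of
#' `n_restarts` runs by final log-likelihood is returned; results are
#' deterministic given `seed`.
#'
#' @param x stacked T_total x C matrix of standardized time courses (e.g. from
#'   [concatenate_scans()]).
#' @param boundaries scan boundary vector `c(0, cumsum(T_i))`; a single scan
#'   may pass `NULL`.
#' @param K number of states (>= 2; the study default is 6).
#' @param n_restarts independent EM restarts.
#' @param max_iter maximum EM iterations per restart.
#' @param tol relative log-likelihood convergence tolerance.
#' @param seed integer seed controlling all restarts.
#' @return a `statedyn_hmm` with `diagnostics` (final log-likelihood, trace,
#'   iteration count, convergence and empty-state flags, restart seed used).
#' @export
fit_hmm <- function(x, boundaries = NULL, K = 6, n_restarts = 5,
                    max_iter = 500, tol = 1e-5, seed = 1L) {
  x <- as.matrix(x)
  if (K < 2) abort("`K` must be >= 2 (use forward_backward for K = 1).")
  if (is.null(boundaries)) boundaries <- c(0L, nrow(x))
  if (boundaries[1] != 0 || boundaries[length(boundaries)] != nrow(x))
    abort("`boundaries` must start at 0 and end at nrow(x).")
  set.seed(seed)
  restart_seeds <- sample.int(.Machine$integer.max - 1L, n_restarts)
  runs <- lapply(restart_seeds, function(rs)
    em_run(x, boundaries, K, max_iter, tol, rs))
  best <- runs[[which.max(vapply(runs, `[[`, numeric(1), "loglik"))]]
  if (!best$converged)
    warn(sprintf("EM did not converge in %d iterations (best restart).",
                 max_iter))
  if (best$empty_state)
    warn("one or more states carried less than one timepoint of posterior mass.")
  model <- best$model
  model$diagnostics <- list(
    loglik = best$loglik, trace = best$trace, n_iter = best$n_iter,
    converged = best$converged, empty_state = best$empty_state,
    restart_seed = best$restart_seed, seed = seed, n_restarts = n_restarts,
    tol = tol
  )
  model
}

#' Match states between two models by their mean vectors
#'
#' State labels of an HMM are arbitrary; comparisons across runs (or against a
#' ground truth) first align states by solving the linear assignment problem
#' on Euclidean distances between state means (Hungarian algorithm).
#'
#' @param means_ref,means_est K x C matrices of state means.
#' @return integer permutation `p` such that estimated state `p[i]` matches
#'   reference state `i`.
#' @export
match_states <- function(means_ref, means_est) {
  stopifnot(nrow(means_ref) == nrow(means_est))
  cost <- as.matrix(stats::dist(rbind(means_ref, means_est)))
  K <- nrow(means_ref)
  cost <- cost[seq_len(K), K + seq_len(K), drop = FALSE]
  as.integer(clue::solve_LSAP(cost))
}

#' Relabel the states of an HMM
#'
#' @param model a `statedyn_hmm`.
#' @param perm integer permutation; state `i` of the result is state `perm[i]`
#'   of the input.
#' @return relabelled `statedyn_hmm`.
#' @export
relabel_states <- function(model, perm) {
  stopifnot(inherits(model, "statedyn_hmm"), length(perm) == model$K)
  model$init_probs <- model$init_probs[perm]
  model$trans <- model$trans[perm, perm, drop = FALSE]
  model$means <- model$means[perm, , drop = FALSE]
  model
}

#' @exportS3Method generics::tidy
tidy.statedyn_hmm <- function(x, ...) {
  tibble(
    state = seq_len(x$K),
    init_prob = x$init_probs,
    persistence = diag(x$trans),
    mean_norm = sqrt(rowSums(x$means^2))
  )
}

#' @exportS3Method generics::glance
glance.statedyn_hmm <- function(x, ...) {
  d <- x$diagnostics
  tibble(
    n_states = x$K, n_channels = x$C,
    loglik = if (is.null(d)) NA_real_ else d$loglik,
    n_iter = if (is.null(d)) NA_integer_ else d$n_iter,
    converged = if (is.null(d)) NA else d$converged
  )
}
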