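#' Fractional occupancy from a state posterior
#'
#' The proportion of scan time each state is active: the mean over timepoints
#' of the posterior state probabilities.
#'
#' @param post a `state_posterior` (or any list with a T x K `gamma`).
#' @return length-K vector on the simplex.
#' @export
fractional_occupancy <- function(post) {
  colMeans(post$gamma)
}

#' Switching rate from a state posterior
#'
#' Expected number of between-state transitions per second of scan time:
#' the off-diagonal mass of the expected transition counts xi divided by the
#' duration of the (T-1) between-volume intervals. Dividing by the scan's
#' repetition time adjusts for between-site TR differences.
#'
#' @param post a `state_posterior`.
#' @param repetition_time seconds per volume (> 0).
#' @return transitions per second.
#' @export
switching_rate <- function(post, repetition_time) {
  if (repetition_time <= 0) abort("`repetition_time` must be positive.")
  n_trans <- sum(post$xi) - sum(diag(post$xi))
  T_ <- nrow(post$gamma)
  n_trans / ((T_ - 1) * repetition_time)
}

#' Per-subject transition/persistence probability matrix
#'
#' Row-normalizes the expected transition counts into a row-stochastic matrix
#' (diagonal: persistence probabilities; off-diagonal: transition
#' probabilities). A state with zero expected outgoing mass cannot be
#' normalized; its row is filled from the group-level model's transition
#' matrix and flagged.
#'
#' @param post a `state_posterior`.
#' @param group_trans optional K x K group-model transition matrix used to
#'   fill zero-mass rows.
#' @return K x K row-stochastic matrix with attribute `filled_rows` (integer
#'   indices of rows taken from the group model).
#' @export
subject_transition_matrix <- function(post, group_trans = NULL) {
  xi <- post$xi
  rs <- rowSums(xi)
  K <- nrow(xi)
  out <- xi / pmax(rs, .Machine$double.eps)
  zero <- which(rs < 1e-12)
  if (length(zero)) {
    if (is.null(group_trans))
      abort("zero-mass transition row; supply `group_trans` to fill it.")
    out[zero, ] <- group_trans[zero, , drop = FALSE]
  }
  attr(out, "filled_rows") <- zero
  out
}

#' State mean activation maps
#'
#' Weights the spatial component maps by each state's Gaussian mean vector,
#' giving one activation map per state.
#'
#' @param component_maps V x C matrix of spatial component weights.
#' @param model a `statedyn_hmm` with matching channel count C.
#' @return V x K matrix, one column per state.
#' @export
mean_activation_map <- function(component_maps, model) {
  component_maps <- as.matrix(component_maps)
  if (ncol(component_maps) != model$C)
    abort("component map columns must match the model's channel count.")
  maps <- component_maps %*% t(model$means)
  colnames(maps) <- paste0("state_", seq_len(model$K))
  maps
}

#' Hard posterior from a known state path
#'
#' Converts an integer state path into the `state_posterior` form (one-hot
#' gamma, hard transition counts), so occupancy/switching/transition metrics
#' can be computed from ground-truth or Viterbi paths with the same code path
#' as soft posteriors.
#'
#' @param path integer vector with values in 1..K.
#' @param K number of states.
#' @return a `state_posterior` with 0/1 gamma and integer-count xi.
#' @export
hard_posterior <- function(path, K) {
  T_ <- length(path)
  gamma <- matrix(0, T_, K)
  gamma[cbind(seq_len(T_), path)] <- 1
  xi <- matrix(0, K, K)
  if (T_ > 1) {
    tab <- table(factor(path[-T_], levels = 1:K),
                 factor(path[-1], levels = 1:K))
    xi <- matrix(as.numeric(tab), K, K)
  }
  structure(list(gamma = gamma, xi = xi, loglik = NA_real_),
            class = "state_posterior")
}

#' Most probable state path (Viterbi)
#'
#' Hard state decoding, available as a sensitivity alternative to the soft
#' posterior metrics used by default.
#'
#' @param model a `statedyn_hmm`.
#' @param scan standardized T x C matrix.
#' @return integer vector of length T with values in 1..K.
#' @export
viterbi_path <- function(model, scan) {
  logB <- emission_logdens(as.matrix(scan), model$means, model$sigma)
  T_ <- nrow(logB); K <- ncol(logB)
  logA <- log(pmax(model$trans, .Machine$double.xmin))
  delta <- log(pmax(model$init_probs, .Machine$double.xmin)) + logB[1, ]
  psi <- matrix(0L, T_, K)
  for (t in seq_len(T_)[-1]) {
    cand <- delta + logA                      # K x K: from-state rows
    psi[t, ] <- apply(cand, 2, which.max)
    delta <- cand[cbind(psi[t, ], seq_len(K))] + logB[t, ]
  }
  path <- integer(T_)
  path[T_] <- which.max(delta)
  for (t in rev(seq_len(T_ - 1))) path[t] <- psi[t + 1, path[t + 1]]
  path
}

#' Per-scan temporal-dynamics metrics table
#'
#' Runs forward-backward state inference for each scan under a fitted group
#' model and tabulates fractional occupancies, the TR-adjusted switching rate
#' and the flattened per-subject transition/persistence matrix (row-major,
#' `P_i_j`). With `method = "viterbi"` metrics come from hard decoded paths
#' instead of soft posteriors.
#'
#' @param model fitted `statedyn_hmm`.
#' @param timecourses named list of standardized T x C matrices (names are
#'   scan ids).
#' @param repetition_times numeric vector of seconds per volume, recycled or
#'   matched by name to the scans.
#' @param method `"soft"` (posterior gamma/xi; default) or `"viterbi"`.
#' @return tibble with one row per scan: `scan_id`, `FO_1..FO_K`, `SR`,
#'   `P_1_1 .. P_K_K`.
#' @export
compute_metrics <- function(model, timecourses, repetition_times,
                            method = c("soft", "viterbi")) {
  method <- match.arg(method)
  K <- model$K
  ids <- names(timecourses) %||% paste0("scan_", seq_along(timecourses))
  if (!is.null(names(repetition_times)) && all(ids %in% names(repetition_times)))
    repetition_times <- repetition_times[ids]
  tr <- rep_len(repetition_times, length(timecourses))
  rows <- purrr::map2(seq_along(timecourses), tr, function(i, tri) {
    post <- if (method == "soft") {
      forward_backward(model, timecourses[[i]])
    } else {
      hard_posterior(viterbi_path(model, timecourses[[i]]), K)
    }
    fo <- fractional_occupancy(post)
    sr <- switching_rate(post, tri)
    P <- subject_transition_matrix(post, group_trans = model$trans)
    out <- c(fo, sr, as.vector(t(P)))
    names(out) <- c(paste0("FO_", 1:K), "SR",
                    paste0("P_", rep(1:K, each = K), "_", rep(1:K, K)))
    c(list(scan_id = ids[i]), as.list(out))
  })
  dplyr::bind_rows(rows)
}

#' Metrics from known state paths
#'
#' Convenience wrapper computing the same per-scan metrics table as
#' [compute_metrics()] but from integer state paths (ground truth from the
#' simulator, or decoded paths), bypassing posterior inference.
#'
#' @param paths named list of integer state paths.
#' @param K number of states.
#' @param repetition_times seconds per volume, recycled or matched by name.
#' @param group_trans optional matrix for zero-mass transition rows.
#' @return tibble as in [compute_metrics()].
#' @export
path_metrics <- function(paths, K, repetition_times, group_trans = NULL) {
  ids <- names(paths) %||% paste0("scan_", seq_along(paths))
  if (!is.null(names(repetition_times)) && all(ids %in% names(repetition_times)))
    repetition_times <- repetition_times[ids]
  tr <- rep_len(repetition_times, length(paths))
  fallback <- group_trans %||% matrix(1 / K, K, K)
  rows <- purrr::map2(seq_along(paths), tr, function(i, tri) {
    post <- hard_posterior(paths[[i]], K)
    fo <- fractional_occupancy(post)
    sr <- switching_rate(post, tri)
    P <- subject_transition_matrix(post, group_trans = fallback)
    out <- c(fo, sr, as.vector(t(P)))
    names(out) <- c(paste0("FO_", 1:K), "SR",
                    paste0("P_", rep(1:K, each = K), "_", rep(1:K, K)))
    c(list(scan_id = ids[i]), as.list(out))
  })
  dplyr::bind_rows(rows)
}
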