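#' Orthonormal Helmert sub-basis for compositions
#'
#' The (K-1) x K Helmert contrast matrix with the constant row removed and
#' rows normalized to unit length: `H %*% t(H)` is the identity and every row
#' sums to zero. This is the isometry used to map simplex-valued data into
#' unconstrained coordinates.
#'
#' @param K number of parts (>= 2).
#' @return (K-1) x K matrix.
#' @export
helmert_basis <- function(K) {
  if (K < 2) abort("`K` must be >= 2.")
  H <- matrix(0, K - 1, K)
  for (j in seq_len(K - 1)) {
    H[j, seq_len(j)] <- 1
    H[j, j + 1] <- -j
    H[j, ] <- H[j, ] / sqrt(j * (j + 1))
  }
  H
}

#' Alpha-transformation of compositional data
#'
#' Power-transforms each composition and maps it through the Helmert basis
#' into (K-1) unconstrained coordinates:
#' `z = H %*% ((K * x^alpha / sum(x^alpha) - 1) / alpha)`.
#' At `alpha = 1` this is the linear map `z = H %*% (K * x - 1)`; the uniform
#' composition maps to the zero vector for every alpha.
#'
#' @param x N x K matrix (or data frame) of compositions, rows on the simplex,
#'   or a single length-K composition.
#' @param alpha transformation parameter, non-zero (the log-ratio limit
#'   `alpha = 0` is not provided).
#' @return N x (K-1) coordinate matrix.
#' @export
alpha_transform <- function(x, alpha = 1) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (alpha == 0) abort("`alpha` must be non-zero.")
  if (any(x < -1e-10)) abort("compositions must be non-negative.")
  if (max(abs(rowSums(x) - 1)) > 1e-6)
    abort("composition rows must sum to 1.")
  if (alpha < 0 && any(x == 0))
    abort("zero parts are not admissible for alpha < 0.")
  K <- ncol(x)
  u <- x^alpha
  v <- (K * u / rowSums(u) - 1) / alpha
  v %*% t(helmert_basis(K))
}

#' Broken-stick expectations
#'
#' `b_k = (1/p) * sum_{i=k}^{p} 1/i`: the expected ordered fragment lengths of
#' a unit stick broken at p-1 uniform points.
#'
#' @param p number of eigenvalues.
#' @return length-p vector.
#' @export
broken_stick_values <- function(p) {
  vapply(seq_len(p), function(k) sum(1 / (k:p)) / p, numeric(1))
}

#' Broken-stick component selection
#'
#' Retains the longest leading run of components whose variance proportion
#' exceeds the broken-stick expectation. When even the first component falls
#' short, one component is retained anyway (flagged via the `forced`
#' attribute) because downstream models require at least one score.
#'
#' @param eigenvalues non-increasing, non-negative eigenvalues.
#' @return integer `n_selected` with attribute `forced`.
#' @export
broken_stick_select <- function(eigenvalues) {
  p <- length(eigenvalues)
  if (sum(eigenvalues) <= 0) abort("eigenvalues must have positive sum.")
  if (is.unsorted(rev(eigenvalues))) abort("eigenvalues must be non-increasing.")
  prop <- eigenvalues / sum(eigenvalues)
  b <- broken_stick_values(p)
  run <- cumprod(prop > b)
  n <- sum(run)
  forced <- n == 0
  if (forced) {
    warn("no component exceeds the broken-stick expectation; retaining one.")
    n <- 1L
  }
  structure(as.integer(n), forced = forced)
}

#' Compositional PCA of state fractional occupancies
#'
#' Reduces per-subject fractional-occupancy compositions to component scores:
#' (1) alpha-transformation into unconstrained coordinates (default
#' `alpha = 1`), (2) PCA on the column-centered coordinates, (3) broken-stick
#' selection of the number of components, (4) varimax rotation of the retained
#' loadings (identity when one component is retained). Scores are computed in
#' transform space; loadings are mapped back to state space through the
#' Helmert basis for interpretation only. Component signs are fixed so each
#' component's largest-magnitude state loading is positive.
#'
#' @param fo N x K matrix or data frame of occupancy compositions (columns
#'   `FO_1..FO_K` are selected when present); row names or a `scan_id` column
#'   label the scores.
#' @param alpha alpha-transformation parameter.
#' @param kaiser_normalize logical; Kaiser row normalization in the varimax
#'   step (off by default; irrelevant for a single component).
#' @return object of class `composition_pca` with eigenvalues, raw and
#'   rotated loadings, `n_selected`, rotation matrix, state-space loadings,
#'   training scores and variance explained.
#' @export
composition_pca <- function(fo, alpha = 1, kaiser_normalize = FALSE) {
  ids <- NULL
  if (is.data.frame(fo)) {
    if ("scan_id" %in% names(fo)) ids <- fo$scan_id
    fo_cols <- grep("^FO_", names(fo), value = TRUE)
    if (length(fo_cols)) fo <- fo[fo_cols]
    fo <- as.matrix(dplyr::select(as_tibble(fo), dplyr::where(is.numeric)))
  }
  fo <- as.matrix(fo)
  if (is.null(ids)) ids <- rownames(fo) %||% paste0("obs_", seq_len(nrow(fo)))
  K <- ncol(fo)
  N <- nrow(fo)
  if (N <= K) warn("fewer observations than parts; PCA may be rank-deficient.")
  Z <- alpha_transform(fo, alpha)
  pc <- prcomp(Z, center = TRUE, scale. = FALSE)
  lambda <- pc$sdev^2
  raw_loadings <- pc$rotation
  n_sel <- broken_stick_select(lambda)
  if (n_sel >= 2) {
    vm <- varimax(raw_loadings[, seq_len(n_sel), drop = FALSE],
                  normalize = kaiser_normalize)
    rotated <- unclass(vm$loadings)
    R <- vm$rotmat
  } else {
    rotated <- raw_loadings[, 1, drop = FALSE]
    R <- matrix(1, 1, 1)
  }
  H <- helmert_basis(K)
  state_loadings <- t(H) %*% rotated
  # deterministic sign: largest-|.| state loading positive per component
  sgn <- vapply(seq_len(ncol(rotated)), function(j) {
    v <- state_loadings[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  rotated <- sweep(rotated, 2, sgn, `*`)
  state_loadings <- sweep(state_loadings, 2, sgn, `*`)
  colnames(rotated) <- colnames(state_loadings) <-
    paste0("comp_", seq_len(ncol(rotated)))
  rownames(state_loadings) <- paste0("state_", seq_len(K))
  scores <- sweep(Z, 2, pc$center) %*% rotated
  obj <- structure(
    list(alpha = alpha, K = K, helmert = H, center = pc$center,
         eigenvalues = lambda, raw_loadings = raw_loadings,
         n_selected = as.integer(n_sel),
         forced_selection = isTRUE(attr(n_sel, "forced")),
         rotation = R, loadings = rotated, state_loadings = state_loadings,
         variance_explained = lambda / sum(lambda),
         scores = tibble(scan_id = ids,
                         !!!setNames(as.data.frame(scores),
                                     colnames(rotated)))),
    class = "composition_pca"
  )
  obj
}

#' Component scores for new compositions
#'
#' Projects new occupancy compositions through a fitted [composition_pca()]:
#' alpha-transform, center at the training mean, multiply by the rotated
#' loadings.
#'
#' @param object fitted `composition_pca`.
#' @param newdata N x K compositions (matrix or data frame as in
#'   [composition_pca()]).
#' @param ... unused.
#' @return tibble of scores, one column per retained component.
#' @export
predict.composition_pca <- function(object, newdata, ...) {
  ids <- NULL
  if (is.data.frame(newdata)) {
    if ("scan_id" %in% names(newdata)) ids <- newdata$scan_id
    fo_cols <- grep("^FO_", names(newdata), value = TRUE)
    if (length(fo_cols)) newdata <- newdata[fo_cols]
  }
  newdata <- as.matrix(newdata)
  Z <- alpha_transform(newdata, object$alpha)
  scores <- sweep(Z, 2, object$center) %*% object$loadings
  tibble(scan_id = ids %||% paste0("obs_", seq_len(nrow(scores))),
         !!!setNames(as.data.frame(scores), colnames(object$loadings)))
}

#' @export
print.composition_pca <- function(x, ...) {
  cat(sprintf(
    "Compositional PCA (alpha = %g): %d of %d components retained%s\n",
    x$alpha, x$n_selected, length(x$eigenvalues),
    if (x$forced_selection) " (forced)" else ""))
  cat(sprintf("Component 1 explains %.1f%% of the variance\n",
              100 * x$variance_explained[1]))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.composition_pca <- function(x, ...) {
  as_tibble(x$state_loadings, rownames = "state") |>
    tidyr::pivot_longer(-"state", names_to = "component",
                        values_to = "loading")
}

#' @exportS3Method generics::glance
glance.composition_pca <- function(x, ...) {
  tibble(n_selected = x$n_selected,
         forced_selection = x$forced_selection,
         variance_explained_1 = x$variance_explained[1],
         total_variance = sum(x$eigenvalues))
}

#' @exportS3Method ggplot2::autoplot
autoplot.composition_pca <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$state, y = .data$loading)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~component) +
    ggplot2::labs(x = NULL, y = "State-space loading",
                  title = "Occupancy component loadings") +
    ggplot2::theme_minimal()
}
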