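contrast_row <- function(effect, F, df1, df2, p) {
  tibble(effect = effect, statistic = F, df1 = df1, df2 = df2,
         p_value = p, p_adjusted = NA_real_,
         effect_size = (F * df1) / (F * df1 + df2))   # partial eta squared
}

#' Cross-sectional group contrast on a dynamics metric
#'
#' Tests the diagnostic-group main effect on one per-subject metric
#' (fractional occupancy, switching rate, component score) with age and sex as
#' covariates. The default engine is a mixed-effects linear model with a scan
#' site random intercept, with the group F test on Satterthwaite-estimated
#' denominator degrees of freedom; `method = "ancova"` gives the
#' fixed-effects-only one-way analysis of covariance used for single-site
#' cohorts. With fewer than two sites the mixed model falls back to the
#' ANCOVA with a warning.
#'
#' @param data data frame holding the metric, grouping factor, covariates and
#'   (for the mixed model) a `site` column.
#' @param metric name of the metric column (string).
#' @param group name of the grouping column (>= 2 levels).
#' @param covariates character vector of covariate column names.
#' @param site name of the site column for the random intercept.
#' @param method `"auto"` (mixed when >= 2 sites), `"mixed"`, or `"ancova"`.
#' @return one-row tibble: `effect`, `statistic` (F), `df1`, `df2`,
#'   `p_value`, `p_adjusted` (NA until adjusted), `effect_size`
#'   (partial eta squared).
#' @export
fit_metric_model <- function(data, metric, group = "group",
                             covariates = c("age", "sex"), site = "site",
                             method = c("auto", "mixed", "ancova")) {
  method <- match.arg(method)
  data <- as.data.frame(data)
  data[[group]] <- droplevels(factor(data[[group]]))
  if (nlevels(data[[group]]) < 2)
    abort("grouping column needs at least 2 levels.")
  n_sites <- if (site %in% names(data)) length(unique(data[[site]])) else 0
  if (method == "auto") method <- if (n_sites >= 2) "mixed" else "ancova"
  if (method == "mixed" && n_sites < 2) {
    warn("fewer than 2 sites; falling back to fixed-effects ANCOVA.")
    method <- "ancova"
  }
  rhs <- c(group, covariates)
  if (method == "mixed") {
    f <- as.formula(paste0("`", metric, "` ~ ", paste(rhs, collapse = " + "),
                           " + (1 | ", site, ")"))
    m <- lmerTest::lmer(f, data = data)
    a <- suppressMessages(anova(m, type = 3))
    row <- a[group, ]
    contrast_row(group, row[["F value"]], row[["NumDF"]], row[["DenDF"]],
                 row[["Pr(>F)"]])
  } else {
    f_full <- as.formula(paste0("`", metric, "` ~ ",
                                paste(rhs, collapse = " + ")))
    f_red <- as.formula(paste0("`", metric, "` ~ ",
                               paste(covariates, collapse = " + ")))
    m_full <- lm(f_full, data = data)
    m_red <- lm(f_red, data = data)
    a <- anova(m_red, m_full)
    contrast_row(group, a$F[2], a$Df[2], a$Res.Df[2], a$`Pr(>F)`[2])
  }
}

#' Compare linear and quadratic age models
#'
#' Fits the metric on orthogonal polynomials of age (degree 1 vs degree 2)
#' with sex as a covariate and a site random intercept where available, by
#' maximum likelihood, and compares the two by likelihood-ratio test and AIC.
#'
#' @inheritParams fit_metric_model
#' @return one-row tibble: log-likelihoods, AICs, LRT chi-square, df and p;
#'   `quadratic_favored` is TRUE when the LRT rejects at 0.05.
#' @export
compare_age_models <- function(data, metric, covariates = "sex",
                               site = "site") {
  data <- as.data.frame(data)
  n_sites <- if (site %in% names(data)) length(unique(data[[site]])) else 0
  fit_one <- function(degree) {
    rhs <- c(sprintf("poly(age, %d)", degree), covariates)
    if (n_sites >= 2) {
      f <- as.formula(paste0("`", metric, "` ~ ",
                             paste(rhs, collapse = " + "),
                             " + (1 | ", site, ")"))
      lme4::lmer(f, data = data, REML = FALSE)
    } else {
      lm(as.formula(paste0("`", metric, "` ~ ",
                           paste(rhs, collapse = " + "))), data = data)
    }
  }
  m1 <- fit_one(1)
  m2 <- fit_one(2)
  ll1 <- as.numeric(logLik(m1)); ll2 <- as.numeric(logLik(m2))
  df_diff <- attr(logLik(m2), "df") - attr(logLik(m1), "df")
  lrt <- 2 * (ll2 - ll1)
  p <- stats::pchisq(lrt, df_diff, lower.tail = FALSE)
  tibble(metric = metric, loglik_linear = ll1, loglik_quadratic = ll2,
         aic_linear = AIC(m1), aic_quadratic = AIC(m2),
         lrt_statistic = lrt, lrt_df = df_diff, lrt_p = p,
         quadratic_favored = p < 0.05)
}

#' Group-by-age interaction test
#'
#' Tests whether the age trajectory of a metric differs between groups, with
#' age entered as an orthogonal polynomial of the requested degree, sex as a
#' covariate and a site random intercept where available. The reported F is
#' for the group-by-age interaction term.
#'
#' @inheritParams fit_metric_model
#' @param degree 1 (linear age) or 2 (quadratic age).
#' @return one-row contrast tibble as in [fit_metric_model()].
#' @export
group_by_age_interaction <- function(data, metric, group = "group",
                                     degree = 2, site = "site") {
  stopifnot(degree %in% 1:2)
  data <- as.data.frame(data)
  data[[group]] <- droplevels(factor(data[[group]]))
  n_sites <- if (site %in% names(data)) length(unique(data[[site]])) else 0
  age_term <- sprintf("poly(age, %d)", degree)
  rhs <- paste0(group, " * ", age_term, " + sex")
  int_name <- paste0(group, ":", age_term)
  if (n_sites >= 2) {
    f <- as.formula(paste0("`", metric, "` ~ ", rhs, " + (1 | ", site, ")"))
    m <- lmerTest::lmer(f, data = data)
    a <- suppressMessages(anova(m, type = 3))
    row <- a[int_name, ]
    contrast_row(int_name, row[["F value"]], row[["NumDF"]], row[["DenDF"]],
                 row[["Pr(>F)"]])
  } else {
    f_full <- as.formula(paste0("`", metric, "` ~ ", rhs))
    f_red <- as.formula(paste0("`", metric, "` ~ ", group, " + ", age_term,
                               " + sex"))
    a <- anova(lm(f_red, data = data), lm(f_full, data = data))
    contrast_row(int_name, a$F[2], a$Df[2], a$Res.Df[2], a$`Pr(>F)`[2])
  }
}

# t statistics for the group column of X across all response columns of Y.
ols_tstats <- function(X, Y, g_col) {
  XtXi <- solve(crossprod(X))
  B <- XtXi %*% crossprod(X, Y)
  res <- Y - X %*% B
  df <- nrow(X) - ncol(X)
  s2 <- colSums(res^2) / df
  B[g_col, ] / sqrt(s2 * XtXi[g_col, g_col])
}

#' Max-statistic permutation test on transition/persistence probabilities
#'
#' Tests, cell by cell, whether the K x K matrix of transition and
#' persistence probabilities differs between two groups, treating the K^2
#' probabilities as one family. Nuisance covariates are handled by the
#' Freedman-Lane scheme: residuals of the covariates-only model are permuted,
#' re-attached to the reduced-model fit, and the full model is refit, giving
#' a null distribution of the maximum |t| over all cells (which covers both
#' contrast directions). Family-wise-error-corrected p values are
#' `(1 + #{perms with max |t| >= |t_obs|}) / (n_perm + 1)`. When there are no
#' covariates and the number of distinct group-label splits is at most
#' `n_perm`, the exact permutation distribution is enumerated instead.
#'
#' @param data data frame with the flattened matrix columns `P_i_j`, the
#'   grouping column and any covariate columns.
#' @param group name of a two-level grouping column.
#' @param covariates character vector of nuisance covariate names (may be
#'   empty).
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed for the permutation stream.
#' @param blocks optional name of an exchangeability-block column; random
#'   permutations are then restricted within blocks.
#' @return object of class `permutation_result`: tibble `cells` with
#'   `from_state`, `to_state`, `t` (signed, direction level2 - level1) and
#'   `fwe_p`, plus fields `n_perm`, `seed`, `exact`, `max_t_null`.
#' @export
permutation_test_transitions <- function(data, group = "group",
                                         covariates = c("age", "sex"),
                                         n_perm = 5000, seed = 1L,
                                         blocks = NULL) {
  if (n_perm < 100) abort("`n_perm` must be at least 100.")
  data <- as.data.frame(data)
  g <- droplevels(factor(data[[group]]))
  if (nlevels(g) != 2) abort("permutation test requires exactly 2 groups.")
  p_cols <- grep("^P_[0-9]+_[0-9]+$", names(data), value = TRUE)
  if (!length(p_cols)) abort("no `P_i_j` transition columns found.")
  Y <- as.matrix(data[p_cols])
  n <- nrow(Y)
  g01 <- as.numeric(g == levels(g)[2])
  covars <- if (length(covariates)) {
    stats::model.matrix(
      as.formula(paste("~", paste(covariates, collapse = " + "))),
      data = data)[, -1, drop = FALSE]
  } else NULL
  X_full <- cbind(`(Intercept)` = 1, group = g01, covars)
  g_col <- 2L
  t_obs <- ols_tstats(X_full, Y, g_col)

  n1 <- sum(g01 == 0)
  exact <- is.null(covars) && is.null(blocks) && choose(n, n1) <= n_perm
  set.seed(seed)
  if (exact) {
    splits <- utils::combn(n, n1)
    max_t <- apply(splits, 2, function(idx) {
      gp <- rep(1, n); gp[idx] <- 0
      max(abs(ols_tstats(cbind(1, gp), Y, 2L)))
    })
    # exact distribution includes the observed split
    fwe_p <- vapply(abs(t_obs), function(t0) mean(max_t >= t0 - 1e-12),
                    numeric(1))
    n_used <- ncol(splits)
  } else {
    X_red <- cbind(1, covars)
    Hr <- X_red %*% solve(crossprod(X_red)) %*% t(X_red)
    fit_red <- Hr %*% Y
    res_red <- Y - fit_red
    block_f <- if (is.null(blocks)) rep(1, n) else data[[blocks]]
    max_t <- vapply(seq_len(n_perm), function(i) {
      perm <- stats::ave(seq_len(n), block_f,
                         FUN = function(ix) ix[sample.int(length(ix))])
      Y_star <- fit_red + res_red[perm, , drop = FALSE]
      max(abs(ols_tstats(X_full, Y_star, g_col)))
    }, numeric(1))
    fwe_p <- vapply(abs(t_obs), function(t0)
      (1 + sum(max_t >= t0 - 1e-12)) / (n_perm + 1), numeric(1))
    n_used <- n_perm
  }
  ij <- do.call(rbind, strsplit(sub("^P_", "", p_cols), "_"))
  cells <- tibble(from_state = as.integer(ij[, 1]),
                  to_state = as.integer(ij[, 2]),
                  t = unname(t_obs), fwe_p = unname(fwe_p))
  structure(list(cells = cells, n_perm = n_used, seed = seed, exact = exact,
                 max_t_null = max_t,
                 direction = paste(levels(g)[2], "-", levels(g)[1])),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "Max-statistic permutation test (%s%d permutations), contrast %s\n",
    if (x$exact) "exact, " else "", x$n_perm, x$direction))
  sig <- dplyr::filter(x$cells, .data$fwe_p < 0.05)
  cat(sprintf("%d of %d cells significant at FWE 5%%\n",
              nrow(sig), nrow(x$cells)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.permutation_result <- function(x, ...) x$cells

#' @exportS3Method generics::glance
glance.permutation_result <- function(x, ...) {
  tibble(n_perm = x$n_perm, exact = x$exact,
         min_fwe_p = min(x$cells$fwe_p),
         n_significant = sum(x$cells$fwe_p < 0.05))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p values controlling the FDR, as applied across each
#' family of related tests.
#'
#' @param p vector of raw p values in `[0, 1]`.
#' @return monotone adjusted p values, same length and order.
#' @export
fdr_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}

#' Converter contrast at the latest presymptomatic scan
#'
#' Compares a metric or component score between presymptomatic carriers who
#' later converted to the symptomatic phase and those who did not, with age
#' and sex covariates and a site random intercept, restricted to
#' presymptomatic subjects (one row each: their latest presymptomatic scan).
#'
#' @param data per-subject data at the latest presymptomatic scan, holding the
#'   metric, a logical `converter` column, `group`, covariates and `site`.
#' @param metric name of the metric column.
#' @inheritParams fit_metric_model
#' @return one-row contrast tibble; the effect direction is converter minus
#'   non-converter.
#' @export
converter_contrast <- function(data, metric, covariates = c("age", "sex"),
                               site = "site") {
  data <- as.data.frame(data)
  if ("group" %in% names(data))
    data <- data[data$group == "presymptomatic", , drop = FALSE]
  if (sum(data$converter) < 2) abort("need at least 2 converters.")
  data$converter <- factor(data$converter, levels = c(FALSE, TRUE),
                           labels = c("non-converter", "converter"))
  fit_metric_model(data, metric, group = "converter",
                   covariates = covariates, site = site)
}
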