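#' Remove subjects at floor (or ceiling) scores at baseline
#'
#' Before slope estimation, subjects whose baseline (earliest-visit) value for
#' an outcome sits at that outcome's floor — or at its ceiling, for timed
#' tests capped at a maximum — are removed for that outcome only; they remain
#' available for other outcomes.
#'
#' @param visits long visits table: `subject_id`, `years_from_baseline`, and
#'   one column per outcome.
#' @param floors named list, one entry per outcome, each a list with optional
#'   `floor` and/or `ceiling` values.
#' @return list with `visits` (named list of per-outcome filtered tables) and
#'   `report` (tibble: outcome, n_removed, removed subject ids).
#' @export
remove_floor <- function(visits, floors) {
  visits <- as_tibble(visits)
  unknown <- setdiff(names(floors), names(visits))
  if (length(unknown))
    abort(paste("unknown outcome(s):", paste(unknown, collapse = ", ")))
  out <- list()
  report <- list()
  for (outcome in names(floors)) {
    def <- floors[[outcome]]
    base <- visits |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::slice_min(.data$years_from_baseline, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
    at_limit <- rep(FALSE, nrow(base))
    if (!is.null(def$floor))
      at_limit <- at_limit | base[[outcome]] <= def$floor
    if (!is.null(def$ceiling))
      at_limit <- at_limit | base[[outcome]] >= def$ceiling
    removed <- base$subject_id[at_limit]
    out[[outcome]] <- dplyr::filter(visits, !.data$subject_id %in% removed)
    report[[outcome]] <- tibble(outcome = outcome,
                                n_removed = length(removed),
                                removed_subjects = paste(removed,
                                                         collapse = ","))
  }
  list(visits = out, report = dplyr::bind_rows(report))
}

#' Per-subject annual slopes from a random-slope mixed model
#'
#' Stage one of the two-step longitudinal analysis: fits
#' `outcome ~ time + (time | subject)` across all retained participants and
#' returns each subject's annual rate of change as the fixed slope plus the
#' conditional (shrunken) random-slope prediction. Subjects with few visits
#' are thereby shrunk toward the population slope. A singular random-effect
#' covariance triggers a refit with independent (diagonal) random effects.
#'
#' @param visits long visits table for one outcome.
#' @param outcome name of the outcome column.
#' @param time,id names of the time (years from baseline) and subject columns.
#' @return tibble: `subject_id`, `intercept`, `slope` (units/year),
#'   `slope_se` (conditional SD of the random slope), `n_visits`; attributes
#'   `fixed_slope`, `fixed_slope_se`, `singular`.
#' @export
estimate_slopes <- function(visits, outcome, time = "years_from_baseline",
                            id = "subject_id") {
  d <- data.frame(y = visits[[outcome]], t = visits[[time]],
                  id = factor(visits[[id]]))
  d <- d[stats::complete.cases(d), ]
  multi <- table(d$id)
  if (sum(multi >= 2) < 2)
    abort("need at least two subjects with two or more visits.")
  fit_formula <- y ~ t + (t | id)
  m <- suppressWarnings(suppressMessages(
    lme4::lmer(fit_formula, data = d,
               control = lme4::lmerControl(check.nobs.vs.nRE = "ignore"))))
  singular <- lme4::isSingular(m, tol = 1e-5)
  if (singular) {
    warn("singular random-effect covariance; refitting with diagonal covariance.")
    m <- suppressWarnings(suppressMessages(
      lme4::lmer(y ~ t + (t || id), data = d,
                 control = lme4::lmerControl(check.nobs.vs.nRE = "ignore"))))
  }
  fe <- lme4::fixef(m)
  re <- lme4::ranef(m, condVar = TRUE)$id
  pv <- attr(re, "postVar")
  slope_sd <- if (is.list(pv)) {
    # diagonal-covariance fits return one block per term
    sqrt(pv[[length(pv)]][1, 1, ])
  } else {
    sqrt(pv[2, 2, ])
  }
  counts <- table(d$id)
  tib <- tibble(
    subject_id = rownames(re),
    intercept = fe[["(Intercept)"]] + re[["(Intercept)"]],
    slope = fe[["t"]] + re[["t"]],
    slope_se = slope_sd,
    n_visits = as.integer(counts[rownames(re)])
  )
  attr(tib, "fixed_slope") <- unname(fe[["t"]])
  attr(tib, "fixed_slope_se") <- unname(sqrt(diag(as.matrix(stats::vcov(m)))[2]))
  attr(tib, "singular") <- singular
  tib
}

#' Predict cognitive decline from baseline component scores
#'
#' Stage two of the two-step analysis: regresses per-subject annual slopes on
#' baseline component scores with baseline age, sex and site as covariates of
#' no interest (site as fixed categorical; single-site cohorts drop it).
#' Continuous variables are z-scored within the modelled sample so the
#' reported betas are standardized. Model forms: `"comp"` (main effect of the
#' score), `"comp_age"` (score-by-age interaction as the headline term),
#' `"comp_age_group"` (three-way score-by-age-by-group interaction as the
#' headline term).
#'
#' @param slopes tibble from [estimate_slopes()].
#' @param scores per-subject baseline component scores: `subject_id` plus a
#'   score column.
#' @param cohort per-subject covariates: `subject_id`, `age`, `sex`, `site`,
#'   and `group` for the three-way form.
#' @param form model form (see above).
#' @param score name of the score column in `scores`.
#' @return one-row tibble: `model_form`, `term` (headline), `std_beta`,
#'   `statistic` (t), `df`, `p_value`, `p_adjusted` (NA), `n`.
#' @export
predict_decline <- function(slopes, scores, cohort,
                            form = c("comp", "comp_age", "comp_age_group"),
                            score = "comp_1") {
  form <- match.arg(form)
  d <- slopes |>
    dplyr::inner_join(scores, by = "subject_id") |>
    dplyr::inner_join(
      dplyr::distinct(as_tibble(cohort), .data$subject_id,
                      .keep_all = TRUE),
      by = "subject_id")
  zs <- function(v) as.numeric(scale(v))
  d$slope_z <- zs(d$slope)
  d$comp_z <- zs(d[[score]])
  d$age_z <- zs(d$age)
  terms <- switch(form,
    comp = "comp_z + age_z",
    comp_age = "comp_z * age_z",
    comp_age_group = "comp_z * age_z * group")
  headline <- switch(form,
    comp = "comp_z",
    comp_age = "comp_z:age_z",
    comp_age_group = NULL)   # matched by pattern below
  covars <- "sex"
  if ("site" %in% names(d) && length(unique(d$site)) >= 2)
    covars <- c(covars, "site")
  f <- as.formula(paste("slope_z ~", terms, "+", paste(covars, collapse = "+")))
  if (form == "comp_age_group") {
    d$group <- droplevels(factor(d$group))
    if (nlevels(d$group) < 2)
      abort("three-way form needs at least 2 groups.")
  }
  m <- lm(f, data = d)
  if (any(is.na(coef(m)))) {
    bad <- names(coef(m))[is.na(coef(m))]
    abort(paste("rank-deficient design; collinear terms:",
                paste(bad, collapse = ", ")))
  }
  cf <- summary(m)$coefficients
  term <- if (form == "comp_age_group") {
    rn <- rownames(cf)
    rn[grepl("^comp_z:age_z:group", rn)][1]
  } else headline
  tibble(model_form = form, term = term,
         std_beta = cf[term, "Estimate"],
         statistic = cf[term, "t value"],
         df = m$df.residual,
         p_value = cf[term, "Pr(>|t|)"],
         p_adjusted = NA_real_,
         n = nrow(d))
}

#' Two-step longitudinal prediction across outcomes
#'
#' Runs floor removal, slope estimation and the second-stage regression for
#' each outcome and model form, returning a results table shaped like a
#' standardized-beta summary (one row per outcome and form) with
#' FDR-adjusted p values within each model form.
#'
#' @param visits long visits table (one column per outcome).
#' @param scores baseline component scores (`subject_id` + score column).
#' @param cohort per-subject covariates (and `group` for the three-way form).
#' @param outcomes character vector of outcome column names.
#' @param floors optional named list of floor/ceiling definitions.
#' @param forms model forms to fit.
#' @param score name of the score column.
#' @return tibble with columns `outcome`, `model_form`, `term`, `std_beta`,
#'   `statistic`, `df`, `p_value`, `p_adjusted`, `n`.
#' @export
two_step_prediction <- function(visits, scores, cohort, outcomes,
                                floors = list(),
                                forms = c("comp", "comp_age",
                                          "comp_age_group"),
                                score = "comp_1") {
  res <- purrr::map_dfr(outcomes, function(oc) {
    v <- if (oc %in% names(floors)) {
      remove_floor(visits, floors[oc])$visits[[oc]]
    } else visits
    sl <- estimate_slopes(v, oc)
    purrr::map_dfr(forms, function(fm)
      dplyr::mutate(
        predict_decline(sl, scores, cohort, form = fm, score = score),
        outcome = oc, .before = 1))
  })
  res |>
    dplyr::group_by(.data$model_form) |>
    dplyr::mutate(p_adjusted = fdr_adjust(.data$p_value)) |>
    dplyr::ungroup()
}
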