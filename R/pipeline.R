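config_defaults <- function() {
  list(
    seed = 1L,
    n_states = 6L,        # six-state model order used throughout the study
    alpha = 1,            # alpha-transformation parameter for the PCA
    n_perm = 5000L,       # permutations for the transition-matrix test
    fdr_level = 0.05,
    fwe_level = 0.05,
    simulate = TRUE,
    qc = list(max_spike_percentage = 10, max_framewise_displacement = 3,
              max_dvars = 5, mean_framewise_displacement = 0.5,
              active = c("max_spike_percentage",
                         "max_framewise_displacement", "max_dvars")),
    hmm = list(n_restarts = 5L, max_iter = 500L, tol = 1e-5),
    cohort = list(),      # overrides passed to cohort_spec()
    floors = list(),      # per-outcome floor/ceiling definitions
    outcomes = "cognition",
    paths = list(timecourse_dir = NULL, cohort_csv = NULL, visits_csv = NULL,
                 out_dir = "statedyn_output")
  )
}

#' Build a pipeline configuration
#'
#' Named overrides are merged into the defaults; unknown keys are rejected.
#' Defaults mirror the study design: a six-state model, alpha = 1
#' compositional PCA, 5000 permutations, and 5% FDR/FWE levels.
#'
#' @param ... overrides of the default configuration entries.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  overrides <- list(...)
  base <- config_defaults()
  unknown <- setdiff(names(overrides), names(base))
  if (length(unknown))
    abort(paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  cfg <- modifyList(base, overrides)
  if (cfg$n_states < 2) abort("`n_states` must be >= 2.")
  if (cfg$n_perm < 100) abort("`n_perm` must be >= 100.")
  if (cfg$fdr_level <= 0 || cfg$fdr_level >= 1 ||
      cfg$fwe_level <= 0 || cfg$fwe_level >= 1)
    abort("FDR/FWE levels must lie in (0, 1).")
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as JSON
#'
#' @param path JSON file path.
#' @return [read_config()] returns a `pipeline_config`.
#' @export
read_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, obj)
}

#' @rdname read_config
#' @param config a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

log_stage <- function(log, stage, msg) {
  line <- sprintf("[%s] %s", stage, msg)
  message(format(Sys.time(), "%H:%M:%S "), line)
  c(log, line)
}

#' Run the full network-dynamics pipeline
#'
#' Executes simulate (optional) -> motion QC -> standardize/concatenate ->
#' HMM fit -> temporal metrics -> compositional PCA -> cross-sectional group
#' statistics -> two-step longitudinal prediction, writing all result tables,
#' the fitted model and a run log under the configured output directory.
#' Reruns with an identical configuration (including the seed) reproduce the
#' output files byte-identically; the run log records stages, seeds and the
#' configuration hash but no wall-clock times for that reason.
#'
#' @param config a [pipeline_config()].
#' @param stages subset of stages to run (`"all"` for everything).
#' @return invisibly, a list with the main in-memory results (cohort table
#'   with QC, fitted model, metrics, PCA, group statistics, permutation
#'   result, longitudinal results).
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = "all") {
  stopifnot(inherits(config, "pipeline_config"))
  all_stages <- c("simulate", "qc", "fit", "metrics", "pca", "stats",
                  "longitudinal")
  if (identical(stages, "all")) stages <- all_stages
  out_dir <- config$paths$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- character(0)
  log <- log_stage(log, "config", sprintf("seed=%d K=%d n_perm=%d",
                                          config$seed, config$n_states,
                                          config$n_perm))

  # --- inputs: simulate or load -------------------------------------------
  if (config$simulate && "simulate" %in% stages) {
    spec <- do.call(cohort_spec,
                    modifyList(list(seed = config$seed,
                                    n_states = config$n_states),
                               config$cohort))
    sim <- simulate_cohort(spec)
    cohort <- sim$cohort
    visits <- sim$visits
    timecourses <- sim$timecourses
    log <- log_stage(log, "simulate",
                     sprintf("%d subjects generated", nrow(cohort)))
  } else {
    p <- config$paths
    if (is.null(p$cohort_csv) || is.null(p$visits_csv) ||
        is.null(p$timecourse_dir))
      abort("simulation disabled and input paths are not all set.")
    cohort <- read_cohort(p$cohort_csv)
    visits <- read_visits(p$visits_csv, cohort)
    timecourses <- lapply(setNames(cohort$scan_id, cohort$scan_id),
                          function(id)
                            read_timecourse(
                              file.path(p$timecourse_dir,
                                        paste0(id, ".tsv"))))
    log <- log_stage(log, "load", sprintf("%d scans read", nrow(cohort)))
  }

  # --- motion QC -----------------------------------------------------------
  thresholds <- do.call(qc_thresholds, config$qc)
  qc <- filter_scans(cohort, thresholds)
  cohort <- dplyr::left_join(cohort, qc, by = "scan_id")
  readr::write_csv(cohort, file.path(out_dir, "cohort_qc.csv"),
                   progress = FALSE)
  readr::write_tsv(dplyr::filter(qc, !.data$qc_pass),
                   file.path(out_dir, "exclusions.tsv"), progress = FALSE)
  log <- log_stage(log, "qc", sprintf("%d/%d scans pass", sum(qc$qc_pass),
                                      nrow(qc)))
  kept <- cohort$scan_id[cohort$qc_pass]
  timecourses <- timecourses[kept]

  # --- standardize, concatenate, fit --------------------------------------
  std <- lapply(timecourses, standardize_timecourse)
  stacked <- concatenate_scans(std)
  model <- fit_hmm(stacked$data, stacked$boundaries, K = config$n_states,
                   n_restarts = config$hmm$n_restarts,
                   max_iter = config$hmm$max_iter, tol = config$hmm$tol,
                   seed = config$seed)
  write_hmm(model, file.path(out_dir, "hmm_model.json"))
  log <- log_stage(log, "fit",
                   sprintf("logLik %.2f in %d iterations (restart seed %d)",
                           model$diagnostics$loglik, model$diagnostics$n_iter,
                           model$diagnostics$restart_seed))

  # --- per-scan metrics ----------------------------------------------------
  tr <- setNames(cohort$repetition_time, cohort$scan_id)[kept]
  metrics <- compute_metrics(model, std, tr)
  readr::write_tsv(metrics, file.path(out_dir, "metrics.tsv"),
                   progress = FALSE)
  log <- log_stage(log, "metrics", sprintf("%d scans", nrow(metrics)))
  mdat <- dplyr::inner_join(metrics, cohort, by = "scan_id")

  # --- compositional PCA ---------------------------------------------------
  cp <- composition_pca(metrics, alpha = config$alpha)
  readr::write_tsv(tidy(cp), file.path(out_dir, "pca_loadings.tsv"),
                   progress = FALSE)
  readr::write_tsv(cp$scores, file.path(out_dir, "pca_scores.tsv"),
                   progress = FALSE)
  log <- log_stage(log, "pca",
                   sprintf("%d component(s), PC1 %.1f%% variance",
                           cp$n_selected, 100 * cp$variance_explained[1]))
  mdat <- dplyr::inner_join(mdat, cp$scores, by = "scan_id")

  # --- cross-sectional statistics -----------------------------------------
  results <- list()
  perm <- NULL
  if ("stats" %in% stages) {
    K <- config$n_states
    fo_stats <- purrr::map_dfr(paste0("FO_", seq_len(K)), function(mcol)
      dplyr::mutate(fit_metric_model(mdat, mcol), metric = mcol, .before = 1))
    other <- purrr::map_dfr(c("SR", "comp_1"), function(mcol)
      dplyr::mutate(fit_metric_model(mdat, mcol), metric = mcol, .before = 1))
    group_stats <- dplyr::bind_rows(fo_stats, other)
    group_stats$p_adjusted <- fdr_adjust(group_stats$p_value)
    two <- dplyr::filter(mdat,
                         .data$group %in% c("non-carrier", "symptomatic"))
    perm <- permutation_test_transitions(two, n_perm = config$n_perm,
                                         seed = config$seed)
    readr::write_tsv(tidy(perm), file.path(out_dir, "permutation.tsv"),
                     progress = FALSE)
    conv <- tryCatch(
      purrr::map_dfr(c("comp_1", paste0("FO_", seq_len(K))), function(mcol)
        dplyr::mutate(converter_contrast(mdat, mcol), metric = mcol,
                      .before = 1)),
      error = function(e) NULL)
    age_cmp <- compare_age_models(
      dplyr::filter(mdat, .data$group != "symptomatic"), "comp_1")
    age_int <- group_by_age_interaction(
      dplyr::filter(mdat, .data$group != "symptomatic"), "comp_1",
      degree = 2)
    results <- list(group_stats = group_stats, converters = conv,
                    age_comparison = age_cmp, age_interaction = age_int)
    readr::write_tsv(group_stats, file.path(out_dir, "group_stats.tsv"),
                     progress = FALSE)
    if (!is.null(conv))
      readr::write_tsv(conv, file.path(out_dir, "converter_stats.tsv"),
                       progress = FALSE)
    log <- log_stage(log, "stats",
                     sprintf("%d group contrasts, %d permutation cells",
                             nrow(group_stats), nrow(tidy(perm))))
  }

  # --- longitudinal prediction --------------------------------------------
  longitudinal <- NULL
  if ("longitudinal" %in% stages) {
    base_scores <- mdat |>
      dplyr::select("subject_id", "comp_1") |>
      dplyr::distinct(.data$subject_id, .keep_all = TRUE)
    symp <- dplyr::filter(cohort, .data$group == "symptomatic")
    carriers <- dplyr::filter(cohort, .data$group != "symptomatic")
    long_symp <- tryCatch(
      two_step_prediction(
        dplyr::semi_join(visits, symp, by = "subject_id"),
        base_scores, symp, outcomes = config$outcomes,
        floors = config$floors, forms = "comp"),
      error = function(e) NULL)
    long_psc <- tryCatch(
      two_step_prediction(
        dplyr::semi_join(visits, carriers, by = "subject_id"),
        base_scores, carriers, outcomes = config$outcomes,
        floors = config$floors, forms = c("comp_age", "comp_age_group")),
      error = function(e) NULL)
    longitudinal <- dplyr::bind_rows(
      if (!is.null(long_symp)) dplyr::mutate(long_symp,
                                             sample = "symptomatic"),
      if (!is.null(long_psc)) dplyr::mutate(long_psc,
                                            sample = "presymptomatic"))
    if (!is.null(longitudinal) && nrow(longitudinal))
      readr::write_tsv(longitudinal, file.path(out_dir, "longitudinal.tsv"),
                       progress = FALSE)
    log <- log_stage(log, "longitudinal",
                     sprintf("%d prediction rows",
                             if (is.null(longitudinal)) 0L
                             else nrow(longitudinal)))
  }

  cfg_hashable <- unclass(config)
  cfg_hashable$paths <- NULL        # hash the analysis settings, not locations
  cfg_json <- jsonlite::toJSON(cfg_hashable, auto_unbox = TRUE,
                               digits = NA, null = "null")
  log <- c(log, sprintf("[done] config_hash=%s version=%s",
                        substr(rlang::hash(cfg_json), 1, 12),
                        as.character(utils::packageVersion("statedyn"))))
  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(list(cohort = cohort, visits = visits, model = model,
                 metrics = metrics, pca = cp, results = results,
                 permutation = perm, longitudinal = longitudinal,
                 log = log))
}
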