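#' Read a component time-course TSV
#'
#' Expects a tab-separated file with header `comp_1..comp_C` and a numeric
#' body; any missing or non-numeric cell is an error naming its row and
#' column.
#'
#' @param path file path.
#' @param repetition_time optional seconds per volume to attach.
#' @return T x C numeric matrix with a `repetition_time` attribute.
#' @export
read_timecourse <- function(path, repetition_time = NULL) {
  df <- suppressWarnings(
    readr::read_tsv(path, col_types = readr::cols(.default = readr::col_double()),
                    progress = FALSE))
  prob <- readr::problems(df)
  if (nrow(prob) > 0)
    abort(sprintf("parse error in %s at line %d, column %d: expected %s",
                  path, prob$row[1] + 1, prob$col[1], prob$expected[1]))
  if (!all(grepl("^comp_[0-9]+$", names(df))))
    abort(sprintf("%s: header must be comp_1..comp_C.", path))
  x <- as.matrix(df)
  if (anyNA(x)) {
    idx <- which(is.na(x), arr.ind = TRUE)[1, ]
    abort(sprintf("%s: missing/non-numeric value at row %d, column %s",
                  path, idx[1], colnames(x)[idx[2]]))
  }
  attr(x, "repetition_time") <- repetition_time
  x
}

#' Write a component time-course TSV
#'
#' @param x T x C matrix with `comp_*` column names.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(x, path) {
  readr::write_tsv(as_tibble(as.data.frame(unclass(x))), path,
                   progress = FALSE)
  invisible(path)
}

cohort_required_cols <- c("subject_id", "scan_id", "group", "age", "sex",
                          "site", "repetition_time")
allowed_groups <- c("non-carrier", "presymptomatic", "symptomatic")

#' Read and validate the cohort metadata CSV
#'
#' @param path file path.
#' @return validated tibble with `group` as a factor over
#'   non-carrier/presymptomatic/symptomatic.
#' @export
read_cohort <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(cohort_required_cols, names(df))
  if (length(missing_cols))
    abort(paste("cohort table missing columns:",
                paste(missing_cols, collapse = ", ")))
  bad <- setdiff(unique(df$group), allowed_groups)
  if (length(bad))
    abort(paste("unknown group value(s):", paste(bad, collapse = ", ")))
  if (anyDuplicated(df$scan_id)) abort("duplicate scan_id in cohort table.")
  df$group <- factor(df$group, levels = allowed_groups)
  df
}

#' Read and validate the longitudinal visits CSV
#'
#' @param path file path.
#' @param cohort optional cohort table for referential-integrity checks
#'   (every visit's subject must exist; no duplicate subject/visit-time).
#' @return validated tibble.
#' @export
read_visits <- function(path, cohort = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("subject_id", "years_from_baseline")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    abort(paste("visits table missing columns:",
                paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(df[c("subject_id", "years_from_baseline")]))
    abort("duplicate (subject_id, years_from_baseline) rows in visits table.")
  if (!is.null(cohort)) {
    orphans <- setdiff(df$subject_id, cohort$subject_id)
    if (length(orphans))
      abort(paste("visits reference unknown subjects:",
                  paste(head(orphans, 5), collapse = ", ")))
  }
  df
}

#' Write a synthetic cohort to disk
#'
#' Writes per-scan time-course TSVs, the cohort CSV, the visits CSV, and a
#' JSON record of the generating conditions (including the seed) alongside.
#'
#' @param sim a `statedyn_cohort` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_data <- function(sim, dir) {
  stopifnot(inherits(sim, "statedyn_cohort"))
  tc_dir <- file.path(dir, "timecourses")
  dir.create(tc_dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(sim$timecourses))
    write_timecourse(sim$timecourses[[id]],
                     file.path(tc_dir, paste0(id, ".tsv")))
  readr::write_csv(sim$cohort, file.path(dir, "cohort.csv"), progress = FALSE)
  readr::write_csv(sim$visits, file.path(dir, "visits.csv"), progress = FALSE)
  jsonlite::write_json(unclass(sim$spec), file.path(dir, "cohort_spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Serialize a fitted HMM to JSON
#'
#' @param model a `statedyn_hmm`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hmm <- function(model, path) {
  obj <- list(K = model$K, C = model$C, init_probs = model$init_probs,
              trans = model$trans, means = model$means, sigma = model$sigma,
              diagnostics = model$diagnostics)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a fitted HMM from JSON
#'
#' @param path file written by [write_hmm()].
#' @return a `statedyn_hmm`.
#' @export
read_hmm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_hmm(obj$init_probs, obj$trans, obj$means, obj$sigma,
          diagnostics = obj$diagnostics)
}
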