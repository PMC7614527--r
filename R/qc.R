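#' Motion quality-control thresholds
#'
#' Upper bounds for the per-scan data-quality indices used to exclude scans
#' before modelling: maximum spike percentage, maximum framewise displacement,
#' maximum DVARS (spatial SD of successive volume differences), and mean
#' framewise displacement. The shipped defaults are placeholders — published
#' threshold values live in the acquisition literature for each cohort and
#' should be supplied per study. Mean-FD filtering is inactive by default and
#' intended for sensitivity re-analyses.
#'
#' @param max_spike_percentage,max_framewise_displacement,max_dvars,mean_framewise_displacement
#'   numeric upper bounds (percent, mm, signal units, mm).
#' @param active character vector naming the indices to enforce.
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(max_spike_percentage = 10,
                          max_framewise_displacement = 3,
                          max_dvars = 5,
                          mean_framewise_displacement = 0.5,
                          active = c("max_spike_percentage",
                                     "max_framewise_displacement",
                                     "max_dvars")) {
  b <- list(max_spike_percentage = max_spike_percentage,
            max_framewise_displacement = max_framewise_displacement,
            max_dvars = max_dvars,
            mean_framewise_displacement = mean_framewise_displacement)
  if (length(active) == 0) abort("at least one QC index must be active.")
  unknown <- setdiff(active, names(b))
  if (length(unknown))
    abort(paste("unknown QC indices:", paste(unknown, collapse = ", ")))
  if (any(unlist(b[active]) <= 0))
    abort("active QC bounds must be positive.")
  structure(c(b, list(active = active)), class = "qc_thresholds")
}

#' Filter scans on motion quality-control indices
#'
#' A scan is excluded if and only if any active index strictly exceeds its
#' bound; scans exactly at a bound are kept. The returned table partitions the
#' input into kept and excluded scans, listing every violated index.
#'
#' @param scans data frame with a `scan_id` column and one column per motion
#'   index named as in [qc_thresholds()].
#' @param thresholds a [qc_thresholds()] object.
#' @return tibble with columns `scan_id`, `qc_pass` (logical) and `reasons`
#'   (comma-separated violated indices, `""` when kept), one row per scan in
#'   input order.
#' @export
filter_scans <- function(scans, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  scans <- as_tibble(scans)
  if (!"scan_id" %in% names(scans)) abort("`scans` needs a `scan_id` column.")
  act <- thresholds$active
  missing_cols <- setdiff(act, names(scans))
  if (length(missing_cols))
    abort(paste("missing motion index columns:",
                paste(missing_cols, collapse = ", ")))
  vals <- as.matrix(scans[act])
  if (any(!is.finite(vals)) || any(vals < 0))
    abort("motion indices must be finite and non-negative.")
  viol <- sweep(vals, 2, unlist(thresholds[act]), `>`)
  reasons <- apply(viol, 1, function(v) paste(act[v], collapse = ","))
  tibble(scan_id = scans$scan_id,
         qc_pass = rowSums(viol) == 0,
         reasons = reasons)
}

#' Select one analysis scan per subject
#'
#' Cross-sectional analyses use each participant's latest scan that passed
#' motion thresholding. Ties on scan time are broken by larger volume count,
#' then lexicographically smallest scan id.
#'
#' @param scans data frame with `subject_id`, `scan_id`, `qc_pass`, a scan
#'   ordering column `scan_time` (any sortable type), and `n_timepoints`.
#' @param which `"latest"` (default, cross-sectional rule) or `"earliest"`
#'   (baseline rule for longitudinal prediction).
#' @return tibble with one row per subject that has any passing scan.
#' @export
select_analysis_scan <- function(scans, which = c("latest", "earliest")) {
  which <- match.arg(which)
  scans <- as_tibble(scans)
  req <- c("subject_id", "scan_id", "qc_pass", "scan_time", "n_timepoints")
  missing_cols <- setdiff(req, names(scans))
  if (length(missing_cols))
    abort(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  sgn <- if (which == "latest") -1 else 1
  scans |>
    dplyr::filter(.data$qc_pass) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::arrange(sgn * xtfrm(.data$scan_time), -.data$n_timepoints,
                   .data$scan_id, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
}
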