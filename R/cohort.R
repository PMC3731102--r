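# Cohort-level aggregation: per-measurement mean/sd tables, per-ratio
# min/max/mean tables, and prevalence percentages.

.cohort_sd <- function(x, estimator) {
  if (length(x) == 1L) return(0)
  if (estimator == "population")
    sqrt(mean((x - mean(x))^2))
  else
    stats::sd(x)
}

#' Summarize a cohort of patient reports
#'
#' Aggregates per-subject analyses into the cohort-level tables: mean and
#' standard deviation of each of the 21 distances, min/max/mean of each
#' facial and mandibular ratio, and the two prevalence percentages
#' (semiangle-symmetric and within the millimetric discrepancy threshold).
#' Subjects whose semiangle test is flagged degenerate are excluded from
#' the angle-based statistics and counted in `excluded`.
#'
#' @param reports a non-empty list of `patient_report` objects.
#' @param config a [ceph_config()]; controls the sd estimator
#'   (sample, n-1 denominator, by default).
#' @return An object of class `cohort_summary`: list with `n_subjects`,
#'   `excluded` (degenerate semiangle count), `measurement_stats`
#'   (data.frame code/mean_mm/sd_mm), `ratio_stats` and
#'   `mandible_ratio_stats` (data.frames with min/max/mean),
#'   `pct_semiangle_symmetric` and `pct_within_threshold` (percent,
#'   unrounded; the print method displays 2 decimals).
#' @examples
#' cohort <- generate_cohort(20, symmetric_fraction = 1, noise_sd = 0,
#'                           seed = 1)
#' summarize_cohort(lapply(cohort$subjects, analyze_patient))
#' @export
summarize_cohort <- function(reports, config = ceph_config()) {
  if (inherits(reports, "patient_report")) reports <- list(reports)
  if (length(reports) == 0L) stop("cannot summarize an empty cohort")
  stopifnot(all(vapply(reports, inherits, logical(1), "patient_report")))
  est <- config$sd_estimator

  mm <- vapply(reports, function(r) r$measurements$values,
               numeric(length(measurement_codes())))
  mm <- matrix(mm, nrow = length(measurement_codes()),
               dimnames = list(measurement_codes(), NULL))
  measurement_stats <- data.frame(
    code = rownames(mm),
    mean_mm = unname(apply(mm, 1, mean)),
    sd_mm = unname(apply(mm, 1, .cohort_sd, estimator = est)),
    row.names = NULL, stringsAsFactors = FALSE)

  fr0 <- reports[[1]]$facial_ratios
  rmat <- vapply(reports, function(r) r$facial_ratios$ratio,
                 numeric(nrow(fr0)))
  rmat <- matrix(rmat, nrow = nrow(fr0))
  ratio_stats <- data.frame(
    numerator = fr0$numerator,
    denominator = fr0$denominator,
    min = unname(apply(rmat, 1, min)),
    max = unname(apply(rmat, 1, max)),
    mean = unname(apply(rmat, 1, mean)),
    stringsAsFactors = FALSE)

  mr <- vapply(reports, function(r) as.numeric(unclass(r$mandible_ratios)),
               numeric(9))
  mr <- matrix(mr, nrow = 9,
               dimnames = list(mandible_ratio_registry()$code, NULL))
  mandible_ratio_stats <- data.frame(
    code = rownames(mr),
    min = unname(apply(mr, 1, min)),
    max = unname(apply(mr, 1, max)),
    mean = unname(apply(mr, 1, mean)),
    row.names = NULL, stringsAsFactors = FALSE)

  degen <- vapply(reports, function(r) r$semiangle$degenerate, logical(1))
  ok <- !degen
  pct_semi <- if (any(ok))
    100 * mean(vapply(reports[ok], function(r) r$semiangle$symmetric,
                      logical(1)))
  else NA_real_
  pct_disc <- 100 * mean(vapply(reports, function(r)
    r$discrepancy$within_threshold, logical(1)))

  structure(list(n_subjects = length(reports),
                 excluded = sum(degen),
                 measurement_stats = measurement_stats,
                 ratio_stats = ratio_stats,
                 mandible_ratio_stats = mandible_ratio_stats,
                 pct_semiangle_symmetric = pct_semi,
                 pct_within_threshold = pct_disc),
            class = "cohort_summary")
}

#' Prevalence of a symmetry criterion in a cohort
#'
#' @param reports non-empty list of `patient_report` objects.
#' @param criterion `"semiangle_4deg"` (semiangle difference within the
#'   report's angular threshold; degenerate subjects excluded) or
#'   `"discrepancy_5mm"` (max left-right discrepancy within the
#'   millimetric threshold).
#' @return Percentage in \[0, 100\]: 100 x (subjects satisfying the
#'   criterion) / (subjects assessed).
#' @export
prevalence <- function(reports,
                       criterion = c("semiangle_4deg", "discrepancy_5mm")) {
  criterion <- match.arg(criterion)
  if (inherits(reports, "patient_report")) reports <- list(reports)
  if (length(reports) == 0L) stop("cannot compute prevalence on an empty cohort")
  if (criterion == "semiangle_4deg") {
    ok <- !vapply(reports, function(r) r$semiangle$degenerate, logical(1))
    if (!any(ok)) stop("all subjects degenerate for the semiangle criterion")
    100 * mean(vapply(reports[ok], function(r) r$semiangle$symmetric,
                      logical(1)))
  } else {
    100 * mean(vapply(reports, function(r) r$discrepancy$within_threshold,
                      logical(1)))
  }
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary> n =", x$n_subjects,
      if (x$excluded > 0) paste0("(", x$excluded, " excluded from angle stats)"),
      "\n")
  cat(sprintf("  semiangle-symmetric: %.2f%%\n", x$pct_semiangle_symmetric))
  cat(sprintf("  within discrepancy threshold: %.2f%%\n",
              x$pct_within_threshold))
  cat("  measurements (first 5 of 21):\n")
  print(transform(utils::head(x$measurement_stats, 5),
                  mean_mm = round(mean_mm, 2), sd_mm = round(sd_mm, 2)))
  invisible(x)
}

#' Write a cohort summary to JSON and CSV tables
#'
#' Emits `cohort_summary.json` plus three CSV tables mirroring the shapes
#' of the per-measurement, facial-ratio and mandibular-ratio summaries.
#'
#' @param summary a `cohort_summary`.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort_summary <- function(summary, dir) {
  stopifnot(inherits(summary, "cohort_summary"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(n_subjects = summary$n_subjects,
         excluded = summary$excluded,
         pct_semiangle_symmetric = summary$pct_semiangle_symmetric,
         pct_within_threshold = summary$pct_within_threshold,
         measurement_stats = summary$measurement_stats,
         ratio_stats = summary$ratio_stats,
         mandible_ratio_stats = summary$mandible_ratio_stats),
    file.path(dir, "cohort_summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(summary$measurement_stats,
                   file.path(dir, "measurement_stats.csv"), row.names = FALSE)
  utils::write.csv(summary$ratio_stats,
                   file.path(dir, "ratio_stats.csv"), row.names = FALSE)
  utils::write.csv(summary$mandible_ratio_stats,
                   file.path(dir, "mandible_ratio_stats.csv"),
                   row.names = FALSE)
  invisible(dir)
}
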