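#' Published accuracy table of a ten-case revision cohort
#'
#' Per-case accuracy analysis of 3D-printed pelvic models for ten revision
#' arthroplasty patients with Paprosky II-IIIA acetabular defects, as printed
#' in the clinical report the toolkit's evaluation defaults emulate: the
#' signed defect-length difference (mm) and percent agreement for the three
#' comparisons (virtual model vs printed model, printed model vs patient,
#' virtual model vs patient). The second comparison column was printed as
#' unsigned magnitudes; [records_from_difference_percent()] reconstructs the
#' signs from the percents.
#'
#' @param as_records Return reconstructed [accuracy_record()] rows (with
#'   back-solved reference/measured lengths) instead of the printed
#'   difference/percent pairs.
#' @return A data.frame.
#' @export
revision_cohort_accuracy <- function(as_records = FALSE) {
  path <- system.file("extdata", "revision_cohort_accuracy.csv", package = "hipplan",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (as_records) records_from_difference_percent(tab) else tab
}

#' Published group means of the ten-case revision cohort
#'
#' Cohort means and standard deviations of the center-of-rotation plane
#' distances (x = sagittal, y = coronal, z = axial, mm) and the radiographic
#' cup angles (degrees) at the three stages: pre-operative (failed cup),
#' 3D-planned, and post-operative.
#'
#' @return A data.frame with columns `stage`, `measure`, `mean`, `sd`, `unit`.
#' @export
revision_cohort_cor_summary <- function() {
  path <- system.file("extdata", "revision_cohort_cor_summary.csv", package = "hipplan",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Absolute planned-vs-achieved differences of stage group means
#'
#' For each measure, the absolute difference between the group means of two
#' stages (by default 3D-planned vs post-operative) — the desk-level
#' agreement summary that can be recomputed from printed group means alone.
#'
#' @param summary_tab Stage summary table, as from
#'   [revision_cohort_cor_summary()].
#' @param from,to Stage labels to compare.
#' @param digits Rounding for reporting (1, matching printed precision).
#' @return Named numeric vector of |mean(to) - mean(from)| per measure.
#' @export
stage_mean_differences <- function(summary_tab = revision_cohort_cor_summary(),
                                   from = "planned", to = "postop", digits = 1) {
  a <- summary_tab[summary_tab$stage == from, ]
  b <- summary_tab[summary_tab$stage == to, ]
  if (nrow(a) == 0L || nrow(b) == 0L) {
    stop(sprintf("stage '%s' or '%s' not present in the summary table", from, to),
         call. = FALSE)
  }
  b <- b[match(a$measure, b$measure), ]
  out <- abs(b$mean - a$mean)
  if (!is.na(digits)) out <- round(out, digits)
  names(out) <- a$measure
  out
}
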