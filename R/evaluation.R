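#' Build one accuracy record
#'
#' One paired caliper/virtual measurement of the acetabular defect length:
#' `difference_mm = measured - reference` and
#' `percent = 100 * measured / reference`. Values are kept at full precision;
#' rounding to 2 decimals happens only at presentation.
#'
#' @param case_id Case identifier.
#' @param defect_label Bone-defect grade label (e.g. Paprosky class).
#' @param comparison One of `"virtual_vs_model"`, `"model_vs_patient"`,
#'   `"virtual_vs_patient"`.
#' @param reference_mm,measured_mm Positive lengths in mm.
#' @return One-row data.frame of class `accuracy_record`.
#' @export
accuracy_record <- function(case_id, defect_label = NA_character_,
                            comparison = c("virtual_vs_model", "model_vs_patient",
                                           "virtual_vs_patient"),
                            reference_mm, measured_mm) {
  comparison <- match.arg(comparison)
  if (!is.finite(reference_mm) || reference_mm <= 0 ||
      !is.finite(measured_mm) || measured_mm <= 0) {
    stop("reference_mm and measured_mm must be positive", call. = FALSE)
  }
  out <- data.frame(case_id = as.character(case_id),
                    defect_label = as.character(defect_label),
                    comparison = comparison,
                    reference_mm = reference_mm,
                    measured_mm = measured_mm,
                    difference_mm = measured_mm - reference_mm,
                    percent = 100 * measured_mm / reference_mm,
                    stringsAsFactors = FALSE)
  class(out) <- c("accuracy_record", "data.frame")
  out
}

#' Accuracy records from printed difference/percent pairs
#'
#' Published accuracy tables often print only the difference and the percent
#' agreement; the underlying reference and measured lengths are recovered as
#' `reference = difference / (percent/100 - 1)`. Some tables print the
#' difference as an unsigned magnitude: whenever the printed difference sign
#' contradicts the percent (positive difference with percent < 100), the sign
#' is reconstructed as negative — the only reading consistent with
#' `sign(difference) = sign(percent - 100)`.
#'
#' @param tab Data.frame with columns `case_id`, `comparison`,
#'   `difference_mm`, `percent` (and optionally `defect_label`).
#' @return Accuracy records data.frame (one row per input row).
#' @export
records_from_difference_percent <- function(tab) {
  required <- c("case_id", "comparison", "difference_mm", "percent")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    d <- tab$difference_mm[i]
    pct <- tab$percent[i]
    if (!is.finite(d) || !is.finite(pct) || pct <= 0 || abs(pct - 100) < 1e-12) {
      stop(sprintf("row %d: cannot recover lengths from difference %.3g, percent %.3g",
                   i, d, pct), call. = FALSE)
    }
    if (sign(d) != sign(pct - 100)) d <- abs(d) * sign(pct - 100)
    ref <- d / (pct / 100 - 1)
    accuracy_record(tab$case_id[i],
                    if ("defect_label" %in% names(tab)) tab$defect_label[i] else NA,
                    tab$comparison[i], ref, ref + d)
  })
  do.call(rbind, rows)
}

#' Summarize accuracy records for one comparison
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of the
#' signed differences (mm) and of the percent agreements.
#'
#' @param records Accuracy records (data.frame from [accuracy_record()] rows).
#' @param comparison Which comparison to summarize; `NULL` summarizes all
#'   rows together.
#' @param digits Rounding applied to the reported summary (2, matching
#'   printed tables); use `NA` for full precision.
#' @return Named list: `n`, `mean_difference_mm`, `sd_difference_mm`,
#'   `mean_percent`, `sd_percent`.
#' @export
summarize_accuracy <- function(records, comparison = NULL, digits = 2) {
  if (!is.null(comparison)) records <- records[records$comparison == comparison, , drop = FALSE]
  if (nrow(records) < 2L) {
    stop("empty or singleton group: need at least 2 records to summarize", call. = FALSE)
  }
  rnd <- function(x) if (is.na(digits)) x else round(x, digits)
  list(n = nrow(records),
       mean_difference_mm = rnd(mean(records$difference_mm)),
       sd_difference_mm = rnd(stats::sd(records$difference_mm)),
       mean_percent = rnd(mean(records$percent)),
       sd_percent = rnd(stats::sd(records$percent)))
}

stat_result <- function(statistic, df = NA_real_, p_value, note = NULL) {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p_value = unname(p_value), note = note),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> statistic %.4f%s, p = %.4g%s\n", x$statistic,
              if (is.na(x$df)) "" else sprintf(" (df = %g)", x$df), x$p_value,
              if (is.null(x$note)) "" else paste0(" [", x$note, "]")))
  invisible(x)
}

#' Two-sided paired t-test
#'
#' `t = mean(d) / (sd(d)/sqrt(n))` on the differences `d = a - b`, with
#' `df = n - 1`. Identical vectors return `t = 0, p = 1`; a constant nonzero
#' difference (zero variance but nonzero mean) is a degenerate test and
#' raises an error.
#'
#' @param a,b Equal-length numeric vectors of paired measurements.
#' @return A `stat_result`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors must have equal length", call. = FALSE)
  if (length(a) < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- a - b
  if (stats::sd(d) < 1e-12 * max(1, abs(mean(d)))) {
    if (max(abs(d)) < 1e-12) return(stat_result(0, df = length(a) - 1, p_value = 1))
    stop("degenerate paired t-test: differences have zero variance", call. = FALSE)
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  stat_result(ht$statistic, df = ht$parameter, p_value = ht$p.value)
}

#' Pearson product-moment correlation
#'
#' Two-sided p-value via the t transform with `df = n - 2`. Perfect
#' correlations (|r| = 1) return `p = 0`.
#'
#' @param a,b Equal-length numeric vectors, n >= 3, both with nonzero
#'   variance.
#' @return A `stat_result` (statistic is r; `df = n - 2`).
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length", call. = FALSE)
  if (length(a) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) {
    stop("degenerate correlation: zero variance", call. = FALSE)
  }
  r <- stats::cor(a, b)
  if (abs(r) >= 1 - 1e-15) return(stat_result(sign(r), df = length(a) - 2, p_value = 0))
  ht <- stats::cor.test(a, b, method = "pearson")
  stat_result(unname(ht$estimate), df = unname(ht$parameter), p_value = ht$p.value)
}

#' One-sample Kolmogorov-Smirnov statistic against a normal distribution
#'
#' `D` is the supremum over the sample of the discrepancy between the
#' empirical CDF (evaluated at both step limits) and the reference normal
#' CDF; the p-value comes from the asymptotic Kolmogorov distribution. The
#' reference mean and sd are taken as supplied; when they were estimated from
#' the same sample the p-value is only approximate (Lilliefors situation) and
#' the result is flagged.
#'
#' @param x Numeric sample, n >= 3.
#' @param mean,sd Parameters of the reference normal distribution.
#' @param estimated Set `TRUE` if `mean`/`sd` were estimated from `x`.
#' @return A `stat_result` (statistic is D).
#' @export
ks_statistic <- function(x, mean = 0, sd = 1, estimated = FALSE) {
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (!is.finite(sd) || sd <= 0) stop("sd must be positive", call. = FALSE)
  if (anyDuplicated(x)) {
    stop("degenerate sample: ties are not supported by the KS statistic", call. = FALSE)
  }
  ht <- suppressWarnings(stats::ks.test(x, "pnorm", mean = mean, sd = sd, exact = FALSE))
  stat_result(unname(ht$statistic), p_value = ht$p.value,
              note = if (estimated) "parameters estimated from sample; p approximate" else NULL)
}

#' Compare planned and achieved cup positions across a cohort
#'
#' For each case the planned and achieved centers of rotation are expressed
#' as signed distances to that case's three reference planes, and the
#' radiographic angles are carried alongside; per measure the report gives
#' the mean difference (achieved - planned), a paired t-test and the Pearson
#' correlation.
#'
#' @param planned List with one element per case: `list(cor = <point or
#'   cor_plan>, inclination = , anteversion = )`.
#' @param achieved Same structure for the post-op measurements.
#' @param frames List of `pelvic_frame` objects, one per case (a single
#'   frame is recycled).
#' @return An object of class `comparison_report`: a per-measure data.frame
#'   `summary` plus the per-case value matrices.
#' @export
compare_plan_vs_postop <- function(planned, achieved, frames) {
  n <- length(planned)
  if (length(achieved) != n) {
    stop(sprintf("pairing error: %d planned vs %d achieved cases", n, length(achieved)),
         call. = FALSE)
  }
  if (inherits(frames, "pelvic_frame")) frames <- rep(list(frames), n)
  if (length(frames) != n) stop("pairing error: need one frame per case", call. = FALSE)

  extract <- function(entry, frame) {
    cor <- if (inherits(entry$cor, "cor_plan")) entry$cor$planned_cor else vec3(entry$cor)
    d <- cor_distances(frame, cor)
    c(x = unname(d[["d_sagittal"]]), y = unname(d[["d_coronal"]]),
      z = unname(d[["d_axial"]]),
      inclination = entry$inclination, anteversion = entry$anteversion)
  }
  pl <- t(vapply(seq_len(n), function(i) extract(planned[[i]], frames[[i]]), numeric(5L)))
  ac <- t(vapply(seq_len(n), function(i) extract(achieved[[i]], frames[[i]]), numeric(5L)))

  measures <- colnames(pl)
  rows <- lapply(measures, function(m) {
    # a constant nonzero offset is a legitimate cohort effect: report the mean
    # difference with an undefined t rather than failing the whole report
    tt <- tryCatch(paired_t(ac[, m], pl[, m]),
                   error = function(e) stat_result(NA_real_, NA_real_, NA_real_))
    rr <- if (n >= 3L && stats::sd(ac[, m]) > 1e-12 && stats::sd(pl[, m]) > 1e-12) {
      pearson_r(ac[, m], pl[, m])
    } else NULL
    data.frame(measure = m,
               mean_planned = mean(pl[, m]), mean_achieved = mean(ac[, m]),
               mean_difference = mean(ac[, m] - pl[, m]),
               t = tt$statistic, t_df = tt$df, t_p = tt$p_value,
               r = if (is.null(rr)) NA_real_ else rr$statistic,
               r_p = if (is.null(rr)) NA_real_ else rr$p_value,
               stringsAsFactors = FALSE)
  })
  structure(list(summary = do.call(rbind, rows), planned = pl, achieved = ac),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %d case(s)\n", nrow(x$planned)))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-12s planned %7.2f  achieved %7.2f  diff %7.2f  t %7.3f (p %.4f)%s\n",
                s$measure[i], s$mean_planned[i], s$mean_achieved[i], s$mean_difference[i],
                s$t[i], s$t_p[i],
                if (is.na(s$r[i])) "" else sprintf("  r %6.3f (p %.4f)", s$r[i], s$r_p[i])))
  }
  invisible(x)
}

#' Compare planned and achieved measure tables column by column
#'
#' Spreadsheet-style cohort comparison: for every numeric measure column
#' present in both tables (rows matched by `case_id` when present, otherwise
#' by order), reports the means, the mean difference (achieved - planned), a
#' paired t-test and, when defined, the Pearson correlation.
#'
#' @param planned,achieved Data.frames with a `case_id` column plus numeric
#'   measure columns.
#' @return Data.frame with one row per measure.
#' @export
compare_measure_tables <- function(planned, achieved) {
  if (nrow(planned) != nrow(achieved)) {
    stop(sprintf("pairing error: %d planned vs %d achieved rows",
                 nrow(planned), nrow(achieved)), call. = FALSE)
  }
  if ("case_id" %in% names(planned) && "case_id" %in% names(achieved)) {
    idx <- match(planned$case_id, achieved$case_id)
    if (anyNA(idx)) stop("pairing error: case_id sets differ", call. = FALSE)
    achieved <- achieved[idx, , drop = FALSE]
  }
  measures <- intersect(names(planned), names(achieved))
  measures <- measures[vapply(planned[measures], is.numeric, logical(1L)) &
                         vapply(achieved[measures], is.numeric, logical(1L))]
  if (length(measures) == 0L) stop("no shared numeric measure columns", call. = FALSE)
  rows <- lapply(measures, function(m) {
    a <- achieved[[m]]
    p <- planned[[m]]
    tt <- tryCatch(paired_t(a, p),
                   error = function(e) stat_result(NA_real_, NA_real_, NA_real_))
    rr <- if (length(a) >= 3L && stats::sd(a) > 1e-12 && stats::sd(p) > 1e-12) {
      pearson_r(a, p)
    } else NULL
    data.frame(measure = m, mean_planned = mean(p), mean_achieved = mean(a),
               mean_difference = mean(a - p),
               t = tt$statistic, t_df = tt$df, t_p = tt$p_value,
               r = if (is.null(rr)) NA_real_ else rr$statistic,
               r_p = if (is.null(rr)) NA_real_ else rr$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Classic 2D center-of-rotation estimate (Ranawat construction)
#'
#' On an AP pelvic radiograph: starting 5 mm lateral to the intersection of
#' the Koehler and Shenton lines, draw a right-angled isosceles triangle
#' whose legs (one lateral, one superior) are one fifth of the pelvic height;
#' the COR sits at the midpoint of the hypotenuse, i.e. at
#' `start + (H/10) * (lateral + superior)`.
#'
#' @param pelvic_height Pelvic height H on the radiograph, mm.
#' @param kohler_shenton_intersection 2D point (mm) where the two reference
#'   lines cross.
#' @param lateral_offset Lateral start offset from the intersection, mm
#'   (default 5).
#' @param lateral_direction,superior_direction 2D unit vectors of the image
#'   axes.
#' @return 2D point (mm): the estimated center of rotation.
#' @export
ranawat_cor_2d <- function(pelvic_height, kohler_shenton_intersection,
                           lateral_offset = 5,
                           lateral_direction = c(1, 0), superior_direction = c(0, 1)) {
  if (!is.finite(pelvic_height) || pelvic_height <= 0) {
    stop("pelvic_height must be positive", call. = FALSE)
  }
  p0 <- as.numeric(kohler_shenton_intersection)
  lat <- as.numeric(lateral_direction)
  sup <- as.numeric(superior_direction)
  if (length(p0) != 2L || length(lat) != 2L || length(sup) != 2L) {
    stop("2D construction: all points/directions must have length 2", call. = FALSE)
  }
  lat <- lat / sqrt(sum(lat^2))
  sup <- sup / sqrt(sum(sup^2))
  start <- p0 + lateral_offset * lat
  start + (pelvic_height / 10) * (lat + sup)
}
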