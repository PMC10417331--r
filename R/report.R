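#' Assemble a plan report
#'
#' Flat, auditable record of one planning run: everything needed to
#' reproduce it (input file digests, settings, seed) plus the frame, COR plan
#' and cup pose results.
#'
#' @param case_id Case identifier.
#' @param cor_plan A `cor_plan`.
#' @param pose A `cup_pose` (optional).
#' @param screws List of `screw_plan` objects (optional).
#' @param inputs Named character vector of input file paths (digested with
#'   md5 into the report).
#' @param seed Seed used for any randomness (NA when none).
#' @return An object of class `plan_report` (a named list of sections).
#' @export
plan_report <- function(case_id, cor_plan, pose = NULL, screws = list(),
                        inputs = character(0L), seed = NA_integer_) {
  stopifnot(inherits(cor_plan, "cor_plan"))
  frame <- cor_plan$frame
  rep <- list(
    meta = list(case_id = case_id,
                tool = paste("hipplan", as.character(utils::packageVersion("hipplan"))),
                created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                seed = seed),
    inputs = c(as.list(inputs),
               if (length(inputs)) as.list(stats::setNames(
                 unname(tools::md5sum(inputs)), paste0(names(inputs), "_md5")))),
    frame = list(x_axis = frame$x_axis, y_axis = frame$y_axis, z_axis = frame$z_axis,
                 sagittal_point = frame$sagittal$point, axial_point = frame$axial$point,
                 coronal_point = frame$coronal$point,
                 quality_tilt_deg = unname(frame$quality)),
    cor = list(intact_cor = cor_plan$intact_cor, planned_cor = cor_plan$planned_cor,
               head_radius = cor_plan$head_radius, side = cor_plan$side,
               distances_intact = unname(cor_plan$distances_intact),
               distances_planned = unname(cor_plan$distances_planned))
  )
  if (!is.null(pose)) {
    rep$cup <- list(center = pose$center, diameter = pose$diameter,
                    inclination = pose$inclination, anteversion = pose$anteversion,
                    axis = pose$axis, side = pose$side, convention = pose$convention)
  }
  if (length(screws)) {
    for (i in seq_along(screws)) {
      rep[[sprintf("screw_%d", i)]] <- list(entry = screws[[i]]$entry,
                                            direction = screws[[i]]$direction,
                                            length = screws[[i]]$length)
    }
  }
  structure(rep, class = "plan_report")
}

#' Write a plan report as structured key-value text
#'
#' One `section.key: value` line per field; numeric vectors are
#' space-separated at full precision.
#'
#' @param report A `plan_report`.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_plan_report <- function(report, path) {
  stopifnot(inherits(report, "plan_report"))
  lines <- character(0L)
  for (section in names(report)) {
    for (key in names(report[[section]])) {
      val <- report[[section]][[key]]
      val_str <- if (is.numeric(val)) paste(sprintf("%.12g", val), collapse = " ")
      else paste(as.character(val), collapse = " ")
      lines <- c(lines, sprintf("%s.%s: %s", section, key, val_str))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a plan report written by [write_plan_report()]
#'
#' @param path Report path.
#' @return A `plan_report`-shaped named list (numeric fields re-parsed).
#' @export
read_plan_report <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^.]+)\\.([^:]+):\\s*(.*)$", ln))[[1L]]
    if (length(m) != 4L) stop(sprintf("malformed report line: '%s'", ln), call. = FALSE)
    toks <- strsplit(m[4L], "\\s+")[[1L]]
    nums <- suppressWarnings(as.numeric(toks))
    val <- if (length(toks) > 0L && !anyNA(nums)) nums else m[4L]
    out[[m[2L]]][[m[3L]]] <- val
  }
  structure(out, class = "plan_report")
}

#' @export
print.plan_report <- function(x, ...) {
  cat(sprintf("<plan_report> case '%s'\n", x$meta$case_id))
  cat(sprintf("  planned COR: (%.2f, %.2f, %.2f) mm\n",
              x$cor$planned_cor[1], x$cor$planned_cor[2], x$cor$planned_cor[3]))
  if (!is.null(x$cup)) {
    cat(sprintf("  cup: %g mm, RI %.1f deg / RA %.1f deg\n",
                x$cup$diameter, x$cup$inclination, x$cup$anteversion))
  }
  invisible(x)
}
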