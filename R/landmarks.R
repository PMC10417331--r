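#' Canonical pelvic landmark names
#'
#' The six bony landmarks required to construct the pelvic reference frame:
#' the center of the pubic symphysis, the center of the sacrum, and the tips
#' of the left/right ischial tuberosities and ischial spines.
#'
#' @return Character vector of the six canonical landmark names.
#' @export
canonical_landmarks <- function() {
  c("pubic_symphysis_center", "sacrum_center",
    "ischial_tuberosity_L", "ischial_tuberosity_R",
    "ischial_spine_L", "ischial_spine_R")
}

#' Landmark name alias table
#'
#' Clinical landmark naming varies between operators and segmentation
#' software; incoming labels are matched case-insensitively against this
#' table (shipped as a CSV data file, so sites can inspect and extend it)
#' before falling back to free-form "extra" status.
#'
#' @return A data.frame with columns `canonical` and `alias`.
#' @export
landmark_aliases <- function() {
  path <- system.file("extdata", "landmark_aliases.csv", package = "hipplan",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

normalize_landmark_name <- function(label) {
  key <- tolower(gsub("[ .-]+", "_", trimws(label)))
  tab <- landmark_alias_cache()
  hit <- match(key, tab$alias)
  if (!is.na(hit)) tab$canonical[hit] else key
}

# alias lookup is on the hot path for file reading; cache per session
landmark_alias_env <- new.env(parent = emptyenv())
landmark_alias_cache <- function() {
  if (is.null(landmark_alias_env$tab)) {
    tab <- landmark_aliases()
    tab$alias <- tolower(gsub("[ .-]+", "_", trimws(tab$alias)))
    landmark_alias_env$tab <- tab
  }
  landmark_alias_env$tab
}

#' Construct a landmark set
#'
#' Container for named anatomical landmark coordinates, an optional femoral
#' head surface point cloud, and the side of the intact (non-revision) hip.
#' Coordinates are stored internally in RAS millimetres (x toward patient
#' right, y anterior, z superior); LPS input is converted at this boundary by
#' negating the first two coordinates.
#'
#' @param landmarks Named list of length-3 coordinates, or an n x 3 matrix
#'   with landmark names as rownames.
#' @param case_id Case identifier string.
#' @param coordinate_system `"RAS"` or `"LPS"`; the convention the supplied
#'   coordinates are expressed in.
#' @param head_points Optional point cloud (n x 3 matrix or list of points)
#'   sampled on the intact femoral head surface.
#' @param intact_side `"left"` or `"right"`: side of the intact hip.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(landmarks, case_id = "case", coordinate_system = c("RAS", "LPS"),
                         head_points = NULL, intact_side = c("left", "right")) {
  coordinate_system <- match.arg(coordinate_system)
  intact_side <- match.arg(intact_side)
  m <- as_points_matrix(landmarks)
  nm <- rownames(m) %||% names(landmarks)
  if (is.null(nm) || anyNA(nm) || any(nm == "")) {
    stop("every landmark must be named", call. = FALSE)
  }
  nm <- vapply(nm, normalize_landmark_name, character(1L), USE.NAMES = FALSE)
  if (anyDuplicated(nm)) {
    stop("duplicate landmark names after alias normalization: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  rownames(m) <- nm
  if (coordinate_system == "LPS") m <- lps_to_ras(m)
  if (!is.null(head_points)) {
    head_points <- as_points_matrix(head_points)
    if (coordinate_system == "LPS") head_points <- lps_to_ras(head_points)
  }
  for (side_pair in list(c("ischial_tuberosity_L", "ischial_tuberosity_R"),
                         c("ischial_spine_L", "ischial_spine_R"))) {
    if (all(side_pair %in% nm) &&
        vnorm(m[side_pair[1L], ] - m[side_pair[2L], ]) < 1e-9) {
      stop(sprintf("left/right pair %s / %s coincide", side_pair[1L], side_pair[2L]),
           call. = FALSE)
    }
  }
  structure(list(case_id = as.character(case_id),
                 coordinate_system = "RAS",
                 landmarks = m,
                 head_points = head_points,
                 intact_side = intact_side),
            class = "landmark_set")
}

#' Convert between LPS and RAS coordinates
#'
#' The conversion negates the first two coordinates and is its own inverse.
#'
#' @param points Length-3 vector or n x 3 matrix of coordinates.
#' @return Coordinates of the same shape in the other convention.
#' @export
lps_to_ras <- function(points) {
  if (is.matrix(points)) {
    points[, 1L] <- -points[, 1L]
    points[, 2L] <- -points[, 2L]
    points
  } else {
    p <- vec3(points)
    c(-p[1L], -p[2L], p[3L])
  }
}

#' @rdname lps_to_ras
#' @export
ras_to_lps <- lps_to_ras

#' Check that a landmark set carries the six canonical landmarks
#'
#' @param x A `landmark_set`.
#' @return Invisibly `x`; errors listing any absent canonical landmark.
#' @export
assert_canonical <- function(x) {
  stopifnot(inherits(x, "landmark_set"))
  missing <- setdiff(canonical_landmarks(), rownames(x$landmarks))
  if (length(missing) > 0L) {
    stop("missing canonical landmark(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(x)
}

#' Extract one landmark coordinate
#'
#' @param x A `landmark_set`.
#' @param name Landmark name (canonical or alias).
#' @return Length-3 RAS coordinate in mm.
#' @export
landmark <- function(x, name) {
  stopifnot(inherits(x, "landmark_set"))
  nm <- normalize_landmark_name(name)
  if (!nm %in% rownames(x$landmarks)) {
    stop(sprintf("landmark '%s' not present", nm), call. = FALSE)
  }
  unname(x$landmarks[nm, ])
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> case '%s' (%s, intact side: %s)\n",
              x$case_id, x$coordinate_system, x$intact_side))
  canon <- intersect(canonical_landmarks(), rownames(x$landmarks))
  extras <- setdiff(rownames(x$landmarks), canon)
  cat(sprintf("  %d canonical landmark(s), %d extra(s), %s head point(s)\n",
              length(canon), length(extras),
              if (is.null(x$head_points)) "no" else nrow(x$head_points)))
  invisible(x)
}
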