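#' Construct a plane
#'
#' A plane is stored as a unit normal plus one point on the plane; the signed
#' distance of a point `p` is `normal . (p - point)`.
#'
#' @param normal Plane normal (normalized internally).
#' @param point Any point on the plane, mm.
#' @return An object of class `plane`.
#' @export
plane <- function(normal, point) {
  structure(list(normal = unitize(vec3(normal), "plane normal"),
                 point = vec3(point)),
            class = "plane")
}

#' Signed point-plane distance
#'
#' @param plane A `plane`.
#' @param p Point, mm.
#' @return Signed perpendicular distance in mm; the sign follows the normal.
#' @export
signed_distance <- function(plane, p) {
  stopifnot(inherits(plane, "plane"))
  sum(plane$normal * (vec3(p) - plane$point))
}

#' Reflect a point across a plane
#'
#' Mirror image `p' = p - 2 d n` where `d` is the signed distance and `n` the
#' unit normal. Reflection is an involution and an isometry; the signed
#' distance of the image is the negative of the original.
#'
#' @param plane A `plane` (the mirror).
#' @param p Point or n x 3 matrix of points, mm.
#' @return Reflected point(s), same shape as `p`.
#' @export
reflect_across <- function(plane, p) {
  stopifnot(inherits(plane, "plane"))
  if (is.matrix(p)) {
    d <- as.numeric((p - matrix(plane$point, nrow(p), 3L, byrow = TRUE)) %*% plane$normal)
    p - 2 * outer(d, plane$normal)
  } else {
    p <- vec3(p)
    p - 2 * signed_distance(plane, p) * plane$normal
  }
}

#' Build the pelvic reference frame from six canonical landmarks
#'
#' Three anatomical reference planes anchor the construction: the sagittal
#' plane passes through the center of the pubic symphysis and the center of
#' the sacrum; the axial plane lies between the tips of the ischial
#' tuberosities; the coronal plane between the tips of the ischial spines.
#' Two landmarks underdetermine a plane, so the frame is completed by
#' Gram-Schmidt orthogonalization in the order sagittal, axial, coronal:
#'
#' 1. `m = unit(sacrum_center - pubic_symphysis_center)` (midline direction,
#'    contained in the sagittal plane by construction);
#' 2. `x_axis = unit(l - (l.m) m)` with `l` the left-to-right tuberosity
#'    chord: the sagittal normal, orthogonal to the midline, so the sagittal
#'    plane contains both midline landmarks exactly;
#' 3. `z_axis = unit(u - (u.x) x)` with `u` pointing from the tuberosity
#'    midpoint up to the spine midpoint: the axial normal;
#' 4. `y_axis = z_axis x x_axis` (anterior), giving a right-handed RAS triad.
#'
#' The axial and coronal planes then contain their landmark pairs only
#' approximately; the residual tilt of each defining chord out of its plane is
#' reported (degrees) as a quality diagnostic and a warning is raised above 5
#' degrees.
#'
#' @param landmarks A `landmark_set` carrying the six canonical landmarks.
#' @return An object of class `pelvic_frame` with unit axes `x_axis` (patient
#'   right), `y_axis` (anterior), `z_axis` (superior), planes `sagittal`,
#'   `axial`, `coronal`, per-plane `quality` tilts in degrees, and `origin`
#'   (the pubic symphysis center, used for reporting).
#' @export
build_pelvic_frame <- function(landmarks) {
  assert_canonical(landmarks)
  ps <- landmark(landmarks, "pubic_symphysis_center")
  sc <- landmark(landmarks, "sacrum_center")
  tl <- landmark(landmarks, "ischial_tuberosity_L")
  tr <- landmark(landmarks, "ischial_tuberosity_R")
  sl <- landmark(landmarks, "ischial_spine_L")
  sr <- landmark(landmarks, "ischial_spine_R")

  if (vnorm(sc - ps) < 1e-9) {
    stop("degenerate frame: pubic symphysis and sacrum centers coincide", call. = FALSE)
  }
  m_hat <- unitize(sc - ps, "midline direction")
  l <- tr - tl
  if (vnorm(l) < 1e-9) {
    stop("degenerate frame: ischial tuberosity tips coincide", call. = FALSE)
  }
  x_raw <- l - sum(l * m_hat) * m_hat
  if (vnorm(x_raw) < 1e-9 * vnorm(l)) {
    stop("degenerate frame: tuberosity chord is collinear with the midline", call. = FALSE)
  }
  x_axis <- unitize(x_raw, "lateral axis")

  u <- (sl + sr) / 2 - (tl + tr) / 2
  z_raw <- u - sum(u * x_axis) * x_axis
  if (vnorm(u) < 1e-9 || vnorm(z_raw) < 1e-9 * max(1, vnorm(u))) {
    stop("degenerate frame: spine-tuberosity direction is collinear with the lateral axis",
         call. = FALSE)
  }
  z_axis <- unitize(z_raw, "superior axis")
  y_axis <- cross3(z_axis, x_axis)

  sagittal <- plane(x_axis, ps)
  axial <- plane(z_axis, (tl + tr) / 2)
  coronal <- plane(y_axis, (sl + sr) / 2)

  # tilt of each defining chord out of its plane (0 deg = chord in plane)
  quality <- c(
    sagittal = rad2deg(asin(min(1, abs(sum(m_hat * x_axis))))),
    axial = rad2deg(asin(min(1, abs(sum(unitize(l, "tuberosity chord") * z_axis))))),
    coronal = rad2deg(asin(min(1, abs(sum(unitize(sr - sl, "spine chord") * y_axis)))))
  )
  if (any(quality > 5)) {
    warning(sprintf("pelvic frame quality: residual plane tilt above 5 degrees (%s)",
                    paste(sprintf("%s %.2f", names(quality)[quality > 5],
                                  quality[quality > 5]), collapse = ", ")),
            call. = FALSE)
  }

  structure(list(x_axis = x_axis, y_axis = y_axis, z_axis = z_axis,
                 sagittal = sagittal, axial = axial, coronal = coronal,
                 quality = quality, origin = ps),
            class = "pelvic_frame")
}

#' @export
print.pelvic_frame <- function(x, ...) {
  cat("<pelvic_frame>\n")
  cat(sprintf("  x (lateral) : % .4f % .4f % .4f\n", x$x_axis[1], x$x_axis[2], x$x_axis[3]))
  cat(sprintf("  y (anterior): % .4f % .4f % .4f\n", x$y_axis[1], x$y_axis[2], x$y_axis[3]))
  cat(sprintf("  z (superior): % .4f % .4f % .4f\n", x$z_axis[1], x$z_axis[2], x$z_axis[3]))
  cat(sprintf("  quality tilt (deg): sagittal %.3f, axial %.3f, coronal %.3f\n",
              x$quality[["sagittal"]], x$quality[["axial"]], x$quality[["coronal"]]))
  invisible(x)
}
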