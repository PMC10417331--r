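#' Cup opening axis from radiographic inclination and anteversion
#'
#' Uses the radiographic convention: anteversion (RA) is the angle between
#' the cup opening axis and the coronal plane; inclination (RI) is the angle
#' between the axis's projection onto the coronal plane and the inferior
#' direction. With `lat` the lateral unit vector of the operated side
#' (`+x_axis` for a right hip, `-x_axis` for a left hip):
#'
#' `axis = sin(RI) cos(RA) lat + sin(RA) y_axis - cos(RI) cos(RA) z_axis`
#'
#' Angles outside the customary planning windows of 30-45 degrees
#' (inclination) and 10-20 degrees (anteversion) trigger a planning warning,
#' not an error.
#'
#' @param frame A `pelvic_frame`.
#' @param inclination Radiographic inclination in degrees, in `[0, 90)`.
#' @param anteversion Radiographic anteversion in degrees, in `(-90, 90)`.
#' @param side `"left"` or `"right"`: the operated hip.
#' @return Unit length-3 vector (cup opening direction) in world coordinates.
#' @export
axis_from_angles <- function(frame, inclination, anteversion, side = c("right", "left")) {
  stopifnot(inherits(frame, "pelvic_frame"))
  side <- match.arg(side)
  if (!is.finite(inclination) || inclination < 0 || inclination >= 90) {
    stop("inclination must lie in [0, 90) degrees", call. = FALSE)
  }
  if (!is.finite(anteversion) || anteversion <= -90 || anteversion >= 90) {
    stop("anteversion must lie in (-90, 90) degrees", call. = FALSE)
  }
  if (inclination < 30 || inclination > 45) {
    warning(sprintf("inclination %.1f deg outside the 30-45 deg planning range", inclination),
            call. = FALSE)
  }
  if (anteversion < 10 || anteversion > 20) {
    warning(sprintf("anteversion %.1f deg outside the 10-20 deg planning range", anteversion),
            call. = FALSE)
  }
  lat <- if (side == "right") frame$x_axis else -frame$x_axis
  ri <- deg2rad(inclination)
  ra <- deg2rad(anteversion)
  sin(ri) * cos(ra) * lat + sin(ra) * frame$y_axis - cos(ri) * cos(ra) * frame$z_axis
}

#' Radiographic angles from a cup opening axis
#'
#' Exact inverse of [axis_from_angles()]: `RA = asin(axis . y_axis)` and
#' `RI = atan2(axis . lat, -axis . z_axis)`. When the axis is parallel to the
#' anterior axis the coronal-plane projection vanishes and inclination is
#' indeterminate; anteversion of +/-90 degrees is returned with
#' `inclination_indeterminate = TRUE`.
#'
#' @param frame A `pelvic_frame`.
#' @param axis Unit cup opening axis.
#' @param side `"left"` or `"right"`.
#' @return Named list with `inclination`, `anteversion` (degrees) and the
#'   `inclination_indeterminate` flag.
#' @export
angles_from_axis <- function(frame, axis, side = c("right", "left")) {
  stopifnot(inherits(frame, "pelvic_frame"))
  side <- match.arg(side)
  axis <- vec3(axis)
  if (abs(vnorm(axis) - 1) > 1e-6) {
    stop("axis must be a unit vector", call. = FALSE)
  }
  lat <- if (side == "right") frame$x_axis else -frame$x_axis
  ay <- max(-1, min(1, sum(axis * frame$y_axis)))
  proj <- c(sum(axis * lat), -sum(axis * frame$z_axis))
  indeterminate <- sqrt(sum(proj^2)) < 1e-9
  list(inclination = if (indeterminate) NA_real_ else rad2deg(atan2(proj[1L], proj[2L])),
       anteversion = rad2deg(asin(ay)),
       inclination_indeterminate = indeterminate)
}

#' Acetabular cup size catalog
#'
#' The planning catalog of hemispherical revision shells: outer diameters
#' from 50 to 64 mm in 2 mm increments.
#'
#' @return Numeric vector of cup outer diameters in mm.
#' @export
cup_catalog <- function() {
  seq(50, 64, by = 2)
}

#' Construct a cup pose
#'
#' Binds a center of rotation, cup diameter and radiographic angles into a
#' pose; the opening axis is derived from the angles so the two
#' parameterizations stay mutually consistent.
#'
#' @param frame A `pelvic_frame`.
#' @param center Cup center (the planned COR), mm.
#' @param diameter Cup outer diameter, mm (catalog membership is checked; use
#'   `allow_noncatalog = TRUE` to override).
#' @param inclination,anteversion Radiographic angles, degrees.
#' @param side `"left"` or `"right"`.
#' @param allow_noncatalog Allow a diameter outside [cup_catalog()].
#' @return An object of class `cup_pose`.
#' @export
cup_pose <- function(frame, center, diameter, inclination, anteversion,
                     side = c("right", "left"), allow_noncatalog = FALSE) {
  side <- match.arg(side)
  if (!allow_noncatalog && !diameter %in% cup_catalog()) {
    stop(sprintf("cup diameter %g mm not in catalog (%s mm)", diameter,
                 paste(cup_catalog(), collapse = ", ")), call. = FALSE)
  }
  if (diameter <= 0) stop("cup diameter must be positive", call. = FALSE)
  axis <- axis_from_angles(frame, inclination, anteversion, side)
  structure(list(center = vec3(center), diameter = diameter,
                 inclination = inclination, anteversion = anteversion,
                 axis = axis, side = side, convention = "radiographic"),
            class = "cup_pose")
}

#' @export
print.cup_pose <- function(x, ...) {
  cat(sprintf("<cup_pose> %g mm %s cup at (%.2f, %.2f, %.2f), RI %.1f deg / RA %.1f deg (%s)\n",
              x$diameter, x$side, x$center[1], x$center[2], x$center[3],
              x$inclination, x$anteversion, x$convention))
  invisible(x)
}

#' Generate a hemispherical cup shell mesh
#'
#' Canonical pose: opening axis +z, rim circle in the z = 0 plane, center of
#' rotation at the origin, dome extending toward -z. The shell has an outer
#' hemisphere at radius `diameter/2`, an inner hemisphere offset inward by
#' `shell_thickness`, and a flat annular rim joining them, built on a
#' latitude/longitude grid at the requested angular resolution.
#'
#' @param diameter Outer diameter, mm; must be in [cup_catalog()] unless
#'   `allow_noncatalog = TRUE`.
#' @param shell_thickness Wall thickness, mm.
#' @param angular_resolution Grid step in degrees (smaller = finer mesh).
#' @param allow_noncatalog Allow a non-catalog diameter.
#' @return A `surface_mesh` whose `regions` attribute indexes the `outer`,
#'   `inner` and `rim` triangle ranges.
#' @export
generate_cup_mesh <- function(diameter, shell_thickness = 3, angular_resolution = 5,
                              allow_noncatalog = FALSE) {
  if (!allow_noncatalog && !diameter %in% cup_catalog()) {
    stop(sprintf("cup diameter %g mm not in catalog (%s mm)", diameter,
                 paste(cup_catalog(), collapse = ", ")), call. = FALSE)
  }
  if (diameter <= 0 || shell_thickness <= 0 || angular_resolution <= 0) {
    stop("diameter, shell_thickness and angular_resolution must be positive", call. = FALSE)
  }
  r_out <- diameter / 2
  r_in <- max(r_out - shell_thickness, r_out * 0.25)
  n_az <- max(8L, as.integer(round(360 / angular_resolution)))
  n_pol <- max(2L, as.integer(round(90 / angular_resolution)))

  hemisphere <- function(radius, flip) {
    # polar angle theta from the -z pole (0) up to the rim (pi/2)
    verts <- matrix(0, 0L, 3L)
    ring_start <- integer(0L)
    for (i in seq_len(n_pol)) {
      th <- pi / 2 * i / n_pol
      az <- 2 * pi * (seq_len(n_az) - 1L) / n_az
      ring <- cbind(radius * sin(th) * cos(az), radius * sin(th) * sin(az),
                    -radius * cos(th))
      ring_start <- c(ring_start, nrow(verts) + 1L)
      verts <- rbind(verts, ring)
    }
    pole <- nrow(verts) + 1L
    verts <- rbind(verts, c(0, 0, -radius))
    tris <- matrix(0L, 0L, 3L)
    for (i in seq_len(n_pol - 1L)) {
      a <- ring_start[i] + (seq_len(n_az) - 1L)
      b <- ring_start[i] + (seq_len(n_az) %% n_az)
      c_ <- ring_start[i + 1L] + (seq_len(n_az) - 1L)
      d <- ring_start[i + 1L] + (seq_len(n_az) %% n_az)
      tris <- rbind(tris, cbind(a, b, c_), cbind(b, d, c_))
    }
    a <- ring_start[1L] + (seq_len(n_az) - 1L)
    b <- ring_start[1L] + (seq_len(n_az) %% n_az)
    tris <- rbind(tris, cbind(a, pole, b))
    if (flip) tris <- tris[, c(1L, 3L, 2L), drop = FALSE]
    list(verts = verts, tris = tris, rim = ring_start[n_pol] + (seq_len(n_az) - 1L))
  }

  outer <- hemisphere(r_out, flip = FALSE)
  inner <- hemisphere(r_in, flip = TRUE)
  off <- nrow(outer$verts)
  verts <- rbind(outer$verts, inner$verts)
  tris <- rbind(outer$tris, inner$tris + off)
  n_outer <- nrow(outer$tris)
  n_inner <- nrow(inner$tris)
  # annular rim in z = 0 joining the two rim circles
  a <- outer$rim
  b <- outer$rim[c(2:n_az, 1L)]
  c_ <- inner$rim + off
  d <- (inner$rim + off)[c(2:n_az, 1L)]
  rim_tris <- rbind(cbind(a, c_, b), cbind(b, c_, d))
  tris <- rbind(tris, rim_tris)

  mesh <- surface_mesh(verts, tris)
  attr(mesh, "regions") <- list(outer = seq_len(n_outer),
                                inner = n_outer + seq_len(n_inner),
                                rim = n_outer + n_inner + seq_len(nrow(rim_tris)))
  attr(mesh, "rim_vertices") <- c(outer$rim, inner$rim + off)
  mesh
}

# minimal rotation carrying unit vector a onto unit vector b (Rodrigues)
rotation_between <- function(a, b) {
  a <- unitize(vec3(a), "rotation source")
  b <- unitize(vec3(b), "rotation target")
  v <- cross3(a, b)
  c_ <- sum(a * b)
  if (vnorm(v) < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate pi about any axis orthogonal to a
    axis <- if (abs(a[1L]) < 0.9) cross3(a, c(1, 0, 0)) else cross3(a, c(0, 1, 0))
    axis <- unitize(axis, "flip axis")
    return(2 * outer(axis, axis) - diag(3))
  }
  vx <- matrix(c(0, v[3L], -v[2L], -v[3L], 0, v[1L], v[2L], -v[1L], 0), 3L, 3L)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

#' Place a canonical cup mesh at a pose
#'
#' Applies the rigid transform carrying the canonical opening axis (+z) onto
#' `pose$axis` and the origin onto `pose$center`. Pairwise vertex distances
#' are preserved (rigid motion) and the transformed rim plane normal equals
#' the pose axis.
#'
#' @param mesh Canonical cup `surface_mesh` from [generate_cup_mesh()].
#' @param pose A `cup_pose`.
#' @return The transformed `surface_mesh` (region attributes preserved).
#' @export
place_cup <- function(mesh, pose) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(pose, "cup_pose"))
  rot <- rotation_between(c(0, 0, 1), pose$axis)
  verts <- mesh$vertices %*% t(rot)
  verts <- sweep(verts, 2L, pose$center, `+`)
  out <- surface_mesh(verts, mesh$triangles)
  attr(out, "regions") <- attr(mesh, "regions")
  attr(out, "rim_vertices") <- attr(mesh, "rim_vertices")
  out
}

# Moller-Trumbore ray/triangle intersection parameters for every triangle;
# returns sorted nonnegative ray parameters t of the hits
ray_mesh_hits <- function(entry, direction, mesh, eps = 1e-9) {
  v0 <- mesh$vertices[mesh$triangles[, 1L], , drop = FALSE]
  v1 <- mesh$vertices[mesh$triangles[, 2L], , drop = FALSE]
  v2 <- mesh$vertices[mesh$triangles[, 3L], , drop = FALSE]
  e1 <- v1 - v0
  e2 <- v2 - v0
  d <- matrix(direction, nrow(v0), 3L, byrow = TRUE)
  pvec <- cbind(d[, 2L] * e2[, 3L] - d[, 3L] * e2[, 2L],
                d[, 3L] * e2[, 1L] - d[, 1L] * e2[, 3L],
                d[, 1L] * e2[, 2L] - d[, 2L] * e2[, 1L])
  det <- rowSums(e1 * pvec)
  ok <- abs(det) > eps
  tvec <- sweep(v0, 2L, entry, `-`) * -1
  u <- rowSums(tvec * pvec) / det
  qvec <- cbind(tvec[, 2L] * e1[, 3L] - tvec[, 3L] * e1[, 2L],
                tvec[, 3L] * e1[, 1L] - tvec[, 1L] * e1[, 3L],
                tvec[, 1L] * e1[, 2L] - tvec[, 2L] * e1[, 1L])
  v <- rowSums(d * qvec) / det
  tt <- rowSums(e2 * qvec) / det
  hit <- ok & u >= -eps & v >= -eps & (u + v) <= 1 + eps & tt >= -eps
  sort(pmax(tt[hit], 0))
}

#' Plan a fixation screw trajectory
#'
#' Casts a ray from the screw entry point along its direction through the
#' bone mesh and measures the bony purchase length. By default the length
#' runs to the last ray-mesh exit intersection (total purchase, matching how
#' surgical screw lengths are chosen); `first_exit = TRUE` instead stops at
#' the first exit.
#'
#' @param entry Screw entry point, mm.
#' @param direction Unit direction of the screw axis.
#' @param bone Bone `surface_mesh`, closed along the ray path.
#' @param first_exit Stop at the first exit intersection instead of the last.
#' @return An object of class `screw_plan` with `entry`, `direction`,
#'   `length` (mm) and the intersection parameters `hits`.
#' @export
plan_screw <- function(entry, direction, bone, first_exit = FALSE) {
  stopifnot(inherits(bone, "surface_mesh"))
  entry <- vec3(entry)
  direction <- unitize(vec3(direction), "screw direction")
  hits <- ray_mesh_hits(entry, direction, bone)
  hits <- hits[hits > 1e-9]
  if (length(hits) == 0L) {
    stop("no bony purchase: screw ray does not intersect the bone mesh", call. = FALSE)
  }
  len <- if (first_exit) hits[1L] else hits[length(hits)]
  structure(list(entry = entry, direction = direction, length = len, hits = hits),
            class = "screw_plan")
}

#' @export
print.screw_plan <- function(x, ...) {
  cat(sprintf("<screw_plan> entry (%.1f, %.1f, %.1f), purchase length %.1f mm (%d crossing(s))\n",
              x$entry[1], x$entry[2], x$entry[3], x$length, length(x$hits)))
  invisible(x)
}
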