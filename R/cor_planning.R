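#' Least-squares sphere fit
#'
#' Fits a sphere to a point cloud sampled on the intact femoral head. An
#' algebraic (Kasa-style) linear least-squares solve provides the starting
#' values; a Gauss-Newton refinement of the orthogonal (geometric) residuals
#' `|p_i - c| - R` then runs to a step tolerance of 1e-10 mm or 100
#' iterations. The fit is exact on noiseless spherical data.
#'
#' @param points n x 3 matrix or list of points on the sphere surface, mm.
#' @return An object of class `sphere_fit` with `center` (mm), `radius` (mm),
#'   `rms_residual` (mm) and `n_points`.
#' @export
fit_sphere <- function(points) {
  p <- as_points_matrix(points)
  n <- nrow(p)
  if (n < 4L) stop("underdetermined sphere fit: need at least 4 points", call. = FALSE)
  centered <- sweep(p, 2L, colMeans(p))
  sv <- svd(centered, nu = 0L, nv = 0L)$d
  if (sv[3L] < 1e-9 * max(sv[1L], 1)) {
    stop("underdetermined sphere fit: points are (near-)coplanar", call. = FALSE)
  }

  # algebraic init: |p|^2 = 2 p.c + (R^2 - |c|^2)
  A <- cbind(2 * p, 1)
  b <- rowSums(p * p)
  sol <- qr.solve(A, b)
  center <- sol[1:3]
  radius <- sqrt(max(sol[4L] + sum(center^2), 0))

  # Gauss-Newton on geometric residuals r_i = |p_i - c| - R
  theta <- c(center, radius)
  for (iter in seq_len(100L)) {
    d <- sweep(p, 2L, theta[1:3])
    li <- sqrt(rowSums(d * d))
    li[li < 1e-12] <- 1e-12
    r <- li - theta[4L]
    J <- cbind(-d / li, -1)
    step <- tryCatch(qr.solve(J, -r), error = function(e) rep(0, 4L))
    theta <- theta + step
    if (max(abs(step)) < 1e-10) break
  }
  d <- sweep(p, 2L, theta[1:3])
  resid <- sqrt(rowSums(d * d)) - theta[4L]
  if (theta[4L] <= 0) stop("sphere fit collapsed to non-positive radius", call. = FALSE)

  structure(list(center = unname(theta[1:3]), radius = unname(theta[4L]),
                 rms_residual = sqrt(mean(resid^2)), n_points = n),
            class = "sphere_fit")
}

#' @export
print.sphere_fit <- function(x, ...) {
  cat(sprintf("<sphere_fit> center (%.3f, %.3f, %.3f) mm, radius %.3f mm, RMS %.4f mm (n = %d)\n",
              x$center[1], x$center[2], x$center[3], x$radius, x$rms_residual, x$n_points))
  invisible(x)
}

#' Signed distances of a point to the three reference planes
#'
#' @param frame A `pelvic_frame`.
#' @param p Point, mm.
#' @return Named triple `(d_sagittal, d_coronal, d_axial)` of signed
#'   perpendicular distances in mm.
#' @export
cor_distances <- function(frame, p) {
  stopifnot(inherits(frame, "pelvic_frame"))
  c(d_sagittal = signed_distance(frame$sagittal, p),
    d_coronal = signed_distance(frame$coronal, p),
    d_axial = signed_distance(frame$axial, p))
}

#' Plan the revision-side center of rotation by contralateral mirroring
#'
#' Runs the core planning chain: build the pelvic frame from the canonical
#' landmarks, fit a sphere to the intact femoral head point cloud (or accept
#' a manual center override), and mirror the intact center of rotation across
#' the sagittal plane to obtain the planned revision-side COR. Mirroring by
#' reflection is exactly equivalent to copying the coronal/axial plane
#' distances and negating the sagittal one, because the frame is orthonormal;
#' both distance triples are recorded for reporting.
#'
#' @param landmarks A `landmark_set` with the six canonical landmarks and
#'   `head_points` (unless `intact_cor` is supplied).
#' @param intact_cor Optional manual override of the intact-side center of
#'   rotation (skips the sphere fit); `head_radius` may be given with it.
#' @param head_radius Head radius in mm when `intact_cor` is supplied;
#'   otherwise taken from the sphere fit.
#' @return An object of class `cor_plan` with `intact_cor`, `planned_cor`,
#'   `head_radius`, `distances_intact`, `distances_planned`, `side` (the
#'   revision side), `frame`, and the `sphere_fit` when one was computed.
#' @export
plan_cor <- function(landmarks, intact_cor = NULL, head_radius = NULL) {
  stopifnot(inherits(landmarks, "landmark_set"))
  frame <- build_pelvic_frame(landmarks)
  fit <- NULL
  if (is.null(intact_cor)) {
    if (is.null(landmarks$head_points)) {
      stop("landmark set has no head_points; supply intact_cor to override", call. = FALSE)
    }
    fit <- fit_sphere(landmarks$head_points)
    intact_cor <- fit$center
    head_radius <- fit$radius
  } else {
    intact_cor <- vec3(intact_cor)
    if (is.null(head_radius)) {
      stop("head_radius must accompany a manual intact_cor", call. = FALSE)
    }
  }
  planned_cor <- reflect_across(frame$sagittal, intact_cor)
  revision_side <- if (landmarks$intact_side == "left") "right" else "left"
  structure(list(intact_cor = intact_cor,
                 planned_cor = planned_cor,
                 head_radius = head_radius,
                 distances_intact = cor_distances(frame, intact_cor),
                 distances_planned = cor_distances(frame, planned_cor),
                 side = revision_side,
                 frame = frame,
                 sphere_fit = fit),
            class = "cor_plan")
}

#' @export
print.cor_plan <- function(x, ...) {
  cat(sprintf("<cor_plan> revision side: %s, head radius %.2f mm\n", x$side, x$head_radius))
  cat(sprintf("  intact COR : (%.2f, %.2f, %.2f) mm\n",
              x$intact_cor[1], x$intact_cor[2], x$intact_cor[3]))
  cat(sprintf("  planned COR: (%.2f, %.2f, %.2f) mm\n",
              x$planned_cor[1], x$planned_cor[2], x$planned_cor[3]))
  d <- x$distances_planned
  cat(sprintf("  planned plane distances (sag, cor, ax): %.2f, %.2f, %.2f mm\n",
              d[[1]], d[[2]], d[[3]]))
  invisible(x)
}
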