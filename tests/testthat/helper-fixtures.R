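# shared fixtures: an axis-aligned symmetric pelvis and small geometry helpers

symmetric_landmarks <- function(head_points = NULL, intact_side = "left") {
  landmark_set(rbind(pubic_symphysis_center = c(0, 80, -20),
                     sacrum_center = c(0, -40, 30),
                     ischial_tuberosity_L = c(-60, 10, -70),
                     ischial_tuberosity_R = c(60, 10, -70),
                     ischial_spine_L = c(-45, 10, -10),
                     ischial_spine_R = c(45, 10, -10)),
               case_id = "symmetric_fixture", head_points = head_points,
               intact_side = intact_side)
}

# uniform random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3L, 3L))
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

transform_landmarks <- function(lm, rot, shift = c(0, 0, 0)) {
  m <- lm$landmarks %*% t(rot)
  m <- sweep(m, 2L, shift, `+`)
  hp <- lm$head_points
  if (!is.null(hp)) hp <- sweep(hp %*% t(rot), 2L, shift, `+`)
  landmark_set(m, case_id = lm$case_id, head_points = hp, intact_side = lm$intact_side)
}

# exact points on a sphere: the 6 axis extremes plus optional random samples
sphere_points <- function(center, radius, n_extra = 0L) {
  pts <- rbind(center + c(radius, 0, 0), center - c(radius, 0, 0),
               center + c(0, radius, 0), center - c(0, radius, 0),
               center + c(0, 0, radius), center - c(0, 0, radius))
  if (n_extra > 0L) {
    v <- matrix(stats::rnorm(3L * n_extra), n_extra, 3L)
    v <- v / sqrt(rowSums(v^2))
    pts <- rbind(pts, sweep(radius * v, 2L, center, `+`))
  }
  pts
}

expect_vector_equal <- function(actual, expected, tol = 1e-9) {
  expect_lt(max(abs(actual - expected)), tol)
}

# independent mini-oracles (deliberately not the package's internals)
cross3_test <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

unitize_test <- function(v) v / sqrt(sum(v^2))

deg2rad_test <- function(x) x * pi / 180

# closed UV-sphere test mesh centered at the origin
sphere_mesh_fixture <- function(radius, step_deg) {
  n_th <- max(8L, ceiling(180 / step_deg))
  n_ph <- max(8L, ceiling(360 / step_deg))
  verts <- matrix(0, 0L, 3L)
  ring_start <- integer(0L)
  for (i in seq_len(n_th - 1L)) {
    th <- pi * i / n_th
    ph <- 2 * pi * (seq_len(n_ph) - 1L) / n_ph
    ring_start <- c(ring_start, nrow(verts) + 1L)
    verts <- rbind(verts, cbind(radius * sin(th) * cos(ph),
                                radius * sin(th) * sin(ph),
                                rep(radius * cos(th), n_ph)))
  }
  top <- nrow(verts) + 1L
  bot <- nrow(verts) + 2L
  verts <- rbind(verts, c(0, 0, radius), c(0, 0, -radius))
  idx <- seq_len(n_ph)
  nxt <- c(2:n_ph, 1L)
  tris <- cbind(top, ring_start[1L] + idx - 1L, ring_start[1L] + nxt - 1L)
  for (i in seq_len(n_th - 2L)) {
    a <- ring_start[i] + idx - 1L
    b <- ring_start[i] + nxt - 1L
    c_ <- ring_start[i + 1L] + idx - 1L
    d <- ring_start[i + 1L] + nxt - 1L
    tris <- rbind(tris, cbind(a, c_, b), cbind(b, c_, d))
  }
  last <- ring_start[n_th - 1L]
  tris <- rbind(tris, cbind(bot, last + nxt - 1L, last + idx - 1L))
  surface_mesh(verts, tris)
}
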