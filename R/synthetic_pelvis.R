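# evaluate code under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Synthetic pelvis configuration
#'
#' Dimensions of the schematic pelvis used by the synthetic generators. The
#' defaults describe an average adult pelvis in RAS millimetres: tuberosity
#' tips 120 mm apart, ischial spines 90 mm apart and 60 mm superior to the
#' tuberosities, a 130 mm symphysis-to-sacrum midline span, a ground-truth
#' center of rotation at plane distances (86, 71, 52) mm (lateral, anterior,
#' superior) mirroring typical planned-cup positions, and a 24 mm femoral
#' head radius (a 54 mm cup with a standard shell allowance). Noise,
#' asymmetry and acetabular defect settings are all off by default.
#'
#' @param inter_tuberosity_width Distance between ischial tuberosity tips, mm.
#' @param inter_spine_width Distance between ischial spine tips, mm.
#' @param spine_elevation Superior offset of the spines over the
#'   tuberosities, mm.
#' @param symphysis_sacrum_span Midline distance from the pubic symphysis
#'   center to the sacrum center, mm.
#' @param cor_offset Ground-truth COR position as signed distances to the
#'   (sagittal, coronal, axial) planes, mm.
#' @param head_radius Femoral head radius, mm.
#' @param landmark_noise_sd Isotropic Gaussian noise added per coordinate to
#'   landmarks and head points, mm.
#' @param asymmetry Length-3 translation (mm) applied to the revision-side
#'   tuberosity and spine landmarks to break mirror symmetry.
#' @param defect `"none"`, `"up_and_in"` (superior-medial migration) or
#'   `"up_and_out"` (superior-lateral).
#' @param migration Defect migration distance, mm (superior component).
#' @param intact_side Side of the intact hip; the mesh and defect live on the
#'   other (revision) side.
#' @param n_head_points Number of femoral head surface samples.
#' @param head_cap_deg Half-angle (degrees) of the sampled spherical cap
#'   around the lateral direction; 120 covers more than a hemisphere.
#' @param outer_radius Outer radius of the schematic hemipelvis block, mm.
#' @param recess_angle_deg Half-angle of the acetabular recess cone, degrees.
#' @param mesh_resolution_deg Angular step of the hemipelvis mesh grid.
#' @param seed Integer RNG seed; all generators are pure functions of the
#'   seed and config.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(inter_tuberosity_width = 120, inter_spine_width = 90,
                         spine_elevation = 60, symphysis_sacrum_span = 130,
                         cor_offset = c(86, 71, 52), head_radius = 24,
                         landmark_noise_sd = 0, asymmetry = c(0, 0, 0),
                         defect = c("none", "up_and_in", "up_and_out"),
                         migration = 0, intact_side = c("left", "right"),
                         n_head_points = 200, head_cap_deg = 120,
                         outer_radius = 60, recess_angle_deg = 60,
                         mesh_resolution_deg = 6, seed = 1L) {
  defect <- match.arg(defect)
  intact_side <- match.arg(intact_side)
  lengths <- c(inter_tuberosity_width, inter_spine_width, spine_elevation,
               symphysis_sacrum_span, head_radius, outer_radius)
  if (any(!is.finite(lengths) | lengths <= 0)) {
    stop("all configured lengths must be positive", call. = FALSE)
  }
  if (landmark_noise_sd < 0 || migration < 0) {
    stop("noise and migration must be non-negative", call. = FALSE)
  }
  if (defect != "none" && migration <= 0) {
    stop("a defect requires migration > 0", call. = FALSE)
  }
  if (head_radius >= outer_radius) {
    stop("head_radius must be smaller than outer_radius", call. = FALSE)
  }
  structure(list(inter_tuberosity_width = inter_tuberosity_width,
                 inter_spine_width = inter_spine_width,
                 spine_elevation = spine_elevation,
                 symphysis_sacrum_span = symphysis_sacrum_span,
                 cor_offset = vec3(cor_offset), head_radius = head_radius,
                 landmark_noise_sd = landmark_noise_sd, asymmetry = vec3(asymmetry),
                 defect = defect, migration = migration, intact_side = intact_side,
                 n_head_points = as.integer(n_head_points), head_cap_deg = head_cap_deg,
                 outer_radius = outer_radius, recess_angle_deg = recess_angle_deg,
                 mesh_resolution_deg = mesh_resolution_deg, seed = as.integer(seed)),
            class = "synth_config")
}

# noiseless landmark geometry: symmetric about x = 0, identity frame
synth_true_landmarks <- function(config) {
  z_tub <- -70
  y_post <- 10
  ps <- c(0, 80, -20)
  midline <- c(0, -120, 50) / 130
  sc <- ps + config$symphysis_sacrum_span * midline
  half_t <- config$inter_tuberosity_width / 2
  half_s <- config$inter_spine_width / 2
  rbind(pubic_symphysis_center = ps,
        sacrum_center = sc,
        ischial_tuberosity_L = c(-half_t, y_post, z_tub),
        ischial_tuberosity_R = c(half_t, y_post, z_tub),
        ischial_spine_L = c(-half_s, y_post, z_tub + config$spine_elevation),
        ischial_spine_R = c(half_s, y_post, z_tub + config$spine_elevation))
}

# ground-truth CORs: cor_offset are signed distances to the (sagittal,
# coronal, axial) planes; the intact-side COR sits on the intact side
synth_true_cors <- function(config) {
  z_tub <- -70
  y_post <- 10
  sgn <- if (config$intact_side == "left") -1 else 1
  intact <- c(sgn * config$cor_offset[1L], y_post + config$cor_offset[2L],
              z_tub + config$cor_offset[3L])
  revision <- intact * c(-1, 1, 1)
  list(intact_cor = intact, revision_cor = revision)
}

#' Generate a synthetic landmark set with ground truth
#'
#' Places the six canonical landmarks symmetrically about the x = 0 plane
#' from the configured dimensions, applies the configured asymmetry
#' translation to the revision-side tuberosity and spine, samples the intact
#' femoral head surface on a spherical cap wider than a hemisphere, then adds
#' i.i.d. Gaussian noise (seeded) to every landmark and head point. The
#' noiseless ground-truth CORs of both sides are returned alongside.
#'
#' @param config A `synth_config`.
#' @return List with `landmarks` (a `landmark_set`) and `truth`
#'   (`intact_cor`, `revision_cor`, plus the config `seed`).
#' @export
synth_landmarks <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  lm <- synth_true_landmarks(config)
  truth <- synth_true_cors(config)
  revision_suffix <- if (config$intact_side == "left") "_R" else "_L"
  rev_rows <- paste0(c("ischial_tuberosity", "ischial_spine"), revision_suffix)
  lm[rev_rows, ] <- sweep(lm[rev_rows, , drop = FALSE], 2L, config$asymmetry, `+`)

  with_seed(config$seed, {
    # head surface: uniform over a cap of half-angle head_cap_deg about the
    # outward lateral direction of the intact side
    lat <- c(if (config$intact_side == "left") -1 else 1, 0, 0)
    n <- config$n_head_points
    cos_max <- cos(deg2rad(config$head_cap_deg))
    u <- stats::runif(n, cos_max, 1)
    phi <- stats::runif(n, 0, 2 * pi)
    s <- sqrt(pmax(0, 1 - u^2))
    # local basis around lat
    b1 <- c(0, 1, 0)
    b2 <- cross3(lat, b1)
    dirs <- outer(u, lat) + outer(s * cos(phi), b1) + outer(s * sin(phi), b2)
    head_points <- sweep(config$head_radius * dirs, 2L, truth$intact_cor, `+`)

    if (config$landmark_noise_sd > 0) {
      lm <- lm + matrix(stats::rnorm(length(lm), 0, config$landmark_noise_sd), nrow(lm), 3L)
      head_points <- head_points +
        matrix(stats::rnorm(length(head_points), 0, config$landmark_noise_sd),
               nrow(head_points), 3L)
    }
    list(landmarks = landmark_set(lm, case_id = sprintf("synth_seed%d", config$seed),
                                  head_points = head_points,
                                  intact_side = config$intact_side),
         truth = c(truth, list(seed = config$seed)))
  })
}

#' Generate a schematic hemipelvis mesh with an acetabular recess
#'
#' A closed, watertight star-shaped surface around the revision-side
#' ground-truth COR: directions within the recess cone (around the outward
#' lateral direction) lie at `head_radius`, directions outside at
#' `outer_radius`, with a smooth cosine blend between. Any ray from the COR
#' along a recess-interior direction therefore first hits the surface at the
#' head radius, emulating the acetabular articular surface; the surrounding
#' block stands in for the segmented hemipelvis.
#'
#' @param config A `synth_config`.
#' @return A `surface_mesh` with attributes `cor` (the recess center) and
#'   `recess_axis`.
#' @export
synth_hemipelvis_mesh <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  truth <- synth_true_cors(config)
  center <- truth$revision_cor
  axis <- c(if (config$intact_side == "left") 1 else -1, 0, 0)  # outward lateral
  alpha <- deg2rad(config$recess_angle_deg)
  blend <- deg2rad(20)

  radius_at <- function(theta) {
    r_in <- config$head_radius
    r_out <- config$outer_radius
    ifelse(theta <= alpha, r_in,
           ifelse(theta >= alpha + blend, r_out,
                  r_in + (r_out - r_in) * (1 - cos(pi * (theta - alpha) / blend)) / 2))
  }

  step <- deg2rad(config$mesh_resolution_deg)
  n_theta <- max(8L, as.integer(ceiling(pi / step)))
  n_phi <- max(8L, as.integer(ceiling(2 * pi / step)))
  b1 <- c(0, 1, 0)
  b2 <- cross3(axis, b1)

  verts <- matrix(0, 0L, 3L)
  ring_start <- integer(0L)
  for (i in seq_len(n_theta - 1L)) {
    th <- pi * i / n_theta
    r <- radius_at(th)
    phi <- 2 * pi * (seq_len(n_phi) - 1L) / n_phi
    dirs <- outer(rep(cos(th), n_phi), axis) + outer(sin(th) * cos(phi), b1) +
      outer(sin(th) * sin(phi), b2)
    ring_start <- c(ring_start, nrow(verts) + 1L)
    verts <- rbind(verts, sweep(r * dirs, 2L, center, `+`))
  }
  pole_top <- nrow(verts) + 1L
  pole_bot <- nrow(verts) + 2L
  verts <- rbind(verts, center + radius_at(0) * axis, center - radius_at(pi) * axis)

  tris <- matrix(0L, 0L, 3L)
  idx <- seq_len(n_phi)
  nxt <- c(2:n_phi, 1L)
  tris <- rbind(tris, cbind(pole_top, ring_start[1L] + idx - 1L, ring_start[1L] + nxt - 1L))
  for (i in seq_len(n_theta - 2L)) {
    a <- ring_start[i] + idx - 1L
    b <- ring_start[i] + nxt - 1L
    c_ <- ring_start[i + 1L] + idx - 1L
    d <- ring_start[i + 1L] + nxt - 1L
    tris <- rbind(tris, cbind(a, c_, b), cbind(b, c_, d))
  }
  last <- ring_start[n_theta - 1L]
  tris <- rbind(tris, cbind(pole_bot, last + nxt - 1L, last + idx - 1L))

  mesh <- surface_mesh(verts, tris)
  attr(mesh, "cor") <- center
  attr(mesh, "recess_axis") <- axis
  mesh
}

#' Carve a migrated acetabular defect into a hemipelvis mesh
#'
#' Displaces the recess (acetabular) region of the mesh by `migration` mm
#' superiorly plus half that distance medially (`up_and_in`) or laterally
#' (`up_and_out`), emulating the superior-medial / superior-lateral cup
#' migration patterns of severe acetabular bone loss. Two `defect_edge`
#' landmark points spanning the displacement are emitted so the defect length
#' can be measured the way a caliper would across the physical model.
#'
#' @param mesh A `surface_mesh` from [synth_hemipelvis_mesh()].
#' @param config A `synth_config` with `defect != "none"` and
#'   `migration > 0`.
#' @return List with `mesh` (displaced), `defect_edges` (2 x 3 matrix:
#'   original and displaced superior rim point) and `displacement`.
#' @export
apply_defect <- function(mesh, config) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(config, "synth_config"))
  if (config$defect == "none") stop("config$defect is 'none'; nothing to apply", call. = FALSE)
  if (config$migration <= 0) stop("migration must be positive", call. = FALSE)
  if (config$migration > config$outer_radius) {
    stop(sprintf("migration %.1f mm exceeds the mesh extent (%.1f mm)",
                 config$migration, config$outer_radius), call. = FALSE)
  }
  center <- attr(mesh, "cor")
  axis <- attr(mesh, "recess_axis")
  if (is.null(center) || is.null(axis)) {
    stop("mesh lacks recess annotations; generate it with synth_hemipelvis_mesh()",
         call. = FALSE)
  }
  medial <- -axis  # toward the midline
  lateral_part <- if (config$defect == "up_and_in") medial else axis
  displacement <- config$migration * c(0, 0, 1) + 0.5 * config$migration * lateral_part

  alpha <- deg2rad(config$recess_angle_deg) + deg2rad(20)
  rel <- sweep(mesh$vertices, 2L, center)
  costh <- as.numeric(rel %*% axis) / pmax(sqrt(rowSums(rel^2)), 1e-12)
  in_recess <- costh >= cos(alpha)
  verts <- mesh$vertices
  verts[in_recess, ] <- sweep(verts[in_recess, , drop = FALSE], 2L, displacement, `+`)

  rim_dir <- cos(deg2rad(config$recess_angle_deg)) * axis +
    sin(deg2rad(config$recess_angle_deg)) * c(0, 0, 1)
  edge_1 <- center + config$head_radius * rim_dir
  edge_2 <- edge_1 + displacement
  out <- surface_mesh(verts, mesh$triangles)
  attr(out, "cor") <- center + displacement
  attr(out, "recess_axis") <- axis
  list(mesh = out,
       defect_edges = rbind(defect_edge_1 = edge_1, defect_edge_2 = edge_2),
       displacement = displacement)
}

#' Measure a defect length between two edge landmarks
#'
#' Euclidean distance between the two caliper points, optionally after
#' projecting both onto the axial reference plane (the plane the physical
#' measurement is taken in).
#'
#' @param a,b The two edge points, mm.
#' @param frame Optional `pelvic_frame` (required when `project_axial`).
#' @param project_axial Project both points onto the axial plane first.
#' @return Length in mm (0 with a warning for coincident points).
#' @export
measure_defect_length <- function(a, b, frame = NULL, project_axial = FALSE) {
  a <- vec3(a)
  b <- vec3(b)
  if (project_axial) {
    if (is.null(frame)) stop("axial projection requires a pelvic_frame", call. = FALSE)
    proj <- function(p) p - signed_distance(frame$axial, p) * frame$axial$normal
    a <- proj(a)
    b <- proj(b)
  }
  len <- vnorm(a - b)
  if (len < 1e-12) warning("coincident defect edge points: length 0", call. = FALSE)
  len
}
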