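test_that("generators are pure functions of seed and config", {
  a <- synth_landmarks(synth_config(seed = 12, landmark_noise_sd = 1.5))
  b <- synth_landmarks(synth_config(seed = 12, landmark_noise_sd = 1.5))
  expect_identical(a$landmarks$landmarks, b$landmarks$landmarks)
  expect_identical(a$landmarks$head_points, b$landmarks$head_points)
  c_ <- synth_landmarks(synth_config(seed = 13, landmark_noise_sd = 1.5))
  expect_false(identical(a$landmarks$landmarks, c_$landmarks$landmarks))
})

test_that("config validation rejects invalid settings", {
  expect_error(synth_config(head_radius = -5), "positive")
  expect_error(synth_config(landmark_noise_sd = -1), "non-negative")
  expect_error(synth_config(defect = "up_and_in", migration = 0), "migration")
  expect_error(synth_config(head_radius = 70, outer_radius = 60), "smaller")
})

test_that("noiseless symmetric generation gives exact mirror recovery on both sides", {
  for (side in c("left", "right")) {
    sim <- synth_landmarks(synth_config(seed = 4, intact_side = side))
    plan <- plan_cor(sim$landmarks)
    expect_vector_equal(plan$planned_cor, sim$truth$revision_cor, 1e-9)
    expect_equal(plan$side, if (side == "left") "right" else "left")
  }
})

test_that("head point cloud lies on the configured sphere and covers a wide cap", {
  cfg <- synth_config(seed = 21)
  sim <- synth_landmarks(cfg)
  hp <- sim$landmarks$head_points
  radii <- sqrt(rowSums(sweep(hp, 2L, sim$truth$intact_cor)^2))
  expect_lt(max(abs(radii - cfg$head_radius)), 1e-9)
  # cap coverage beyond a hemisphere: some points on the medial half
  lat <- c(-1, 0, 0)  # intact left
  cosang <- sweep(hp, 2L, sim$truth$intact_cor) %*% lat / cfg$head_radius
  expect_lt(min(cosang), 0)
})

test_that("planning error grows monotonically with landmark noise", {
  median_err <- vapply(c(0, 0.5, 1, 2), function(sd_) {
    errs <- vapply(1:60, function(s) {
      sim <- synth_landmarks(synth_config(seed = 1000L + s, landmark_noise_sd = sd_))
      sqrt(sum((plan_cor(sim$landmarks)$planned_cor - sim$truth$revision_cor)^2))
    }, numeric(1L))
    median(errs)
  }, numeric(1L))
  expect_true(all(diff(median_err) > 0))
  expect_lt(median_err[1L], 1e-9)
})

test_that("the hemipelvis mesh is watertight with a recess at the head radius", {
  cfg <- synth_config(seed = 2, mesh_resolution_deg = 9)
  mesh <- synth_hemipelvis_mesh(cfg)
  # watertight: every edge shared by exactly two triangles
  edges <- rbind(mesh$triangles[, c(1L, 2L)], mesh$triangles[, c(2L, 3L)],
                 mesh$triangles[, c(3L, 1L)])
  keys <- paste(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
  expect_true(all(table(keys) == 2L))
  # rays from the COR along recess-interior directions first hit at ~head_radius
  cor <- attr(mesh, "cor")
  axis <- attr(mesh, "recess_axis")
  set.seed(31)
  for (rep in 1:5) {
    ang <- runif(1, 0, deg2rad_test(cfg$recess_angle_deg - 10))
    phi <- runif(1, 0, 2 * pi)
    perp1 <- c(0, 1, 0)
    perp2 <- cross3_test(axis, perp1)
    dir <- cos(ang) * axis + sin(ang) * (cos(phi) * perp1 + sin(phi) * perp2)
    hit <- plan_screw(cor, dir, mesh, first_exit = TRUE)
    expect_lt(abs(hit$length - cfg$head_radius), 0.2)
  }
  # a screw entering at the articular surface and angled into the rim wall
  # traverses bone: positive purchase, bounded by the block diameter
  entry <- cor + cfg$head_radius * axis
  screw <- plan_screw(entry, -axis, mesh)  # medially, through the whole block
  expect_gt(screw$length, 0)
  expect_lt(abs(screw$length - (cfg$head_radius + cfg$outer_radius)), 0.5)
})

test_that("defects displace the rim superiorly by the migration distance", {
  cfg_in <- synth_config(seed = 3, defect = "up_and_in", migration = 30,
                         mesh_resolution_deg = 9)
  mesh <- synth_hemipelvis_mesh(cfg_in)
  res <- apply_defect(mesh, cfg_in)
  expect_equal(res$displacement[3L], 30)
  expect_lt(res$displacement[1L], 0)  # medial for a right-side revision ('up and in')
  # recess vertices moved superiorly by >= migration
  moved <- res$mesh$vertices - mesh$vertices
  moved_z <- moved[rowSums(abs(moved)) > 1e-9, 3L]
  expect_true(length(moved_z) > 0 && all(moved_z >= 30 - 1e-9))
  cfg_out <- synth_config(seed = 3, defect = "up_and_out", migration = 30,
                          mesh_resolution_deg = 9)
  res_out <- apply_defect(synth_hemipelvis_mesh(cfg_out), cfg_out)
  expect_gt(res_out$displacement[1L], 0)  # lateral
  expect_error(apply_defect(mesh, synth_config(seed = 3, defect = "up_and_in",
                                               migration = 80)), "exceeds")
})

test_that("defect edge span equals the configured displacement and grows with migration", {
  spans <- vapply(c(10, 20, 30, 40), function(mig) {
    cfg <- synth_config(seed = 5, defect = "up_and_in", migration = mig,
                        mesh_resolution_deg = 12)
    res <- apply_defect(synth_hemipelvis_mesh(cfg), cfg)
    measure_defect_length(res$defect_edges[1L, ], res$defect_edges[2L, ])
  }, numeric(1L))
  expect_true(all(diff(spans) > 0))
  expect_lt(abs(spans[3L] - 30 * sqrt(1.25)), 0.5)
})

test_that("defect lengths project correctly onto the axial plane", {
  expect_equal(measure_defect_length(c(0, 0, 0), c(30, 0, 0)), 30)
  fr <- build_pelvic_frame(symmetric_landmarks())
  expect_equal(suppressWarnings(measure_defect_length(c(5, 5, 0), c(5, 5, 40), frame = fr,
                                                      project_axial = TRUE)), 0)
  expect_warning(measure_defect_length(c(1, 2, 3), c(1, 2, 3)), "coincident")
  set.seed(37)
  for (rep in 1:20) {
    a <- runif(3, -50, 50)
    b <- runif(3, -50, 50)
    expect_lt(abs(measure_defect_length(a, b) - sqrt(sum((a - b)^2))), 1e-12)
  }
})
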