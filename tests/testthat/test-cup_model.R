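identity_frame <- function() build_pelvic_frame(symmetric_landmarks())

test_that("cup axis closed forms hold in the identity frame", {
  fr <- identity_frame()
  expect_vector_equal(suppressWarnings(axis_from_angles(fr, 45, 0, "right")),
                      c(sqrt(0.5), 0, -sqrt(0.5)), 1e-9)
  expect_vector_equal(axis_from_angles(fr, 40, 15, "right"),
                      c(0.6209, 0.2588, -0.7399), 1e-4)
  expect_vector_equal(suppressWarnings(axis_from_angles(fr, 0, 0, "right")),
                      c(0, 0, -1), 1e-12)
  expect_error(axis_from_angles(fr, 95, 10, "right"), "\\[0, 90\\)")
  expect_warning(axis_from_angles(fr, 55, 15, "right"), "30-45")
  expect_warning(axis_from_angles(fr, 40, 25, "right"), "10-20")
})

test_that("angles and axis are exact inverses over the planning grid", {
  fr <- identity_frame()
  for (side in c("right", "left")) {
    for (ri in c(30, 35, 40, 45)) {
      for (ra in c(10, 15, 20)) {
        ax <- axis_from_angles(fr, ri, ra, side)
        ang <- angles_from_axis(fr, ax, side)
        expect_lt(abs(ang$inclination - ri), 1e-9)
        expect_lt(abs(ang$anteversion - ra), 1e-9)
      }
    }
  }
  expect_equal(angles_from_axis(fr, c(0, 0, -1), "right")$inclination, 0)
  expect_equal(angles_from_axis(fr, c(0, 0, -1), "right")$anteversion, 0)
  # pure anterior axis: inclination indeterminate
  pure <- angles_from_axis(fr, c(0, 1, 0), "right")
  expect_true(pure$inclination_indeterminate)
  expect_equal(pure$anteversion, 90)
})

test_that("angle recovery matches a brute-force grid search", {
  fr <- identity_frame()
  set.seed(53)
  for (rep in 1:10) {
    ri0 <- runif(1, 5, 85)
    ra0 <- runif(1, -60, 60)
    ax <- suppressWarnings(axis_from_angles(fr, ri0, ra0, "right"))
    ang <- angles_from_axis(fr, ax, "right")
    # oracle: coarse-to-fine search minimizing axis reconstruction error
    obj <- function(p) {
      cand <- sin(p[1]) * cos(p[2]) * c(1, 0, 0) + sin(p[2]) * c(0, 1, 0) -
        cos(p[1]) * cos(p[2]) * c(0, 0, 1)
      sum((cand - ax)^2)
    }
    best <- optim(c(pi / 4, 0), obj, method = "L-BFGS-B",
                  lower = c(0, -pi / 2 + 1e-6), upper = c(pi / 2 - 1e-6, pi / 2 - 1e-6),
                  control = list(factr = 1))
    expect_lt(abs(ang$inclination - best$par[1] * 180 / pi), 1e-4)
    expect_lt(abs(ang$anteversion - best$par[2] * 180 / pi), 1e-4)
  }
})

test_that("left/right mirror symmetry of the cup axis", {
  fr <- identity_frame()
  axr <- axis_from_angles(fr, 40, 15, "right")
  axl <- axis_from_angles(fr, 40, 15, "left")
  expect_vector_equal(axl, axr * c(-1, 1, 1))
})

test_that("the cup catalog runs 50-64 mm in 2 mm steps", {
  cat <- cup_catalog()
  expect_length(cat, 8L)
  expect_equal(min(cat), 50)
  expect_equal(max(cat), 64)
  expect_true(all(diff(cat) == 2))
  expect_true(54 %in% cat)
})

test_that("cup meshes respect the construction constraints", {
  mesh <- generate_cup_mesh(54, shell_thickness = 3, angular_resolution = 5)
  regions <- attr(mesh, "regions")
  outer_idx <- unique(as.integer(mesh$triangles[regions$outer, ]))
  radii <- sqrt(rowSums(mesh$vertices[outer_idx, ]^2))
  expect_true(all(radii > 26.99 & radii < 27.01))
  rim_z <- mesh$vertices[attr(mesh, "rim_vertices"), 3L]
  expect_lt(max(abs(rim_z)), 1e-9)
  expect_true(all(mesh$vertices[, 3L] <= 1e-9))  # dome toward -z, opening +z
  expect_error(generate_cup_mesh(-5, allow_noncatalog = TRUE), "positive")
  expect_error(generate_cup_mesh(53), "catalog")
})

test_that("outer hemisphere area approaches the analytic limit with resolution", {
  analytic <- 2 * pi * 27^2
  area_at <- function(res) {
    mesh <- generate_cup_mesh(54, angular_resolution = res)
    mesh_area(mesh, attr(mesh, "regions")$outer)
  }
  expect_lt(abs(area_at(1) - analytic) / analytic, 0.01)
  # refinement monotonically approaches the limit
  expect_lt(abs(area_at(2) - analytic), abs(area_at(8) - analytic))
})

test_that("placing a cup is a rigid motion consistent with its pose", {
  fr <- identity_frame()
  mesh <- generate_cup_mesh(54, angular_resolution = 10)
  # identity pose leaves the canonical mesh unchanged
  pose0 <- suppressWarnings(cup_pose(fr, c(0, 0, 0), 54, 0, 0, side = "right",
                                     allow_noncatalog = TRUE))
  expect_true(abs(sum(pose0$axis * c(0, 0, -1)) - 1) < 1e-12)  # axis convention check
  set.seed(59)
  pose <- cup_pose(fr, c(86, 81, -18), 54, 40, 15, side = "right")
  placed <- place_cup(mesh, pose)
  # rigid: pairwise distances preserved
  pick <- sample(nrow(mesh$vertices), 40L)
  expect_lt(max(abs(dist(placed$vertices[pick, ]) - dist(mesh$vertices[pick, ]))), 1e-9)
  # rim centroid maps to the pose center and rim normal to the pose axis
  rim <- placed$vertices[attr(placed, "rim_vertices"), ]
  expect_vector_equal(colMeans(rim), pose$center, 1e-9)
  rel <- sweep(rim, 2L, pose$center)
  sv <- svd(rel)
  rim_normal <- sv$v[, 3L]
  if (sum(rim_normal * pose$axis) < 0) rim_normal <- -rim_normal
  expect_vector_equal(rim_normal, pose$axis, 1e-9)
  ang <- angles_from_axis(fr, rim_normal, "right")
  expect_lt(abs(ang$inclination - 40), 1e-6)
  expect_lt(abs(ang$anteversion - 15), 1e-6)
})

test_that("screw purchase length matches the analytic chord through a sphere", {
  mesh <- sphere_mesh_fixture(20, 3)
  plan <- plan_screw(c(0, 0, 0), c(0, 0, 1), mesh)
  expect_lt(abs(plan$length - 20), 0.05)
  expect_error(plan_screw(c(50, 0, 0), c(0, 0, 1), mesh), "purchase")
})

test_that("ray-mesh lengths agree with an exhaustive per-triangle oracle", {
  mesh <- sphere_mesh_fixture(20, 6)
  set.seed(61)
  for (rep in 1:10) {
    entry <- runif(3, -5, 5)
    dir <- unitize_test(rnorm(3))
    plan <- plan_screw(entry, dir, mesh)
    # oracle: solve each triangle's barycentric system directly
    oracle_ts <- c()
    for (i in seq_len(nrow(mesh$triangles))) {
      v <- mesh$vertices[mesh$triangles[i, ], ]
      A <- cbind(v[2, ] - v[1, ], v[3, ] - v[1, ], -dir)
      if (abs(det(A)) < 1e-12) next
      sol <- solve(A, entry - v[1, ])
      if (sol[1] >= -1e-9 && sol[2] >= -1e-9 && sol[1] + sol[2] <= 1 + 1e-9 && sol[3] >= 0) {
        oracle_ts <- c(oracle_ts, sol[3])
      }
    }
    expect_lt(abs(plan$length - max(oracle_ts)), 1e-9)
  }
})
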