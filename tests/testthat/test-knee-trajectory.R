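test_that("contact search finds the sphere support point", {
  g <- sphere_knee_20()
  cm <- find_contact_point(g$condyle_medial, g$plateau_medial, "medial")
  expect_equal(cm$p, c(0, -40, 0), tolerance = 1e-6)
  expect_equal(cm$n, c(0, 0, -1), tolerance = 1e-6)
  # tilted plane: support point rotates to c - r * n_plane
  n_tilt <- c(sin(10 * pi / 180), 0, cos(10 * pi / 180))
  cm2 <- find_contact_point(g$condyle_medial,
                            plateau_plane(c(0, -40, -5), n_tilt), "medial")
  expect_equal(cm2$p, c(0, -40, 20) - 20 * n_tilt, tolerance = 0.01)
  expect_error(find_contact_point(tri_mesh(matrix(0, 0, 3),
                                           matrix(integer(0), 0, 3)),
                                  g$plateau_medial), "empty")
})

test_that("contact search matches exhaustive per-triangle minimisation", {
  g <- cylinder_knee_20()
  cm <- find_contact_point(g$condyle_medial, g$plateau_medial, "medial")
  # brute force: the distance minimum over all vertices
  d <- as.numeric(sweep(g$condyle_medial$vertices, 2,
                        g$plateau_medial$point) %*% g$plateau_medial$normal)
  expect_lte(cm$distance, min(d) + 1e-9)
  # refined point lies on the bottom generatrix (z = 0, x = 0)
  expect_lt(abs(cm$p[1]), 0.05)
  expect_lt(abs(cm$p[3]), 1e-4)
})

test_that("helical axis solve recovers the sphere and cylinder oracles", {
  g <- sphere_knee_20()
  cm <- find_contact_point(g$condyle_medial, g$plateau_medial, "medial")
  cl <- find_contact_point(g$condyle_lateral, g$plateau_lateral, "lateral")
  sol <- solve_helical_axis(cm, cl, g$field_medial, g$field_lateral)
  expect_equal(sol$medial$r, 20, tolerance = 0.01 * 20)
  expect_equal(sol$lateral$r, 20, tolerance = 0.01 * 20)
  expect_lt(sqrt(sum((sol$axis$I_m - g$truth$center_medial)^2)), 0.5)
  expect_lt(sqrt(sum((sol$axis$I_l - g$truth$center_lateral)^2)), 0.5)
  # I = p - r n against the stored outward normal
  expect_equal(sol$axis$I_m, sol$medial$p - sol$medial$r * sol$medial$n,
               tolerance = 1e-9)
  # cylinder: axis parallel to the generator
  gc <- cylinder_knee_20()
  cmc <- find_contact_point(gc$condyle_medial, gc$plateau_medial, "medial")
  clc <- find_contact_point(gc$condyle_lateral, gc$plateau_lateral, "lateral")
  solc <- solve_helical_axis(cmc, clc, gc$field_medial, gc$field_lateral)
  expect_lt(acos(min(1, abs(sum(solc$axis$direction * c(0, 1, 0))))),
            0.5 * pi / 180)
  expect_equal(solc$medial$r, 20, tolerance = 0.2)
})

test_that("isotropic curvature makes the solve initialisation-independent", {
  g <- sphere_knee_20()
  cm <- find_contact_point(g$condyle_medial, g$plateau_medial, "medial")
  cl <- find_contact_point(g$condyle_lateral, g$plateau_lateral, "lateral")
  # perturb contact normals slightly to shift the initial axis; the sphere's
  # isotropic tensor must give the same radii
  sol1 <- solve_helical_axis(cm, cl, g$field_medial, g$field_lateral)
  cl_shift <- cl
  cl_shift$p <- cl$p + c(0.5, 0, 0)
  sol2 <- solve_helical_axis(cm, cl_shift, g$field_medial, g$field_lateral)
  expect_equal(sol1$medial$r, sol2$medial$r, tolerance = 1e-6)
})

test_that("step_flexion is an isometry with the group property", {
  g <- sphere_knee_20()
  cm <- find_contact_point(g$condyle_medial, g$plateau_medial, "medial")
  cl <- find_contact_point(g$condyle_lateral, g$plateau_lateral, "lateral")
  sol <- solve_helical_axis(cm, cl, g$field_medial, g$field_lateral)
  st <- step_flexion(g, sol$axis, 0.5)
  # plateau point distance to the axis is preserved
  axis_dist <- function(p) {
    d <- p - sol$axis$I_m
    sqrt(sum(d^2) - sum(d * sol$axis$direction)^2)
  }
  expect_equal(axis_dist(st$geometry$plateau_medial$point),
               axis_dist(g$plateau_medial$point), tolerance = 1e-9)
  # two 0.5-degree steps about a fixed axis equal one 1.0-degree step
  st2 <- step_flexion(st$geometry, sol$axis, 0.5)
  st1 <- step_flexion(g, sol$axis, 1.0)
  expect_equal(st2$geometry$plateau_medial$point,
               st1$geometry$plateau_medial$point, tolerance = 1e-9)
  # tangency preserved: plane stays tangent to the sphere
  pl <- st$geometry$plateau_medial
  d_center <- abs(sum((g$truth$center_medial - pl$point) * pl$normal))
  expect_lt(abs(d_center - 20) / 20, 1e-6)
  expect_error(step_flexion(g, sol$axis, 7), "<= 5")
  expect_error(step_flexion(g, sol$axis, 0), "<= 5")
})

test_that("trajectory reaches the target in the expected number of steps", {
  g <- sphere_knee_20()
  traj <- cached("sphere_traj_40", compute_flexion_trajectory(g, 40, 0.5))
  expect_length(traj$steps, 80)
  expect_equal(traj$cumulative_angle, 40, tolerance = 1e-9)
  # truncated final step
  traj2 <- compute_flexion_trajectory(g, 1.25, 0.5)
  expect_length(traj2$steps, 3)
  expect_equal(traj2$steps[[3]]$angle, 0.25, tolerance = 1e-12)
})

test_that("sphere fixture: tibia-frame contact drift stays below 2% of R", {
  g <- sphere_knee_20()
  traj <- cached("sphere_traj_40", compute_flexion_trajectory(g, 40, 0.5))
  for (comp in c("medial", "lateral")) {
    tc <- traj$contacts[traj$contacts$compartment == comp, ]
    drift <- sum(sqrt(diff(tc$tx)^2 + diff(tc$ty)^2 + diff(tc$tz)^2))
    expect_lt(drift, 0.02 * 20)
  }
})

test_that("cylinder fixture: composed trajectory matches the analytic hinge", {
  g <- cylinder_knee_20()
  traj <- cached("cyl_traj_40", compute_flexion_trajectory(g, 40, 0.5))
  hinge <- rodrigues(g$truth$axis_dir, 40, g$truth$axis_point)
  rel <- traj$composed_transform$rotation %*% t(hinge$rotation)
  aa <- arthropose:::rotation_angle_axis(rel)
  expect_lt(aa$angle, 0.5)
  aa_traj <- arthropose:::rotation_angle_axis(traj$composed_transform$rotation)
  expect_lt(acos(min(1, abs(sum(aa_traj$axis * g$truth$axis_dir)))),
            0.5 * pi / 180)
})

test_that("step-size consistency: 0.5 vs 0.25 degree trajectories agree", {
  g <- sphere_knee_20()
  t1 <- compute_flexion_trajectory(g, 10, 0.5)
  t2 <- compute_flexion_trajectory(g, 10, 0.25)
  rel <- t1$composed_transform$rotation %*% t(t2$composed_transform$rotation)
  expect_lt(arthropose:::rotation_angle_axis(rel)$angle, 0.2)
})

test_that("trajectories are deterministic and round trip through JSON", {
  g <- cylinder_knee_20()
  t1 <- compute_flexion_trajectory(g, 3, 0.5)
  t2 <- compute_flexion_trajectory(g, 3, 0.5)
  expect_identical(t1$composed_transform, t2$composed_transform)
  expect_identical(t1$contacts, t2$contacts)
  f <- withr::local_tempfile(fileext = ".json")
  write_trajectory(t1, f)
  t3 <- read_trajectory(f)
  expect_equal(t3$composed_transform$rotation,
               t1$composed_transform$rotation, tolerance = 1e-12)
  expect_equal(t3$cumulative_angle, 3)
  # exact inverse replay
  ti <- invert_trajectory(t1)
  comp <- compose_transform(ti$composed_transform, t1$composed_transform)
  expect_equal(comp$rotation, diag(3), tolerance = 1e-12)
  expect_equal(comp$translation, c(0, 0, 0), tolerance = 1e-9)
})

test_that("ellipsoid fixture: pole curvature analytic and axis varies", {
  g <- cached("ellipsoid_knee",
              make_ellipsoid_knee(a = 25, b = 20, c = 18, edge = 1.5,
                                  lateral_scale = 0.85))
  # kn at the bottom pole along the x tangent = c/a^2
  m <- g$condyle_medial
  pole <- which.min(m$vertices[, 3])
  C <- arthropose:::.sym6_to_mat(g$field_medial$tensors[pole, ])
  expect_equal(normal_curvature(C, c(1, 0, 0)), 18 / 25^2,
               tolerance = 0.05 * 18 / 25^2)
  expect_equal(normal_curvature(C, c(0, 1, 0)), 18 / 20^2,
               tolerance = 0.05 * 18 / 20^2)
  # per-step axis direction varies for a != b
  traj <- compute_flexion_trajectory(g, 10, 1)
  d1 <- traj$steps[[1]]$axis$direction
  dn <- traj$steps[[length(traj$steps)]]$axis$direction
  expect_gt(acos(min(1, abs(sum(d1 * dn)))), 0)
})

test_that("trajectory errors carry the partial trajectory", {
  g <- sphere_knee_20()
  # flat plateau against a flat 'condyle' triggers the curvature error
  flat <- flat_grid_mesh(6)
  gg <- g
  gg$condyle_medial <- flat
  gg$field_medial <- suppressWarnings(curvature_tensor_field(flat))
  err <- tryCatch(compute_flexion_trajectory(gg, 2, 0.5), error = identity)
  expect_s3_class(err, "arthropose_trajectory_error")
  expect_s3_class(err$partial, "knee_trajectory")
})
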