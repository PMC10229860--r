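# small two-part model: upper arm part 1 (z in [0, 50]), forearm part 2
# (z in [-50, 0]), hinge at the origin about y
two_part_model <- function() {
  upper <- hex_block_model(2, 2, 5)
  m <- upper
  m$nodes$x <- m$nodes$x - 1; m$nodes$y <- m$nodes$y - 1
  m$nodes$z <- m$nodes$z * 10
  lo <- m
  n0 <- max(m$nodes$id)
  lower_nodes <- m$nodes
  lower_nodes$id <- lower_nodes$id + n0
  lower_nodes$z <- -lower_nodes$z
  e0 <- max(m$solids$eid)
  lower_solids <- m$solids
  lower_solids$eid <- lower_solids$eid + e0
  lower_solids$pid <- 2L
  for (k in paste0("n", 1:8)) lower_solids[[k]] <- lower_solids[[k]] + n0
  # restore positive orientation after the z flip (swap bottom/top faces)
  tmp <- lower_solids[, paste0("n", 1:4)]
  lower_solids[, paste0("n", 1:4)] <- lower_solids[, paste0("n", 5:8)]
  lower_solids[, paste0("n", 5:8)] <- tmp
  fe_model(rbind(m$nodes, lower_nodes), rbind(m$solids, lower_solids),
           parts = data.frame(pid = 1:2, title = c("upper", "fore")))
}

test_that("ball centres and hinge axes are fitted from node sets", {
  # spherical node set embedded in a model
  set.seed(14)
  dirs <- matrix(stats::rnorm(240), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  sph <- sweep(15 * dirs, 2, c(0, 0, 60), `+`)
  nodes <- data.frame(id = seq_len(nrow(sph) + 1),
                      x = c(sph[, 1], 0), y = c(sph[, 2], 0),
                      z = c(sph[, 3], 0))
  shells <- data.frame(eid = 1L, pid = 1L, n1 = 1L, n2 = 2L, n3 = 3L,
                       n4 = NA_integer_)
  model <- fe_model(nodes, shells = shells,
                    parts = data.frame(pid = 1L, title = "p"),
                    node_sets = list("10" = seq_len(nrow(sph))))
  cfg <- list(joints = list(
    shoulder = list(type = "ball", surface_set = "10", driven_parts = 1L)))
  defs <- build_joint_definitions(model, cfg)
  expect_equal(defs$shoulder$center, c(0, 0, 60), tolerance = 1e-6)
  expect_equal(defs$shoulder$fitted_radius, 15, tolerance = 1e-6)
  # trochlear-notch style cylinder set
  th <- stats::runif(300, -pi / 3, pi / 3)
  zc <- stats::runif(300, -8, 8)
  cyl <- cbind(zc, 9 * cos(th), 9 * sin(th)) +
    0.05 * matrix(stats::rnorm(900), ncol = 3)
  nodes2 <- data.frame(id = seq_len(nrow(cyl)), x = cyl[, 1], y = cyl[, 2],
                       z = cyl[, 3])
  model2 <- fe_model(nodes2,
                     shells = data.frame(eid = 1L, pid = 1L, n1 = 1L,
                                         n2 = 2L, n3 = 3L, n4 = NA_integer_),
                     parts = data.frame(pid = 1L, title = "p"),
                     node_sets = list("11" = nodes2$id))
  cfg2 <- list(joints = list(
    elbow = list(type = "hinge", surface_set = "11", driven_parts = 1L)))
  defs2 <- build_joint_definitions(model2, cfg2)
  expect_lt(acos(min(1, abs(defs2$elbow$axis[1]))), 0.5 * pi / 180)
  expect_equal(defs2$elbow$fitted_radius, 9, tolerance = 0.1)
})

test_that("posing an undefined joint fails with its name", {
  m <- two_part_model()
  defs <- build_joint_definitions(m, list(joints = list(
    elbow = list(type = "hinge", axis = c(0, 1, 0), center = c(0, 0, 0),
                 driven_parts = 2L))))
  expect_error(reconfigure_skeleton(m, defs, list(hip_L = 30)), "hip_L")
})

test_that("vertebra_center averages the top and bottom face centroids", {
  m <- hex_block_model(2, 2, 2)
  top <- m$nodes$id[m$nodes$z == 2]
  bot <- m$nodes$id[m$nodes$z == 0]
  ctr <- vertebra_center(m, 1L, top, bot)
  expect_equal(ctr, c(1, 1, 1))
  # single-node sets: midpoint of the two nodes
  expect_equal(vertebra_center(m, 1L, top[1], bot[5]),
               (node_coords(m, top[1]) + node_coords(m, bot[5])) / 2,
               ignore_attr = TRUE)
  expect_error(vertebra_center(m, 1L, integer(), bot), "empty")
})

test_that("spine transforms split evenly and chain caudal to cranial", {
  centers <- cbind(0, 0, seq(0, 40, by = 10))  # 5 vertebrae along z
  st <- spine_transforms(centers, list(axis = c(0, 1, 0), angle = 25))
  # cranial-most cumulative rotation is the full 25 degrees
  aa <- arthropose:::rotation_angle_axis(st[[5]]$rotation)
  expect_equal(aa$angle, 25, tolerance = 1e-9)
  # zero rotation -> identities
  st0 <- spine_transforms(centers, list(axis = c(0, 1, 0), angle = 0))
  for (s in st0) expect_equal(s$rotation, diag(3), tolerance = 1e-12)
  # brute-force sequential application oracle for the cranial-most centre
  totals <- list(axis = c(0, 1, 0), angle = 90)
  st90 <- spine_transforms(centers, totals)
  p <- centers[5, ]
  Tacc <- rigid_transform()
  for (k in 1:5) {
    ck <- as.numeric(apply_transform(Tacc, centers[k, ]))
    ax <- as.numeric(c(0, 1, 0) %*% t(Tacc$rotation))
    Tacc <- compose_transform(rodrigues(ax, 18, ck), Tacc)
  }
  expect_equal(apply_transform(st90[[5]], p), apply_transform(Tacc, p),
               tolerance = 1e-9)
})

test_that("zero pose leaves every part transform at identity", {
  fx <- toy_limb_fx()
  defs <- build_joint_definitions(fx$model, fx$config)
  tr <- reconfigure_skeleton(fx$model, defs, list())
  for (tf in tr) {
    expect_equal(tf$rotation, diag(3))
    expect_equal(tf$translation, c(0, 0, 0))
  }
})

test_that("elbow flexion rotates the forearm only, about the fitted axis", {
  m <- two_part_model()
  defs <- build_joint_definitions(m, list(joints = list(
    elbow = list(type = "hinge", axis = c(0, 1, 0), center = c(0, 0, 0),
                 driven_parts = 2L))))
  tr <- reconfigure_skeleton(m, defs, list(elbow = 90))
  expect_equal(tr[["1"]]$rotation, diag(3))
  expect_equal(tr[["2"]]$rotation, rodrigues(c(0, 1, 0), 90)$rotation,
               tolerance = 1e-12)
  out <- apply_part_transforms(m, tr)
  # forearm tip (0,0,-50) swings to (-50,0,0) under +90 about y
  tip <- out$nodes[which.min(m$nodes$z), ]
  expect_equal(unname(unlist(tip[c("x", "y", "z")])),
               as.numeric(apply_transform(rodrigues(c(0, 1, 0), 90),
                                          c(-1, -1, -50))), tolerance = 1e-9)
})

test_that("hip + knee chain equals brute-force sequential transformation", {
  fx <- toy_limb_fx()
  defs <- build_joint_definitions(fx$model, fx$config)
  pose <- list(hip = c(0, 30, 0), knee = 10)
  tr <- reconfigure_skeleton(fx$model, defs, pose, step = 1)
  # brute force: apply the hip rotation, recompute the knee trajectory in
  # the moved frame, compose
  hipR <- euler_intrinsic(0, 30, 0)
  hip_tf <- local({
    ctr <- defs$hip$center
    rigid_transform(hipR, ctr - as.numeric(hipR %*% ctr))
  })
  g_moved <- knee_geometry(
    transform_mesh(defs$knee$condyle_medial, hip_tf),
    transform_mesh(defs$knee$condyle_lateral, hip_tf),
    plateau_plane(as.numeric(apply_transform(hip_tf, defs$knee$plateau_medial$point)),
                  as.numeric(defs$knee$plateau_medial$normal %*% t(hip_tf$rotation))),
    plateau_plane(as.numeric(apply_transform(hip_tf, defs$knee$plateau_lateral$point)),
                  as.numeric(defs$knee$plateau_lateral$normal %*% t(hip_tf$rotation))))
  traj <- compute_flexion_trajectory(g_moved, 10, step = 1)
  expected <- compose_transform(traj$composed_transform, hip_tf)
  got <- tr[["2"]]
  expect_equal(got$rotation, expected$rotation, tolerance = 1e-9)
  expect_equal(got$translation, expected$translation, tolerance = 1e-6)
})

test_that("bone transforms are exact isometries", {
  fx <- toy_limb_fx()
  defs <- build_joint_definitions(fx$model, fx$config)
  tr <- reconfigure_skeleton(fx$model, defs, list(knee = 15), step = 1)
  out <- apply_part_transforms(fx$model, tr)
  ids <- unique(unlist(fx$model$solids[fx$model$solids$pid == 2,
                                       paste0("n", 1:8)]))[1:40]
  d0 <- stats::dist(node_coords(fx$model, ids))
  d1 <- stats::dist(node_coords(out, ids))
  expect_lt(max(abs(d1 - d0)) / max(d0), 1e-9)
})

test_that("knee pose replayed in reverse returns the tibia to its origin", {
  fx <- toy_limb_fx()
  defs <- build_joint_definitions(fx$model, fx$config)
  tr <- reconfigure_skeleton(fx$model, defs, list(knee = 20), step = 1)
  fwd <- tr[["2"]]
  # reverse: replay the recorded trajectory inverted, step by step
  traj <- attr(tr, "trajectories")$knee
  inv <- invert_trajectory(traj)
  total <- compose_transform(inv$composed_transform, fwd)
  pts <- node_coords(fx$model,
                     unique(unlist(fx$model$solids[fx$model$solids$pid == 2,
                                                   paste0("n", 1:8)])))
  back <- apply_transform(total, pts)
  expect_lt(max(sqrt(rowSums((back - pts)^2))), 1e-6)
})

test_that("mirrored model with mirrored pose gives mirrored positions", {
  m <- two_part_model()
  defs <- build_joint_definitions(m, list(joints = list(
    elbow = list(type = "hinge", axis = c(0, 1, 0), center = c(0, 0, 0),
                 driven_parts = 2L))))
  out <- apply_part_transforms(m, reconfigure_skeleton(m, defs,
                                                       list(elbow = 35)))
  # mirror about x = 0: the hinge axis y is preserved but handedness flips,
  # so the mirrored pose angle is -35; node positions must mirror exactly
  mm <- m
  mm$nodes$x <- -mm$nodes$x  # (element orientation flips too; irrelevant here)
  out2 <- apply_part_transforms(mm, reconfigure_skeleton(mm, defs,
                                                         list(elbow = -35)))
  expect_equal(out2$nodes$x, -out$nodes$x, tolerance = 1e-9)
  expect_equal(out2$nodes$y, out$nodes$y, tolerance = 1e-9)
  expect_equal(out2$nodes$z, out$nodes$z, tolerance = 1e-9)
})

test_that("joint config and pose files round trip", {
  cfg <- list(joints = list(elbow = list(type = "hinge", axis = c(0, 1, 0),
                                         center = c(1, 2, 3),
                                         driven_parts = 2L)))
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cfg, f, auto_unbox = TRUE, digits = NA)
  cfg2 <- read_joint_config(f)
  expect_equal(unlist(cfg2$joints$elbow$center), c(1, 2, 3),
               ignore_attr = TRUE)
  fp <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(knee = 40, hip = c(0, 30, 0)), fp,
                       auto_unbox = TRUE)
  pose <- read_pose(fp)
  expect_equal(pose$knee, 40)
  expect_equal(pose$hip, c(0, 30, 0))
})
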