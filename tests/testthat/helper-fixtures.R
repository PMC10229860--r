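# Shared fixtures, built once per test run (several are expensive).
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

sphere_knee_20 <- function() cached("sphere_knee_20", make_sphere_knee(R = 20, edge = 1))
cylinder_knee_20 <- function() cached("cylinder_knee_20", make_cylinder_knee(R = 20, length = 30, edge = 1))
toy_limb_fx <- function() cached("toy_limb", make_toy_limb())

toy_limb_reposed <- function() cached("toy_limb_reposed", {
  fx <- toy_limb_fx()
  joints <- build_joint_definitions(fx$model, fx$config)
  reposition(fx$model, joints, list(knee = 40))
})

# full morph-contact chain on the tube-capsule fixture (criterion 6 world)
tube_flow <- function() cached("tube_flow", {
  fx <- make_tube_capsule()
  seg <- segment_capsule(fx$capsule, fx$femur, fx$tibia)
  tf <- rodrigues(fx$truth$flexion_axis, 40, fx$truth$flexion_center)
  lm <- reduced_bone_landmarks(fx$femur, fx$tibia, rigid_transform(), tf)
  cap1 <- preliminary_morph(fx$capsule, lm, seg, rigid_transform(), tf)
  tib_post <- transform_mesh(fx$tibia, tf)
  rs <- list(femur = sign(mesh_signed_distance(fx$capsule, fx$femur$vertices)$signed),
             tibia = sign(mesh_signed_distance(fx$capsule, fx$tibia$vertices)$signed))
  fixed <- c(seg$proximal, seg$distal)
  cap2 <- cap1
  n_pen <- 0
  for (bp in list(list(post = fx$femur, rs = rs$femur),
                  list(post = tib_post, rs = rs$tibia))) {
    rp <- detect_penetrations(bp$post, cap2, bp$rs)
    n_pen <- n_pen + length(rp$nodes)
    if (length(rp$nodes)) cap2 <- resolve_penetrations(cap2, rp, fixed = fixed)
  }
  cap3 <- refine_interface(cap2, cap2, baseline = fx$capsule,
                           free = seg$interior)
  list(fx = fx, seg = seg, tf = tf, cap1 = cap1, cap2 = cap2, cap3 = cap3,
       tib_post = tib_post, ref_signs = rs, n_pen = n_pen)
})

# small structured helpers used across files ---------------------------------

# flat triangulated grid in the z = 0 plane
flat_grid_mesh <- function(n = 8, h = 1) {
  g <- expand.grid(x = 0:n, y = 0:n)
  verts <- cbind(g$x * h, g$y * h, 0)
  idx <- function(i, j) j * (n + 1) + i + 1
  faces <- NULL
  for (j in 0:(n - 1)) for (i in 0:(n - 1))
    faces <- rbind(faces,
                   c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
                   c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
  tri_mesh(verts, faces)
}

# uv sphere / cylinder strip via the package's fixture internals
uv_sphere <- function(R = 1, edge = 0.15, center = c(0, 0, 0))
  arthropose:::.uv_sphere_mesh(rep(R, 3), edge, center)

cyl_strip <- function(R = 2, L = 8, edge = 0.2)
  arthropose:::.cylinder_strip_mesh(R, -L / 2, L / 2, edge)

# single-hex FE model (unit cube, ids offset to exercise id mapping)
one_hex_model <- function(origin = c(0, 0, 0), scale = c(1, 1, 1)) {
  corners <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  # standard ordering: bottom 1-4 CCW, top 5-8
  ord <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
               c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  nd <- sweep(ord %*% diag(scale), 2, origin, `+`)
  nodes <- data.frame(id = 1:8, x = nd[, 1], y = nd[, 2], z = nd[, 3])
  solids <- data.frame(eid = 1L, pid = 1L, n1 = 1L, n2 = 2L, n3 = 3L,
                       n4 = 4L, n5 = 5L, n6 = 6L, n7 = 7L, n8 = 8L)
  fe_model(nodes, solids, parts = data.frame(pid = 1L, title = "hex"))
}

# block of nx x ny x nz unit hexes
hex_block_model <- function(nx = 1, ny = 1, nz = 1) {
  idx <- function(i, j, k) k * (nx + 1) * (ny + 1) + j * (nx + 1) + i + 1
  g <- expand.grid(i = 0:nx, j = 0:ny, k = 0:nz)
  g <- g[order(g$k, g$j, g$i), ]
  nodes <- data.frame(id = seq_len(nrow(g)), x = g$i, y = g$j, z = g$k)
  el <- list()
  for (k in 0:(nz - 1)) for (j in 0:(ny - 1)) for (i in 0:(nx - 1))
    el[[length(el) + 1]] <- c(idx(i, j, k), idx(i + 1, j, k),
                              idx(i + 1, j + 1, k), idx(i, j + 1, k),
                              idx(i, j, k + 1), idx(i + 1, j, k + 1),
                              idx(i + 1, j + 1, k + 1), idx(i, j + 1, k + 1))
  conn <- do.call(rbind, el)
  solids <- data.frame(eid = seq_len(nrow(conn)), pid = 1L)
  for (c_ in 1:8) solids[[paste0("n", c_)]] <- conn[, c_]
  fe_model(nodes, solids, parts = data.frame(pid = 1L, title = "block"))
}

# random rigid transform (seeded by caller)
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
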