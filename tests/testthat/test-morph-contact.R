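# capsule spheres for penetration tests: normals toward the contained bone
# (the capsule wall faces the joint cavity)
inward_sphere <- function(R, edge = 0.25) {
  m <- uv_sphere(R = R, edge = edge)
  tri_mesh(m$vertices, m$faces[, c(1, 3, 2)], normals = -m$normals)
}

test_that("segment_capsule matches brute-force distance classification", {
  fl <- tube_flow()
  fx <- fl$fx; seg <- fl$seg
  v <- fx$capsule$vertices
  df <- mesh_closest_point(fx$femur, v)$distance
  dt <- mesh_closest_point(fx$tibia, v)$distance
  # brute-force re-classification
  bf_prox <- which(df <= 1 & df <= dt)
  bf_dist <- setdiff(which(dt <= 1), bf_prox)
  expect_setequal(seg$proximal, bf_prox)
  expect_setequal(seg$distal, bf_dist)
  # inner wall (r ~ rb + gap, |z| < 35) is interior; outer wall exterior
  r <- sqrt(v[, 1]^2 + v[, 2]^2)
  wall_in <- which(abs(r - (fx$truth$rb + fx$truth$gap)) < 0.1 &
                     abs(v[, 3]) < 30)
  wall_out <- which(abs(r - fx$truth$r_out) < 0.1 & abs(v[, 3]) < 30)
  expect_true(all(wall_in %in% seg$interior))
  expect_true(all(wall_out %in% seg$exterior))
  # partition: disjoint and covering
  all_idx <- sort(c(seg$proximal, seg$distal, seg$interior, seg$exterior))
  expect_identical(all_idx, seq_len(nrow(v)))
})

test_that("segment_capsule with tol = 0 empties the attachment sets", {
  fx <- tube_flow()$fx
  seg0 <- segment_capsule(fx$capsule, fx$femur, fx$tibia, tol = 0)
  expect_length(seg0$proximal, 0)
  expect_length(seg0$distal, 0)
})

test_that("preliminary morph: identity and rigid-motion reproduction", {
  fl <- tube_flow()
  fx <- fl$fx; seg <- fl$seg
  id_lm <- reduced_bone_landmarks(fx$femur, fx$tibia)
  cap_id <- preliminary_morph(fx$capsule, id_lm, seg,
                              rigid_transform(), rigid_transform())
  expect_lt(max(abs(cap_id$vertices - fx$capsule$vertices)), 1e-8)
  # whole-joint rigid rotation: affine reproduction moves the capsule rigidly
  tf <- rodrigues(c(1, 1, 0) / sqrt(2), 25, c(5, 0, 3))
  lm <- reduced_bone_landmarks(fx$femur, fx$tibia, tf, tf)
  cap_r <- preliminary_morph(fx$capsule, lm, seg, tf, tf)
  expect_lt(max(abs(cap_r$vertices - apply_transform(tf, fx$capsule$vertices))),
            1e-6)
})

test_that("flexing the tube fixture produces penetrations (contact needed)", {
  fl <- tube_flow()
  expect_gte(fl$n_pen, 1)
})

test_that("detect_penetrations matches brute-force signed distances", {
  capsule <- inward_sphere(1.0)
  bone_in <- uv_sphere(R = 0.8, edge = 0.2)
  expect_length(detect_penetrations(bone_in, capsule)$nodes, 0)
  bone_out <- uv_sphere(R = 1.2, edge = 0.2)
  rep_ <- detect_penetrations(bone_out, capsule)
  # brute force: every bone node lies at radius 1.2 > 1.0 -> all penetrate
  expect_setequal(rep_$nodes, seq_len(nrow(bone_out$vertices)))
  # depths ~ 0.2 (slightly more against the faceted capsule chords)
  expect_equal(mean(-rep_$depths), 0.2, tolerance = 0.05)
  # grazing: the capsule's own vertices pushed 5e-7 past the wall -> below
  # the 1e-6 detection tolerance, report stays empty
  graze <- list(vertices = capsule$vertices - 5e-7 * capsule$normals)
  expect_length(detect_penetrations(graze, capsule)$nodes, 0)
})

test_that("resolve_penetrations clears the sphere overlap", {
  capsule <- inward_sphere(1.0, edge = 0.15)
  bone <- uv_sphere(R = 1.2, edge = 0.3)
  rep_ <- detect_penetrations(bone, capsule)
  fixed_cap <- resolve_penetrations(capsule, rep_)
  expect_length(detect_penetrations(bone, fixed_cap)$nodes, 0)
  # max displacement ~ depth + clearance (within 20%)
  disp <- max(sqrt(rowSums((fixed_cap$vertices - capsule$vertices)^2)))
  expect_lt(abs(disp - (0.2 + 0.1)) / 0.3, 0.2)
  # empty report: unchanged; idempotence on the clean configuration
  empty <- detect_penetrations(bone, fixed_cap)
  expect_identical(resolve_penetrations(fixed_cap, empty)$vertices,
                   fixed_cap$vertices)
})

test_that("refinement is near-stationary on an already-smooth capsule", {
  fx <- tube_flow()$fx
  seg <- tube_flow()$seg
  out <- refine_interface(fx$capsule, fx$capsule, baseline = fx$capsule,
                          free = seg$interior, max_iter = 60)
  expect_lt(max(sqrt(rowSums((out$vertices - fx$capsule$vertices)^2))), 0.05)
})

test_that("refinement halves oscillation while staying on the target shape", {
  fx <- tube_flow()$fx
  seg <- tube_flow()$seg
  clean <- fx$capsule
  pert <- clean
  sel <- seg$interior[seq(1, length(seg$interior), by = 2)]
  sel2 <- setdiff(seg$interior, sel)
  pv <- pert$vertices
  pv[sel, ] <- pv[sel, ] + 0.3 * clean$normals[sel, ]
  pv[sel2, ] <- pv[sel2, ] - 0.3 * clean$normals[sel2, ]
  pert <- tri_mesh(pv, pert$faces)
  cv_before <- edge_length_cv(pert, clean, seg$interior)
  out <- refine_interface(pert, clean, baseline = clean, free = seg$interior)
  cv_after <- edge_length_cv(out, clean, seg$interior)
  expect_lt(cv_after, 0.5 * cv_before)
  expect_lt(chamfer_distance(out, clean), 0.2)
})

test_that("refinement never moves the attachment nodes", {
  fl <- tube_flow()
  att <- c(fl$seg$proximal, fl$seg$distal)
  expect_identical(fl$cap3$vertices[att, ], fl$cap2$vertices[att, ])
})

test_that("penetration freedom survives refinement on the resolved fixture", {
  fl <- tube_flow()
  expect_length(detect_penetrations(fl$tib_post, fl$cap3,
                                    fl$ref_signs$tibia)$nodes, 0)
  expect_length(detect_penetrations(fl$fx$femur, fl$cap3,
                                    fl$ref_signs$femur)$nodes, 0)
})

test_that("deform_soft_tissue: identity and rigid-motion landmark cases", {
  fx <- toy_limb_fx()
  m <- fx$model
  bone <- extract_surface(m, 1)
  lm_id <- list(source = bone$vertices, target = bone$vertices,
                node_ids = bone$source_node_ids)
  out <- deform_soft_tissue(m, lm_id, 3)
  expect_lt(max(abs(as.matrix(out$nodes[, c("x", "y", "z")]) -
                    as.matrix(m$nodes[, c("x", "y", "z")]))), 1e-8)
  tf <- rodrigues(c(0, 0, 1), 30, c(1, 2, 3))
  lm_r <- list(source = bone$vertices,
               target = apply_transform(tf, bone$vertices),
               node_ids = bone$source_node_ids)
  out_r <- deform_soft_tissue(m, lm_r, 3)
  flesh_ids <- unique(unlist(m$solids[m$solids$pid == 3, paste0("n", 1:8)]))
  expect_lt(max(abs(node_coords(out_r, flesh_ids) -
                    apply_transform(tf, node_coords(m, flesh_ids)))), 1e-6)
})

test_that("segmentation is invariant to vertex-order permutation", {
  fx <- tube_flow()$fx
  set.seed(33)
  p <- sample(nrow(fx$capsule$vertices))
  inv <- integer(length(p)); inv[p] <- seq_along(p)
  cap_p <- tri_mesh(fx$capsule$vertices[p, ],
                    matrix(inv[fx$capsule$faces], ncol = 3),
                    normals = fx$capsule$normals[p, ])
  seg1 <- segment_capsule(fx$capsule, fx$femur, fx$tibia)
  seg2 <- segment_capsule(cap_p, fx$femur, fx$tibia)
  expect_setequal(p[seg2$interior], seg1$interior)
  expect_setequal(p[seg2$proximal], seg1$proximal)
})
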