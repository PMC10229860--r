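# Analytic synthetic fixtures with known ground truth. Vertices are placed
# exactly on the analytic surfaces (no post-smoothing) so the curvature and
# trajectory oracles are clean. Everything is deterministic given the
# parameters; seeds are recorded for the stages that sample.

# UV (lat/long) sphere or ellipsoid mesh; poles on the +-z axis so the
# bottom pole vertex is an exact support point. Semi-axes (a, b, c).
.uv_sphere_mesh <- function(abc, edge, center = c(0, 0, 0)) {
  a <- abc[1]; b <- abc[2]; c_ <- abc[3]
  rmean <- mean(abc)
  nlat <- max(8L, ceiling(pi * rmean / edge))
  nlon <- max(12L, ceiling(2 * pi * rmean / edge))
  th <- seq(0, pi, length.out = nlat + 1)
  ph <- seq(0, 2 * pi, length.out = nlon + 1)[-(nlon + 1)]
  verts <- rbind(c(0, 0, c_))
  for (i in 2:nlat)
    verts <- rbind(verts, cbind(a * sin(th[i]) * cos(ph),
                                b * sin(th[i]) * sin(ph),
                                c_ * cos(th[i])))
  verts <- rbind(verts, c(0, 0, -c_))
  idx <- function(i, j) 1 + (i - 2) * nlon + ((j - 1) %% nlon) + 1
  faces <- vector("list", nlat)
  faces[[1]] <- cbind(1, vapply(1:nlon, function(j) idx(2, j), 0),
                      vapply(1:nlon, function(j) idx(2, j + 1), 0))
  for (i in 2:(nlat - 1)) {
    j <- 1:nlon
    faces[[i]] <- rbind(cbind(idx(2, 1) * 0 + mapply(idx, i, j),
                              mapply(idx, i + 1, j), mapply(idx, i + 1, j + 1)),
                        cbind(mapply(idx, i, j), mapply(idx, i + 1, j + 1),
                              mapply(idx, i, j + 1)))
  }
  last <- nrow(verts)
  faces[[nlat]] <- cbind(last, vapply(1:nlon, function(j) idx(nlat, j + 1), 0),
                         vapply(1:nlon, function(j) idx(nlat, j), 0))
  # analytic outward normals (ellipsoid gradient), exact like the vertices
  nrm <- .normalize_rows(cbind(verts[, 1] / a^2, verts[, 2] / b^2,
                               verts[, 3] / c_^2))
  tri_mesh(sweep(verts, 2, center, `+`), do.call(rbind, faces), normals = nrm)
}

# Open cylindrical strip, axis along +y through (x0, z0), radius R,
# angular range +-phi_half around the bottom (-z) direction.
.cylinder_strip_mesh <- function(R, y0, y1, edge, phi_half = pi / 3,
                                 x0 = 0, z0 = R) {
  ny <- max(4L, ceiling((y1 - y0) / edge))
  nphi <- max(8L, ceiling(2 * phi_half * R / edge))
  ys <- seq(y0, y1, length.out = ny + 1)
  phis <- seq(-phi_half, phi_half, length.out = nphi + 1)
  verts <- NULL
  for (y in ys)
    verts <- rbind(verts, cbind(x0 + R * sin(phis), y, z0 - R * cos(phis)))
  np <- nphi + 1
  idx <- function(i, j) (i - 1) * np + j
  faces <- NULL
  for (i in 1:ny) {
    j <- 1:nphi
    faces <- rbind(faces,
                   cbind(idx(i, j), idx(i, j + 1), idx(i + 1, j + 1)),
                   cbind(idx(i, j), idx(i + 1, j + 1), idx(i + 1, j)))
  }
  # analytic outward (radial) normals
  nrm <- .normalize_rows(cbind(verts[, 1] - x0, 0, verts[, 3] - z0))
  m <- tri_mesh(verts, faces, normals = nrm)
  fn <- face_normals(verts, faces)$normals
  if (mean(rowSums(fn * nrm[faces[, 1], , drop = FALSE])) < 0)
    m <- tri_mesh(verts, faces[, c(1, 3, 2)], normals = nrm)
  m
}

# Closed surface of revolution about the z axis from a closed (r, z)
# profile polyline (all r > 0); oriented with positive enclosed volume.
.revolve_mesh <- function(profile, nseg) {
  npf <- nrow(profile)
  ph <- seq(0, 2 * pi, length.out = nseg + 1)[-(nseg + 1)]
  verts <- NULL
  for (k in seq_len(npf))
    verts <- rbind(verts, cbind(profile[k, 1] * cos(ph),
                                profile[k, 1] * sin(ph), profile[k, 2]))
  idx <- function(k, j) (k - 1) * nseg + ((j - 1) %% nseg) + 1
  faces <- NULL
  for (k in seq_len(npf)) {
    k2 <- (k %% npf) + 1
    j <- 1:nseg
    faces <- rbind(faces,
                   cbind(mapply(idx, k, j), mapply(idx, k2, j),
                         mapply(idx, k2, j + 1)),
                   cbind(mapply(idx, k, j), mapply(idx, k2, j + 1),
                         mapply(idx, k, j + 1)))
  }
  m <- tri_mesh(verts, faces)
  if (mesh_signed_volume(m) < 0)
    m <- tri_mesh(m$vertices, m$faces[, c(1, 3, 2)])
  m
}

# resample a polyline at ~spacing h (keeps original corners)
.resample_polyline <- function(pts, h) {
  out <- pts[1, , drop = FALSE]
  for (k in 2:nrow(pts)) {
    seg <- pts[k, ] - pts[k - 1, ]
    len <- sqrt(sum(seg^2))
    n <- max(1L, ceiling(len / h))
    for (s in seq_len(n)) out <- rbind(out, pts[k - 1, ] + seg * s / n)
  }
  out[-nrow(out), , drop = FALSE]  # closed: drop duplicate of first point
}

# Closed cylinder (side + fan caps), axis z, oriented outward.
.closed_cylinder_mesh <- function(R, z0, z1, edge) {
  nz <- max(2L, ceiling((z1 - z0) / edge))
  nc <- max(12L, ceiling(2 * pi * R / edge))
  zs <- seq(z0, z1, length.out = nz + 1)
  ph <- seq(0, 2 * pi, length.out = nc + 1)[-(nc + 1)]
  verts <- NULL
  for (z in zs) verts <- rbind(verts, cbind(R * cos(ph), R * sin(ph), z))
  idx <- function(i, j) (i - 1) * nc + ((j - 1) %% nc) + 1
  faces <- NULL
  for (i in 1:nz) {
    j <- 1:nc
    faces <- rbind(faces,
                   cbind(mapply(idx, i, j), mapply(idx, i, j + 1),
                         mapply(idx, i + 1, j + 1)),
                   cbind(mapply(idx, i, j), mapply(idx, i + 1, j + 1),
                         mapply(idx, i + 1, j)))
  }
  cb <- nrow(verts) + 1L  # bottom centre
  ct <- nrow(verts) + 2L  # top centre
  verts <- rbind(verts, c(0, 0, z0), c(0, 0, z1))
  j <- 1:nc
  faces <- rbind(faces,
                 cbind(cb, mapply(idx, 1, j + 1), mapply(idx, 1, j)),
                 cbind(ct, mapply(idx, nz + 1, j), mapply(idx, nz + 1, j + 1)))
  m <- tri_mesh(verts, faces)
  if (mesh_signed_volume(m) < 0)
    m <- tri_mesh(m$vertices, m$faces[, c(1, 3, 2)])
  m
}

.check_fixture_dims <- function(dims, edge) {
  if (any(dims <= 0) || edge <= 0) .stopf("fixture: dimensions must be > 0")
  if (edge >= min(dims) / 4)
    .stopf("fixture: mesh edge length must be < smallest radius / 4")
}

#' Sphere-on-plane knee fixture
#'
#' Two spherical condyles of radius `R` (medial/lateral centres 4R apart
#' along y) over tangent plateau planes. The analytic truth (osculating
#' radius R in every direction, flexion axis through the centres) is
#' attached in `$truth`.
#'
#' @param R condyle radius (mm). @param gap initial plateau clearance (mm).
#' @param edge target mesh edge length (mm).
#' @return a `knee_geometry` with `$truth` (centres, radius, axis).
#' @export
make_sphere_knee <- function(R = 20, gap = 0, edge = 1) {
  .check_fixture_dims(R, edge)
  c_m <- c(0, -2 * R, R)
  c_l <- c(0, 2 * R, R)
  cm <- .uv_sphere_mesh(c(R, R, R), edge, c_m)
  cl <- .uv_sphere_mesh(c(R, R, R), edge, c_l)
  knee_geometry(cm, cl,
                plateau_plane(c(0, -2 * R, -gap), c(0, 0, 1)),
                plateau_plane(c(0, 2 * R, -gap), c(0, 0, 1)),
                truth = list(kind = "sphere_knee", radius = R,
                             center_medial = c_m, center_lateral = c_l,
                             axis_dir = c(0, 1, 0)))
}

#' Coaxial-cylinder (hinge-limit) knee fixture
#'
#' Two cylindrical condyle strips of radius `R` on a common axis parallel to
#' y; the trajectory degenerates to a fixed hinge about that axis.
#'
#' @param R cylinder radius (mm). @param length strip length (mm).
#' @param edge target mesh edge length (mm).
#' @return a `knee_geometry` with `$truth` (axis point/direction, radius).
#' @export
make_cylinder_knee <- function(R = 20, length = 30, edge = 1) {
  .check_fixture_dims(c(R, length), edge)
  cm <- .cylinder_strip_mesh(R, -1.5 * length, -0.5 * length, edge)
  cl <- .cylinder_strip_mesh(R, 0.5 * length, 1.5 * length, edge)
  knee_geometry(cm, cl,
                plateau_plane(c(0, -length, 0), c(0, 0, 1)),
                plateau_plane(c(0, length, 0), c(0, 0, 1)),
                truth = list(kind = "cylinder_knee", radius = R,
                             axis_point = c(0, 0, R), axis_dir = c(0, 1, 0)))
}

#' Ellipsoidal knee fixture (varying helical axis)
#'
#' Ellipsoidal condyles with semi-axes (a, b, c); the instantaneous axis
#' varies along the trajectory for a != b. Analytic normal curvature at the
#' bottom pole: c/a^2 along the x tangent, c/b^2 along y.
#'
#' @param a,b,c semi-axes (mm) per compartment.
#' @param edge target mesh edge length (mm).
#' @return a `knee_geometry` with `$truth`.
#' @export
make_ellipsoid_knee <- function(a = 25, b = 20, c = 18, edge = 1,
                                lateral_scale = 1) {
  .check_fixture_dims(c(a, b, c), edge)
  # identical (translated) compartments keep the axis direction exactly
  # constant by symmetry; a lateral_scale != 1 mimics the smaller lateral
  # condyle and makes the instantaneous axis direction vary with flexion
  al <- lateral_scale * a; bl <- lateral_scale * b; cl_ <- lateral_scale * c
  c_m <- c(0, -2 * b, c)
  c_l <- c(0, 2 * b, cl_)
  cm <- .uv_sphere_mesh(c(a, b, c), edge, c_m)
  cl <- .uv_sphere_mesh(c(al, bl, cl_), edge, c_l)
  knee_geometry(cm, cl,
                plateau_plane(c(0, -2 * b, 0), c(0, 0, 1)),
                plateau_plane(c(0, 2 * b, 0), c(0, 0, 1)),
                truth = list(kind = "ellipsoid_knee", abc = c(a, b, c),
                             center_medial = c_m, center_lateral = c_l,
                             kn_pole_x = c / a^2, kn_pole_y = c / b^2))
}

#' Tube-capsule contact fixture
#'
#' Two coaxial closed bone cylinders (radius `rb`) separated by a joint
#' space, wrapped by a closed capsule surface of revolution: attachment
#' rings on each bone, an inner wall at `rb + gap`, and an outer wall at
#' `r_out`. The capsule is oriented outward from the flesh volume it
#' bounds, i.e. inner-wall normals point at the bones.
#'
#' @param rb bone radius (mm). @param gap inner-wall clearance (mm).
#' @param r_out outer wall radius (mm). @param edge mesh edge length (mm).
#' @return list with `capsule`, `femur`, `tibia` (`tri_mesh`es) and `truth`.
#' @export
make_tube_capsule <- function(rb = 10, gap = 2, r_out = 18, edge = 2) {
  if (gap <= 0) .stopf("fixture: dimensions must be > 0")
  .check_fixture_dims(c(rb, r_out), edge)
  femur <- .closed_cylinder_mesh(rb, 5, 60, edge)
  tibia <- .closed_cylinder_mesh(rb, -60, -5, edge)
  prof <- rbind(c(rb, 40), c(rb + gap, 35), c(rb + gap, -35), c(rb, -40),
                c(r_out, -35), c(r_out, 35))
  prof <- .resample_polyline(rbind(prof, prof[1, ]), edge)
  nseg <- max(16L, ceiling(2 * pi * r_out / edge))
  capsule <- .revolve_mesh(prof, nseg)
  list(capsule = capsule, femur = femur, tibia = tibia,
       truth = list(rb = rb, gap = gap, r_out = r_out,
                    attach_z = c(40, -40), inner_z = c(35, -35),
                    # knee-like flexion: instant axis through the condylar
                    # region of the proximal bone, above the joint line
                    flexion_axis = c(0, 1, 0),
                    flexion_center = c(0, 0, 20)))
}

# O-grid cross-section: square core grid morphing to a circle of radius rb.
# Returns pts (n x 2), quads (m x 4, CCW), boundary (ordered indices of the
# outer circle ring, at equally spaced angles starting at theta = 0).
.ogrid_section <- function(rb, n_core = 3, n_ring = 1, core_frac = 0.6) {
  a <- rb * core_frac
  g <- 2 * n_core + 1
  xs <- seq(-a, a, length.out = g)
  pts <- as.matrix(expand.grid(x = xs, y = xs))  # x fastest
  pid <- function(i, j) (j - 1) * g + i          # i = x index, j = y index
  quads <- NULL
  for (j in 1:(g - 1)) for (i in 1:(g - 1))
    quads <- rbind(quads, c(pid(i, j), pid(i + 1, j),
                            pid(i + 1, j + 1), pid(i, j + 1)))
  # square boundary ordered CCW starting at (a, 0)
  mid <- n_core + 1
  right <- vapply(mid:g, function(j) pid(g, j), 0)
  top <- vapply((g - 1):1, function(i) pid(i, g), 0)
  left <- vapply((g - 1):1, function(j) pid(1, j), 0)
  bot <- vapply(2:g, function(i) pid(i, 1), 0)
  right2 <- vapply(2:(mid - 1), function(j) pid(g, j), 0)
  loop <- c(right, top, left, bot, right2)
  nb <- length(loop)  # = 8 * n_core
  theta <- 2 * pi * (seq_len(nb) - 1) / nb
  ring_pts <- NULL
  ring_idx <- matrix(0L, n_ring, nb)
  nxt <- nrow(pts)
  for (k in seq_len(n_ring)) {
    t <- k / n_ring
    circ <- cbind(rb * cos(theta), rb * sin(theta))
    lev <- (1 - t) * pts[loop, , drop = FALSE] + t * circ
    ring_pts <- rbind(ring_pts, lev)
    ring_idx[k, ] <- nxt + seq_len(nb)
    nxt <- nxt + nb
  }
  pts <- rbind(pts, ring_pts)
  lev_idx <- rbind(loop, ring_idx)
  for (k in seq_len(n_ring)) {
    for (j in seq_len(nb)) {
      j2 <- (j %% nb) + 1
      # wound radially-out first so the quad stays CCW in the xy plane
      quads <- rbind(quads, c(lev_idx[k, j], lev_idx[k + 1, j],
                              lev_idx[k + 1, j2], lev_idx[k, j2]))
    }
  }
  list(pts = pts, quads = quads, boundary = ring_idx[n_ring, ],
       n_boundary = nb)
}

#' Toy limb FE fixture
#'
#' A desk-scale stand-in for a lower limb: two hexahedral bone cylinders
#' (femur above, tibia below) joined by a knee joint space, a shared-node
#' flesh annulus spanning the whole limb, a quad-shell capsule on the
#' bone/flesh interface around the joint, and an outer skin shell. Analytic
#' spherical condyles and tangent plateau planes (not FE elements, exactly
#' as segmented articular surfaces would be) are emitted in the joint
#' config, together with truth values. The baseline mesh passes all quality
#' thresholds.
#'
#' @param rb bone radius (mm). @param r_skin outer skin radius (mm).
#' @param half_len half limb length (mm). @param z_gap joint half-space (mm).
#' @param condyle_R condyle sphere radius (mm).
#' @param condyle_sep lateral half-separation of condyle centres (mm).
#' @param edge target condyle mesh edge (mm). @param seed recorded seed.
#' @return list with `model` (`fe_model`), `config` (joint definitions
#'   input), `truth` (construction record).
#' @export
make_toy_limb <- function(rb = 10, r_skin = 22, half_len = 110, z_gap = 8,
                          condyle_R = 12, condyle_sep = 6, edge = 1.2,
                          seed = 0) {
  .check_fixture_dims(c(rb, r_skin - rb, condyle_R), edge)
  sec <- .ogrid_section(rb)
  nb <- sec$n_boundary                       # 24 sectors
  theta <- 2 * pi * (seq_len(nb) - 1) / nb
  z_bone <- seq(z_gap, half_len, length.out = 20)
  z_gapst <- seq(-z_gap, z_gap, length.out = 4)
  stations <- sort(unique(round(c(-rev(z_bone), z_gapst, z_bone), 10)))
  ns <- length(stations)
  is_bone <- abs(stations) >= z_gap - 1e-9
  cap_half <- max(stations[stations <= 35 + 1e-9])  # capsule axial extent
  # flesh inner radius stands off the bone by `standoff` near the joint
  # (synovial space), returning to the bone surface at the attachment rings
  standoff <- 2; detach_z <- 32; ramp <- 6
  r_inner <- function(z)
    rb + standoff * pmin(1, pmax(0, (detach_z - abs(z)) / ramp))

  nodes <- list(); nid <- 0L
  bone_ids <- vector("list", ns)   # full bone-section node ids
  inner_ids <- vector("list", ns)  # flesh inner-surface ring (capsule wall)
  flesh_ids <- vector("list", ns)  # 3 x 24 ids of outer flesh levels
  for (s in seq_len(ns)) {
    z <- stations[s]
    ri <- r_inner(z)
    if (is_bone[s]) {
      ids <- nid + seq_len(nrow(sec$pts))
      nodes[[length(nodes) + 1]] <- cbind(ids, sec$pts[, 1], sec$pts[, 2], z)
      nid <- nid + nrow(sec$pts)
      bone_ids[[s]] <- ids
    }
    if (is_bone[s] && ri <= rb + 1e-9) {
      inner_ids[[s]] <- bone_ids[[s]][sec$boundary]  # attached: shared nodes
    } else {
      ids <- nid + seq_len(nb)
      nodes[[length(nodes) + 1]] <- cbind(ids, ri * cos(theta),
                                          ri * sin(theta), z)
      nid <- nid + nb
      inner_ids[[s]] <- ids
    }
    radii <- seq(ri, r_skin, length.out = 4)
    ids <- nid + seq_len(3 * nb)
    fl <- NULL
    for (k in 2:4) fl <- rbind(fl, cbind(radii[k] * cos(theta),
                                         radii[k] * sin(theta)))
    nodes[[length(nodes) + 1]] <- cbind(ids, fl[, 1], fl[, 2], z)
    nid <- nid + 3 * nb
    flesh_ids[[s]] <- matrix(ids, nrow = 3, byrow = TRUE)
  }
  nd <- do.call(rbind, nodes)
  nodes_df <- data.frame(id = as.integer(nd[, 1]), x = nd[, 2], y = nd[, 3],
                         z = nd[, 4])

  solids <- list(); eid <- 0L
  add_solid <- function(pid, lower4, upper4) {
    eid <<- eid + 1L
    solids[[length(solids) + 1L]] <<- c(eid, pid, lower4, upper4)
  }
  femur_layers <- which(is_bone & stations >= z_gap - 1e-9)
  tibia_layers <- which(is_bone & stations <= -z_gap + 1e-9)
  for (pid_spec in list(list(pid = 1L, st = femur_layers),
                        list(pid = 2L, st = tibia_layers))) {
    st <- pid_spec$st
    for (q in seq_len(length(st) - 1)) {
      lo <- bone_ids[[st[q]]]; hi <- bone_ids[[st[q + 1]]]
      for (e in seq_len(nrow(sec$quads)))
        add_solid(pid_spec$pid, lo[sec$quads[e, ]], hi[sec$quads[e, ]])
    }
  }
  ring4 <- function(idlev, j) {
    j2 <- (j %% nb) + 1
    c(idlev$in_[j], idlev$out[j], idlev$out[j2], idlev$in_[j2])
  }
  for (s in seq_len(ns - 1)) {
    for (k in 1:3) {
      lo_in <- if (k == 1) inner_ids[[s]] else flesh_ids[[s]][k - 1, ]
      lo_out <- flesh_ids[[s]][k, ]
      hi_in <- if (k == 1) inner_ids[[s + 1]] else flesh_ids[[s + 1]][k - 1, ]
      hi_out <- flesh_ids[[s + 1]][k, ]
      for (j in seq_len(nb))
        add_solid(3L,
                  ring4(list(in_ = lo_in, out = lo_out), j),
                  ring4(list(in_ = hi_in, out = hi_out), j))
    }
  }
  solid_m <- do.call(rbind, solids)
  solids_df <- data.frame(eid = as.integer(solid_m[, 1]),
                          pid = as.integer(solid_m[, 2]))
  for (k in 1:8) solids_df[[paste0("n", k)]] <- as.integer(solid_m[, 2 + k])

  shells <- list(); seid <- 100000L
  cap_st <- which(abs(stations) <= cap_half + 1e-9)
  for (q in seq_len(length(cap_st) - 1)) {
    lo <- inner_ids[[cap_st[q]]]; hi <- inner_ids[[cap_st[q + 1]]]
    for (j in seq_len(nb)) {
      j2 <- (j %% nb) + 1
      seid <- seid + 1L
      # wound so the shell normal points at the bone axis (outward from flesh)
      shells[[length(shells) + 1]] <- c(seid, 4L, lo[j], hi[j], hi[j2], lo[j2])
    }
  }
  for (s in seq_len(ns - 1)) {
    lo <- flesh_ids[[s]][3, ]; hi <- flesh_ids[[s + 1]][3, ]
    for (j in seq_len(nb)) {
      j2 <- (j %% nb) + 1
      seid <- seid + 1L
      shells[[length(shells) + 1]] <- c(seid, 5L, lo[j], lo[j2], hi[j2], hi[j])
    }
  }
  shell_m <- do.call(rbind, shells)
  shells_df <- data.frame(eid = as.integer(shell_m[, 1]),
                          pid = as.integer(shell_m[, 2]))
  for (k in 1:4) shells_df[[paste0("n", k)]] <- as.integer(shell_m[, 2 + k])

  parts <- data.frame(pid = 1:5,
                      title = c("femur", "tibia", "flesh", "knee capsule",
                                "skin"))
  node_sets <- list(
    "1" = as.integer(unlist(inner_ids[cap_st])),                 # capsule
    "2" = as.integer(bone_ids[[femur_layers[1]]]),               # femur distal face
    "3" = as.integer(bone_ids[[tibia_layers[length(tibia_layers)]]]))

  model <- fe_model(nodes_df, solids_df, shells_df, parts, node_sets)

  cz <- z_gap + condyle_R / 3            # condyle centres protrude downward
  c_m <- c(0, -condyle_sep, cz)
  c_l <- c(0, condyle_sep, cz)
  condyle_m <- .uv_sphere_mesh(rep(condyle_R, 3), edge, c_m)
  condyle_l <- .uv_sphere_mesh(rep(condyle_R, 3), edge, c_l)
  plat_z <- cz - condyle_R               # tangent plane under the condyles
  config <- list(
    joints = list(
      hip = list(type = "ball", center = c(0, 0, half_len),
                 driven_parts = c(1L), child_joints = "knee"),
      knee = list(type = "knee", driven_parts = c(2L),
                  condyle_medial = condyle_m, condyle_lateral = condyle_l,
                  plateau_medial = plateau_plane(c(0, -condyle_sep, plat_z),
                                                 c(0, 0, 1)),
                  plateau_lateral = plateau_plane(c(0, condyle_sep, plat_z),
                                                  c(0, 0, 1)),
                  capsule_part = 4L, flesh_parts = 3L,
                  proximal_part = 1L, distal_part = 2L,
                  child_joints = character())))
  truth <- list(seed = seed, rb = rb, r_skin = r_skin, z_gap = z_gap,
                condyle_R = condyle_R,
                condyle_centers = rbind(c_m, c_l), plateau_z = plat_z,
                capsule_half = cap_half, stations = stations,
                n_nodes = nrow(nodes_df), n_solids = nrow(solids_df),
                n_shells = nrow(shells_df))
  list(model = model, config = config, truth = truth)
}
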