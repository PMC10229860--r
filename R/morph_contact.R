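# Morph-contact algorithm for sliding joint interfaces.
#
# TPS interpolation cannot represent the displacement discontinuity a
# sliding capsule experiences, so the capsule is treated separately: it is
# preliminarily morphed from a reduced set of bone landmarks, bone nodes
# that cross the capsule wall (orientation flips of their signed distance)
# are eliminated by pulling the wall outward, the interior mesh is
# regularised by gradient descent on a Chamfer + edge-regularity + normal-
# coherence loss, and only then does the capsule serve as the landmark cage
# for the enclosed flesh.
#
# Sign convention: capsule normals point toward the joint cavity (outward
# from the flesh volume the capsule bounds). A bone node is penetrating when
# its signed distance to the capsule is negative (it crossed into flesh).

#' Segment a joint capsule into proximal/distal/interior/exterior nodes
#'
#' Nodes within `tol` of the femur surface are proximal, within `tol` of the
#' tibia distal (a node within `tol` of both is assigned to the nearer bone
#' with a warning). Remaining nodes are interior when their normal points
#' toward the nearest bone (positive dot with the direction to the nearest
#' bone point), exterior otherwise. The four sets are disjoint and cover all
#' capsule vertices.
#'
#' @param capsule,femur,tibia `tri_mesh`es in a common frame.
#' @param tol attachment distance tolerance (mm).
#' @return object of class `capsule_segmentation` with vertex-index sets
#'   `proximal`, `distal`, `interior`, `exterior`.
#' @export
segment_capsule <- function(capsule, femur, tibia, tol = 1.0) {
  v <- capsule$vertices
  df <- mesh_closest_point(femur, v)
  dt <- mesh_closest_point(tibia, v)
  near_f <- df$distance < tol  # strict: tol = 0 keeps the sets empty
  near_t <- dt$distance < tol
  both <- near_f & near_t
  if (any(both))
    .warnf("segment_capsule: %d nodes within tol of both bones; assigned to the nearer", sum(both))
  proximal <- which(near_f & (!near_t | df$distance <= dt$distance))
  distal <- which(near_t & !(seq_len(nrow(v)) %in% proximal))
  rest <- setdiff(seq_len(nrow(v)), c(proximal, distal))
  use_f <- df$distance[rest] <= dt$distance[rest]
  nearest <- ifelse(use_f, 1, 2)
  npt <- df$point[rest, , drop = FALSE]
  npt[!use_f, ] <- dt$point[rest[!use_f], , drop = FALSE]
  dir <- .normalize_rows(npt - v[rest, , drop = FALSE])
  facing <- rowSums(capsule$normals[rest, , drop = FALSE] * dir) > 0
  structure(list(proximal = proximal, distal = distal,
                 interior = rest[facing], exterior = rest[!facing],
                 node_ids = capsule$source_node_ids),
            class = "capsule_segmentation")
}

#' Preliminary capsule morph from reduced bone landmarks
#'
#' Displaces every capsule node by a TPS fitted to a reduced bone landmark
#' set, then overwrites the proximal/distal attachment nodes with their
#' exact rigid bone transforms (they move with the bones by definition).
#'
#' @param capsule a `tri_mesh`.
#' @param landmarks list with `source`, `target` matrices (reduced bone
#'   landmark pairs, e.g. from [reduced_bone_landmarks()]).
#' @param segmentation optional `capsule_segmentation` (required for the
#'   attachment overwrite).
#' @param transform_proximal,transform_distal `rigid_transform`s of the two
#'   bones (identity when omitted).
#' @return the morphed `tri_mesh` (normals recomputed).
#' @export
preliminary_morph <- function(capsule, landmarks, segmentation = NULL,
                              transform_proximal = NULL,
                              transform_distal = NULL) {
  tps <- fit_tps(landmarks$source, landmarks$target)
  v <- apply_tps(tps, capsule$vertices)
  if (!is.null(segmentation)) {
    if (!is.null(transform_proximal) && length(segmentation$proximal))
      v[segmentation$proximal, ] <-
        apply_transform(transform_proximal,
                        capsule$vertices[segmentation$proximal, , drop = FALSE])
    if (!is.null(transform_distal) && length(segmentation$distal))
      v[segmentation$distal, ] <-
        apply_transform(transform_distal,
                        capsule$vertices[segmentation$distal, , drop = FALSE])
  }
  tri_mesh(v, capsule$faces, source_node_ids = capsule$source_node_ids)
}

#' Reduced bone landmark pairs for the preliminary morph
#'
#' Farthest-point subsample (default ~10% density) of each bone's surface
#' vertices, excluding vertices whose normals face the joint space (the
#' inter-bone gap): those are exactly the anchors that would drag the
#' capsule into the joint space. Targets are the rigidly transformed
#' sources.
#'
#' @param femur,tibia bone `tri_mesh`es (pre-transform).
#' @param transform_femur,transform_distal `rigid_transform`s of each bone.
#' @param density fraction of surface vertices kept per bone.
#' @param facing_cut dot-product threshold above which a vertex normal is
#'   considered to face the joint space.
#' @return list with `source`, `target` matrices.
#' @export
reduced_bone_landmarks <- function(femur, tibia,
                                   transform_femur = rigid_transform(),
                                   transform_tibia = rigid_transform(),
                                   density = 0.1, facing_cut = 0.5) {
  pick <- function(bone, other, tf) {
    joint_dir <- .unit(colMeans(other$vertices) - colMeans(bone$vertices))
    ok <- which(as.numeric(bone$normals %*% joint_dir) < facing_cut)
    keep <- ok[farthest_point_sample(bone$vertices[ok, , drop = FALSE],
                                     max(4L, ceiling(density * length(ok))))]
    src <- bone$vertices[keep, , drop = FALSE]
    list(source = src, target = apply_transform(tf, src))
  }
  f <- pick(femur, tibia, transform_femur)
  t_ <- pick(tibia, femur, transform_tibia)
  list(source = rbind(f$source, t_$source),
       target = rbind(f$target, t_$target))
}

#' Detect bone-capsule penetrations
#'
#' Computes the signed distance of every bone node to the capsule surface
#' (positive on the capsule's normal side, i.e. the joint-cavity side).
#' Nodes whose sign flipped against the pre-morph reference and are now
#' negative (beyond a 1e-6 mm grazing tolerance) are reported with their
#' depths. Without a reference, all negative nodes are reported (the
#' pre-morph configuration is assumed penetration-free).
#'
#' @param bone a `tri_mesh` (its vertices are the slave nodes).
#' @param capsule an oriented, near-watertight `tri_mesh` (master surface).
#' @param reference_signs optional vector of pre-morph signs (+1/-1).
#' @return object of class `penetration_report`: `nodes` (bone vertex
#'   indices), `depths` (negative, mm), `nearest_face`, `points` (the bone
#'   node coordinates, kept so re-detection after a pull needs no bone
#'   mesh), `signed` (all signed distances).
#' @export
detect_penetrations <- function(bone, capsule, reference_signs = NULL) {
  sd <- mesh_signed_distance(capsule, bone$vertices)
  pen <- sd$signed < -1e-6
  if (!is.null(reference_signs)) pen <- pen & reference_signs >= 0
  # For an open (non-watertight) capsule the sign is meaningless for query
  # points that project onto the free rim (e.g. the bone shaft continuing
  # past the tube ends): drop nodes whose nearest face has 2+ rim vertices.
  ed <- mesh_edges(capsule$faces)
  rim <- unique(c(ed$v1[is.na(ed$f2)], ed$v2[is.na(ed$f2)]))
  if (length(rim) && any(pen)) {
    nf <- capsule$faces[sd$face[pen], , drop = FALSE]
    on_rim <- rowSums(matrix(nf %in% rim, nrow = nrow(nf))) >= 2
    pen[which(pen)[on_rim]] <- FALSE
  }
  structure(list(nodes = which(pen), depths = sd$signed[pen],
                 nearest_face = sd$face[pen],
                 points = bone$vertices[pen, , drop = FALSE],
                 signed = sd$signed),
            class = "penetration_report")
}

#' @export
print.penetration_report <- function(x, ...) {
  if (length(x$nodes) == 0) cat("penetration_report: clean\n")
  else cat(sprintf("penetration_report: %d nodes, max depth %.4f mm\n",
                   length(x$nodes), -min(x$depths)))
  invisible(x)
}

#' Export a penetration report as CSV (node id, depth, nearest face)
#' @param report a `penetration_report`. @param path output path.
#' @export
write_penetration_report <- function(report, path) {
  utils::write.csv(data.frame(node = report$nodes, depth = report$depths,
                              nearest_face = report$nearest_face),
                   path, row.names = FALSE)
  invisible(path)
}

# vertex 1-ring adjacency list
.vertex_rings <- function(faces, nv) {
  adj <- vector("list", nv)
  ed <- mesh_edges(faces)
  for (k in seq_len(nrow(ed))) {
    adj[[ed$v1[k]]] <- c(adj[[ed$v1[k]]], ed$v2[k])
    adj[[ed$v2[k]]] <- c(adj[[ed$v2[k]]], ed$v1[k])
  }
  adj
}

#' Eliminate penetrations by pulling capsule patches outward
#'
#' For each penetrated region, the capsule patch nearest the penetrating
#' bone nodes (the nearest faces' vertices plus their 1-ring) is displaced
#' against the capsule normal (away from the joint cavity) by depth +
#' clearance, with a raised-cosine falloff (full displacement on the patch
#' core, half on the 1-ring). Penetrations are re-detected against the
#' stored bone node positions and the pull repeats until the report is
#' clean or `max_iter` is reached (then an error carrying the residual
#' report is raised).
#'
#' @param capsule a `tri_mesh`.
#' @param report a `penetration_report` from [detect_penetrations()].
#' @param max_iter pull/re-detect iteration cap.
#' @param clearance extra pull distance (mm).
#' @param fixed vertex indices never moved (bone attachments).
#' @return the penetration-free `tri_mesh`.
#' @export
resolve_penetrations <- function(capsule, report, max_iter = 50,
                                 clearance = 0.1, fixed = integer()) {
  if (length(report$nodes) == 0) return(capsule)
  pts <- report$points
  rings <- .vertex_rings(capsule$faces, nrow(capsule$vertices))
  ed <- mesh_edges(capsule$faces)
  rim <- unique(c(ed$v1[is.na(ed$f2)], ed$v2[is.na(ed$f2)]))
  for (it in seq_len(max_iter)) {
    sd <- mesh_signed_distance(capsule, pts)
    pen <- sd$signed < -1e-6
    if (length(rim) && any(pen)) {
      nf <- capsule$faces[sd$face[pen], , drop = FALSE]
      on_rim <- rowSums(matrix(nf %in% rim, nrow = nrow(nf))) >= 2
      pen[which(pen)[on_rim]] <- FALSE
    }
    if (!any(pen)) {
      return(tri_mesh(capsule$vertices, capsule$faces,
                      source_node_ids = capsule$source_node_ids))
    }
    disp <- numeric(nrow(capsule$vertices))
    core_faces <- sd$face[pen]
    need <- -sd$signed[pen] + clearance
    for (k in seq_along(core_faces)) {
      vs <- capsule$faces[core_faces[k], ]
      disp[vs] <- pmax(disp[vs], need[k])
    }
    core <- which(disp > 0)
    ring_d <- numeric(nrow(capsule$vertices))
    for (i in core)
      ring_d[rings[[i]]] <- pmax(ring_d[rings[[i]]], 0.5 * disp[i])
    ring_d[core] <- 0
    disp <- disp + ring_d
    disp[fixed] <- 0
    move <- which(disp > 0)
    v <- capsule$vertices
    v[move, ] <- v[move, ] - capsule$normals[move, , drop = FALSE] * disp[move]
    capsule <- tri_mesh(v, capsule$faces,
                        source_node_ids = capsule$source_node_ids)
  }
  residual <- structure(list(nodes = which(pen), depths = sd$signed[pen],
                             nearest_face = sd$face[pen],
                             points = pts[pen, , drop = FALSE],
                             signed = sd$signed),
                        class = "penetration_report")
  cond <- structure(class = c("arthropose_contact_error", "error", "condition"),
                    list(message = sprintf(
                      "resolve_penetrations: %d nodes still penetrating after %d iterations",
                      sum(pen), max_iter), call = sys.call(),
                      residual = residual))
  stop(cond)
}

#' Symmetric Chamfer distance between two meshes
#'
#' Mean nearest-point distance, point-sampled at vertices plus face
#' centroids, symmetrised.
#' @param a,b `tri_mesh`es.
#' @return scalar distance (mm).
#' @export
chamfer_distance <- function(a, b) {
  samp <- function(m) rbind(m$vertices,
                            (m$vertices[m$faces[, 1], , drop = FALSE] +
                             m$vertices[m$faces[, 2], , drop = FALSE] +
                             m$vertices[m$faces[, 3], , drop = FALSE]) / 3)
  pa <- samp(a); pb <- samp(b)
  nn_mean <- function(x, y) {
    chunk <- max(64L, as.integer(floor(4e6 / nrow(y))))
    tot <- 0
    for (i0 in seq(1, nrow(x), by = chunk)) {
      i <- i0:min(i0 + chunk - 1, nrow(x))
      d2 <- outer(rowSums(x[i, , drop = FALSE]^2), rep(1, nrow(y))) +
        outer(rep(1, length(i)), rowSums(y^2)) -
        2 * x[i, , drop = FALSE] %*% t(y)
      tot <- tot + sum(sqrt(pmax(d2[cbind(seq_along(i), max.col(-d2))], 0)))
    }
    tot / nrow(x)
  }
  (nn_mean(pa, pb) + nn_mean(pb, pa)) / 2
}

#' Edge-length coefficient of variation
#'
#' CV of the edge lengths; with a `baseline` mesh of identical topology the
#' CV is taken over the per-edge length ratios current/baseline, so a mesh
#' that deformed without local distortion scores 0 regardless of how
#' non-uniform its original edge lengths were.
#'
#' @param mesh a `tri_mesh`.
#' @param baseline optional same-topology `tri_mesh` supplying reference
#'   edge lengths.
#' @param vertices optional vertex-index subset; only edges with both ends
#'   in the subset are measured.
#' @return scalar coefficient of variation.
#' @export
edge_length_cv <- function(mesh, baseline = NULL, vertices = NULL) {
  ed <- mesh_edges(mesh$faces)
  if (!is.null(vertices))
    ed <- ed[ed$v1 %in% vertices & ed$v2 %in% vertices, , drop = FALSE]
  l <- .row_norms(mesh$vertices[ed$v2, , drop = FALSE] -
                  mesh$vertices[ed$v1, , drop = FALSE])
  if (!is.null(baseline)) {
    l0 <- .row_norms(baseline$vertices[ed$v2, , drop = FALSE] -
                     baseline$vertices[ed$v1, , drop = FALSE])
    l <- l / pmax(l0, .Machine$double.xmin)
  }
  stats::sd(l) / mean(l)
}

#' Optimisation-based interface refinement
#'
#' Redistributes the capsule's free (interior) nodes by gradient descent on
#' `L = w_c Chamfer^2(current, reference) + w_e Var(edge)/mean(edge)^2 +
#' w_n mean(1 - cos angle(adjacent face normals))`, holding all other nodes
#' fixed. The reference supplies the target shape (the penetration-fixed
#' surface), so penetration freedom is preserved while oscillatory node
#' patterns are smoothed out. Descent uses a displacement-normalised step
#' (`step_size` mm, decaying 0.95 per 50 iterations) and stops when the
#' relative loss change drops below 1e-5 or after `max_iter` iterations; a
#' step that flips a face normal is rolled back and halts with a warning.
#'
#' @param capsule_raw a `tri_mesh` (same topology as `reference`).
#' @param reference the target-shape `tri_mesh`.
#' @param baseline optional same-topology `tri_mesh` whose edge lengths are
#'   the regularity reference (the original undeformed capsule); edge
#'   inconsistency is then measured on current/baseline length ratios.
#' @param free vertex indices allowed to move (default: all).
#' @param weights list `w_c`, `w_e`, `w_n`.
#' @param step_size initial per-iteration displacement scale (mm).
#' @param max_iter iteration cap.
#' @return the refined `tri_mesh`.
#' @export
refine_interface <- function(capsule_raw, reference, baseline = NULL,
                             free = seq_len(nrow(capsule_raw$vertices)),
                             weights = list(w_c = 1.0, w_e = 0.1, w_n = 0.01),
                             step_size = 0.05, max_iter = 500) {
  if (!identical(dim(capsule_raw$faces), dim(reference$faces)))
    .stopf("refine_interface: meshes do not share topology")
  v <- capsule_raw$vertices
  f <- capsule_raw$faces
  nv <- nrow(v)
  ed <- mesh_edges(f)
  pairs <- ed[!is.na(ed$f2), c("f1", "f2")]
  free <- sort(free)
  # Chamfer is evaluated over the region the optimiser can actually move
  # (free vertices and their faces), subsampled to a fixed budget so the
  # nearest-neighbour matrix stays small; the edge and normal terms still
  # see the whole mesh.
  region_f <- which(rowSums(matrix(f %in% free, nrow = nrow(f))) > 0)
  region_v <- sort(unique(c(as.integer(f[region_f, ]), free)))
  budget <- 1500L
  stride_pick <- function(idx) {
    if (length(idx) <= budget) idx
    else idx[round(seq(1, length(idx), length.out = budget))]
  }
  samp_v <- stride_pick(region_v)
  samp_f <- stride_pick(region_f)
  l0 <- if (is.null(baseline)) rep(1, nrow(ed)) else
    .row_norms(baseline$vertices[ed$v2, , drop = FALSE] -
               baseline$vertices[ed$v1, , drop = FALSE])
  ref_samp <- function(m)
    rbind(m$vertices[samp_v, , drop = FALSE],
          (m$vertices[m$faces[samp_f, 1], , drop = FALSE] +
           m$vertices[m$faces[samp_f, 2], , drop = FALSE] +
           m$vertices[m$faces[samp_f, 3], , drop = FALSE]) / 3)
  tgt <- ref_samp(reference)
  # target sample normals: the shape term is evaluated point-to-plane so
  # tangential node redistribution is not penalised as shape deviation
  rf <- face_normals(reference$vertices, reference$faces)$normals
  tgt_n <- rbind(reference$normals[samp_v, , drop = FALSE],
                 rf[samp_f, , drop = FALSE])
  scatter <- function(acc, idx, val) {
    for (d in 1:3) {
      s <- rowsum(val[, d], group = idx)
      ii <- as.integer(rownames(s))
      acc[ii, d] <- acc[ii, d] + s[, 1]
    }
    acc
  }
  nsv <- length(samp_v)
  corr <- NULL  # frozen NN correspondence, refreshed every 10 iterations
  loss_grad <- function(v) {
    a <- v[f[, 1], , drop = FALSE]; b <- v[f[, 2], , drop = FALSE]
    c_ <- v[f[, 3], , drop = FALSE]
    # Chamfer shape term (sampled nodes + centroids vs target samples)
    cur <- rbind(v[samp_v, , drop = FALSE],
                 (a[samp_f, , drop = FALSE] + b[samp_f, , drop = FALSE] +
                  c_[samp_f, , drop = FALSE]) / 3)
    if (is.null(corr)) {
      d2 <- outer(rowSums(cur^2), rep(1, nrow(tgt))) +
        outer(rep(1, nrow(cur)), rowSums(tgt^2)) - 2 * cur %*% t(tgt)
      d2 <- pmax(d2, 0)
      corr <<- list(jn = max.col(-d2), in_ = max.col(-t(d2)))
    }
    jn <- corr$jn                            # nearest target per sample
    in_ <- corr$in_                          # nearest sample per target
    # symmetric point-to-plane residuals against the target shape
    res_f <- rowSums((cur - tgt[jn, , drop = FALSE]) * tgt_n[jn, , drop = FALSE])
    res_b <- rowSums((tgt - cur[in_, , drop = FALSE]) * tgt_n)
    Lc <- mean(res_f^2) + mean(res_b^2)
    # forward term: each sample pulls along the target normal
    gs <- 2 * res_f * tgt_n[jn, , drop = FALSE] / nrow(cur)
    # backward term: each target pulls its nearest sample
    gb_acc <- matrix(0, nrow(cur), 3)
    gb_acc <- scatter(gb_acc, in_, -2 * res_b * tgt_n / nrow(tgt))
    gs <- gs + gb_acc
    g_c <- matrix(0, nv, 3)
    g_c <- scatter(g_c, samp_v, gs[seq_len(nsv), , drop = FALSE])
    cen_g <- gs[nsv + seq_along(samp_f), , drop = FALSE] / 3
    for (k in 1:3) g_c <- scatter(g_c, f[samp_f, k], cen_g)
    # edge regularity (length ratios against the baseline, if given)
    evec <- v[ed$v2, , drop = FALSE] - v[ed$v1, , drop = FALSE]
    l <- .row_norms(evec)
    ehat <- evec / pmax(l, .Machine$double.xmin)
    r <- l / l0
    E <- length(r); mbar <- mean(r); V <- stats::var(r) * (E - 1) / E
    Le <- V / mbar^2
    dLdr <- 2 * (r - mbar) / (E * mbar^2) - 2 * V / (E * mbar^3)
    dLdl <- dLdr / l0
    g_e <- matrix(0, nv, 3)
    g_e <- scatter(g_e, ed$v2, ehat * dLdl)
    g_e <- scatter(g_e, ed$v1, -ehat * dLdl)
    # normal coherence
    Nf <- .cross3(b - a, c_ - a)
    nl <- .row_norms(Nf)
    nf <- Nf / pmax(nl, .Machine$double.xmin)
    n1 <- nf[pairs$f1, , drop = FALSE]; n2 <- nf[pairs$f2, , drop = FALSE]
    P <- nrow(pairs)
    Ln <- mean(1 - rowSums(n1 * n2))
    dLdn <- matrix(0, nrow(f), 3)
    dLdn <- scatter(dLdn, pairs$f1, -n2 / P)
    dLdn <- scatter(dLdn, pairs$f2, -n1 / P)
    # through the normalisation: dL/dN = (I - n n') dL/dn / |N|
    dLdN <- (dLdn - nf * rowSums(dLdn * nf)) / pmax(nl, .Machine$double.xmin)
    g_n <- matrix(0, nv, 3)
    g_n <- scatter(g_n, f[, 1], .cross3(b - c_, dLdN))
    g_n <- scatter(g_n, f[, 2], .cross3(c_ - a, dLdN))
    g_n <- scatter(g_n, f[, 3], .cross3(a - b, dLdN))
    list(loss = weights$w_c * Lc + weights$w_e * Le + weights$w_n * Ln,
         grad = weights$w_c * g_c + weights$w_e * g_e + weights$w_n * g_n,
         nf = nf)
  }
  lg <- loss_grad(v)
  step <- step_size
  nf_prev <- lg$nf
  for (it in seq_len(max_iter)) {
    g <- lg$grad
    g[setdiff(seq_len(nv), free), ] <- 0
    gmax <- max(.row_norms(g))
    if (gmax < 1e-14) break
    v_new <- v - g * (step / gmax)
    lg_new <- loss_grad(v_new)
    if (any(rowSums(lg_new$nf * nf_prev) < 0)) {
      .warnf("refine_interface: face flip at iteration %d; rolled back", it)
      break
    }
    if (lg_new$loss > lg$loss) {
      step <- step * 0.5           # overshoot: shrink and retry next iter
      if (step < 1e-5) break
      next
    }
    rel <- (lg$loss - lg_new$loss) / max(lg$loss, .Machine$double.xmin)
    v <- v_new; lg <- lg_new; nf_prev <- lg$nf
    if (it %% 50 == 0) step <- step * 0.95
    if (it %% 10 == 0) { corr <- NULL; lg <- loss_grad(v) }
    if (rel < 1e-5) break
  }
  tri_mesh(v, f, source_node_ids = capsule_raw$source_node_ids)
}

#' Deform enclosed soft tissue by boundary-landmark TPS
#'
#' Fits a TPS on the boundary landmarks (refined capsule nodes plus bone
#' surface nodes, pre to post positions) and displaces every node of the
#' given flesh parts; landmark nodes present in the model are set exactly
#' to their targets.
#'
#' @param model an `fe_model`.
#' @param boundary_landmarks list with `source`, `target` and optional
#'   `node_ids` (FE node ids of the landmarks, for exact assignment).
#' @param flesh_parts part ids whose nodes are deformed.
#' @return the deformed `fe_model`.
#' @export
deform_soft_tissue <- function(model, boundary_landmarks, flesh_parts) {
  tps <- fit_tps(boundary_landmarks$source, boundary_landmarks$target)
  conn <- as.matrix(model$solids[model$solids$pid %in% flesh_parts,
                                 paste0("n", 1:8)])
  conn2 <- as.matrix(model$shells[model$shells$pid %in% flesh_parts,
                                  paste0("n", 1:4)])
  ids <- unique(c(as.integer(conn), as.integer(conn2)))
  ids <- ids[!is.na(ids)]
  idx <- .node_index(model, ids)
  model$nodes[idx, c("x", "y", "z")] <-
    apply_tps(tps, as.matrix(model$nodes[idx, c("x", "y", "z")]))
  if (!is.null(boundary_landmarks$node_ids)) {
    bidx <- match(boundary_landmarks$node_ids, model$nodes$id)
    ok <- !is.na(bidx)
    model$nodes[bidx[ok], c("x", "y", "z")] <-
      boundary_landmarks$target[ok, , drop = FALSE]
  }
  model
}
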