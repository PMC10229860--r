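#' Triangle surface mesh
#'
#' Lightweight container for a triangulated surface: an `n x 3` vertex matrix
#' (mm), an `m x 3` integer face matrix (1-based vertex indices), per-vertex
#' unit normals (angle-weighted, computed when not supplied), and an optional
#' `source_node_ids` vector bridging mesh vertices back to FE-model node ids.
#'
#' @param vertices numeric `n x 3` matrix of coordinates (mm).
#' @param faces integer `m x 3` matrix of 1-based vertex indices.
#' @param normals optional `n x 3` matrix of unit vertex normals.
#' @param source_node_ids optional integer vector of FE node ids per vertex.
#' @return an object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces, normals = NULL, source_node_ids = NULL) {
  vertices <- .as_pts(vertices)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (!all(is.finite(vertices))) .stopf("tri_mesh: non-finite vertex coordinates")
  if (nrow(faces) > 0) {
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      .stopf("tri_mesh: face index out of range [1, %d]", nrow(vertices))
    degen <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
      faces[, 1] == faces[, 3]
    if (any(degen))
      .stopf("tri_mesh: %d degenerate (repeated-index) faces", sum(degen))
  }
  if (is.null(normals)) normals <- vertex_normals(vertices, faces)
  m <- structure(list(vertices = vertices, faces = faces,
                      normals = normals, source_node_ids = source_node_ids),
                 class = "tri_mesh")
  m
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d vertices, %d faces%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (is.null(x$source_node_ids)) "" else " (FE-linked)"))
  invisible(x)
}

# per-face unit normals and areas
face_normals <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c_ <- vertices[faces[, 3], , drop = FALSE]
  n <- .cross3(b - a, c_ - a)
  list(normals = .normalize_rows(n), areas = 0.5 * .row_norms(n))
}

#' Angle-weighted vertex normals
#'
#' @param vertices `n x 3` vertex matrix.
#' @param faces `m x 3` face matrix.
#' @return `n x 3` matrix of unit normals.
#' @export
vertex_normals <- function(vertices, faces) {
  nv <- nrow(vertices)
  acc <- matrix(0, nv, 3)
  if (nrow(faces) > 0) {
    fn <- face_normals(vertices, faces)$normals
    for (k in 1:3) {
      i <- faces[, k]
      j <- faces[, (k %% 3) + 1]
      l <- faces[, ((k + 1) %% 3) + 1]
      e1 <- .normalize_rows(vertices[j, , drop = FALSE] - vertices[i, , drop = FALSE])
      e2 <- .normalize_rows(vertices[l, , drop = FALSE] - vertices[i, , drop = FALSE])
      ang <- acos(pmin(1, pmax(-1, rowSums(e1 * e2))))
      for (d in 1:3) {
        s <- rowsum(fn[, d] * ang, group = i)
        acc[as.integer(rownames(s)), d] <- acc[as.integer(rownames(s)), d] + s[, 1]
      }
    }
  }
  n <- .row_norms(acc)
  zero <- n < 1e-300
  if (any(zero)) acc[zero, ] <- matrix(rep(c(0, 0, 1), sum(zero)),
                                       ncol = 3, byrow = TRUE)
  .normalize_rows(acc)
}

# Unique edge table with adjacency.
# Returns data.frame: v1 < v2, f1, f2 (NA on boundary), plus the orientation
# of the edge inside f1 (TRUE if f1 traverses v1 -> v2).
mesh_edges <- function(faces) {
  m <- nrow(faces)
  he_from <- c(faces[, 1], faces[, 2], faces[, 3])
  he_to <- c(faces[, 2], faces[, 3], faces[, 1])
  he_face <- rep(seq_len(m), 3)
  key_lo <- pmin(he_from, he_to)
  key_hi <- pmax(he_from, he_to)
  key <- paste(key_lo, key_hi)
  first <- !duplicated(key)
  idx <- match(key, key[first])
  ne <- sum(first)
  f1 <- he_face[first]
  fwd <- he_from[first] == key_lo[first]
  f2 <- rep(NA_integer_, ne)
  second <- which(!first)
  f2[idx[second]] <- he_face[second]  # >2-manifold: last extra face wins
  data.frame(v1 = key_lo[first], v2 = key_hi[first],
             f1 = f1, f2 = f2, f1_forward = fwd)
}

#' Check whether a mesh is watertight
#'
#' A mesh is watertight when every edge is shared by exactly two faces.
#' @param mesh a `tri_mesh`.
#' @return logical scalar.
#' @export
is_watertight <- function(mesh) {
  if (nrow(mesh$faces) == 0) return(FALSE)
  ed <- mesh_edges(mesh$faces)
  all(!is.na(ed$f2))
}

# signed volume (positive when normals point outward)
mesh_signed_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]; b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(rowSums(a * .cross3(b, c_))) / 6
}

#' Apply a rigid transform to a mesh
#' @param mesh a `tri_mesh`.
#' @param tf a `rigid_transform`.
#' @return the transformed `tri_mesh`.
#' @export
transform_mesh <- function(mesh, tf) {
  mesh$vertices <- apply_transform(tf, mesh$vertices)
  mesh$normals <- mesh$normals %*% t(tf$rotation)
  mesh
}

# ---- closest point on mesh -------------------------------------------------

# Closest point on triangle (a,b,c) from p, all given as row-paired matrices.
# Vectorised port of the standard (Ericson) region classification.
.closest_point_tri <- function(p, a, b, c_) {
  ab <- b - a; ac <- c_ - a; ap <- p - a
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- p - b
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- p - c_
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  n <- nrow(p)
  out <- matrix(NA_real_, n, 3)
  u <- numeric(n); v <- numeric(n)  # bary coords for b and c
  done <- rep(FALSE, n)

  set <- function(mask, pts, uu, vv) {
    mask <- mask & !done
    if (any(mask)) {
      out[mask, ] <<- pts[mask, , drop = FALSE]
      u[mask] <<- uu[mask]; v[mask] <<- vv[mask]
      done[mask] <<- TRUE
    }
  }
  zero <- numeric(n)
  set(d1 <= 0 & d2 <= 0, a, zero, zero)                       # vertex a
  set(d3 >= 0 & d4 <= d3, b, zero + 1, zero)                  # vertex b
  vc <- d1 * d4 - d3 * d2
  t_ab <- d1 / pmax(d1 - d3, .Machine$double.xmin)
  set(vc <= 0 & d1 >= 0 & d3 <= 0, a + ab * t_ab, t_ab, zero) # edge ab
  set(d6 >= 0 & d5 <= d6, c_, zero, zero + 1)                 # vertex c
  vb <- d5 * d2 - d1 * d6
  t_ac <- d2 / pmax(d2 - d6, .Machine$double.xmin)
  set(vb <= 0 & d2 >= 0 & d6 <= 0, a + ac * t_ac, zero, t_ac) # edge ac
  va <- d3 * d6 - d5 * d4
  t_bc <- (d4 - d3) / pmax((d4 - d3) + (d5 - d6), .Machine$double.xmin)
  set(va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0,
      b + (c_ - b) * t_bc, 1 - t_bc, t_bc)                    # edge bc
  denom <- pmax(va + vb + vc, .Machine$double.xmin)
  uu <- vb / denom; vv <- vc / denom
  set(rep(TRUE, n), a + ab * uu + ac * vv, uu, vv)            # interior
  list(point = out, bary = cbind(1 - u - v, u, v))
}

#' Closest points on a mesh
#'
#' For each query point, finds the nearest point on the mesh surface, the
#' face it lies in, its barycentric coordinates, and the distance. Exact:
#' a centroid-ball candidate filter is expanded until it provably contains
#' the minimiser.
#'
#' @param mesh a `tri_mesh`.
#' @param points `k x 3` query matrix.
#' @return list with `distance`, `point`, `face`, `bary`.
#' @export
mesh_closest_point <- function(mesh, points) {
  points <- .as_pts(points)
  v <- mesh$vertices; f <- mesh$faces
  np <- nrow(points); nf <- nrow(f)
  chunk_np <- max(64L, as.integer(floor(4e6 / max(nf, 1L))))
  if (np > chunk_np) {
    # keep the centroid distance matrix small
    chunks <- split(seq_len(np), ceiling(seq_len(np) / chunk_np))
    parts <- lapply(chunks, function(i)
      mesh_closest_point(mesh, points[i, , drop = FALSE]))
    return(list(distance = unlist(lapply(parts, `[[`, "distance"),
                                  use.names = FALSE),
                point = do.call(rbind, lapply(parts, `[[`, "point")),
                face = unlist(lapply(parts, `[[`, "face"), use.names = FALSE),
                bary = do.call(rbind, lapply(parts, `[[`, "bary"))))
  }
  a <- v[f[, 1], , drop = FALSE]; b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  cen <- (a + b + c_) / 3
  # circumscribing radius bound per face
  rad <- pmax(.row_norms(a - cen), .row_norms(b - cen), .row_norms(c_ - cen))
  rmax <- max(rad)
  k <- min(nf, 32L)
  # centroid distances
  d2 <- outer(rowSums(points^2), rep(1, nf)) +
    outer(rep(1, np), rowSums(cen^2)) - 2 * points %*% t(cen)
  d2[d2 < 0] <- 0
  best_d <- rep(Inf, np)
  best_pt <- matrix(NA_real_, np, 3)
  best_f <- integer(np); best_b <- matrix(NA_real_, np, 3)

  eval_pairs <- function(pi, fi) {
    cp <- .closest_point_tri(points[pi, , drop = FALSE],
                             a[fi, , drop = FALSE], b[fi, , drop = FALSE],
                             c_[fi, , drop = FALSE])
    d <- .row_norms(points[pi, , drop = FALSE] - cp$point)
    for (grp in split(seq_along(pi), pi)) {
      i <- pi[grp[1]]
      jbest <- grp[which.min(d[grp])]
      if (d[jbest] < best_d[i]) {
        best_d[i] <<- d[jbest]
        best_pt[i, ] <<- cp$point[jbest, ]
        best_f[i] <<- fi[jbest]
        best_b[i, ] <<- cp$bary[jbest, ]
      }
    }
  }

  ord <- apply(d2, 1, function(r) order(r)[seq_len(k)])
  pi0 <- rep(seq_len(np), each = k)
  fi0 <- as.integer(ord)
  eval_pairs(pi0, fi0)
  # exact completion: any face whose centroid ball could beat current best
  need_p <- integer(0); need_f <- integer(0)
  dcen <- sqrt(d2)
  for (i in seq_len(np)) {
    cand <- which(dcen[i, ] - rad < best_d[i])
    cand <- setdiff(cand, ord[, i])
    if (length(cand)) {
      need_p <- c(need_p, rep(i, length(cand)))
      need_f <- c(need_f, cand)
    }
  }
  if (length(need_p)) eval_pairs(need_p, need_f)
  list(distance = best_d, point = best_pt, face = best_f, bary = best_b)
}

#' Signed distance from points to an oriented mesh
#'
#' Sign is positive on the side of the surface the vertex normals point to,
#' using barycentric interpolation of angle-weighted vertex pseudonormals at
#' the closest point (robust near edges and vertices of near-watertight
#' meshes).
#'
#' @param mesh a `tri_mesh` with coherent orientation.
#' @param points `k x 3` query matrix.
#' @return list with `signed` (mm), plus the `mesh_closest_point` fields.
#' @export
mesh_signed_distance <- function(mesh, points) {
  points <- .as_pts(points)
  cp <- mesh_closest_point(mesh, points)
  f <- mesh$faces[cp$face, , drop = FALSE]
  n <- cp$bary[, 1] * mesh$normals[f[, 1], , drop = FALSE] +
    cp$bary[, 2] * mesh$normals[f[, 2], , drop = FALSE] +
    cp$bary[, 3] * mesh$normals[f[, 3], , drop = FALSE]
  n <- .normalize_rows(n)
  s <- sign(rowSums((points - cp$point) * n))
  s[s == 0] <- 1
  cp$signed <- s * cp$distance
  cp$pseudonormal <- n
  cp
}
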