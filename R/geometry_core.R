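# Discrete differential geometry and fitting primitives.

#' Rigid transform
#'
#' @param rotation 3x3 rotation matrix (orthonormal, det = +1).
#' @param translation length-3 vector (mm).
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    .stopf("rigid_transform: rotation is not orthonormal")
  if (abs(det(rotation) - 1) > 1e-8)
    .stopf("rigid_transform: det(R) != +1")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#' @param tf a `rigid_transform`.
#' @param points `n x 3` matrix or length-3 vector.
#' @return transformed points, same shape convention (always a matrix).
#' @export
apply_transform <- function(tf, points) {
  p <- .as_pts(points)
  sweep(p %*% t(tf$rotation), 2, tf$translation, `+`)
}

#' Compose rigid transforms (`a` applied after `b`)
#' @param a,b `rigid_transform`s.
#' @return `rigid_transform` equal to `x -> a(b(x))`.
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param tf a `rigid_transform`.
#' @return the inverse `rigid_transform`.
#' @export
invert_transform <- function(tf) {
  rigid_transform(t(tf$rotation), -as.numeric(t(tf$rotation) %*% tf$translation))
}

#' Rotation about an arbitrary line (Rodrigues formula)
#'
#' Builds the rigid transform rotating by `angle` degrees about the line
#' through `center` with direction `axis`, via
#' R = I + sin(theta) K + (1 - cos(theta)) K^2.
#'
#' @param axis unit direction vector.
#' @param angle rotation angle in degrees.
#' @param center a point on the rotation axis (mm). Default origin.
#' @return a `rigid_transform`.
#' @export
rodrigues <- function(axis, angle, center = c(0, 0, 0)) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) .stopf("rodrigues: zero axis")
  axis <- axis / n
  th <- .deg2rad(angle)
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  rigid_transform(R, as.numeric(center - R %*% center))
}

#' Intrinsic Euler rotation in the internal/external, flexion/extension,
#' adduction/abduction sequence
#'
#' The intrinsic composition about anatomical axes `a1, a2, a3` equals the
#' ordered matrix product R(a1, t1) R(a2, t2) R(a3, t3) of rotations about
#' the *original* axes.
#'
#' @param internal_external,flexion_extension,adduction_abduction angles (deg).
#' @param joint_axes 3x3 matrix whose rows are the mutually orthogonal unit
#'   anatomical axes (internal/external, flexion, adduction). Defaults to the
#'   global axes (Z, Y, X): X anterior, Y left, Z superior.
#' @return 3x3 rotation matrix.
#' @export
euler_intrinsic <- function(internal_external, flexion_extension,
                            adduction_abduction,
                            joint_axes = rbind(c(0, 0, 1),
                                               c(0, 1, 0),
                                               c(1, 0, 0))) {
  joint_axes <- as.matrix(joint_axes)
  g <- abs(joint_axes %*% t(joint_axes) - diag(3))
  if (max(g) > 1e-6) .stopf("euler_intrinsic: joint axes not orthonormal")
  r1 <- rodrigues(joint_axes[1, ], internal_external)$rotation
  r2 <- rodrigues(joint_axes[2, ], flexion_extension)$rotation
  r3 <- rodrigues(joint_axes[3, ], adduction_abduction)$rotation
  r1 %*% r2 %*% r3
}

#' Algebraic least-squares sphere fit
#'
#' Linearises |x - c|^2 = r^2 into a linear system in (c, r^2 - |c|^2).
#'
#' @param points `n x 3` matrix, n >= 4, non-coplanar.
#' @return list with `center` (mm) and `radius` (mm).
#' @export
fit_sphere <- function(points) {
  p <- .as_pts(points)
  if (nrow(p) < 4) .stopf("fit_sphere: need at least 4 points")
  ctr <- colMeans(p)
  sv <- svd(sweep(p, 2, ctr))$d
  if (sv[3] < 1e-9 * max(sv[1], 1)) .stopf("fit_sphere: points are coplanar")
  A <- cbind(2 * p, 1)
  b <- rowSums(p^2)
  sol <- qr.solve(A, b)
  center <- sol[1:3]
  list(center = as.numeric(center),
       radius = as.numeric(sqrt(sol[4] + sum(center^2))))
}

# algebraic (Taubin-like via linearized Kasa) circle fit in 2D
.fit_circle2d <- function(xy) {
  A <- cbind(2 * xy, 1)
  sol <- qr.solve(A, rowSums(xy^2))
  c2 <- as.numeric(sol[1:2])
  list(center = c2, radius = as.numeric(sqrt(sol[3] + sum(c2^2))))
}

#' Nonlinear least-squares cylinder fit
#'
#' Minimises sum over points of (distance-to-axis - r)^2. The axis direction
#' is optimised over its two spherical angles; for each candidate direction
#' the axis point and radius come from a closed-form circle fit of the
#' projected points. Initialised from the smallest-variance principal
#' direction of the cloud.
#'
#' @param points `n x 3` matrix (n >= 6) spanning a (partial) cylinder.
#' @param max_iter maximum optimiser iterations.
#' @param tol convergence tolerance on the residual change.
#' @return list with `axis_point`, `axis_dir` (unit), `radius`, `residual`.
#' @export
fit_cylinder <- function(points, max_iter = 200, tol = 1e-10) {
  p <- .as_pts(points)
  if (nrow(p) < 6) .stopf("fit_cylinder: need at least 6 points")
  ctr <- colMeans(p)
  q <- sweep(p, 2, ctr)
  sv <- svd(q)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    .stopf("fit_cylinder: points are collinear")
  # candidate initial axes: all three principal directions (the cylinder axis
  # is the largest- or smallest-variance direction depending on arc coverage)
  eval_dir <- function(d) {
    d <- .unit(d)
    u <- .any_orthogonal(d); v <- .cross3(d, u)[1, ]
    xy <- cbind(q %*% u, q %*% as.numeric(v))
    fc <- .fit_circle2d(xy)
    res <- sum((sqrt(rowSums(sweep(xy, 2, fc$center)^2)) - fc$radius)^2)
    list(res = res, u = u, v = as.numeric(v), circ = fc)
  }
  obj <- function(ang) {
    d <- c(cos(ang[2]) * cos(ang[1]), cos(ang[2]) * sin(ang[1]), sin(ang[2]))
    eval_dir(d)$res
  }
  best <- NULL
  for (k in 1:3) {
    d0 <- sv$v[, k]
    ang0 <- c(atan2(d0[2], d0[1]), asin(max(-1, min(1, d0[3]))))
    fit <- stats::optim(ang0, obj, method = "Nelder-Mead",
                        control = list(maxit = max_iter, reltol = tol))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  ang <- best$par
  d <- c(cos(ang[2]) * cos(ang[1]), cos(ang[2]) * sin(ang[1]), sin(ang[2]))
  ev <- eval_dir(d)
  n_pts <- nrow(p)
  if (sqrt(best$value / n_pts) > 0.25 * ev$circ$radius)
    .stopf("fit_cylinder: did not converge (rms residual %.3g mm)",
           sqrt(best$value / n_pts))
  axis_point <- ctr + ev$circ$center[1] * ev$u + ev$circ$center[2] * ev$v
  list(axis_point = as.numeric(axis_point), axis_dir = .unit(d),
       radius = ev$circ$radius, residual = best$value)
}

#' Plateau plane
#' @param point a point on the plane (mm).
#' @param normal unit normal, pointing toward the articulating condyle.
#' @return object of class `plateau_plane`.
#' @export
plateau_plane <- function(point, normal) {
  structure(list(point = as.numeric(point), normal = .unit(normal)),
            class = "plateau_plane")
}

#' Least-squares plane through points (total least squares)
#' @param points `n x 3` matrix.
#' @param toward optional point; the normal is flipped to point toward it.
#' @return a `plateau_plane`.
#' @export
fit_plane <- function(points, toward = NULL) {
  p <- .as_pts(points)
  ctr <- colMeans(p)
  n <- svd(sweep(p, 2, ctr))$v[, 3]
  if (!is.null(toward) && sum((toward - ctr) * n) < 0) n <- -n
  plateau_plane(ctr, n)
}

# ---- curvature tensor field ------------------------------------------------

# Meyer mixed Voronoi area per vertex (obtuse-safe).
.mixed_voronoi_area <- function(vertices, faces) {
  nv <- nrow(vertices)
  area <- numeric(nv)
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c_ <- vertices[faces[, 3], , drop = FALSE]
  tot <- 0.5 * .row_norms(.cross3(b - a, c_ - a))
  corn <- list(list(a, b, c_), list(b, c_, a), list(c_, a, b))
  cotangent <- function(u, w) rowSums(u * w) / pmax(.row_norms(.cross3(u, w)),
                                                   .Machine$double.xmin)
  # angles at each corner
  angs <- matrix(0, nrow(faces), 3)
  for (k in 1:3) {
    x <- corn[[k]]
    e1 <- .normalize_rows(x[[2]] - x[[1]]); e2 <- .normalize_rows(x[[3]] - x[[1]])
    angs[, k] <- acos(pmin(1, pmax(-1, rowSums(e1 * e2))))
  }
  obtuse_face <- apply(angs, 1, max) > pi / 2
  for (k in 1:3) {
    x <- corn[[k]]
    i <- faces[, k]
    # cot of angles opposite the two edges incident at this corner
    cot_opp1 <- 1 / tan(angs[, (k %% 3) + 1])        # opposite edge to x3
    cot_opp2 <- 1 / tan(angs[, ((k + 1) %% 3) + 1])  # opposite edge to x2
    l2_e2 <- rowSums((x[[2]] - x[[1]])^2)
    l2_e3 <- rowSums((x[[3]] - x[[1]])^2)
    vor <- (l2_e2 * cot_opp2 + l2_e3 * cot_opp1) / 8
    contrib <- ifelse(!obtuse_face, vor,
                      ifelse(angs[, k] > pi / 2, tot / 2, tot / 4))
    s <- rowsum(contrib, group = i)
    idx <- as.integer(rownames(s))
    area[idx] <- area[idx] + s[, 1]
  }
  area
}

#' Per-vertex discrete curvature tensor field (normal-cycle estimator)
#'
#' Estimates, at every vertex p, the 3x3 curvature tensor
#' C(p) = (1/A_p) * sum over incident edges e of
#' beta(e) * |e intersect A_p| * (ebar x ebar), where beta(e) is the signed
#' dihedral angle at e (positive when convex), A_p the mixed Voronoi 1-ring
#' area, |e intersect A_p| the half edge length falling in the 1-ring cell,
#' and ebar the unit edge vector. The raw normal-cycle tensor's tangent-plane
#' eigenvectors are the principal directions but carry *exchanged*
#' eigenvalues; after projection to the tangent plane the two tangent
#' eigenvalues are therefore swapped so that [normal_curvature()] reproduces
#' analytic normal curvature (validated on sphere/cylinder oracles).
#'
#' @param mesh a `tri_mesh`, manifold around the evaluated vertices.
#' @return object of class `curvature_field`: `tensors` (n x 6 symmetric
#'   components xx, xy, xz, yy, yz, zz, units 1/mm), `areas` (mm^2),
#'   `normals`, `reliable` (FALSE at boundary vertices), `mesh`.
#' @export
curvature_tensor_field <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  nv <- nrow(v)
  ed <- mesh_edges(f)
  fn <- face_normals(v, f)$normals
  areas <- .mixed_voronoi_area(v, f)
  if (any(areas <= 0))
    .stopf("curvature_tensor_field: zero-area vertex fan at vertex %d",
           which(areas <= 0)[1])
  interior <- !is.na(ed$f2)
  # signed dihedral angle, positive when convex w.r.t. outward normals.
  # Edge direction taken as traversed by f1 (consistent with its winding).
  evec <- v[ed$v2, , drop = FALSE] - v[ed$v1, , drop = FALSE]
  evec[!ed$f1_forward, ] <- -evec[!ed$f1_forward, , drop = FALSE]
  elen <- .row_norms(evec)
  ehat <- evec / pmax(elen, .Machine$double.xmin)
  beta <- numeric(nrow(ed))
  ii <- which(interior)
  n1 <- fn[ed$f1[ii], , drop = FALSE]
  n2 <- fn[ed$f2[ii], , drop = FALSE]
  beta[ii] <- atan2(rowSums(.cross3(n1, n2) * ehat[ii, , drop = FALSE]),
                    rowSums(n1 * n2))
  # per-edge tensor weight: beta * |e|/2 (half of each incident edge lies in
  # the 1-ring Voronoi cell of either endpoint); boundary edges contribute 0
  w <- beta * elen / 2
  comp <- cbind(ehat[, 1]^2, ehat[, 1] * ehat[, 2], ehat[, 1] * ehat[, 3],
                ehat[, 2]^2, ehat[, 2] * ehat[, 3], ehat[, 3]^2) * w
  tens <- matrix(0, nv, 6)
  for (side in c("v1", "v2")) {
    s <- rowsum(comp, group = ed[[side]])
    idx <- as.integer(rownames(s))
    tens[idx, ] <- tens[idx, ] + s
  }
  tens <- tens / areas
  # boundary vertices are unreliable (open fan)
  reliable <- rep(TRUE, nv)
  bverts <- unique(c(ed$v1[!interior], ed$v2[!interior]))
  reliable[bverts] <- FALSE
  # tangent-plane projection + eigenvalue swap
  nrm <- mesh$normals
  for (i in seq_len(nv)) {
    C <- .sym6_to_mat(tens[i, ])
    n <- nrm[i, ]
    # diagonalise inside an explicit 2D tangent basis: a 3x3 eigen solve is
    # ambiguous when a tangent eigenvalue degenerates with the (zero)
    # normal eigenvalue, e.g. on a cylinder
    u <- .any_orthogonal(n)
    w <- as.numeric(.cross3(n, u))
    M <- rbind(c(u %*% C %*% u, u %*% C %*% w),
               c(w %*% C %*% u, w %*% C %*% w))
    M <- (M + t(M)) / 2
    eg <- eigen(M, symmetric = TRUE)
    v1 <- eg$vectors[1, 1] * u + eg$vectors[2, 1] * w
    v2 <- eg$vectors[1, 2] * u + eg$vectors[2, 2] * w
    # eigenvalue swap between the two tangent principal directions
    Cc <- eg$values[2] * tcrossprod(v1) + eg$values[1] * tcrossprod(v2)
    tens[i, ] <- .mat_to_sym6(Cc)
  }
  structure(list(tensors = tens, areas = areas, normals = nrm,
                 reliable = reliable, mesh = mesh),
            class = "curvature_field")
}

#' Normal curvature from a curvature tensor (quadratic form)
#'
#' @param tensor 3x3 symmetric curvature tensor (1/mm).
#' @param tangent unit tangent direction.
#' @return normal curvature (1/mm), `t' C t`.
#' @export
normal_curvature <- function(tensor, tangent) {
  if (abs(sqrt(sum(tangent^2)) - 1) > 1e-6)
    .stopf("normal_curvature: tangent is not unit length")
  as.numeric(tangent %*% tensor %*% tangent)
}

#' Barycentric interpolation of vertex curvature tensors inside a face
#'
#' @param field a `curvature_field`.
#' @param face face index into the field's mesh.
#' @param barycentric 3 non-negative weights summing to 1.
#' @return 3x3 symmetric tensor.
#' @export
interpolate_tensor <- function(field, face, barycentric) {
  w <- as.numeric(barycentric)
  if (any(w < -1e-9) || abs(sum(w) - 1) > 1e-9)
    .stopf("interpolate_tensor: weights must be >= 0 and sum to 1")
  f <- field$mesh$faces[face, ]
  s <- w[1] * field$tensors[f[1], ] + w[2] * field$tensors[f[2], ] +
    w[3] * field$tensors[f[3], ]
  .sym6_to_mat(s)
}

#' Export a curvature field to CSV (debugging aid)
#' @param field a `curvature_field`.
#' @param path output CSV path.
#' @export
write_curvature_csv <- function(field, path) {
  df <- data.frame(vertex = seq_len(nrow(field$tensors)),
                   field$tensors, area = field$areas,
                   reliable = field$reliable)
  names(df)[2:7] <- c("cxx", "cxy", "cxz", "cyy", "cyz", "czz")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
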