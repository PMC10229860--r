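# Geometrically neutral tibiofemoral flexion trajectory.
#
# The knee has no structural hinge: the instantaneous flexion axis is
# re-derived at every increment from the articulating geometry. At each
# configuration the medial and lateral contact points are found (condyle
# point whose outward normal is antiparallel to the plateau-plane normal),
# the osculating radii r_m, r_l are solved so that they match the normal
# curvature radii 1/(t' C t) in the tangent directions perpendicular to the
# axis candidate, and the axis joins the osculating centres
# I = p - r * n_outward. Rotating the tibia-side entities about that axis is
# locally tangential in both compartments, so the contact point is
# stationary in the tibia frame (the "neutral" path).

#' Knee articulation geometry
#'
#' @param condyle_medial,condyle_lateral `tri_mesh` femoral condyle surfaces.
#' @param plateau_medial,plateau_lateral `plateau_plane`s; normals must point
#'   toward the corresponding condyle.
#' @param tibia_bodies list of `tri_mesh`es rigidly attached to the tibia.
#' @param truth optional list of analytic ground-truth values (fixtures).
#' @param field_medial,field_lateral optional precomputed `curvature_field`s
#'   (computed here when omitted).
#' @return object of class `knee_geometry`.
#' @export
knee_geometry <- function(condyle_medial, condyle_lateral,
                          plateau_medial, plateau_lateral,
                          tibia_bodies = list(), truth = list(),
                          field_medial = NULL, field_lateral = NULL) {
  for (side in c("medial", "lateral")) {
    pl <- if (side == "medial") plateau_medial else plateau_lateral
    cm <- if (side == "medial") condyle_medial else condyle_lateral
    if (sum((colMeans(cm$vertices) - pl$point) * pl$normal) <= 0)
      .stopf("knee_geometry: %s plateau normal does not point at its condyle",
             side)
  }
  if (is.null(field_medial)) field_medial <- curvature_tensor_field(condyle_medial)
  if (is.null(field_lateral)) field_lateral <- curvature_tensor_field(condyle_lateral)
  structure(list(condyle_medial = condyle_medial,
                 condyle_lateral = condyle_lateral,
                 field_medial = field_medial, field_lateral = field_lateral,
                 plateau_medial = plateau_medial,
                 plateau_lateral = plateau_lateral,
                 tibia_bodies = tibia_bodies, truth = truth),
            class = "knee_geometry")
}

#' Tibiofemoral contact search
#'
#' Finds the condyle surface point whose outward normal is antiparallel to
#' the plateau normal: the minimum-signed-distance vertex is located first,
#' then the contact is refined inside its incident triangles by a two-level
#' barycentric grid search (resolution 0.05, then 0.0025) over the
#' interpolated position/normal, minimising the alignment
#' dot(surface normal, plateau normal). Penetration beyond 0.5 mm triggers a
#' warning; the support point is still returned.
#'
#' @param condyle `tri_mesh` of the condyle.
#' @param plateau a `plateau_plane`.
#' @param compartment `"medial"` or `"lateral"` label.
#' @return a `contact_state`: `p` (mm), `n` (outward unit surface normal),
#'   `face`, `bary`, `distance` (signed, mm).
#' @export
find_contact_point <- function(condyle, plateau, compartment = "medial") {
  v <- condyle$vertices
  if (nrow(v) == 0) .stopf("find_contact_point: empty condyle mesh")
  d <- as.numeric(sweep(v, 2, plateau$point) %*% plateau$normal)
  imin <- which.min(d)
  if (d[imin] < -0.5)
    .warnf("find_contact_point: %s condyle penetrates plateau by %.3f mm",
           compartment, -d[imin])
  f <- condyle$faces
  cand <- which(f[, 1] == imin | f[, 2] == imin | f[, 3] == imin)
  nrm <- condyle$normals
  eval_grid <- function(face, W) {
    # W: k x 3 barycentric weights; returns alignment of the interpolated
    # unit normal with the plateau normal (minimise: want antiparallel)
    fi <- f[face, ]
    nn <- W %*% nrm[fi, , drop = FALSE]
    nn <- .normalize_rows(nn)
    as.numeric(nn %*% plateau$normal)
  }
  grid_w <- function(center, half, res) {
    w1 <- seq(max(0, center[1] - half), min(1, center[1] + half), by = res)
    w2 <- seq(max(0, center[2] - half), min(1, center[2] + half), by = res)
    g <- expand.grid(w1 = w1, w2 = w2)
    g <- g[g$w1 + g$w2 <= 1 + 1e-12, ]
    cbind(g$w1, g$w2, pmax(0, 1 - g$w1 - g$w2))
  }
  best <- list(align = Inf)
  coarse <- grid_w(c(1 / 3, 1 / 3), 1, 0.05)
  for (face in cand) {
    al <- eval_grid(face, coarse)
    k <- which.min(al)
    if (al[k] < best$align)
      best <- list(align = al[k], face = face, w = coarse[k, ])
  }
  # refine around the best cell, shrinking the window by 10x per level
  half <- 0.05
  for (lev in 1:3) {
    res <- half / 10
    fine <- grid_w(best$w[1:2], half, res)
    al <- eval_grid(best$face, fine)
    k <- which.min(al)
    if (al[k] < best$align)
      best <- list(align = al[k], face = best$face, w = fine[k, ])
    half <- res
  }
  fi <- f[best$face, ]
  w <- best$w
  pos <- as.numeric(w %*% v[fi, , drop = FALSE])
  nn <- .unit(as.numeric(w %*% nrm[fi, , drop = FALSE]))
  structure(list(compartment = compartment, p = pos,
                 n = nn, t = NULL, r = NULL, I = NULL,
                 face = best$face, bary = as.numeric(w),
                 distance = sum((pos - plateau$point) * plateau$normal)),
            class = "contact_state")
}

#' Solve the instantaneous helical axis from both compartments
#'
#' Fixed-point solve of the mean-square objective
#' `argmin (r_m - 1/(t_m' C(p_m) t_m))^2 + (r_l - 1/(t_l' C(p_l) t_l))^2`,
#' where `t_m`, `t_l` are the tangent directions perpendicular to the
#' current axis candidate. Each half-step zeroes one squared term (the
#' minimiser), then the axis is rebuilt from the osculating centres
#' `I = p - r * n_outward`; iterate until the radii are stationary.
#' The axis candidate is initialised as `normalize(p_l - p_m)`.
#'
#' @param medial,lateral `contact_state`s from [find_contact_point()].
#' @param field_medial,field_lateral `curvature_field`s of the two condyles.
#' @param max_iter,tol iteration cap and radii-change tolerance (mm).
#' @return list with updated `medial`, `lateral` (t, r, I filled) and
#'   `axis` (class `helical_axis`: unit `direction`, points `I_m`, `I_l`).
#' @export
solve_helical_axis <- function(medial, lateral, field_medial, field_lateral,
                               max_iter = 100, tol = 1e-6) {
  C_m <- interpolate_tensor(field_medial, medial$face, medial$bary)
  C_l <- interpolate_tensor(field_lateral, lateral$face, lateral$bary)
  p_m <- medial$p; n_m <- medial$n
  p_l <- lateral$p; n_l <- lateral$n
  u <- .unit(p_l - p_m)
  r_prev <- c(NA, NA)
  half_step <- function(p, n, C, comp) {
    tvec <- .cross3(u, n)[1, ]
    if (sqrt(sum(tvec^2)) < 1e-9)
      .stopf("solve_helical_axis: axis parallel to %s normal", comp)
    tvec <- .unit(tvec)
    kn <- normal_curvature(C, tvec)
    if (kn <= 1e-6)
      .stopf("solve_helical_axis: non-positive curvature at %s contact (kn = %.3g)",
             comp, kn)
    r <- 1 / kn
    list(t = tvec, r = r, I = p - r * n)
  }
  for (it in seq_len(max_iter)) {
    hm <- half_step(p_m, n_m, C_m, "medial")
    hl <- half_step(p_l, n_l, C_l, "lateral")
    sep <- hl$I - hm$I
    if (sqrt(sum(sep^2)) < 1e-9)
      .stopf("solve_helical_axis: degenerate axis (I_m == I_l)")
    u <- .unit(sep)
    r_now <- c(hm$r, hl$r)
    if (!anyNA(r_prev) && max(abs(r_now - r_prev)) < tol) break
    if (it == max_iter)
      .stopf("solve_helical_axis: no convergence after %d iterations (last residual %.3g mm)",
             max_iter, max(abs(r_now - r_prev)))
    r_prev <- r_now
  }
  medial$t <- hm$t; medial$r <- hm$r; medial$I <- hm$I
  lateral$t <- hl$t; lateral$r <- hl$r; lateral$I <- hl$I
  axis <- structure(list(direction = u, I_m = hm$I, I_l = hl$I),
                    class = "helical_axis")
  list(medial = medial, lateral = lateral, axis = axis)
}

#' Rotate the tibia-side entities about a helical axis
#'
#' @param geometry a `knee_geometry`.
#' @param axis a `helical_axis`.
#' @param delta step angle, degrees (|delta| <= 5, nonzero; negative =
#'   extension).
#' @return list `geometry` (tibia-side entities transformed; femur side
#'   untouched) and `transform` (the `rigid_transform` applied).
#' @export
step_flexion <- function(geometry, axis, delta) {
  if (abs(delta) > 5 || delta == 0)
    .stopf("step_flexion: step angle must be nonzero and |delta| <= 5 deg")
  tf <- rodrigues(axis$direction, delta, axis$I_m)
  for (side in c("plateau_medial", "plateau_lateral")) {
    pl <- geometry[[side]]
    geometry[[side]] <- plateau_plane(
      as.numeric(apply_transform(tf, pl$point)),
      as.numeric(pl$normal %*% t(tf$rotation)))
  }
  geometry$tibia_bodies <- lapply(geometry$tibia_bodies, transform_mesh, tf = tf)
  list(geometry = geometry, transform = tf)
}

#' Integrate the geometrically neutral flexion trajectory
#'
#' Repeats contact search (both compartments) -> helical-axis solve ->
#' incremental tibia rotation until the accumulated angle reaches
#' `target_angle`; the final step is truncated to land exactly on the
#' target. Negative targets run the same loop in extension.
#'
#' @param geometry a `knee_geometry`.
#' @param target_angle total flexion, degrees (nonzero).
#' @param step increment, degrees (0 < step <= 5); 0.5 by default.
#' @param offset_hook optional `function(step_index)` returning a length-2
#'   offset (mm) applied to both osculating centres along (t_m, axis):
#'   experimental contact-trace retrieval hook; default neutral path.
#' @return object of class `knee_trajectory`: `steps` (per step: axis,
#'   angle, transform), `cumulative_angle`, `composed_transform`,
#'   `contacts` (per-step contact points in world and tibia frames),
#'   and the final `geometry`.
#' @export
compute_flexion_trajectory <- function(geometry, target_angle, step = 0.5,
                                       offset_hook = NULL) {
  if (target_angle == 0) .stopf("compute_flexion_trajectory: zero target")
  if (step <= 0 || step > 5) .stopf("compute_flexion_trajectory: bad step")
  sgn <- sign(target_angle)
  total <- abs(target_angle)
  n_full <- floor(total / step + 1e-9)
  angles <- rep(step, n_full)
  rem <- total - n_full * step
  if (rem > 1e-9) angles <- c(angles, rem)
  angles <- sgn * angles
  steps <- vector("list", length(angles))
  contacts <- vector("list", length(angles))
  cum <- rigid_transform()
  cum_angle <- 0
  g <- geometry
  for (k in seq_along(angles)) {
    res <- tryCatch({
      cm <- find_contact_point(g$condyle_medial, g$plateau_medial, "medial")
      cl <- find_contact_point(g$condyle_lateral, g$plateau_lateral, "lateral")
      sol <- solve_helical_axis(cm, cl, g$field_medial, g$field_lateral)
      if (!is.null(offset_hook)) {
        off <- offset_hook(k)
        shift <- off[1] * sol$medial$t + off[2] * sol$axis$direction
        sol$axis$I_m <- sol$axis$I_m + shift
        sol$axis$I_l <- sol$axis$I_l + shift
      }
      st <- step_flexion(g, sol$axis, angles[k])
      list(sol = sol, st = st)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      partial <- structure(list(steps = steps[seq_len(k - 1)],
                                cumulative_angle = cum_angle,
                                composed_transform = cum,
                                contacts = do.call(rbind, contacts),
                                geometry = g),
                           class = "knee_trajectory")
      cond <- structure(class = c("arthropose_trajectory_error", "error",
                                  "condition"),
                        list(message = sprintf(
                          "trajectory aborted at step %d: %s", k,
                          conditionMessage(res)),
                          call = sys.call(), partial = partial))
      stop(cond)
    }
    g <- res$st$geometry
    inv_prev <- invert_transform(cum)
    contacts[[k]] <- data.frame(
      step = k, compartment = c("medial", "lateral"),
      rbind(res$sol$medial$p, res$sol$lateral$p),
      rbind(apply_transform(inv_prev, res$sol$medial$p),
            apply_transform(inv_prev, res$sol$lateral$p)))
    cum <- compose_transform(res$st$transform, cum)
    cum_angle <- cum_angle + angles[k]
    steps[[k]] <- list(axis = res$sol$axis, angle = angles[k],
                       transform = res$st$transform)
  }
  contacts <- do.call(rbind, contacts)
  names(contacts)[3:8] <- c("wx", "wy", "wz", "tx", "ty", "tz")
  structure(list(steps = steps, cumulative_angle = cum_angle,
                 composed_transform = cum, contacts = contacts,
                 geometry = g),
            class = "knee_trajectory")
}

#' @export
print.knee_trajectory <- function(x, ...) {
  cat(sprintf("knee_trajectory: %d steps, cumulative %.3f deg\n",
              length(x$steps), x$cumulative_angle))
  invisible(x)
}

# rotation angle (deg) and axis of a rotation matrix
rotation_angle_axis <- function(R) {
  ang <- acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
  if (ang < 1e-12) return(list(angle = 0, axis = c(0, 0, 1)))
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  if (sqrt(sum(ax^2)) < 1e-12) {
    # angle ~ pi: extract axis from R + I
    M <- (R + diag(3)) / 2
    ax <- sqrt(pmax(0, diag(M)))
    k <- which.max(ax)
    ax <- M[, k] / ax[k]
  }
  list(angle = .rad2deg(ang), axis = .unit(ax))
}

#' Export a trajectory to JSON or CSV
#'
#' JSON holds, per step, the axis point pair, direction, step angle and the
#' 4x4 homogeneous matrix; CSV holds one flat row per step.
#' @param traj a `knee_trajectory`.
#' @param path output path ending in `.json` or `.csv`.
#' @export
write_trajectory <- function(traj, path) {
  ext <- tolower(tools::file_ext(path))
  rows <- lapply(seq_along(traj$steps), function(k) {
    s <- traj$steps[[k]]
    M <- rbind(cbind(s$transform$rotation, s$transform$translation), c(0, 0, 0, 1))
    list(step = k, angle = s$angle, I_m = s$axis$I_m, I_l = s$axis$I_l,
         direction = s$axis$direction, matrix = M)
  })
  if (ext == "json") {
    jsonlite::write_json(list(steps = rows,
                              cumulative_angle = traj$cumulative_angle),
                         path, auto_unbox = TRUE, digits = NA)
  } else if (ext == "csv") {
    df <- do.call(rbind, lapply(rows, function(r)
      data.frame(step = r$step, angle = r$angle,
                 t(c(r$I_m, r$I_l, r$direction)))))
    names(df)[3:11] <- c("Imx", "Imy", "Imz", "Ilx", "Ily", "Ilz",
                         "ux", "uy", "uz")
    utils::write.csv(df, path, row.names = FALSE)
  } else .stopf("write_trajectory: unsupported extension '%s'", ext)
  invisible(path)
}

#' Import a JSON trajectory for replay
#' @param path a JSON file written by [write_trajectory()].
#' @return a `knee_trajectory` (steps and composed transform only).
#' @export
read_trajectory <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  cum <- rigid_transform()
  steps <- lapply(j$steps, function(s) {
    M <- matrix(unlist(s$matrix), 4, 4, byrow = TRUE)  # JSON is row-major
    tf <- rigid_transform(M[1:3, 1:3], M[1:3, 4])
    list(axis = structure(list(direction = unlist(s$direction),
                               I_m = unlist(s$I_m), I_l = unlist(s$I_l)),
                          class = "helical_axis"),
         angle = s$angle, transform = tf)
  })
  for (s in steps) cum <- compose_transform(s$transform, cum)
  structure(list(steps = steps,
                 cumulative_angle = sum(vapply(steps, `[[`, 0, "angle")),
                 composed_transform = cum, contacts = NULL, geometry = NULL),
            class = "knee_trajectory")
}

#' Invert a trajectory (exact step-by-step replay in reverse)
#' @param traj a `knee_trajectory`.
#' @return a `knee_trajectory` whose composed transform is the exact inverse.
#' @export
invert_trajectory <- function(traj) {
  steps <- rev(lapply(traj$steps, function(s) {
    s$transform <- invert_transform(s$transform)
    s$angle <- -s$angle
    s
  }))
  cum <- rigid_transform()
  for (s in steps) cum <- compose_transform(s$transform, cum)
  structure(list(steps = steps,
                 cumulative_angle = -traj$cumulative_angle,
                 composed_transform = cum, contacts = NULL, geometry = NULL),
            class = "knee_trajectory")
}
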