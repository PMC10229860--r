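# Joint parameterisation and skeleton reconfiguration.
#
# Ball joints (shoulder, hip) rotate about least-squares sphere centres of
# the articular surfaces; the elbow is an in-plane hinge about the fitted
# trochlear-notch cylinder axis (the radius follows the ulna; supination/
# pronation is not modelled); the knee follows the geometry-derived flexion
# trajectory; vertebral columns split the total rotation evenly over the
# involved vertebrae, compounded caudal -> cranial as a kinematic chain
# (independent per-vertebra rotation would disarticulate the column).

.default_axes <- rbind(c(0, 0, 1), c(0, 1, 0), c(1, 0, 0))

#' Build joint definitions from a model and a joint config
#'
#' The config is a named list `joints`, one entry per joint with a `type`
#' (`ball`, `hinge`, `knee`, `spine`), `driven_parts`, optional
#' `child_joints`, and either explicit geometry (`center`, `axis`, condyle
#' meshes and plateau planes for a knee, vertebra entries for a spine) or
#' node-set references (`surface_set`) from which the geometry is fitted:
#' sphere centres for ball joints, cylinder axis + centre for hinges, and
#' per-vertebra centres for spines.
#'
#' @param model an `fe_model`.
#' @param config joint config list (see [read_joint_config()]).
#' @return named list of `joint_definition` objects.
#' @export
build_joint_definitions <- function(model, config) {
  joints <- config$joints
  if (is.null(joints)) .stopf("build_joint_definitions: config has no joints")
  out <- list()
  for (nm in names(joints)) {
    j <- joints[[nm]]
    def <- list(name = nm, type = j$type,
                driven_parts = j$driven_parts,
                child_joints = j$child_joints %||% character(),
                axes = if (!is.null(j$axes)) as.matrix(j$axes) else .default_axes)
    if (is.null(def$driven_parts) || length(def$driven_parts) == 0)
      .stopf("build_joint_definitions: joint '%s' drives no parts", nm)
    if (j$type == "ball") {
      if (!is.null(j$center)) {
        def$center <- as.numeric(j$center)
      } else {
        fs <- fit_sphere(node_coords(model, .set_ids(model, j$surface_set)))
        def$center <- fs$center
        def$fitted_radius <- fs$radius
      }
    } else if (j$type == "hinge") {
      if (!is.null(j$axis) && !is.null(j$center)) {
        def$axis <- .unit(as.numeric(j$axis))
        def$center <- as.numeric(j$center)
      } else {
        fc <- fit_cylinder(node_coords(model, .set_ids(model, j$surface_set)))
        def$axis <- fc$axis_dir
        def$center <- fc$axis_point
        def$fitted_radius <- fc$radius
      }
    } else if (j$type == "knee") {
      def$condyle_medial <- j$condyle_medial
      def$condyle_lateral <- j$condyle_lateral
      def$plateau_medial <- j$plateau_medial
      def$plateau_lateral <- j$plateau_lateral
      def$capsule_part <- j$capsule_part
      def$flesh_parts <- j$flesh_parts
      def$proximal_part <- j$proximal_part
      def$distal_part <- j$distal_part
      def$step <- j$step %||% 0.5
      if (is.null(def$condyle_medial) || is.null(def$plateau_medial))
        .stopf("build_joint_definitions: knee '%s' lacks condyle/plateau geometry", nm)
    } else if (j$type == "spine") {
      if (!is.null(j$centers)) {
        def$centers <- .as_pts(j$centers)
        def$vertebra_parts <- j$vertebra_parts
      } else {
        vs <- j$vertebrae
        def$centers <- do.call(rbind, lapply(vs, function(v)
          vertebra_center(model, v$part, v$top_set, v$bottom_set)))
        def$vertebra_parts <- vapply(vs, `[[`, 0L, "part")
      }
      def$flexion_only <- isTRUE(j$flexion_only)
    } else .stopf("build_joint_definitions: unknown joint type '%s'", j$type)
    out[[nm]] <- structure(def, class = "joint_definition")
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.set_ids <- function(model, set_ref) {
  # character (or a length-1 value naming an existing set) -> node-set
  # lookup; any other numeric vector is taken as explicit node ids
  key <- as.character(set_ref[1])
  if (is.character(set_ref) ||
      (length(set_ref) == 1 && key %in% names(model$node_sets))) {
    ids <- model$node_sets[[key]]
    if (is.null(ids)) .stopf("joint config references unknown node set '%s'",
                             key)
    ids
  } else as.integer(set_ref)
}

#' Rotation centre of a vertebra
#'
#' Midpoint of the centroids of the vertebra's top-face and bottom-face
#' node sets.
#' @param model an `fe_model`.
#' @param vertebra_part part id (unused in the computation, recorded).
#' @param top_set,bottom_set node-set ids or node-id vectors.
#' @return length-3 centre (mm).
#' @export
vertebra_center <- function(model, vertebra_part, top_set, bottom_set) {
  top <- .set_ids(model, top_set); bot <- .set_ids(model, bottom_set)
  if (length(top) == 0 || length(bot) == 0)
    .stopf("vertebra_center: empty node set")
  as.numeric(colMeans(node_coords(model, top)) +
               colMeans(node_coords(model, bot))) / 2
}

#' Per-vertebra transforms from an evenly split total rotation
#'
#' The total rotation is split evenly over the vertebrae; each vertebra
#' rotates about its own centre by the per-segment rotation (Rodrigues),
#' compounded caudal -> cranial: vertebra k receives segments 1..k, with
#' each segment's centre and axes first moved by the inferior segments.
#' A 3-angle total is split per axis and composed in the intrinsic
#' internal/external, flexion, adduction order per segment.
#'
#' @param centers `n x 3` ordered vertebra centres, caudal first.
#' @param total_rotation either `list(axis =, angle =)` (degrees) or a
#'   length-3 vector of intrinsic angles (degrees).
#' @param n_segments number of vertebrae (must equal `nrow(centers)`).
#' @param axes 3 x 3 anatomical axes rows for the 3-angle form.
#' @return list of `rigid_transform`s, one per vertebra (caudal first).
#' @export
spine_transforms <- function(centers, total_rotation,
                             n_segments = nrow(.as_pts(centers)),
                             axes = .default_axes) {
  centers <- .as_pts(centers)
  if (n_segments != nrow(centers) || n_segments < 1)
    .stopf("spine_transforms: n_segments must equal the number of centers")
  out <- vector("list", n_segments)
  Tacc <- rigid_transform()
  for (k in seq_len(n_segments)) {
    ck <- as.numeric(apply_transform(Tacc, centers[k, ]))
    if (is.list(total_rotation)) {
      ax <- as.numeric(total_rotation$axis %*% t(Tacc$rotation))
      Sk <- rodrigues(ax, total_rotation$angle / n_segments, ck)
    } else {
      ang <- as.numeric(total_rotation) / n_segments
      axk <- axes %*% t(Tacc$rotation)
      R <- euler_intrinsic(ang[1], ang[2], ang[3], joint_axes = axk)
      Sk <- rigid_transform(R, ck - as.numeric(R %*% ck))
    }
    Tacc <- compose_transform(Sk, Tacc)
    out[[k]] <- Tacc
  }
  out
}

# pose entry -> rotation matrix for a ball joint (3 intrinsic angles or an
# explicit 3x3 matrix, per the toolbox's pose conventions)
.ball_rotation <- function(entry, axes) {
  if (is.matrix(entry) && all(dim(entry) == c(3, 3))) return(entry)
  a <- as.numeric(entry)
  if (length(a) != 3) .stopf("ball joint pose must be 3 angles or a 3x3 matrix")
  euler_intrinsic(a[1], a[2], a[3], joint_axes = axes)
}

#' Reconfigure the skeleton from pose parameters
#'
#' Propagates rigid transforms down each kinematic chain from the fixed
#' root (pelvis/torso): each joint's rotation is built in its
#' proximally-moved frame (centres and axes transformed by the accumulated
#' proximal motion before use), knee transforms come from
#' [compute_flexion_trajectory()]'s composed transform, and every driven
#' part receives the accumulated transform.
#'
#' @param model an `fe_model`.
#' @param joints named `joint_definition` list from
#'   [build_joint_definitions()].
#' @param pose named list of pose parameters (degrees): ball joints take 3
#'   intrinsic angles or a 3x3 matrix, hinges and knees a flexion angle,
#'   spines an angle (flexion) or 3 angles. Absent entries mean identity.
#' @param step knee trajectory step (deg).
#' @return named list mapping part id (as character) to `rigid_transform`;
#'   attribute `trajectories` holds the knee trajectories by joint name.
#' @export
reconfigure_skeleton <- function(model, joints, pose, step = 0.5) {
  posed <- setdiff(names(pose), names(joints))
  if (length(posed))
    .stopf("reconfigure_skeleton: pose names undefined joint '%s'", posed[1])
  children <- unlist(lapply(joints, `[[`, "child_joints"))
  roots <- setdiff(names(joints), children)
  transforms <- list()
  trajectories <- list()
  visit <- function(nm, Tprox, seen) {
    if (nm %in% seen)
      .stopf("reconfigure_skeleton: cyclic joint chain at '%s'", nm)
    j <- joints[[nm]]
    if (is.null(j))
      .stopf("reconfigure_skeleton: missing definition for joint '%s'", nm)
    p <- pose[[nm]]
    Tj <- Tprox
    if (!is.null(p)) {
      if (j$type == "ball") {
        ctr <- as.numeric(apply_transform(Tprox, j$center))
        R <- Tprox$rotation %*% .ball_rotation(p, j$axes) %*% t(Tprox$rotation)
        Tj <- compose_transform(rigid_transform(R, ctr - as.numeric(R %*% ctr)),
                                Tprox)
      } else if (j$type == "hinge") {
        ctr <- as.numeric(apply_transform(Tprox, j$center))
        ax <- as.numeric(j$axis %*% t(Tprox$rotation))
        Tj <- compose_transform(rodrigues(ax, as.numeric(p), ctr), Tprox)
      } else if (j$type == "knee") {
        ang <- as.numeric(p)
        if (abs(ang) > 1e-12) {
          g <- knee_geometry(
            transform_mesh(j$condyle_medial, Tprox),
            transform_mesh(j$condyle_lateral, Tprox),
            plateau_plane(as.numeric(apply_transform(Tprox, j$plateau_medial$point)),
                          as.numeric(j$plateau_medial$normal %*% t(Tprox$rotation))),
            plateau_plane(as.numeric(apply_transform(Tprox, j$plateau_lateral$point)),
                          as.numeric(j$plateau_lateral$normal %*% t(Tprox$rotation))))
          traj <- compute_flexion_trajectory(g, ang, step = j$step %||% step)
          trajectories[[nm]] <<- traj
          Tj <- compose_transform(traj$composed_transform, Tprox)
        }
      } else if (j$type == "spine") {
        tot <- if (isTRUE(j$flexion_only) && length(p) == 1)
          c(0, as.numeric(p), 0) else p
        st <- spine_transforms(j$centers, tot, axes = j$axes)
        # vertebra parts get their own chain transforms
        for (k in seq_along(st)) {
          pid <- as.character(j$vertebra_parts[k])
          transforms[[pid]] <<- compose_transform(st[[k]], Tprox)
        }
        Tj <- compose_transform(st[[length(st)]], Tprox)
      }
    }
    if (j$type != "spine") {
      for (pid in j$driven_parts)
        transforms[[as.character(pid)]] <<- Tj
    }
    for (child in j$child_joints) visit(child, Tj, c(seen, nm))
  }
  for (r in roots) visit(r, rigid_transform(), character())
  for (pid in unique(c(model$solids$pid, model$shells$pid))) {
    key <- as.character(pid)
    if (is.null(transforms[[key]])) transforms[[key]] <- rigid_transform()
  }
  attr(transforms, "trajectories") <- trajectories
  transforms
}

#' Apply per-part rigid transforms to a model's nodes
#'
#' Each part's element nodes are moved by the part's transform. Nodes
#' shared between parts with different transforms are claimed by the first
#' part in id order (a warning is emitted when the transforms disagree
#' beyond 1e-9 at a shared node).
#'
#' @param model an `fe_model`.
#' @param transforms named list part id -> `rigid_transform`.
#' @return the transformed `fe_model`.
#' @export
apply_part_transforms <- function(model, transforms) {
  coords <- as.matrix(model$nodes[, c("x", "y", "z")])
  newc <- coords
  claimed <- rep(NA_character_, nrow(coords))
  part_nodes <- function(pid) {
    conn <- c(as.matrix(model$solids[model$solids$pid == pid, paste0("n", 1:8)]),
              as.matrix(model$shells[model$shells$pid == pid, paste0("n", 1:4)]))
    unique(conn[!is.na(conn)])
  }
  is_ident <- vapply(transforms, function(tf)
    max(abs(tf$rotation - diag(3))) < 1e-15 &&
      max(abs(tf$translation)) < 1e-15, TRUE)
  # identity transforms first, so shared nodes end up with the moving part
  for (key in names(transforms)[order(!is_ident)]) {
    tf <- transforms[[key]]
    ids <- part_nodes(as.integer(key))
    if (length(ids) == 0) next
    idx <- .node_index(model, ids)
    moved <- apply_transform(tf, coords[idx, , drop = FALSE])
    conflict <- !is.na(claimed[idx]) & claimed[idx] != key &
      !is_ident[claimed[idx]] & !is_ident[key] &
      .row_norms(moved - newc[idx, , drop = FALSE]) > 1e-9
    if (any(conflict))
      .warnf("apply_part_transforms: %d shared nodes claimed by parts with different transforms",
             sum(conflict))
    newc[idx, ] <- moved
    claimed[idx] <- key
  }
  model$nodes[, c("x", "y", "z")] <- newc
  model
}

#' Read a joint config (JSON or YAML file)
#' @param path config path.
#' @return config list for [build_joint_definitions()].
#' @export
read_joint_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      .stopf("read_joint_config: yaml package not installed; use JSON")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  # inline condyle/plateau geometry may be given as file references
  for (nm in names(cfg$joints)) {
    j <- cfg$joints[[nm]]
    for (fld in c("condyle_medial", "condyle_lateral"))
      if (is.character(j[[fld]]))
        cfg$joints[[nm]][[fld]] <- read_surface_mesh(j[[fld]])
    for (fld in c("plateau_medial", "plateau_lateral"))
      if (is.list(j[[fld]]) && !inherits(j[[fld]], "plateau_plane"))
        cfg$joints[[nm]][[fld]] <- plateau_plane(unlist(j[[fld]]$point),
                                                 unlist(j[[fld]]$normal))
  }
  cfg
}

#' Read a pose-parameter file (JSON, degrees)
#' @param path pose JSON path.
#' @return named pose list.
#' @export
read_pose <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(p, function(x) if (is.list(x)) unlist(x) else x)
}
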