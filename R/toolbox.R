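# Pipeline orchestration: skeleton reconfiguration -> per-joint
# morph-contact -> flesh TPS -> quality audit, plus the command-line
# interface.

#' Reposition an FE body model from pose parameters
#'
#' Bones are first rigidly reconfigured along the kinematic chains
#' ([reconfigure_skeleton()]); each synovial joint's capsule is then carried
#' through the morph-contact chain (preliminary reduced-landmark morph,
#' penetration detection/elimination, interface refinement), the enclosed
#' flesh is TPS-deformed from the boundary landmarks, and the result is
#' audited with [quality_report()]. Bone rigidity is verified (spot
#' isometry check) before returning. A zero pose returns the input model
#' unchanged.
#'
#' @param model an `fe_model`.
#' @param joints `joint_definition` list ([build_joint_definitions()]).
#' @param pose named pose list (degrees).
#' @param config optional overrides: `step` (knee step, deg), `lambda`
#'   (TPS ridge), `refine_weights`, `refine_iter`, `clearance` (mm),
#'   `seed` (recorded; the pipeline is deterministic).
#' @return list with `model` (repositioned), `report` (`quality_report`),
#'   `trajectories` (per knee joint), `transforms` (per part).
#' @export
reposition <- function(model, joints, pose, config = list()) {
  step <- config$step %||% 0.5
  transforms <- reconfigure_skeleton(model, joints, pose, step = step)
  trajectories <- attr(transforms, "trajectories")
  ident <- vapply(transforms, function(tf)
    max(abs(tf$rotation - diag(3))) < 1e-12 && max(abs(tf$translation)) < 1e-12,
    TRUE)
  if (all(ident)) {
    return(list(model = model, report = quality_report(model),
                trajectories = trajectories, transforms = transforms))
  }
  pre_nodes <- model$nodes
  out <- apply_part_transforms(model, transforms)
  # morph-contact for each knee-type joint that names a capsule
  soft_done <- FALSE
  for (nm in names(joints)) {
    j <- joints[[nm]]
    if (is.null(j$capsule_part)) next
    tf_prox <- transforms[[as.character(j$proximal_part)]]
    tf_dist <- transforms[[as.character(j$distal_part)]]
    # geometry in the *pre-transform* model frame
    pre_model <- model
    pre_model$nodes <- pre_nodes
    capsule <- extract_surface(pre_model, j$capsule_part)
    femur <- extract_surface(pre_model, j$proximal_part)
    tibia <- extract_surface(pre_model, j$distal_part)
    seg <- segment_capsule(capsule, femur, tibia)
    lm <- reduced_bone_landmarks(femur, tibia, tf_prox, tf_dist)
    cap1 <- preliminary_morph(capsule, lm, seg, tf_prox, tf_dist)
    # slave (involved) bone nodes: those the capsule actually covers, i.e.
    # whose pre-morph projection lands on the capsule interior, not its rim
    ed_c <- mesh_edges(capsule$faces)
    rim <- unique(c(ed_c$v1[is.na(ed_c$f2)], ed_c$v2[is.na(ed_c$f2)]))
    involved <- function(bone) {
      cp <- mesh_closest_point(capsule, bone$vertices)
      nf <- capsule$faces[cp$face, , drop = FALSE]
      which(rowSums(matrix(nf %in% rim, nrow = nrow(nf))) < 2)
    }
    femur_inv <- involved(femur); tibia_inv <- involved(tibia)
    femur_post <- transform_mesh(femur, tf_prox)
    tibia_post <- transform_mesh(tibia, tf_dist)
    slave <- function(mesh, keep) list(vertices = mesh$vertices[keep, , drop = FALSE])
    fixed <- c(seg$proximal, seg$distal)
    cap2 <- cap1
    slaves <- list(list(pre = slave(femur, femur_inv),
                        post = slave(femur_post, femur_inv)),
                   list(pre = slave(tibia, tibia_inv),
                        post = slave(tibia_post, tibia_inv)))
    for (bone_pair in slaves) {
      ref_signs <- sign(mesh_signed_distance(capsule, bone_pair$pre$vertices)$signed)
      rep_ <- detect_penetrations(bone_pair$post, cap2, ref_signs)
      if (length(rep_$nodes))
        cap2 <- resolve_penetrations(cap2, rep_, fixed = fixed,
                                     clearance = config$clearance %||% 0.1)
    }
    cap3 <- refine_interface(cap2, cap2, baseline = capsule,
                             free = seg$interior,
                             weights = config$refine_weights %||%
                               list(w_c = 1.0, w_e = 0.1, w_n = 0.01),
                             max_iter = config$refine_iter %||% 500)
    # refinement may graze a bone again: one corrective pull pass
    for (bone_pair in slaves) {
      rep_ <- detect_penetrations(bone_pair$post, cap3)
      if (length(rep_$nodes))
        cap3 <- resolve_penetrations(cap3, rep_, fixed = fixed,
                                     clearance = config$clearance %||% 0.1)
    }
    boundary <- list(
      source = rbind(capsule$vertices, femur$vertices, tibia$vertices),
      target = rbind(cap3$vertices, femur_post$vertices,
                     tibia_post$vertices),
      node_ids = c(capsule$source_node_ids, femur$source_node_ids,
                   tibia$source_node_ids))
    # capsule and bones share FE nodes at the attachment rings: keep the
    # capsule's (post-morph) copy of each duplicated landmark
    keep <- !duplicated(boundary$node_ids)
    boundary <- list(source = boundary$source[keep, , drop = FALSE],
                     target = boundary$target[keep, , drop = FALSE],
                     node_ids = boundary$node_ids[keep])
    soft_parts <- unique(c(j$flesh_parts, j$capsule_part))
    driven <- unique(unlist(lapply(joints, `[[`, "driven_parts")))
    skin <- setdiff(unique(c(out$solids$pid, out$shells$pid)),
                    c(driven, soft_parts))
    out <- deform_soft_tissue(out, boundary, unique(c(soft_parts, skin)))
    soft_done <- TRUE
  }
  # bone rigidity verification (spot check on inter-node distances)
  for (nm in names(joints)) {
    for (pid in joints[[nm]]$driven_parts) {
      conn <- model$solids[model$solids$pid == pid, paste0("n", 1:8)]
      if (nrow(conn) == 0) next
      ids <- unique(unlist(conn[1, ], use.names = FALSE))
      ids <- ids[!is.na(ids)]
      pre <- pre_nodes[match(ids, pre_nodes$id), c("x", "y", "z")]
      post <- out$nodes[match(ids, out$nodes$id), c("x", "y", "z")]
      d_pre <- stats::dist(pre); d_post <- stats::dist(post)
      if (max(abs(d_pre - d_post)) > 1e-6 * max(d_pre))
        .stopf("reposition: bone part %d is not rigid after transform", pid)
    }
  }
  list(model = out, report = quality_report(out),
       trajectories = trajectories, transforms = transforms)
}

# ---- command-line interface ------------------------------------------------

.cli_opts <- function(args) {
  # --key value pairs -> named list (flags win over a --config YAML/JSON)
  out <- list()
  k <- 1
  while (k <= length(args)) {
    key <- sub("^--", "", args[k])
    if (!startsWith(args[k], "--"))
      .stopf("unexpected CLI argument '%s'", args[k])
    out[[key]] <- if (k < length(args) && !startsWith(args[k + 1], "--")) {
      k <- k + 1; args[k]
    } else TRUE
    k <- k + 1
  }
  if (!is.null(out$config)) {
    cfg <- if (grepl("\\.ya?ml$", out$config)) yaml::read_yaml(out$config)
    else jsonlite::read_json(out$config, simplifyVector = TRUE)
    for (nm in names(cfg)) if (is.null(out[[nm]])) out[[nm]] <- cfg[[nm]]
  }
  out
}

#' Toolbox command-line entry point
#'
#' Subcommands: `reposition` (full pipeline: `--model`, `--joints`,
#' `--pose`, `--out`, optional `--report`, `--step`, `--seed`),
#' `knee-traj` (standalone trajectory: `--medial`, `--lateral`,
#' `--plateau-medial`, `--plateau-lateral`, `--target`, `--step`, `--out`),
#' `quality` (`--model`, thresholds, `--out`), and `fixture`
#' (`--kind toy_limb`, `--out` directory, `--seed`). Exit codes: 0 success,
#' 2 validation failure, 3 algorithm non-convergence, 4 I/O error.
#'
#' @param args character vector of CLI arguments (default: the command
#'   line).
#' @return exit status, invisibly (also used by the `arthropose` script).
#' @export
arthropose_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    cat("usage: arthropose <reposition|knee-traj|quality|fixture> [--opts]\n")
    return(invisible(2L))
  }
  cmd <- args[1]
  status <- tryCatch({
    o <- .cli_opts(args[-1])
    if (cmd == "reposition") {
      model <- read_keyword_model(o$model)
      cfg <- read_joint_config(o$joints)
      pose <- read_pose(o$pose)
      joints <- build_joint_definitions(model, cfg)
      res <- reposition(model, joints, pose,
                        config = list(step = as.numeric(o$step %||% 0.5),
                                      seed = as.integer(o$seed %||% 0)))
      write_keyword_model(res$model, o$out)
      if (!is.null(o$report)) write_quality_report(res$report, o$report)
      0L
    } else if (cmd == "knee-traj") {
      g <- knee_geometry(
        read_surface_mesh(o$medial), read_surface_mesh(o$lateral),
        local({p <- jsonlite::read_json(o[["plateau-medial"]], simplifyVector = TRUE)
               plateau_plane(p$point, p$normal)}),
        local({p <- jsonlite::read_json(o[["plateau-lateral"]], simplifyVector = TRUE)
               plateau_plane(p$point, p$normal)}))
      traj <- compute_flexion_trajectory(g, as.numeric(o$target),
                                         step = as.numeric(o$step %||% 0.5))
      write_trajectory(traj, o$out)
      0L
    } else if (cmd == "quality") {
      model <- read_keyword_model(o$model)
      thr <- list(warpage = as.numeric(o$warpage %||% 15),
                  aspect = as.numeric(o$aspect %||% 5),
                  jacobian = as.numeric(o$jacobian %||% 0.5))
      rep_ <- quality_report(model, thr)
      print(rep_)
      if (!is.null(o$out)) write_quality_report(rep_, o$out)
      0L
    } else if (cmd == "fixture") {
      kind <- o$kind %||% "toy_limb"
      dir.create(o$out, showWarnings = FALSE, recursive = TRUE)
      if (kind == "toy_limb") {
        fx <- make_toy_limb(seed = as.integer(o$seed %||% 0))
        write_keyword_model(fx$model, file.path(o$out, "toy_limb.k"))
        write_surface_mesh(fx$config$joints$knee$condyle_medial,
                           file.path(o$out, "condyle_medial.obj"))
        write_surface_mesh(fx$config$joints$knee$condyle_lateral,
                           file.path(o$out, "condyle_lateral.obj"))
        jsonlite::write_json(fx$truth, file.path(o$out, "truth.json"),
                             auto_unbox = TRUE, digits = NA)
      } else if (kind == "sphere_knee") {
        g <- make_sphere_knee()
        write_surface_mesh(g$condyle_medial, file.path(o$out, "condyle_medial.obj"))
        write_surface_mesh(g$condyle_lateral, file.path(o$out, "condyle_lateral.obj"))
        jsonlite::write_json(g$truth, file.path(o$out, "truth.json"),
                             auto_unbox = TRUE, digits = NA)
      } else .stopf("fixture: unknown kind '%s'", kind)
      0L
    } else {
      cat(sprintf("unknown subcommand '%s'\n", cmd))
      2L
    }
  },
  arthropose_trajectory_error = function(e) { message(conditionMessage(e)); 3L },
  arthropose_contact_error = function(e) { message(conditionMessage(e)); 3L },
  error = function(e) {
    message(conditionMessage(e))
    if (grepl("no such file|unwritable|cannot open", conditionMessage(e))) 4L
    else 2L
  })
  invisible(status)
}
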