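# LS-DYNA keyword-format subset I/O and boundary-surface extraction.
#
# Supported blocks: *NODE, *ELEMENT_SOLID, *ELEMENT_SHELL, *PART,
# *SET_NODE(_LIST). Unknown blocks are preserved verbatim so a read/write
# round trip does not lose solver cards this toolbox does not interpret.
# Coordinates are millimetres; ids are 1-based as in the format.

#' FE model container
#'
#' @param nodes data.frame with columns `id`, `x`, `y`, `z` (mm).
#' @param solids data.frame `eid`, `pid`, `n1`..`n8` (tets: n5..n8 = NA).
#' @param shells data.frame `eid`, `pid`, `n1`..`n4` (tris: n4 = NA).
#' @param parts data.frame `pid`, `title`.
#' @param node_sets named list: set id (as character) -> node-id vector.
#' @param extra character vector of verbatim unrecognised keyword blocks.
#' @return object of class `fe_model`.
#' @export
fe_model <- function(nodes = NULL, solids = NULL, shells = NULL,
                     parts = NULL, node_sets = list(), extra = character()) {
  empty_e <- function(n) {
    d <- as.data.frame(matrix(numeric(0), 0, 2 + n))
    names(d) <- c("eid", "pid", paste0("n", seq_len(n)))
    d
  }
  if (is.null(nodes)) nodes <- data.frame(id = integer(), x = numeric(),
                                          y = numeric(), z = numeric())
  if (is.null(solids)) solids <- empty_e(8)
  if (is.null(shells)) shells <- empty_e(4)
  if (is.null(parts)) parts <- data.frame(pid = integer(), title = character())
  m <- structure(list(nodes = nodes, solids = solids, shells = shells,
                      parts = parts, node_sets = node_sets, extra = extra),
                 class = "fe_model")
  validate_fe_model(m)
  m
}

#' Validate an FE model's invariants
#'
#' Checks id positivity/uniqueness, coordinate finiteness and element-to-node
#' referential integrity; stops with a descriptive error on violation.
#' @param model an `fe_model`.
#' @return the model, invisibly.
#' @export
validate_fe_model <- function(model) {
  nd <- model$nodes
  if (nrow(nd) > 0) {
    if (any(nd$id <= 0)) .stopf("fe_model: non-positive node id")
    if (anyDuplicated(nd$id)) .stopf("fe_model: duplicate node id %d",
                                     nd$id[anyDuplicated(nd$id)])
    if (!all(is.finite(as.matrix(nd[, c("x", "y", "z")]))))
      .stopf("fe_model: non-finite node coordinate")
  }
  for (tab in c("solids", "shells")) {
    e <- model[[tab]]
    if (nrow(e) == 0) next
    if (anyDuplicated(e$eid)) .stopf("fe_model: duplicate %s element id", tab)
    conn <- as.matrix(e[, grep("^n", names(e)), drop = FALSE])
    ref <- conn[!is.na(conn)]
    miss <- setdiff(unique(ref), nd$id)
    if (length(miss))
      .stopf("fe_model: %s element references missing node id %d",
             tab, miss[1])
  }
  for (sid in names(model$node_sets)) {
    miss <- setdiff(model$node_sets[[sid]], nd$id)
    if (length(miss))
      .stopf("fe_model: node set %s references missing node id %d",
             sid, miss[1])
  }
  invisible(model)
}

#' @export
print.fe_model <- function(x, ...) {
  cat(sprintf(
    "fe_model: %d nodes, %d solids, %d shells, %d parts, %d node sets\n",
    nrow(x$nodes), nrow(x$solids), nrow(x$shells), nrow(x$parts),
    length(x$node_sets)))
  invisible(x)
}

# split a data line: comma-separated, else fixed-width, else whitespace
.kw_fields <- function(line, widths) {
  if (grepl(",", line, fixed = TRUE)) {
    return(trimws(strsplit(line, ",", fixed = TRUE)[[1]]))
  }
  if (nchar(line) <= sum(widths) + 2 && !grepl("\\S\\s\\S.*\\s{3,}", line)) {
    # try fixed-width first
    starts <- cumsum(c(1, widths[-length(widths)]))
    out <- substring(line, starts, starts + widths - 1)
    out <- trimws(out)
    if (all(out == "" | grepl("^[-+0-9.eEdD ]+$", out))) return(out[out != ""])
  }
  trimws(strsplit(trimws(line), "\\s+")[[1]])
}

.kw_num <- function(x) suppressWarnings(as.numeric(gsub("[dD]", "e", x)))

#' Read an LS-DYNA keyword model (subset)
#'
#' Parses *NODE, *ELEMENT_SOLID, *ELEMENT_SHELL, *PART and
#' *SET_NODE(_LIST) blocks; both fixed-width and comma-separated data cards
#' are accepted (detected per line). All other keyword blocks are kept
#' verbatim and re-emitted by [write_keyword_model()].
#'
#' @param path path to a `.k`/`.key` file containing at least one *NODE block.
#' @return an `fe_model`.
#' @export
read_keyword_model <- function(path) {
  if (!file.exists(path)) .stopf("read_keyword_model: no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  n <- length(lines)
  is_kw <- startsWith(lines, "*")
  is_comment <- startsWith(lines, "$")
  nodes <- list(); solids <- list(); shells <- list()
  parts <- list(); node_sets <- list(); extra <- character()
  i <- 1
  parse_err <- function(ln, what)
    .stopf("read_keyword_model: malformed %s line %d: '%s'", what, ln,
           lines[ln])
  while (i <= n) {
    if (is_comment[i] || !nzchar(trimws(lines[i]))) { i <- i + 1; next }
    if (!is_kw[i]) .stopf("read_keyword_model: stray data at line %d", i)
    kw <- toupper(trimws(lines[i]))
    j <- i + 1
    while (j <= n && !is_kw[j]) j <- j + 1  # block body = [i+1, j-1]
    body <- setdiff(seq(i + 1, length.out = max(0, j - i - 1)),
                    which(is_comment))
    if (kw == "*END") break
    if (startsWith(kw, "*NODE")) {
      for (ln in body) {
        fl <- .kw_fields(lines[ln], c(8, 16, 16, 16))
        if (length(fl) < 4 || anyNA(.kw_num(fl[1:4]))) parse_err(ln, "*NODE")
        nodes[[length(nodes) + 1]] <- .kw_num(fl[1:4])
      }
    } else if (startsWith(kw, "*ELEMENT_SOLID")) {
      for (ln in body) {
        fl <- .kw_num(.kw_fields(lines[ln], rep(8, 10)))
        if (length(fl) < 6 || anyNA(fl)) parse_err(ln, "*ELEMENT_SOLID")
        fl <- c(fl, rep(NA_real_, 10 - length(fl)))[1:10]
        conn <- fl[3:10]
        # 4-noded tets may pad with zeros or repeat the last node
        conn[conn == 0] <- NA
        solids[[length(solids) + 1]] <- c(fl[1:2], conn)
      }
    } else if (startsWith(kw, "*ELEMENT_SHELL")) {
      for (ln in body) {
        fl <- .kw_num(.kw_fields(lines[ln], rep(8, 6)))
        if (length(fl) < 5 || anyNA(fl)) parse_err(ln, "*ELEMENT_SHELL")
        fl <- c(fl, rep(NA_real_, 6 - length(fl)))[1:6]
        conn <- fl[3:6]
        conn[conn == 0] <- NA
        if (!is.na(conn[4]) && conn[4] == conn[3]) conn[4] <- NA
        shells[[length(shells) + 1]] <- c(fl[1:2], conn)
      }
    } else if (startsWith(kw, "*PART")) {
      if (length(body) < 2) parse_err(i, "*PART")
      title <- trimws(lines[body[1]])
      pid <- .kw_num(.kw_fields(lines[body[2]], rep(10, 8)))[1]
      if (is.na(pid)) parse_err(body[2], "*PART")
      parts[[length(parts) + 1]] <- list(pid = as.integer(pid), title = title)
    } else if (startsWith(kw, "*SET_NODE")) {
      if (length(body) < 1) parse_err(i, "*SET_NODE")
      sid <- .kw_num(.kw_fields(lines[body[1]], rep(10, 8)))[1]
      ids <- integer()
      for (ln in body[-1]) {
        fl <- .kw_num(.kw_fields(lines[ln], rep(10, 8)))
        if (anyNA(fl)) parse_err(ln, "*SET_NODE")
        ids <- c(ids, as.integer(fl[fl != 0]))
      }
      node_sets[[as.character(as.integer(sid))]] <- ids
    } else if (kw == "*KEYWORD") {
      # header, ignore
    } else {
      extra <- c(extra, lines[i:(j - 1)])
    }
    i <- j
  }
  if (length(nodes) == 0)
    .stopf("read_keyword_model: no *NODE block in %s", path)
  nd <- do.call(rbind, nodes)
  nodes_df <- data.frame(id = as.integer(nd[, 1]), x = nd[, 2],
                         y = nd[, 3], z = nd[, 4])
  mk_elem <- function(lst, nn) {
    if (length(lst) == 0) return(NULL)
    m <- do.call(rbind, lst)
    d <- data.frame(eid = as.integer(m[, 1]), pid = as.integer(m[, 2]))
    for (k in seq_len(nn)) d[[paste0("n", k)]] <- as.integer(m[, 2 + k])
    d
  }
  parts_df <- if (length(parts))
    data.frame(pid = vapply(parts, `[[`, integer(1), "pid"),
               title = vapply(parts, `[[`, character(1), "title"))
  else NULL
  fe_model(nodes_df, mk_elem(solids, 8), mk_elem(shells, 4), parts_df,
           node_sets, extra)
}

#' Write an LS-DYNA keyword model (subset)
#'
#' Emits a file that [read_keyword_model()] reparses to an equal model.
#' Node coordinates are written comma-separated with 17 significant digits
#' (exact double round trip); preserved unknown blocks are re-emitted
#' verbatim.
#'
#' @param model an `fe_model` (validated before writing).
#' @param path output path.
#' @export
write_keyword_model <- function(model, path) {
  validate_fe_model(model)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  w("*KEYWORD")
  if (nrow(model$parts)) {
    for (i in seq_len(nrow(model$parts))) {
      w("*PART", model$parts$title[i], sprintf("%10d", model$parts$pid[i]))
    }
  }
  w("*NODE")
  nd <- model$nodes
  w(sprintf("%d,%.17g,%.17g,%.17g", nd$id, nd$x, nd$y, nd$z))
  if (nrow(model$solids)) {
    w("*ELEMENT_SOLID")
    conn <- as.matrix(model$solids[, paste0("n", 1:8)])
    conn[is.na(conn)] <- 0L
    w(sprintf("%d,%d,%s", model$solids$eid, model$solids$pid,
              apply(conn, 1, paste, collapse = ",")))
  }
  if (nrow(model$shells)) {
    w("*ELEMENT_SHELL")
    conn <- as.matrix(model$shells[, paste0("n", 1:4)])
    conn[is.na(conn)] <- 0L
    w(sprintf("%d,%d,%s", model$shells$eid, model$shells$pid,
              apply(conn, 1, paste, collapse = ",")))
  }
  for (sid in names(model$node_sets)) {
    w("*SET_NODE_LIST", sprintf("%10s", sid))
    ids <- model$node_sets[[sid]]
    for (k in seq(1, length(ids), by = 8))
      w(paste(sprintf("%10d", ids[k:min(k + 7, length(ids))]), collapse = ""))
  }
  if (length(model$extra)) w(model$extra)
  w("*END")
  invisible(path)
}

# node-id -> row-index lookup
.node_index <- function(model, ids) {
  idx <- match(ids, model$nodes$id)
  if (anyNA(idx))
    .stopf("fe_model: unknown node id %d", ids[which(is.na(idx))[1]])
  idx
}

#' Node coordinates by id
#' @param model an `fe_model`.
#' @param ids node ids.
#' @return `length(ids) x 3` coordinate matrix.
#' @export
node_coords <- function(model, ids) {
  as.matrix(model$nodes[.node_index(model, ids), c("x", "y", "z")])
}

# outward-oriented local face connectivities
.hex_faces <- rbind(c(1, 4, 3, 2), c(5, 6, 7, 8), c(1, 2, 6, 5),
                    c(2, 3, 7, 6), c(3, 4, 8, 7), c(4, 1, 5, 8))
.tet_faces <- rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))

#' Extract the boundary surface of FE parts as a triangle mesh
#'
#' Solid-element faces shared by exactly one solid form the boundary;
#' boundary quadrilaterals are split into two triangles along the shorter
#' diagonal (fewer sliver triangles for curvature estimation). Shell
#' elements contribute directly. Face orientation follows the standard
#' outward-corner ordering, so normals point away from the solid interior.
#' `source_node_ids` maps every mesh vertex back to its FE node id.
#'
#' @param model an `fe_model`.
#' @param part_ids part ids whose boundary is wanted.
#' @return a `tri_mesh`.
#' @export
extract_surface <- function(model, part_ids) {
  missing_parts <- setdiff(part_ids, c(model$solids$pid, model$shells$pid))
  if (length(missing_parts))
    .stopf("extract_surface: part %d has no elements", missing_parts[1])
  sol <- model$solids[model$solids$pid %in% part_ids, , drop = FALSE]
  shl <- model$shells[model$shells$pid %in% part_ids, , drop = FALSE]
  quads <- list(); tris <- list()
  if (nrow(sol)) {
    conn <- as.matrix(sol[, paste0("n", 1:8)])
    is_hex <- !is.na(conn[, 5])
    faces <- list()
    if (any(is_hex)) {
      hc <- conn[is_hex, , drop = FALSE]
      for (k in seq_len(nrow(.hex_faces)))
        faces[[length(faces) + 1]] <- hc[, .hex_faces[k, ], drop = FALSE]
    }
    if (any(!is_hex)) {
      tc <- conn[!is_hex, 1:4, drop = FALSE]
      for (k in seq_len(nrow(.tet_faces))) {
        f3 <- tc[, .tet_faces[k, ], drop = FALSE]
        faces[[length(faces) + 1]] <- cbind(f3, NA)
      }
    }
    allf <- do.call(rbind, faces)
    key <- apply(allf, 1, function(r) paste(sort(r[!is.na(r)]), collapse = "_"))
    cnt <- table(key)
    boundary <- allf[cnt[key] == 1, , drop = FALSE]
    isq <- !is.na(boundary[, 4])
    if (any(isq)) quads[[length(quads) + 1]] <- boundary[isq, , drop = FALSE]
    if (any(!isq)) tris[[length(tris) + 1]] <- boundary[!isq, 1:3, drop = FALSE]
  }
  if (nrow(shl)) {
    conn <- as.matrix(shl[, paste0("n", 1:4)])
    isq <- !is.na(conn[, 4])
    if (any(isq)) quads[[length(quads) + 1]] <- conn[isq, , drop = FALSE]
    if (any(!isq)) tris[[length(tris) + 1]] <- conn[!isq, 1:3, drop = FALSE]
  }
  quads <- if (length(quads)) do.call(rbind, quads) else matrix(0L, 0, 4)
  tris <- if (length(tris)) do.call(rbind, tris) else matrix(0L, 0, 3)
  used <- sort(unique(c(as.integer(quads), as.integer(tris))))
  used <- used[!is.na(used)]
  coords <- node_coords(model, used)
  remap <- function(ids) matrix(match(ids, used), nrow = nrow(ids))
  tri_out <- list()
  if (nrow(tris)) tri_out[[1]] <- remap(tris)
  if (nrow(quads)) {
    q <- remap(quads)
    d13 <- .row_norms(coords[q[, 1], , drop = FALSE] - coords[q[, 3], , drop = FALSE])
    d24 <- .row_norms(coords[q[, 2], , drop = FALSE] - coords[q[, 4], , drop = FALSE])
    use13 <- d13 <= d24
    tri_out[[length(tri_out) + 1]] <- rbind(
      q[use13, c(1, 2, 3), drop = FALSE], q[use13, c(1, 3, 4), drop = FALSE],
      q[!use13, c(1, 2, 4), drop = FALSE], q[!use13, c(2, 3, 4), drop = FALSE])
  }
  faces <- do.call(rbind, tri_out)
  mesh <- tri_mesh(coords, faces, source_node_ids = used)
  he <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  if (any(tabulate(match(key, unique(key))) > 2))
    .warnf("extract_surface: non-manifold boundary for parts %s",
           paste(part_ids, collapse = ","))
  mesh
}

# ---- standalone surface formats -------------------------------------------

#' Read a surface mesh (OBJ, ASCII STL, or ASCII PLY)
#' @param path input path; format chosen by extension.
#' @return a `tri_mesh`.
#' @export
read_surface_mesh <- function(path) {
  if (!file.exists(path)) .stopf("read_surface_mesh: no such file: %s", path)
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path, warn = FALSE)
  if (ext == "obj") {
    vl <- lines[startsWith(lines, "v ")]
    fl <- lines[startsWith(lines, "f ")]
    verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                   function(x) as.numeric(x[2:4])))
    faces <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(x) {
      idx <- as.integer(vapply(strsplit(x[-1], "/"), `[[`, "", 1))
      if (length(idx) != 3) .stopf("read_surface_mesh: non-triangle OBJ face")
      idx
    }))
    return(tri_mesh(verts, faces))
  }
  if (ext == "stl") {
    vl <- lines[grepl("^\\s*vertex ", lines)]
    verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                   function(x) as.numeric(x[2:4])))
    key <- apply(round(verts, 12), 1, paste, collapse = "_")
    uid <- match(key, unique(key))
    uverts <- verts[!duplicated(key), , drop = FALSE]
    faces <- matrix(uid, ncol = 3, byrow = TRUE)
    return(tri_mesh(uverts, faces))
  }
  if (ext == "ply") {
    nv <- as.integer(sub(".*vertex\\s+", "", lines[grepl("element vertex", lines)]))
    nf <- as.integer(sub(".*face\\s+", "", lines[grepl("element face", lines)]))
    hdr_end <- which(trimws(lines) == "end_header")[1]
    vl <- lines[hdr_end + seq_len(nv)]
    fl <- lines[hdr_end + nv + seq_len(nf)]
    verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                   function(x) as.numeric(x[1:3])))
    faces <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"),
                                   function(x) as.integer(x[2:4]) + 1L))
    return(tri_mesh(verts, faces))
  }
  .stopf("read_surface_mesh: unsupported extension '%s'", ext)
}

#' Write a surface mesh (OBJ, ASCII STL, or ASCII PLY)
#' @param mesh a `tri_mesh`.
#' @param path output path; format chosen by extension.
#' @export
write_surface_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  v <- mesh$vertices; f <- mesh$faces
  if (ext == "obj") {
    writeLines(c(sprintf("v %.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]),
                 sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])), path)
  } else if (ext == "stl") {
    fn <- face_normals(v, f)$normals
    body <- character(0)
    tri <- sprintf(
      "facet normal %g %g %g\n outer loop\n  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n endloop\nendfacet",
      fn[, 1], fn[, 2], fn[, 3],
      v[f[, 1], 1], v[f[, 1], 2], v[f[, 1], 3],
      v[f[, 2], 1], v[f[, 2], 2], v[f[, 2], 3],
      v[f[, 3], 1], v[f[, 3], 2], v[f[, 3], 3])
    writeLines(c("solid arthropose", tri, "endsolid arthropose"), path)
  } else if (ext == "ply") {
    hdr <- c("ply", "format ascii 1.0",
             sprintf("element vertex %d", nrow(v)),
             "property double x", "property double y", "property double z",
             sprintf("element face %d", nrow(f)),
             "property list uchar int vertex_indices", "end_header")
    writeLines(c(hdr, sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]),
                 sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)),
               path)
  } else .stopf("write_surface_mesh: unsupported extension '%s'", ext)
  invisible(path)
}
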