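# FE element quality metrics and threshold audits. All three metrics are
# dimensionless and invariant to rigid motion and uniform scaling.

# corner -> (neighbour a, b, c) orderings giving det = +1 on the unit cube
.hex_corner_nbrs <- rbind(c(2, 4, 5), c(3, 1, 6), c(4, 2, 7), c(1, 3, 8),
                          c(8, 6, 1), c(5, 7, 2), c(6, 8, 3), c(7, 5, 4))

.hex_edges <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1),
                    c(5, 6), c(6, 7), c(7, 8), c(8, 5),
                    c(1, 5), c(2, 6), c(3, 7), c(4, 8))
.tet_edges <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))

# vectorised scaled Jacobian over an n x 8 x 3 corner array (list of 8
# n x 3 matrices); returns length-n vector
.scaled_jacobian_hex_vec <- function(C) {
  n <- nrow(C[[1]])
  mn <- rep(Inf, n)
  for (k in 1:8) {
    nb <- .hex_corner_nbrs[k, ]
    e1 <- C[[nb[1]]] - C[[k]]
    e2 <- C[[nb[2]]] - C[[k]]
    e3 <- C[[nb[3]]] - C[[k]]
    l1 <- .row_norms(e1); l2 <- .row_norms(e2); l3 <- .row_norms(e3)
    d <- rowSums(e1 * .cross3(e2, e3)) / pmax(l1 * l2 * l3,
                                              .Machine$double.xmin)
    d[l1 < 1e-12 | l2 < 1e-12 | l3 < 1e-12] <- 0  # coincident corners
    mn <- pmin(mn, d)
  }
  pmax(pmin(mn, 1), -1)
}

.warpage_quad_vec <- function(a, b, c_, d) {
  ang <- function(n1, n2) {
    cs <- rowSums(n1 * n2) /
      pmax(.row_norms(n1) * .row_norms(n2), .Machine$double.xmin)
    .rad2deg(acos(pmin(1, pmax(-1, cs))))
  }
  # split along diagonal a-c and along b-d, take the worse
  w1 <- ang(.cross3(b - a, c_ - a), .cross3(c_ - a, d - a))
  w2 <- ang(.cross3(b - a, d - a), .cross3(c_ - b, d - b))
  pmax(w1, w2)
}

.aspect_ratio_vec <- function(corners, edges) {
  n <- nrow(corners[[1]])
  mx <- rep(0, n); mn <- rep(Inf, n)
  for (k in seq_len(nrow(edges))) {
    l <- .row_norms(corners[[edges[k, 2]]] - corners[[edges[k, 1]]])
    mx <- pmax(mx, l); mn <- pmin(mn, l)
  }
  ifelse(mn < 1e-12, Inf, mx / mn)
}

#' Scaled Jacobian of a hexahedral element
#'
#' Minimum over the 8 corners of the determinant of the normalised
#' edge-vector triad at that corner (preprocessor convention): 1 for a
#' cube, <= 0 for a degenerate or inverted element.
#'
#' @param corners `8 x 3` matrix in standard hex node ordering (nodes 1-4
#'   bottom face counter-clockwise, 5-8 the top face above them).
#' @return scalar in `[-1, 1]`.
#' @export
scaled_jacobian_hex <- function(corners) {
  corners <- .as_pts(corners)
  if (nrow(corners) != 8) .stopf("scaled_jacobian_hex: need 8 corners")
  C <- lapply(1:8, function(k) corners[k, , drop = FALSE])
  .scaled_jacobian_hex_vec(C)
}

#' Warpage of a quadrilateral face
#'
#' Angle (degrees) between the normals of the two triangles obtained by
#' splitting the quad along a diagonal, maximised over the two diagonals.
#' Zero for a planar quad.
#'
#' @param corners `4 x 3` matrix of corner coordinates in order.
#' @return warpage angle in degrees, >= 0.
#' @export
warpage_quad <- function(corners) {
  corners <- .as_pts(corners)
  if (nrow(corners) != 4 || anyDuplicated(round(corners, 12)))
    .stopf("warpage_quad: need 4 distinct corners")
  n1 <- .cross3(corners[2, ] - corners[1, ], corners[3, ] - corners[1, ])
  if (.row_norms(n1) < 1e-12) .stopf("warpage_quad: collinear corners")
  .warpage_quad_vec(corners[1, , drop = FALSE], corners[2, , drop = FALSE],
                    corners[3, , drop = FALSE], corners[4, , drop = FALSE])
}

#' Aspect ratio of an element
#'
#' Longest edge length over shortest edge length along the element's edge
#' list (hex: 12 edges, tet: 6, quad: 4, triangle: 3).
#'
#' @param corners `k x 3` corner matrix (k in 3, 4 with `type`, or 8).
#' @param type one of `"hex"`, `"tet"`, `"quad"`, `"tri"`; inferred from the
#'   corner count when unambiguous (8 -> hex, 3 -> tri, 4 -> quad).
#' @return scalar >= 1 (`Inf` sentinel for a zero-length edge).
#' @export
aspect_ratio <- function(corners, type = NULL) {
  corners <- .as_pts(corners)
  if (is.null(type))
    type <- switch(as.character(nrow(corners)), "8" = "hex", "4" = "quad",
                   "3" = "tri", .stopf("aspect_ratio: ambiguous corner count"))
  edges <- switch(type,
                  hex = .hex_edges, tet = .tet_edges,
                  quad = rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1)),
                  tri = rbind(c(1, 2), c(2, 3), c(3, 1)),
                  .stopf("aspect_ratio: unknown type '%s'", type))
  C <- lapply(seq_len(nrow(corners)), function(k) corners[k, , drop = FALSE])
  .aspect_ratio_vec(C, edges)
}

#' Threshold-based mesh-quality audit
#'
#' Evaluates warpage on shell quads and on every hex face (element value =
#' max over its 6 faces), scaled Jacobian on hexes, and aspect ratio on all
#' elements, then counts elements violating `warpage > thresholds$warpage`,
#' `aspect > thresholds$aspect`, `jacobian < thresholds$jacobian`. Each
#' metric's failing fraction is taken over the elements the metric applies
#' to; the report is a pure function of the model.
#'
#' @param model an `fe_model` with at least one element.
#' @param thresholds named list with `warpage` (deg), `aspect`, `jacobian`.
#' @return object of class `quality_report`.
#' @export
quality_report <- function(model,
                           thresholds = list(warpage = 15.0, aspect = 5.0,
                                             jacobian = 0.5)) {
  n_sol <- nrow(model$solids); n_shl <- nrow(model$shells)
  if (n_sol + n_shl == 0) .stopf("quality_report: model has no elements")
  metrics <- list(warpage = list(values = numeric(0), ids = integer(0)),
                  aspect = list(values = numeric(0), ids = integer(0)),
                  jacobian = list(values = numeric(0), ids = integer(0)))
  push <- function(metric, ids, vals) {
    metrics[[metric]]$values <<- c(metrics[[metric]]$values, vals)
    metrics[[metric]]$ids <<- c(metrics[[metric]]$ids, ids)
  }
  if (n_sol) {
    conn <- as.matrix(model$solids[, paste0("n", 1:8)])
    is_hex <- !is.na(conn[, 5])
    if (any(is_hex)) {
      hc <- conn[is_hex, , drop = FALSE]
      ids <- model$solids$eid[is_hex]
      C <- lapply(1:8, function(k) node_coords(model, hc[, k]))
      push("jacobian", ids, .scaled_jacobian_hex_vec(C))
      push("aspect", ids, .aspect_ratio_vec(C, .hex_edges))
      wmax <- rep(0, nrow(hc))
      for (k in seq_len(nrow(.hex_faces))) {
        fidx <- .hex_faces[k, ]
        wmax <- pmax(wmax, .warpage_quad_vec(C[[fidx[1]]], C[[fidx[2]]],
                                             C[[fidx[3]]], C[[fidx[4]]]))
      }
      push("warpage", ids, wmax)
    }
    if (any(!is_hex)) {
      tc <- conn[!is_hex, 1:4, drop = FALSE]
      C <- lapply(1:4, function(k) node_coords(model, tc[, k]))
      push("aspect", model$solids$eid[!is_hex], .aspect_ratio_vec(C, .tet_edges))
    }
  }
  if (n_shl) {
    conn <- as.matrix(model$shells[, paste0("n", 1:4)])
    isq <- !is.na(conn[, 4])
    if (any(isq)) {
      qc <- conn[isq, , drop = FALSE]
      C <- lapply(1:4, function(k) node_coords(model, qc[, k]))
      push("warpage", model$shells$eid[isq],
           .warpage_quad_vec(C[[1]], C[[2]], C[[3]], C[[4]]))
      push("aspect", model$shells$eid[isq],
           .aspect_ratio_vec(C, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1))))
    }
    if (any(!isq)) {
      tc <- conn[!isq, 1:3, drop = FALSE]
      C <- lapply(1:3, function(k) node_coords(model, tc[, k]))
      push("aspect", model$shells$eid[!isq],
           .aspect_ratio_vec(C, rbind(c(1, 2), c(2, 3), c(3, 1))))
    }
  }
  out <- list()
  for (m in names(metrics)) {
    vals <- metrics[[m]]$values; ids <- metrics[[m]]$ids
    thr <- thresholds[[m]]
    fail <- switch(m, warpage = vals > thr, aspect = vals > thr,
                   jacobian = vals < thr)
    worst_i <- switch(m, jacobian = which.min(vals), which.max(vals))
    out[[m]] <- list(threshold = thr, n_evaluated = length(vals),
                     failing_count = sum(fail),
                     failing_fraction = if (length(vals)) sum(fail) / length(vals) else 0,
                     worst_value = if (length(vals)) vals[worst_i] else NA,
                     worst_element = if (length(vals)) ids[worst_i] else NA,
                     failing_ids = ids[fail])
  }
  structure(list(metrics = out, n_solids = n_sol, n_shells = n_shl,
                 thresholds = thresholds),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("quality_report: %d solids, %d shells\n", x$n_solids, x$n_shells))
  for (m in names(x$metrics)) {
    mm <- x$metrics[[m]]
    cat(sprintf("  %-9s thr %-6g fail %d/%d (%.2f%%), worst %.4g (elem %s)\n",
                m, mm$threshold, mm$failing_count, mm$n_evaluated,
                100 * mm$failing_fraction, mm$worst_value,
                as.character(mm$worst_element)))
  }
  invisible(x)
}

#' Write a quality report as JSON
#' @param report a `quality_report`.
#' @param path output path.
#' @export
write_quality_report <- function(report, path) {
  flat <- lapply(report$metrics, function(m)
    m[c("threshold", "n_evaluated", "failing_count", "failing_fraction",
        "worst_value", "worst_element")])
  jsonlite::write_json(list(metrics = flat, n_solids = report$n_solids,
                            n_shells = report$n_shells),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
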