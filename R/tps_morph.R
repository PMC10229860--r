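# Thin-plate-spline displacement interpolation. The interpolated variable is
# the nodal displacement field (target - source); the stored affine block is
# the total affine map, so an identity morph has affine = [I | 0] and zero
# kernel weights. Kernel: phi(r) = r, the 3D biharmonic spline (the 2D
# r^2 log r kernel would not minimise bending energy in a volume).

# The 3D biharmonic kernel is phi(r) = r up to sign; the sign is absorbed
# by the weights and does not change the fitted interpolant, but -r makes
# the kernel block conditionally positive definite under the polynomial
# side conditions, so the lambda ridge is well-posed and w' K w is a
# non-negative bending-energy norm.
.tps_kernel <- function(d) -d

# greedy farthest-point subsample, deterministic (starts nearest centroid)
farthest_point_sample <- function(points, m) {
  points <- .as_pts(points)
  n <- nrow(points)
  if (m >= n) return(seq_len(n))
  start <- which.min(.row_norms(sweep(points, 2, colMeans(points))))
  sel <- integer(m)
  sel[1] <- start
  d <- .row_norms(sweep(points, 2, points[start, ]))
  for (k in 2:m) {
    sel[k] <- which.max(d)
    d <- pmin(d, .row_norms(sweep(points, 2, points[sel[k], ])))
  }
  sort(sel)
}

#' Fit a thin-plate-spline displacement model
#'
#' Solves the standard TPS linear system with 3D kernel `phi(r) = r` and an
#' affine term; interpolation is exact at the landmarks when `lambda = 0`.
#' Above 5000 landmarks the set is reduced by deterministic farthest-point
#' subsampling (dense O(n^3) solve), with a warning.
#'
#' @param source,target `n x 3` homologous landmark matrices (mm), n >= 4,
#'   source non-coplanar and pairwise distinct.
#' @param lambda ridge regularisation on the kernel block, >= 0.
#' @return object of class `tps_model`: `source`, `affine` (3 x 4 total
#'   affine map), `weights` (n x 3 kernel weights), `lambda`.
#' @export
fit_tps <- function(source, target, lambda = 0) {
  source <- .as_pts(source); target <- .as_pts(target)
  if (nrow(source) != nrow(target))
    .stopf("fit_tps: source/target landmark counts differ")
  if (nrow(source) < 4) .stopf("fit_tps: need at least 4 landmarks")
  if (nrow(source) > 5000) {
    .warnf("fit_tps: %d landmarks, farthest-point subsampling to 5000",
           nrow(source))
    keep <- farthest_point_sample(source, 5000)
    source <- source[keep, , drop = FALSE]
    target <- target[keep, , drop = FALSE]
  }
  n <- nrow(source)
  D <- as.matrix(stats::dist(source))
  if (lambda == 0 && any(D[upper.tri(D)] < 1e-6))
    .stopf(paste("fit_tps: duplicate source landmarks (min distance < 1e-6);",
                 "deduplicate or use lambda > 0"))
  P <- cbind(1, source)
  if (qr(P)$rank < 4)
    .stopf("fit_tps: source landmarks are coplanar (rank-deficient system)")
  K <- .tps_kernel(D)
  A <- rbind(cbind(K + lambda * diag(n), P),
             cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(target - source, matrix(0, 4, 3))
  sol <- solve(A, rhs)
  for (pass in 1:3) {                          # iterative refinement
    resid <- rhs - A %*% sol
    if (max(abs(resid)) < 1e-12) break
    sol <- sol + solve(A, resid)
  }
  W <- unname(sol[seq_len(n), , drop = FALSE])
  aff_disp <- sol[n + 1:4, , drop = FALSE]     # [a0; B'] of the displacement
  affine <- unname(cbind(t(aff_disp[2:4, , drop = FALSE]) + diag(3),
                         aff_disp[1, ]))
  structure(list(source = unname(source), affine = affine, weights = W,
                 lambda = lambda),
            class = "tps_model")
}

#' Evaluate a thin-plate-spline model
#'
#' `f(x) = affine [x; 1] + sum_i w_i phi(|x - s_i|)`, evaluated for all rows.
#'
#' @param model a `tps_model`.
#' @param points `m x 3` matrix of points to map.
#' @return `m x 3` matrix of mapped points.
#' @export
apply_tps <- function(model, points) {
  x <- .as_pts(points)
  out <- x %*% t(model$affine[, 1:3]) +
    matrix(model$affine[, 4], nrow(x), 3, byrow = TRUE)
  src <- model$source
  chunk <- max(1L, floor(4e6 / nrow(src)))
  for (i0 in seq(1, nrow(x), by = chunk)) {
    i <- i0:min(i0 + chunk - 1, nrow(x))
    xi <- x[i, , drop = FALSE]
    d2 <- outer(rowSums(xi^2), rep(1, nrow(src))) +
      outer(rep(1, length(i)), rowSums(src^2)) - 2 * xi %*% t(src)
    # the expanded form cancels catastrophically near d = 0 (sqrt of the
    # ~1e-14 residue is ~1e-7): recompute tiny entries directly
    tau <- 1e3 * .Machine$double.eps * max(1, max(abs(d2)))
    small <- which(d2 < tau, arr.ind = TRUE)
    if (nrow(small)) {
      d2[small] <- rowSums((xi[small[, 1], , drop = FALSE] -
                            src[small[, 2], , drop = FALSE])^2)
    }
    out[i, ] <- out[i, ] + .tps_kernel(sqrt(pmax(d2, 0))) %*% model$weights
  }
  out
}

#' Bending-energy norm of a TPS model
#'
#' `trace(W' K W)` with K the kernel matrix on the source landmarks;
#' non-increasing in the regularisation `lambda` for a fixed landmark set.
#' @param model a `tps_model`.
#' @return scalar energy norm.
#' @export
tps_bending_energy <- function(model) {
  K <- .tps_kernel(as.matrix(stats::dist(model$source)))
  sum(diag(t(model$weights) %*% K %*% model$weights))
}

#' Read/write landmark pairs as CSV (id, sx, sy, sz, tx, ty, tz)
#' @param path CSV path.
#' @return list with `source` and `target` matrices.
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path)
  list(source = as.matrix(df[, c("sx", "sy", "sz")]),
       target = as.matrix(df[, c("tx", "ty", "tz")]))
}

#' @rdname read_landmarks
#' @param source,target landmark matrices to write.
#' @export
write_landmarks <- function(source, target, path) {
  source <- .as_pts(source); target <- .as_pts(target)
  df <- data.frame(id = seq_len(nrow(source)), sx = source[, 1],
                   sy = source[, 2], sz = source[, 3], tx = target[, 1],
                   ty = target[, 2], tz = target[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
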