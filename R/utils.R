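# Internal vector helpers. All geometry is in millimetres; angles at the
# public interface are degrees, radians internally.

.row_norms <- function(m) sqrt(rowSums(m * m))

.normalize_rows <- function(m) {
  n <- .row_norms(m)
  m / pmax(n, .Machine$double.xmin)
}

.cross3 <- function(a, b) {
  # row-wise cross product of n x 3 matrices (or length-3 vectors)
  if (is.null(dim(a))) a <- matrix(a, nrow = 1)
  if (is.null(dim(b))) b <- matrix(b, nrow = 1)
  if (nrow(a) == 1L && nrow(b) > 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

.unit <- function(v) {
  n <- sqrt(sum(v * v))
  if (n < .Machine$double.xmin) stop("cannot normalize a zero vector")
  v / n
}

.deg2rad <- function(d) d * pi / 180
.rad2deg <- function(r) r * 180 / pi

.as_pts <- function(x) {
  if (is.null(dim(x))) matrix(x, ncol = 3) else as.matrix(x)
}

# any unit vector orthogonal to v
.any_orthogonal <- function(v) {
  v <- .unit(v)
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  .unit(ref - sum(ref * v) * v)
}

.sym6_to_mat <- function(s) {
  # (xx, xy, xz, yy, yz, zz) -> 3x3 symmetric
  matrix(c(s[1], s[2], s[3],
           s[2], s[4], s[5],
           s[3], s[5], s[6]), 3, 3)
}

.mat_to_sym6 <- function(m) {
  c(m[1, 1], m[1, 2], m[1, 3], m[2, 2], m[2, 3], m[3, 3])
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
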