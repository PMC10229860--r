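# independent brute-force metric oracles: direct enumeration over corners,
# diagonal splits and edge lists (never call the package's vectorised path)

bf_scaled_jacobian <- function(corners) {
  nbrs <- arthropose:::.hex_corner_nbrs
  vals <- vapply(1:8, function(k) {
    e <- lapply(1:3, function(j) {
      v <- corners[nbrs[k, j], ] - corners[k, ]
      v / sqrt(sum(v^2))
    })
    det(cbind(e[[1]], e[[2]], e[[3]]))
  }, 0)
  min(vals)
}

bf_warpage <- function(corners) {
  ang <- function(n1, n2)
    acos(min(1, max(-1, sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))))) * 180 / pi
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  a <- corners[1, ]; b <- corners[2, ]; c_ <- corners[3, ]; d <- corners[4, ]
  max(ang(cr(b - a, c_ - a), cr(c_ - a, d - a)),
      ang(cr(b - a, d - a), cr(c_ - b, d - b)))
}

bf_aspect_hex <- function(corners) {
  e <- arthropose:::.hex_edges
  l <- vapply(seq_len(nrow(e)), function(k)
    sqrt(sum((corners[e[k, 2], ] - corners[e[k, 1], ])^2)), 0)
  max(l) / min(l)
}
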