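test_that("curvature tensor vanishes on a flat grid", {
  fld <- curvature_tensor_field(flat_grid_mesh(8))
  interior <- which(fld$reliable)
  expect_gt(length(interior), 0)
  expect_lt(max(abs(fld$tensors[interior, ])), 1e-9)
})

test_that("curvature field matches analytic sphere and cylinder values", {
  # unit sphere: kn = 1 in every tangent direction, within 5%
  m <- uv_sphere(R = 1, edge = 0.1)
  fld <- curvature_tensor_field(m)
  set.seed(7)
  for (i in sample(nrow(m$vertices), 60)) {
    n <- fld$normals[i, ]
    t1 <- arthropose:::.any_orthogonal(n)
    ang <- stats::runif(1, 0, pi)
    tv <- cos(ang) * t1 + sin(ang) * as.numeric(arthropose:::.cross3(n, t1))
    kn <- normal_curvature(arthropose:::.sym6_to_mat(fld$tensors[i, ]), tv)
    expect_gt(kn, 0.95); expect_lt(kn, 1.05)
  }
  # cylinder R = 2: 0.5 circumferential, ~0 axial (eigenvalue-swap check)
  mc <- cyl_strip(R = 2, L = 8, edge = 0.2)
  fc <- curvature_tensor_field(mc)
  mid <- which(fc$reliable & abs(mc$vertices[, 2]) < 1)
  for (i in mid[seq(1, length(mid), by = 23)]) {
    n <- fc$normals[i, ]
    C <- arthropose:::.sym6_to_mat(fc$tensors[i, ])
    t_circ <- arthropose:::.unit(as.numeric(arthropose:::.cross3(c(0, 1, 0), n)))
    t_ax <- arthropose:::.unit(c(0, 1, 0) - sum(c(0, 1, 0) * n) * n)
    expect_equal(normal_curvature(C, t_circ), 0.5, tolerance = 0.05)
    expect_lt(abs(normal_curvature(C, t_ax)), 0.025)
  }
})

test_that("curvature error decreases monotonically with refinement", {
  errs <- vapply(c(0.4, 0.2, 0.1), function(edge) {
    m <- uv_sphere(R = 1, edge = edge)
    fld <- curvature_tensor_field(m)
    ks <- vapply(seq_len(nrow(m$vertices)), function(i) {
      tv <- arthropose:::.any_orthogonal(fld$normals[i, ])
      normal_curvature(arthropose:::.sym6_to_mat(fld$tensors[i, ]), tv)
    }, 0)
    max(abs(ks - 1))
  }, 0)
  expect_true(all(diff(errs) < 0))
})

test_that("tensor field is rotation-equivariant", {
  m <- uv_sphere(R = 1.5, edge = 0.3, center = c(0.3, -0.2, 0.1))
  fld <- curvature_tensor_field(m)
  set.seed(11)
  R <- random_rotation()
  m2 <- tri_mesh(m$vertices %*% t(R), m$faces, normals = m$normals %*% t(R))
  fld2 <- curvature_tensor_field(m2)
  for (i in seq(1, nrow(m$vertices), by = 57)) {
    C <- arthropose:::.sym6_to_mat(fld$tensors[i, ])
    C2 <- arthropose:::.sym6_to_mat(fld2$tensors[i, ])
    expect_equal(C2, R %*% C %*% t(R), tolerance = 1e-8)
  }
})

test_that("normal_curvature implements the quadratic form", {
  u <- c(1, 0, 0); v <- c(0, 1, 0)
  C <- 1 * tcrossprod(u) + 0 * tcrossprod(v)
  expect_equal(normal_curvature(C, u), 1)
  t45 <- (u + v) / sqrt(2)
  expect_equal(normal_curvature(C, t45), 0.5)  # Euler's formula
  expect_equal(normal_curvature(matrix(0, 3, 3), t45), 0)
  expect_error(normal_curvature(C, c(1, 1, 0)), "unit")
})

test_that("interpolate_tensor is the barycentric weighted sum", {
  m <- flat_grid_mesh(2)
  fld <- curvature_tensor_field(m)
  fld$tensors[m$faces[1, ], ] <- matrix(stats::rnorm(18), 3, 6)
  C1 <- arthropose:::.sym6_to_mat(fld$tensors[m$faces[1, 1], ])
  expect_equal(interpolate_tensor(fld, 1, c(1, 0, 0)), C1)
  Cm <- (arthropose:::.sym6_to_mat(fld$tensors[m$faces[1, 1], ]) +
         arthropose:::.sym6_to_mat(fld$tensors[m$faces[1, 2], ]) +
         arthropose:::.sym6_to_mat(fld$tensors[m$faces[1, 3], ])) / 3
  expect_equal(interpolate_tensor(fld, 1, rep(1 / 3, 3)), Cm)
  expect_error(interpolate_tensor(fld, 1, c(0.6, 0.6, 0.2)), "sum to 1")
})

test_that("fit_sphere recovers exact and noisy spheres, rejects coplanar", {
  set.seed(3)
  dirs <- matrix(stats::rnorm(300), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  pts <- sweep(25 * dirs, 2, c(1, 2, 3), `+`)
  fs <- fit_sphere(pts)
  expect_equal(fs$center, c(1, 2, 3), tolerance = 1e-9)
  expect_equal(fs$radius, 25, tolerance = 1e-9)
  # hemisphere + noise
  set.seed(42)
  d2 <- matrix(stats::rnorm(1500), ncol = 3)
  d2 <- d2 / sqrt(rowSums(d2^2))
  d2[, 3] <- abs(d2[, 3])
  noisy <- sweep(25 * d2 + 0.1 * matrix(stats::rnorm(1500), ncol = 3),
                 2, c(1, 2, 3), `+`)
  fs2 <- fit_sphere(noisy)
  expect_lt(sqrt(sum((fs2$center - c(1, 2, 3))^2)), 0.05)
  expect_error(fit_sphere(cbind(stats::runif(4), stats::runif(4), 0)),
               "coplanar")
  expect_error(fit_sphere(pts[1:3, ]), "at least 4")
})

test_that("fit_cylinder recovers exact and partial-arc cylinders", {
  th <- seq(0, 2 * pi, length.out = 40)[-40]
  pts <- NULL
  for (z in seq(-5, 5, by = 1))
    pts <- rbind(pts, cbind(10 * cos(th), 10 * sin(th), z))
  fc <- fit_cylinder(pts)
  expect_lt(acos(min(1, abs(sum(fc$axis_dir * c(0, 0, 1))))), 1e-6)
  expect_equal(fc$radius, 10, tolerance = 1e-6)
  # 120-degree partial notch with noise
  set.seed(5)
  th2 <- stats::runif(400, -pi / 3, pi / 3)
  z2 <- stats::runif(400, -6, 6)
  notch <- cbind(8 * cos(th2) + 1, 8 * sin(th2) - 2, z2) +
    0.05 * matrix(stats::rnorm(1200), ncol = 3)
  fc2 <- fit_cylinder(notch)
  expect_lt(acos(min(1, abs(sum(fc2$axis_dir * c(0, 0, 1))))),
            0.5 * pi / 180)
  expect_lt(abs(fc2$radius - 8), 0.1)
  expect_error(fit_cylinder(cbind(1:10, 1:10, 1:10)), "collinear")
})

test_that("rodrigues builds proper rotations about arbitrary lines", {
  tf <- rodrigues(c(0, 0, 1), 90)
  expect_equal(as.numeric(apply_transform(tf, c(1, 0, 0))), c(0, 1, 0),
               tolerance = 1e-12)
  expect_equal(rodrigues(c(1, 0, 0), 0)$rotation, diag(3))
  set.seed(9)
  for (k in 1:5) {
    ax <- arthropose:::.unit(stats::rnorm(3))
    tf <- rodrigues(ax, stats::runif(1, -180, 180), stats::rnorm(3))
    expect_equal(crossprod(tf$rotation), diag(3), tolerance = 1e-12)
    expect_equal(det(tf$rotation), 1, tolerance = 1e-12)
  }
  expect_error(rodrigues(c(0, 0, 0), 10), "zero axis")
})

test_that("euler_intrinsic composes in the stated order", {
  expect_equal(euler_intrinsic(0, 0, 0), diag(3))
  # single-axis case equals rodrigues about the flexion axis
  expect_equal(euler_intrinsic(0, 25, 0),
               rodrigues(c(0, 1, 0), 25)$rotation, tolerance = 1e-12)
  # independent matrix-product oracle
  R1 <- rodrigues(c(0, 0, 1), 10)$rotation
  R2 <- rodrigues(c(0, 1, 0), 20)$rotation
  R3 <- rodrigues(c(1, 0, 0), 30)$rotation
  expect_equal(euler_intrinsic(10, 20, 30), R1 %*% R2 %*% R3,
               tolerance = 1e-12)
  expect_error(euler_intrinsic(1, 2, 3, joint_axes = rbind(c(1, 0, 0),
                                                           c(1, 0, 0),
                                                           c(0, 0, 1))),
               "orthonormal")
})

test_that("fit_sphere is equivariant under rigid motion of exact data", {
  set.seed(21)
  dirs <- matrix(stats::rnorm(150), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  pts <- sweep(7 * dirs, 2, c(-1, 4, 2), `+`)
  R <- random_rotation(); v <- c(10, -3, 5)
  f1 <- fit_sphere(pts)
  f2 <- fit_sphere(sweep(pts %*% t(R), 2, v, `+`))
  expect_equal(f2$center, as.numeric(R %*% f1$center + v), tolerance = 1e-8)
  expect_equal(f2$radius, f1$radius, tolerance = 1e-9)
})
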