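test_that("rigid fit recovers synthetic rotations exactly, never a reflection", {
  set.seed(11)
  for (trial in 1:25) {
    X <- matrix(rnorm(30, sd = 40), 10, 3)
    R <- random_rotation()
    t_ <- rnorm(3, sd = 20)
    Y <- t(R %*% t(X)) + rep(t_, each = 10)
    tf <- fit_rigid(X, Y)
    expect_lt(sqrt(mean((apply_points(tf, X) - Y)^2)), 1e-9)
    expect_equal(det(tf$rotation), 1, tolerance = 1e-12)
  }
  # pure translation leaves rotation at identity
  X <- matrix(rnorm(15), 5, 3)
  tf <- fit_rigid(X, X + rep(c(5, -3, 2), each = 5))
  expect_equal(tf$rotation, diag(3), tolerance = 1e-9)
  expect_equal(tf$translation, c(5, -3, 2), tolerance = 1e-9)
  # identity case
  tf0 <- fit_rigid(X, X)
  expect_equal(tf0$rotation, diag(3), tolerance = 1e-12)
  expect_equal(tf0$translation, c(0, 0, 0), tolerance = 1e-12)
  # degenerate geometry is refused
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(fit_rigid(line, line), "collinear")
  expect_error(fit_rigid(X[1:2, ], X[1:2, ]), "at least 3")
})

test_that("affine fit is exact on affine-consistent data and validates input", {
  cube <- as.matrix(expand.grid(c(0, 10), c(0, 10), c(0, 10)))
  A <- matrix(c(1, 0.5, 0, 0, 1, 0.3, 0.2, 0, 1), 3, 3, byrow = TRUE)  # shear
  dst <- t(A %*% t(cube)) + rep(c(1, 2, 3), each = 8)
  tf <- fit_affine(cube, dst)
  expect_lt(max(abs(tf$matrix - A)), 1e-9)
  expect_lt(max(abs(tf$translation - c(1, 2, 3))), 1e-9)
  # uniform scaling
  tf2 <- fit_affine(cube, 2 * cube)
  expect_equal(tf2$matrix, 2 * diag(3), tolerance = 1e-9)
  expect_equal(tf2$translation, c(0, 0, 0), tolerance = 1e-9)
  expect_error(fit_affine(cube[1:3, ], cube[1:3, ]), "at least 4")
  plane <- cbind(runif(6), runif(6), 0)
  expect_error(fit_affine(plane, plane), "coplanar")
})

test_that("TPS interpolates landmarks exactly at lambda = 0", {
  set.seed(13)
  for (trial in 1:20) {
    n <- sample(4:30, 1)
    repeat {
      src <- matrix(runif(3 * n) * 200, n, 3)
      if (qr(sweep(src, 2, colMeans(src)), tol = 1e-7)$rank == 3) break
    }
    dst <- src + matrix(rnorm(3 * n, 0, 15), n, 3)
    tt <- fit_tps(src, dst)
    expect_lt(max(abs(apply_points(tt, src) - dst)), 1e-6)
    # side conditions on the warp coefficients
    expect_lt(max(abs(colSums(tt$warp))), 1e-8)
    expect_lt(max(abs(crossprod(src, tt$warp))), 1e-8)
  }
  expect_error(fit_tps(matrix(rnorm(9), 3, 3), matrix(rnorm(9), 3, 3)),
               "at least 4")
})

test_that("TPS of affine-consistent landmarks equals the affine fit", {
  set.seed(17)
  src <- matrix(runif(36) * 100, 12, 3)
  A <- diag(3) + matrix(rnorm(9, 0, 0.1), 3, 3)
  dst <- t(A %*% t(src)) + rep(c(4, -2, 7), each = 12)
  tt <- fit_tps(src, dst)
  ta <- fit_affine(src, dst)
  expect_lt(sqrt(sum(tt$warp^2)), 1e-8)
  P <- matrix(runif(300) * 100, 100, 3)
  expect_lt(max(abs(apply_points(tt, P) - apply_points(ta, P))), 1e-6)
  # identity landmarks give the identity map everywhere
  t_id <- fit_tps(src, src)
  expect_lt(max(abs(apply_points(t_id, P) - P)), 1e-6)
})

test_that("transform application preserves the right invariants", {
  set.seed(19)
  pts <- matrix(rnorm(60, sd = 30), 20, 3)
  # identity
  expect_equal(apply_points(identity_transform(), pts), pts, ignore_attr = TRUE)
  # rigid transforms conserve pairwise distances
  tf <- rigid_from(random_rotation(), c(3, 1, -4))
  mapped <- apply_points(tf, pts)
  expect_equal(as.matrix(dist(mapped)), as.matrix(dist(pts)), tolerance = 1e-9)
  # inversion composes to identity for rigid and affine
  expect_equal(apply_points(invert_transform(tf), mapped), pts,
               tolerance = 1e-9, ignore_attr = TRUE)
  af <- fit_affine(pts[1:8, ], pts[1:8, ] %*% diag(c(2, 1, 3)) + 5)
  expect_equal(apply_points(invert_transform(af), apply_points(af, pts)), pts,
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("morphology transformation maps coordinates, never topology", {
  m <- random_tree(60, seed = 5)
  tf <- rigid_from(rot_z(25), c(10, -5, 3))
  m2 <- apply_morphology(tf, m)
  expect_identical(m2$nodes$parent, m$nodes$parent)
  expect_identical(m2$nodes$id, m$nodes$id)
  expect_identical(m2$nodes$radius, m$nodes$radius)  # fixed policy
  expect_equal(cable_length(m2), cable_length(m), tolerance = 1e-9)

  # uniform 2x scaling with local_scale doubles radii and path lengths
  scale2 <- structure(list(matrix = 2 * diag(3), translation = c(0, 0, 0)),
                      class = "affine_transform")
  m3 <- apply_morphology(scale2, m, radius_policy = "local_scale")
  expect_equal(m3$nodes$radius, 2 * m$nodes$radius, tolerance = 1e-6)
  expect_equal(cable_length(m3), 2 * cable_length(m), tolerance = 1e-9)
})

test_that("image resampling honours identity, integer shifts and known warps", {
  set.seed(23)
  v <- array(sample(0:255, 10 * 12 * 14, TRUE), dim = c(10, 12, 14))
  s <- image_stack(v, spacing = c(2, 1, 1))
  # identity transform reproduces the stack voxelwise
  r0 <- resample_image(identity_transform(), s, s)
  expect_equal(r0$voxels, v + 0, tolerance = 1e-12)
  # pure translation by one voxel pitch in x: interior shifted exactly
  tsh <- rigid_from(diag(3), c(1, 0, 0))
  r1 <- resample_image(tsh, s, s)
  expect_equal(r1$voxels[, , 2:14], v[, , 1:13] + 0, tolerance = 1e-9)
  expect_true(all(r1$voxels[, , 1] == 0))

  # known affine moves a bright ball's centroid to the predicted position
  vb <- array(0, dim = c(24, 32, 32))
  st <- image_stack(vb, spacing = c(1, 1, 1))
  ctr <- c(14, 16, 11)  # (x, y, z)
  idx <- which(vb == 0)
  kji <- arrayInd(idx, dim(vb))
  xyz <- voxel_to_physical(st, kji)
  inside <- rowSums(sweep(xyz, 2, ctr)^2) <= 36
  vb[idx[inside]] <- 255
  st$voxels <- vb
  af <- structure(list(matrix = diag(c(1.2, 1, 0.9)),
                       translation = c(3, -2, 4)), class = "affine_transform")
  rw <- resample_image(af, st, st)
  w <- rw$voxels / sum(rw$voxels)
  idx2 <- which(rw$voxels >= 0)
  xyz2 <- voxel_to_physical(rw, arrayInd(idx2, dim(rw$voxels)))
  centroid <- colSums(xyz2 * as.vector(w)[idx2])
  pred <- as.numeric(apply_points(af, matrix(ctr, ncol = 3)))
  expect_lt(max(abs(centroid - pred)), 0.5)
})

test_that("mirroring is an involution and reflects coordinates correctly", {
  set.seed(29)
  v <- array(sample(0:255, 6 * 8 * 10, TRUE), dim = c(6, 8, 10))
  s <- image_stack(v, spacing = c(2, 1, 1))
  for (ax in c("x", "y", "z"))
    expect_identical(mirror(mirror(s, ax), ax)$voxels, v)

  lm <- landmark_set(c("RMC", "CCB"), c(100, 150), c(10, 10), c(5, 5))
  ml <- mirror(lm, "x", extent = c(0, 300))
  expect_equal(ml$x, c(200, 150))
  mlr <- mirror(lm, "x", extent = c(0, 300), rename_lr = TRUE)
  expect_equal(mlr$name, c("LMC", "CCB"))

  m <- random_tree(40, seed = 31)
  mm <- mirror(m, "y", extent = c(0, 200))
  expect_equal(cable_length(mm), cable_length(m), tolerance = 1e-9)
  expect_equal(mirror(mm, "y", extent = c(0, 200))$nodes, m$nodes,
               tolerance = 1e-12)
})

test_that("TPS image registration pulls a warped volume back onto the reference", {
  # smooth synthetic warp, 12 fitting landmarks, inverse-direction resampling
  set.seed(37)
  vb <- array(0, dim = c(16, 24, 24))
  st <- image_stack(vb, spacing = c(1, 1, 1))
  idx <- seq_along(vb)
  xyz <- voxel_to_physical(st, arrayInd(idx, dim(vb)))
  ctr <- c(12, 12, 8)
  vb[rowSums(sweep(xyz, 2, ctr)^2) <= 16] <- 200
  st$voxels <- array(vb, dim = dim(st$voxels))
  src <- as.matrix(expand.grid(c(3, 20), c(3, 20), c(3, 12)))
  src <- rbind(src, c(12, 12, 8), c(12, 3, 8), c(3, 12, 8), c(20, 12, 8))
  warp_fun <- function(p) p + cbind(2 * sin(p[, 2] / 8), 0.5 * cos(p[, 1] / 6), 0)
  dst <- warp_fun(src)
  tf <- fit_tps(src, dst)
  moved <- resample_image(tf, st, st)
  expect_gt(sum(moved$voxels), 0.5 * sum(st$voxels))
  back <- resample_image(invert_transform(tf), moved, st)
  inter <- sum(back$voxels > 100 & st$voxels > 100)
  uni <- sum(back$voxels > 100 | st$voxels > 100)
  expect_gt(inter / uni, 0.8)
})
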