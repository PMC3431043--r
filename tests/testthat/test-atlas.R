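test_that("brain origin re-anchoring is exact and idempotent", {
  s <- image_stack(array(0, dim = c(160, 64, 64)), spacing = c(2, 1, 1))
  # voxel (81, 33, 33) -> physical (x, y, z) = (32, 32, 160)
  s2 <- set_brain_origin(s, esophagus_center = c(32, 32), middle_slice_index = 81)
  p <- voxel_to_physical(s2, matrix(c(81, 33, 33), ncol = 3))
  expect_equal(as.numeric(p), c(0, 0, 0), tolerance = 1e-12)
  s3 <- set_brain_origin(s2, esophagus_center = c(0, 0), middle_slice_index = 81)
  expect_equal(s3$origin, s2$origin, tolerance = 1e-12)
  expect_error(set_brain_origin(s, c(1e5, 0), 81), "outside")
  expect_error(set_brain_origin(s, c(32, 32), 1000), "outside")
})

test_that("stack averaging is exact, permutation-invariant and geometry-checked", {
  set.seed(41)
  v <- array(runif(4 * 5 * 6, 0, 255), dim = c(4, 5, 6))
  s <- image_stack(v, spacing = c(2, 1, 1))
  expect_equal(average_stacks(list(s, s, s))$voxels, v, tolerance = 1e-12)
  a <- image_stack(array(0, dim = c(4, 5, 6)), spacing = c(2, 1, 1))
  b <- image_stack(array(100, dim = c(4, 5, 6)), spacing = c(2, 1, 1))
  expect_equal(unique(as.vector(average_stacks(list(a, b))$voxels)), 50)
  s2 <- image_stack(array(runif(120, 0, 255), dim = c(4, 5, 6)), spacing = c(2, 1, 1))
  s3 <- image_stack(array(runif(120, 0, 255), dim = c(4, 5, 6)), spacing = c(2, 1, 1))
  expect_equal(average_stacks(list(s, s2, s3))$voxels,
               average_stacks(list(s3, s, s2))$voxels, tolerance = 1e-12)
  bad <- image_stack(array(0, dim = c(4, 5, 7)), spacing = c(2, 1, 1))
  expect_error(average_stacks(list(s, bad)), "geometry")
  expect_error(average_stacks(list(s)), "at least 2")
})

test_that("outline binarization keeps one filled component", {
  # bright ball on dark background, plus a distant speck; hollow shell fills
  v <- array(10, dim = c(24, 32, 32))
  st <- image_stack(v, spacing = c(1, 1, 1))
  xyz <- voxel_to_physical(st, arrayInd(seq_along(v), dim(v)))
  ctr <- c(16, 16, 12)
  r2 <- rowSums(sweep(xyz, 2, ctr)^2)
  ball <- r2 <= 64
  v[ball] <- 200
  v[2, 2, 2] <- 250  # speck
  st$voxels <- v
  out <- binarize_outline(st)
  expect_equal(out$voxels[2, 2, 2], 0)           # speck removed
  expect_equal(array(out$voxels != 0, dim(v))[ball], rep(TRUE, sum(ball)))
  # hollow shell: interior filled
  v2 <- array(10, dim = c(24, 32, 32))
  v2[r2 <= 100 & r2 >= 49] <- 200
  st$voxels <- v2
  out2 <- binarize_outline(st)
  expect_true(all(array(out2$voxels != 0, dim(v2))[r2 <= 100]))
  expect_error(binarize_outline(image_stack(array(5, c(2, 2, 2))),
                                method = "fixed", value = 10), "empty")
})

test_that("surface extraction is watertight with exact voxel volume", {
  # 10x10x10 um solid cube
  mask <- array(FALSE, dim = c(14, 14, 14))
  mask[3:12, 3:12, 3:12] <- TRUE
  mesh <- extract_surface(mask, spacing = c(1, 1, 1))
  expect_equal(mesh_volume(mesh), 1000, tolerance = 1e-9)
  expect_true(mesh_is_watertight(mesh))

  # sphere r = 20 um within 5% of (4/3) pi r^3
  d <- c(50, 50, 50)
  st <- image_stack(array(0, dim = d), spacing = c(1, 1, 1))
  xyz <- voxel_to_physical(st, arrayInd(seq_len(prod(d)), d))
  sph <- array(rowSums(sweep(xyz, 2, c(24, 24, 24))^2) <= 400, dim = d)
  mesh2 <- extract_surface(sph, spacing = c(1, 1, 1))
  expect_equal(mesh_volume(mesh2), 4 / 3 * pi * 20^3, tolerance = 0.05)
  expect_true(mesh_is_watertight(mesh2))
  expect_error(extract_surface(array(FALSE, c(2, 2, 2))), "empty")
})

test_that("landmark-driven rigid alignment restores a rotated brain", {
  st <- synthetic_brain()
  lm <- brain_landmarks(st)
  ctr <- colMeans(stack_extent(st))
  R <- rot_z(15)
  tf <- rigid_from(R, as.numeric(ctr - R %*% ctr))  # rotate about centre
  rotated <- resample_image(tf, st, st)
  rot_lm <- apply_landmarks(tf, lm)
  back <- align_to_reference(rotated, rot_lm, lm, st)
  expect_lt(attr(back, "landmark_rms"), 1e-6)
  d <- dice_coefficient(back$voxels > 100, st$voxels > 100)
  expect_gt(d, 0.98)
  expect_error(align_to_reference(st, lm[1:2, ], lm), "at least 3")
})

test_that("the full atlas pipeline recovers the ground-truth outline", {
  set.seed(43)
  st <- synthetic_brain()
  lm <- brain_landmarks(st)
  gt_mask <- st$voxels > 100
  stacks <- list()
  lms <- list()
  hemi <- character(0)
  ctr <- colMeans(stack_extent(st))
  for (i in 1:12) {
    if (i == 1) {
      tf <- identity_transform()
    } else {
      R <- random_rotation()
      # small jitter rotation: blend toward identity
      R <- svd(0.15 * R + 0.85 * diag(3))
      R <- R$u %*% t(R$v)
      if (det(R) < 0) R <- R$u %*% diag(c(1, 1, -1)) %*% t(R$v)
      tf <- rigid_from(R, as.numeric(ctr - R %*% ctr) + rnorm(3, 0, 2))
    }
    stk <- if (i == 1) st else resample_image(tf, st, st)
    lmk <- apply_landmarks(tf, lm)
    if (i %% 2 == 0) {  # present half the inputs as left hemispheres
      stk <- mirror(stk, "x")
      lmk <- mirror(lmk, "x", extent = stk, rename_lr = TRUE)
    }
    stacks[[i]] <- stk
    lms[[i]] <- lmk
    hemi[i] <- if (i %% 2 == 0) "L" else "R"
  }
  bundle <- build_standard_brain(list(stacks = stacks, landmarks = lms,
                                      hemisphere = hemi, reference = 1))
  expect_gt(dice_coefficient(bundle$outline_mask$voxels != 0, gt_mask), 0.95)
  expect_true(mesh_is_watertight(bundle$surface))
  expect_equal(length(bundle$provenance), 12)

  # single input with identity landmarks: average equals the input
  solo <- build_standard_brain(list(stacks = list(st), landmarks = list(lm),
                                    hemisphere = "R"))
  expect_equal(solo$average_stack$voxels, st$voxels, tolerance = 1e-9)

  # validation-first: a missing landmark file aborts before computation
  expect_error(build_standard_brain(list(stacks = list(st),
                                         landmarks = list("/nonexistent.csv"),
                                         hemisphere = "R")), "missing landmark")
})

test_that("atlas bundles write to disk in open formats", {
  st <- synthetic_brain(shape = c(16, 24, 24))
  lm <- brain_landmarks(st)
  bundle <- build_standard_brain(list(stacks = list(st, st),
                                      landmarks = list(lm, lm),
                                      hemisphere = c("R", "R")))
  dir <- withr::local_tempdir()
  write_atlas_bundle(bundle, dir)
  expect_true(all(file.exists(file.path(dir, c("average.tif", "outline.tif",
                                               "surface.obj", "landmarks.csv",
                                               "provenance.json")))))
  back <- read_stack(file.path(dir, "outline.tif"))
  expect_equal(back$voxels != 0, bundle$outline_mask$voxels != 0)
})
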