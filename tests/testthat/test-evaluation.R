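test_that("consistency is 1 with zero discrepancy on self-comparison", {
  for (seed in 1:20) {
    m <- random_tree(sample(5:60, 1), seed = seed)
    rep_ <- consistency(m, m)
    expect_equal(rep_$c_miss, 1)
    expect_equal(rep_$c_false, 1)
    expect_equal(rep_$consistency, 1)
    expect_equal(rep_$diameter_discrepancy, 0, tolerance = 1e-12)
  }
})

test_that("consistency degrades predictably with known structural defects", {
  # two equal 30 um arms; delete one: c_miss ~ remaining fraction, c_false ~ 1
  nd <- data.frame(id = 1:3, type = c(1L, 3L, 3L),
                   x = c(0, 30, -30), y = 0, z = 0, radius = 1,
                   parent = c(-1L, 1L, 1L))
  m <- morphology(nd)
  half <- morphology(nd[1:2, ])
  rep_ <- consistency(m, half)
  # remaining arm (30 um) plus the tau = 2 um of the deleted arm adjacent
  # to the junction still finds support: (30 + 2) / 60
  expect_equal(rep_$c_miss, 32 / 60, tolerance = 0.02)
  expect_equal(rep_$c_false, 1, tolerance = 1e-9)

  # spatially disjoint trees score 0
  far <- apply_morphology(rigid_from(diag(3), c(1000, 0, 0)), m)
  expect_equal(consistency(m, far)$consistency, 0)

  # empty extraction scores 0, not 0.5
  expect_equal(consistency(m, NULL)$consistency, 0)

  # directional identity: c_miss(a -> b) == c_false(b -> a)
  a <- random_tree(30, seed = 101)
  b <- random_tree(25, seed = 102)
  expect_equal(consistency(a, b)$c_miss, consistency(b, a)$c_false,
               tolerance = 1e-12)

  # invariance under a joint rigid motion
  tf <- rigid_from(rot_z(40), c(5, 6, 7))
  r1 <- consistency(a, b)
  r2 <- consistency(apply_morphology(tf, a), apply_morphology(tf, b))
  expect_equal(r1$consistency, r2$consistency, tolerance = 1e-9)
  expect_equal(r1$diameter_discrepancy, r2$diameter_discrepancy,
               tolerance = 1e-9)

  # diameter discrepancy sees radius errors
  fat <- a
  fat$nodes$radius <- fat$nodes$radius * 1.3
  expect_equal(consistency(a, fat)$diameter_discrepancy, 0.3, tolerance = 1e-6)

  expect_error(consistency(a, b, tau = 0), "tau")
})

test_that("landmark variability follows the 3D Maxwell mean under jitter", {
  set.seed(53)
  nlm <- 15
  base <- landmark_set(sprintf("P%02d", seq_len(nlm)),
                       runif(nlm, 0, 300), runif(nlm, 0, 300), runif(nlm, 0, 150))
  # trivial: copies of base have zero distance
  rep0 <- landmark_error(base, list(base, base))
  expect_equal(rep0$mean, 0)
  # single offset by (3, 4, 0) is distance 5
  off <- base
  off$x[1] <- off$x[1] + 3
  off$y[1] <- off$y[1] + 4
  rep1 <- landmark_error(base, list(off))
  expect_equal(rep1$table$distance[rep1$table$name == "P01"], 5,
               tolerance = 1e-12)

  # isotropic sigma jitter: grand mean ~ sigma * sqrt(8 / pi) within 10%
  sigma <- 12
  samples <- lapply(1:12, function(i)
    landmark_set(base$name, base$x + rnorm(nlm, 0, sigma),
                 base$y + rnorm(nlm, 0, sigma), base$z + rnorm(nlm, 0, sigma)))
  repj <- landmark_error(base, samples)
  expect_equal(repj$mean, sigma * sqrt(8 / pi), tolerance = 0.1)

  # the per-name centroid minimizes the grand mean (average-brain property)
  centroid <- landmark_set(base$name,
                           rowMeans(sapply(samples, `[[`, "x")),
                           rowMeans(sapply(samples, `[[`, "y")),
                           rowMeans(sapply(samples, `[[`, "z")))
  m_centroid <- landmark_error(centroid, samples)$mean
  for (k in c(1, 5, 9))
    expect_lt(m_centroid, landmark_error(samples[[k]],
                                         samples[-k])$mean)
})

test_that("registration error drops at held-out points after TPS fitting", {
  set.seed(59)
  # smooth synthetic warp of the whole field
  warp <- function(p) p + cbind(8 * sin(p[, 2] / 60), 6 * cos(p[, 1] / 50),
                                4 * sin(p[, 3] / 40))
  fit_names <- sprintf("L%02d", 1:12)
  fit_src <- cbind(runif(12, 0, 200), runif(12, 0, 200), runif(12, 0, 100))
  distinct <- c("CCB", "RMC", "LMC", "RMP", "LMP")
  # distinct points inside the landmark hull
  dpts <- rbind(c(100, 100, 50), c(140, 90, 40), c(60, 90, 40),
                c(150, 150, 60), c(50, 150, 60))
  standard <- landmark_set(distinct, dpts[, 1], dpts[, 2], dpts[, 3])
  sample_before <- landmark_set(distinct, warp(dpts)[, 1], warp(dpts)[, 2],
                                warp(dpts)[, 3])
  # registration: TPS fitted on the 12 landmarks, warped -> standard
  tf <- fit_tps(warp(fit_src), fit_src)
  after_xyz <- apply_points(tf, landmark_xyz <- as.matrix(sample_before[, c("x", "y", "z")]))
  sample_after <- landmark_set(distinct, after_xyz[, 1], after_xyz[, 2],
                               after_xyz[, 3])
  tab <- registration_error(distinct, standard, sample_before, sample_after)
  expect_true(all(tab$after < tab$before))
  # after == standard gives zero error
  tab0 <- registration_error(distinct, standard, sample_before, standard)
  expect_equal(tab0$after, rep(0, 5))
  expect_error(registration_error(c("XXX"), standard, sample_before,
                                  sample_after), "missing")

  # a point far outside the landmark hull may stay worse than interior ones
  far <- matrix(c(400, 400, 200), ncol = 3)
  far_before <- warp(far)
  far_after <- apply_points(tf, far_before)
  err_far <- sqrt(sum((far_after - far)^2))
  expect_gt(err_far, median(tab$after))
})
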