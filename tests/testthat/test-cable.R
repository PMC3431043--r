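test_that("compartmentalization computes frustum areas and handles degeneracy", {
  # 100 um cylinder of radius 2: lateral area 2 pi r L
  m <- morphology(data.frame(id = 1:2, type = c(1L, 3L), x = c(0, 100),
                             y = 0, z = 0, radius = 2, parent = c(-1L, 1L)))
  cm <- build_cable(m)
  expect_equal(cm$total_area, 2 * pi * 2 * 100, tolerance = 1e-9)

  # splitting an edge changes neither total area nor end-to-end resistance
  m2 <- morphology(data.frame(id = 1:3, type = c(1L, 3L, 3L),
                              x = c(0, 50, 100), y = 0, z = 0, radius = 2,
                              parent = c(-1L, 1L, 2L)))
  cm2 <- build_cable(m2)
  expect_equal(cm2$total_area, cm$total_area, tolerance = 1e-9)
  expect_equal(sum(1 / cm2$g_axial), sum(1 / cm$g_axial), tolerance = 1e-9)

  # zero-length edge merged with a warning
  m3 <- morphology(data.frame(id = 1:3, type = c(1L, 3L, 3L),
                              x = c(0, 0, 100), y = 0, z = 0, radius = 2,
                              parent = c(-1L, 1L, 2L)))
  expect_warning(cm3 <- build_cable(m3), "zero-length")
  expect_equal(cm3$total_area, cm$total_area, tolerance = 1e-9)

  # multi-root morphologies are refused
  frag <- morphology(data.frame(id = 1:2, type = 3L, x = c(0, 10), y = 0,
                                z = 0, radius = 1, parent = c(-1L, -1L)))
  expect_error(build_cable(frag), "single-rooted")
})

test_that("steady state matches the sealed-cable closed form within 1%", {
  pp <- passive_params()
  for (cfg in list(c(500, 2), c(1000, 2), c(800, 1))) {
    L <- cfg[1]; a <- cfg[2]
    n <- L  # 1 um compartments
    nd <- data.frame(id = seq_len(n + 1), type = 3L,
                     x = seq(0, L, length.out = n + 1), y = 0, z = 0,
                     radius = a, parent = c(-1L, seq_len(n)))
    nd$type[1] <- 1L
    cable <- build_cable(morphology(nd), pp)
    v <- steady_state(cable, I_inject = 0.1)
    lambda <- sqrt((pp$Rm * a * 1e-4) / (2 * pp$Ra)) * 1e4  # um
    ratio <- (v[length(v)] - pp$E_rest) / (v[1] - pp$E_rest)
    expect_equal(as.numeric(ratio), 1 / cosh(L / lambda), tolerance = 0.01)
  }
})

test_that("the conductance system is linear and balanced", {
  m <- random_tree(40, seed = 61)
  cable <- build_cable(m)
  pp <- cable$params
  # no current: everything at rest
  v0 <- steady_state(cable, 0)
  expect_equal(as.numeric(v0), rep(pp$E_rest, length(v0)))
  # doubling current doubles all deflections
  v1 <- steady_state(cable, 0.1)
  v2 <- steady_state(cable, 0.2)
  expect_equal(as.numeric(v2 - pp$E_rest), 2 * as.numeric(v1 - pp$E_rest),
               tolerance = 1e-9)
  # Kirchhoff balance at every node: G v = i
  nd <- cable$nodes
  n <- nrow(nd)
  ii <- c(cable$edge_child, cable$edge_parent, cable$edge_child,
          cable$edge_parent, seq_len(n))
  jj <- c(cable$edge_parent, cable$edge_child, cable$edge_child,
          cable$edge_parent, seq_len(n))
  xx <- c(-cable$g_axial, -cable$g_axial, cable$g_axial, cable$g_axial,
          cable$g_membrane)
  G <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  resid <- as.numeric(G %*% ((as.numeric(v1) - pp$E_rest) / 1e3))
  inj <- which(nd$parent == -1L)
  expected <- numeric(n)
  expected[inj] <- 0.1 * 1e-9
  expect_lt(max(abs(resid - expected)) / max(abs(expected)), 1e-9)
})

test_that("grid refinement leaves tip voltages essentially unchanged", {
  # same cable sampled at 2 um and 1 um node spacing
  make_cable <- function(h) {
    n <- round(400 / h)
    nd <- data.frame(id = seq_len(n + 1), type = 3L,
                     x = seq(0, 400, length.out = n + 1), y = 0, z = 0,
                     radius = 1.5, parent = c(-1L, seq_len(n)))
    nd$type[1] <- 1L
    steady_state(build_cable(morphology(nd)), 0.1)
  }
  v2 <- make_cable(2)
  v1 <- make_cable(1)
  tip2 <- as.numeric(v2[length(v2)]) + 65
  tip1 <- as.numeric(v1[length(v1)]) + 65
  expect_lt(abs(tip2 - tip1) / abs(tip1), 0.005)
})

test_that("the transient step response converges to the steady state", {
  n <- 100
  nd <- data.frame(id = seq_len(n + 1), type = 3L,
                   x = seq(0, 200, length.out = n + 1), y = 0, z = 0,
                   radius = 2, parent = c(-1L, seq_len(n)))
  nd$type[1] <- 1L
  cable <- build_cable(morphology(nd))
  vss <- steady_state(cable, 0.1)
  tr <- transient_response(cable, 0.1, t_end = 0.1, dt = 25e-6,
                           record = c(1L, n + 1L))
  # after ~10 membrane time constants the step response has settled
  expect_equal(tr$node_1[nrow(tr)], as.numeric(vss[1]), tolerance = 1e-3)
  expect_equal(tr[[3]][nrow(tr)], as.numeric(vss[n + 1]), tolerance = 1e-3)
  # monotone charging from rest
  expect_true(all(diff(tr$node_1) >= -1e-9))
  expect_equal(tr$node_1[1], cable$params$E_rest)
})

test_that("response error separates faithful from distorted reconstructions", {
  m <- random_tree(50, seed = 67)
  # self comparison: zero error
  r0 <- response_error(m, m)
  expect_equal(r0$tip_error, 0, tolerance = 1e-12)
  expect_equal(r0$input_resistance_error, 0, tolerance = 1e-12)
  # uniformly fattened copy: lower input resistance, positive error
  fat <- m
  fat$nodes$radius <- fat$nodes$radius * 1.5
  rf <- response_error(m, fat)
  expect_lt(rf$Rin_test, rf$Rin_gt)
  expect_gt(rf$tip_error, 0)
})
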