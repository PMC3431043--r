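test_that("a straight cylinder is traced as one accurate unbranched path", {
  m <- cylinder_morph(L = 50, r = 2)
  st <- render_morphology(m, c(64, 64, 96), spacing = c(1, 1, 1),
                          fg = 200, bg = 20)
  tr <- trace_neurites(st, tracer_params(seed_point = c(20, 32, 32)))
  expect_length(morph_tips(tr), 1)
  expect_length(morph_bifurcations(tr), 0)
  expect_lt(abs(cable_length(tr) - 50), 2)
  expect_lt(abs(mean(tr$nodes$radius) - 2), 0.5)
  # deterministic re-run
  tr2 <- trace_neurites(st, tracer_params(seed_point = c(20, 32, 32)))
  expect_identical(tr$nodes, tr2$nodes)
})

test_that("a Y-shaped phantom yields exactly one bifurcation and two tips", {
  mY <- y_morph()
  st <- render_morphology(mY, c(32, 64, 96), spacing = c(1, 1, 1),
                          fg = 200, bg = 20)
  tr <- trace_neurites(st, tracer_params(seed_point = c(20, 32, 16)))
  expect_length(morph_bifurcations(tr), 1)
  expect_length(morph_tips(tr), 2)
  expect_gt(consistency(mY, tr)$consistency, 0.95)
})

test_that("segmentation validates input and background subtraction helps", {
  expect_error(segment_foreground(image_stack(array(7, c(4, 4, 4)))),
               "constant")
  # clean phantom: mask close to the rendered ground truth
  spec <- small_spec(seed = 3)
  gt <- generate_tree(spec)
  st <- render_morphology(gt, spec$volume_shape, spec$spacing,
                          fg = spec$fg, bg = spec$bg)
  gt_mask <- st$voxels == spec$fg
  seg <- segment_foreground(st, tracer_params())
  expect_gt(dice_coefficient(seg$voxels != 0, gt_mask), 0.9)

  # biased background: subtraction recovers a better mask than none
  bb <- corrupt_stack(st, "biased_background",
                      list(bias_amplitude = 100,
                           center = colMeans(morph_xyz(gt))), seed = 4)
  p_on <- tracer_params(threshold = (spec$fg + spec$bg) / 2,
                        background_subtract = TRUE)
  p_off <- tracer_params(threshold = (spec$fg + spec$bg) / 2)
  d_on <- dice_coefficient(segment_foreground(bb, p_on)$voxels != 0, gt_mask)
  d_off <- dice_coefficient(segment_foreground(bb, p_off)$voxels != 0, gt_mask)
  expect_gt(d_on, d_off)

  # disconnected component is left untraced but reported
  v <- array(20, dim = c(24, 40, 60))
  s2 <- image_stack(v, spacing = c(1, 1, 1))
  occ <- rasterize_frusta(cylinder_morph(L = 20, r = 2, x0 = 5, y = 20, z = 12),
                          dim(v), c(1, 1, 1))
  occ2 <- rasterize_frusta(cylinder_morph(L = 10, r = 2, x0 = 45, y = 20, z = 12),
                           dim(v), c(1, 1, 1))
  s2$voxels[occ | occ2] <- 200
  expect_warning(tr <- trace_neurites(s2, tracer_params(seed_point = c(5, 20, 12))),
                 "not traced")
  expect_gt(attr(tr, "uncovered_voxels"), 0)
  expect_lt(cable_length(tr), 30)
  # seed far away from any foreground is refused
  expect_error(trace_neurites(s2, tracer_params(seed_point = c(5, 38, 2))),
               "outside the foreground")
})

test_that("edit scripts apply in order and preserve forest validity", {
  m <- y_morph()
  # empty script: identity
  expect_identical(apply_edits(m, edit_script())$nodes, m$nodes)

  # delete one arm of the Y: node count drops by exactly that subtree size
  m2 <- apply_edits(m, edit_script(edit_delete_subtree(3L)))
  expect_equal(nrow(m2$nodes), nrow(m$nodes) - 1)
  expect_false(3L %in% m2$nodes$id)

  # add a path: nodes appended, chained to the attachment point
  pts <- cbind(x = c(70, 75), y = c(17, 17), z = 16, r = 1)
  m3 <- apply_edits(m, edit_script(edit_add_path(pts, at = 4L)))
  expect_equal(nrow(m3$nodes), nrow(m$nodes) + 2)
  expect_equal(cable_length(m3), cable_length(m) + 10, tolerance = 1e-9)

  # connect two fragments into a single tree
  frag <- morphology(data.frame(id = c(10L, 11L), type = 3L,
                                x = c(80, 90), y = 17, z = 16, radius = 1,
                                parent = c(-1L, 10L)))
  both <- morphology(rbind(m$nodes, frag$nodes))
  expect_length(morph_roots(both), 2)
  joined <- apply_edits(both, edit_script(edit_connect(4L, 10L)))
  expect_length(morph_roots(joined), 1)

  # invalid edits are refused
  expect_error(apply_edits(m, edit_script(edit_delete_subtree(99L))), "no node")
  expect_error(apply_edits(m, edit_script(edit_connect(2L, 3L))), "cycle")
  expect_error(apply_edits(m, edit_script(edit_delete_subtree(1L))),
               "every node")
})

test_that("semiautomatic corrections fix known defects deterministically", {
  # perfect trace: no edits generated
  m <- cylinder_morph(L = 50, r = 2)
  st <- render_morphology(m, c(64, 64, 96), spacing = c(1, 1, 1),
                          fg = 200, bg = 20)
  prm <- tracer_params(seed_point = c(20, 32, 32))
  sa <- trace_semiauto(st, prm, m)
  expect_length(attr(sa, "edits"), 0)

  # one branch occluded (not rendered): exactly one add_path is generated
  mY <- y_morph()
  m_missing <- apply_edits(mY, edit_script(edit_delete_subtree(4L)))
  st2 <- render_morphology(m_missing, c(32, 64, 96), spacing = c(1, 1, 1),
                           fg = 200, bg = 20)
  prm2 <- tracer_params(seed_point = c(20, 32, 16))
  sa2 <- trace_semiauto(st2, prm2, mY)
  edits <- attr(sa2, "edits")
  expect_length(edits, 1)
  expect_equal(edits[[1]]$op, "add_path")
  expect_gt(consistency(mY, sa2)$consistency,
            consistency(mY, attr(sa2, "auto_trace"))$consistency)
})
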