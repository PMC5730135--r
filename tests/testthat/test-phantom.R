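test_that("phantom generation is deterministic and voxel counts match analytic volumes", {
  spec <- box_jaw_spec(noise_sd = 10, seed = 5L)
  a <- make_phantom(spec)
  b <- make_phantom(spec)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$labels$data, b$labels$data)
  # 40 x 40 x 20 mm box at 0.5 mm: count within 2% of the analytic volume
  n_vox <- sum(a$labels$data == 1L)
  expect_lt(abs(n_vox - 40 * 40 * 20 / 0.5^3) / (40 * 40 * 20 / 0.5^3), 0.02)
})

test_that("invalid phantom geometry is rejected with the primitive named", {
  geom <- default_skull_geometry()
  geom$mandible$hi <- geom$mandible$lo          # empty box
  expect_error(phantom_spec(skull_geometry = geom), "mandible")
  geom <- default_skull_geometry()
  geom$maxilla$hi[2] <- 1e4                     # outside the grid
  expect_error(phantom_spec(skull_geometry = geom), "maxilla")
  geom <- default_skull_geometry()
  geom$maxilla$lo[2] <- geom$soft_maxilla$lo[2] # overlap
  geom$maxilla$hi[2] <- geom$soft_maxilla$hi[2]
  expect_error(phantom_spec(skull_geometry = geom), "overlap")
  geom <- default_skull_geometry()
  geom$cranial_base <- NULL
  expect_error(phantom_spec(skull_geometry = geom), "cranial_base")
})

test_that("a null surgical plan returns the inputs unchanged", {
  ph <- fx_boxjaw()$ph
  out <- apply_surgery(ph$volume, ph$labels, surgical_plan())
  expect_identical(out$volume$data, ph$volume$data)
  expect_identical(out$labels$data, ph$labels$data)
})

test_that("surgery moves each label by its planned displacement", {
  bj <- fx_boxjaw()
  # 5 mm advancement = exactly 10 voxel layers at 0.5 mm: label sets shift
  l1 <- bj$ph$labels$data; l2 <- bj$t2$labels$data
  expect_identical(sum(l1 == 1L), sum(l2 == 1L))   # conservation (exact here)
  i1 <- which(l1 == 1L, arr.ind = TRUE)
  i2 <- which(l2 == 1L, arr.ind = TRUE)
  expect_identical(i2[, 2], i1[, 2] + 10L)
  gt <- bj$t2$ground_truth
  expect_equal(gt$adv_y[gt$component == "maxilla"], 5)
  expect_equal(gt$adv_y[gt$component == "cranial_base"], 0)
})

test_that("soft tissue follows the coupled displacement of its jaw", {
  spec <- phantom_spec(noise_sd = 0)
  ph <- make_phantom(spec)
  plan <- surgical_plan(maxilla_advance_mm = 5, soft_coupling_maxilla = 0.9)
  t2 <- apply_surgery(ph$volume, ph$labels, plan)
  gt <- t2$ground_truth
  expect_equal(gt$adv_y[gt$component == "soft_maxilla"], 4.5)
  # track the shell surface itself: front face plane moves by 4.5 mm
  m1 <- extract_surface(ph$labels, "soft_tissue")
  m2 <- extract_surface(t2$labels, "soft_tissue")
  front1 <- max(m1$vertices[, 2][m1$vertices[, 3] > 52 & m1$vertices[, 3] < 72])
  front2 <- max(m2$vertices[, 2][m2$vertices[, 3] > 52 & m2$vertices[, 3] < 72])
  expect_equal(front2 - front1, 4.5, tolerance = 1e-6)
})

test_that("surgery errors when a primitive would leave the grid or is absent", {
  bj <- fx_boxjaw()
  expect_error(
    apply_surgery(bj$ph$volume, bj$ph$labels,
                  surgical_plan(maxilla_advance_mm = 500)),
    "outside the grid")
  expect_error(
    apply_surgery(bj$ph$volume, bj$ph$labels,
                  surgical_plan(mandible_advance_mm = 3)),
    "no mandible")
})

test_that("label counts are conserved through surgery within 2%", {
  spec <- phantom_spec(noise_sd = 0)
  ph <- make_phantom(spec)
  plan <- surgical_plan(4, 9, rigid_transform(c(1, -1, 1), c(1, 1, -1),
                                              spec$grid_shape * spec$spacing_mm / 2),
                        soft_coupling_maxilla = 0.9,
                        soft_coupling_mandible = 0.9)
  t2 <- apply_surgery(ph$volume, ph$labels, plan)
  for (code in 1:4) {
    n1 <- sum(ph$labels$data == code)
    n2 <- sum(t2$labels$data == code)
    expect_lt(abs(n2 - n1) / n1, 0.02)
  }
})

test_that("cohorts are reproducible and validate their inputs", {
  spec <- box_jaw_spec()
  dist <- plan_distribution(mandible_advance = c(0, 0), pose_rot = c(0, 0),
                            pose_trans = c(0, 0), soft_noise_sd = 0,
                            nose_shift_sd = 0)
  a <- make_cohort(3, spec, dist, seed = 9L)
  b <- make_cohort(3, spec, dist, seed = 9L)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_identical(a$subjects[[2]]$volume_t2$data, b$subjects[[2]]$volume_t2$data)
  expect_error(make_cohort(1, spec, dist), "n >= 2")
  expect_error(plan_distribution(maxilla_advance = c(5, 1)), "min > max")
})
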