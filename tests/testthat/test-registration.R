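test_that("resampling preserves identity, convexity and analytic ramps", {
  v <- fx_boxjaw()$ph$volume
  expect_identical(resample(v, v$spacing_mm[1])$data, v$data)
  # constant volume stays constant at any spacing (convexity)
  cv <- new_volume(array(7, c(20, 20, 20)), 0.4)
  r <- resample(cv, 0.5)
  expect_true(all(r$data == 7))
  # extent preserved within one voxel
  expect_lt(max(abs(dim(r$data) * 0.5 - dim(cv$data) * 0.4)), 0.5)
  # linear ramp along x reproduced exactly at the new voxel centres
  n <- 40
  ramp <- new_volume(array(rep((0:(n - 1)) * 0.4, times = n * n), c(n, n, n)), 0.4)
  r2 <- resample(ramp, 0.5)
  centres <- (seq_len(dim(r2$data)[1]) - 1) * 0.5
  inside <- centres <= (n - 1) * 0.4
  expect_lt(max(abs(r2$data[inside, 2, 2] - centres[inside])), 1e-6)
  expect_error(resample(ramp, -1), "positive")
  # range not expanded
  expect_gte(min(r2$data), min(ramp$data))
  expect_lte(max(r2$data), max(ramp$data))
})

test_that("mutual information is symmetric, self-informative and near zero for noise", {
  set.seed(31)
  dm <- c(50, 50, 44)
  a <- new_volume(array(stats::runif(prod(dm)), dm), 0.5)
  b <- new_volume(array(stats::runif(prod(dm)), dm), 0.5)
  mask <- array(TRUE, dm)
  # MI(a, a) equals the histogram entropy of a under the same binning
  xa <- as.numeric(a$data)
  h <- tabulate(dispquant:::bin_index(xa, min(xa), max(xa), 32) + 1L, 32)
  p <- h / sum(h)
  expect_equal(mutual_information(a, a, mask), -sum(p * log2(p)),
               tolerance = 1e-12)
  expect_identical(mutual_information(a, b, mask),
                   mutual_information(b, a, mask))
  # independent volumes share almost no information (>= 1e5 mask voxels)
  expect_lt(mutual_information(a, b, mask, bins = 32), 0.05)
  expect_error(mutual_information(a, b, array(FALSE, dm)), "empty")
})

test_that("self-registration recovers the identity", {
  ph <- fx_boxjaw()$ph
  tfm <- register_rigid(ph$volume, ph$volume, ph$labels)
  expect_true(attr(tfm, "converged"))
  expect_lt(max(abs(tfm$translation_mm)), 0.05)
  expect_lt(rotation_angle_deg(tfm), 0.05)
  expect_error(register_rigid(ph$volume, ph$volume,
                              array(FALSE, dim(ph$volume$data))),
               "zero voxels")
})

test_that("mutual information peaks at the ground-truth pose", {
  spec <- box_jaw_spec(noise_sd = 0)
  ph <- make_phantom(spec)
  pose <- rigid_transform(c(1.5, -1, 2), c(1, -1.5, 0.5),
                          spec$grid_shape * spec$spacing_mm / 2)
  t2 <- apply_surgery(ph$volume, ph$labels, surgical_plan(head_pose = pose))
  mask <- dispquant:::dilate_mask(label_mask(ph$labels, "cranial_base"),
                                  ph$labels$spacing_mm, 3)
  mi_at <- function(tr) {
    moved <- apply_transform(t2$volume, tr)
    mutual_information(ph$volume, moved, mask)
  }
  truth <- invert_transform(pose)
  mi_truth <- mi_at(truth)
  set.seed(12)
  for (k in 1:10) {
    pert <- compose_transforms(
      rigid_transform(stats::runif(3, -1, 1), stats::runif(3, -1, 1),
                      spec$grid_shape * spec$spacing_mm / 2),
      truth)
    expect_gt(mi_truth, mi_at(pert))
  }
})

test_that("registration recovers a known head pose to sub-voxel accuracy", {
  spec <- phantom_spec()
  ph <- make_phantom(spec)
  pose <- rigid_transform(c(2, -1.5, 1), c(2, -2, 1.5),
                          spec$grid_shape * spec$spacing_mm / 2)
  plan <- surgical_plan(3, 7, pose, soft_coupling_maxilla = 0.9,
                        soft_coupling_mandible = 0.9)
  t2 <- apply_surgery(ph$volume, ph$labels, plan)
  tfm <- register_rigid(ph$volume, t2$volume, ph$labels)
  expect_true(attr(tfm, "converged"))
  res <- compose_transforms(tfm, pose)
  cb <- which(ph$labels$data == 4L)
  ctr <- colMeans(voxel_to_world(ph$labels, arrayInd(cb, dim(ph$labels$data))))
  tre <- sqrt(sum((apply_transform(rbind(ctr), res) - ctr)^2))
  expect_lt(tre, 0.1)
  expect_lt(rotation_angle_deg(res), 0.1)
})
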