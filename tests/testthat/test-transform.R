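test_that("rigid transforms compose, invert and preserve distances", {
  set.seed(11)
  for (i in 1:10) {
    t1 <- rigid_transform(runif(3, -30, 30), runif(3, -10, 10), runif(3, 0, 50))
    # inverse composes to identity within 1e-9
    m <- transform_matrix(compose_transforms(t1, invert_transform(t1)))
    expect_lt(max(abs(m - diag(4))), 1e-9)
    # rigidity: pairwise distances preserved
    pts <- matrix(runif(30, -20, 20), ncol = 3)
    out <- apply_transform(pts, t1)
    expect_lt(max(abs(dist(out) - dist(pts))) / max(dist(pts)), 1e-9)
    # centroid maps as a point
    expect_equal(colMeans(out),
                 as.numeric(apply_transform(rbind(colMeans(pts)), t1)),
                 tolerance = 1e-12)
  }
})

test_that("identity transform and translation round trip leave meshes unchanged", {
  m <- fx_submesh()
  expect_equal(apply_transform(m, rigid_transform())$vertices, m$vertices)
  fwd <- rigid_transform(translation_mm = c(5, 0, 0))
  back <- rigid_transform(translation_mm = c(-5, 0, 0))
  m2 <- apply_transform(apply_transform(m, fwd), back)
  expect_lt(max(abs(m2$vertices - m$vertices)), 1e-9)
})

test_that("transform JSON serialization round trips", {
  t1 <- rigid_transform(c(2, -1.5, 1), c(0.5, -2, 3), c(10, 20, 30))
  f <- withr::local_tempfile(fileext = ".json")
  write_transform(t1, f)
  t2 <- read_transform(f)
  expect_equal(t2$rotation_deg, t1$rotation_deg)
  expect_equal(t2$translation_mm, t1$translation_mm)
  expect_equal(t2$center_mm, t1$center_mm)
})
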