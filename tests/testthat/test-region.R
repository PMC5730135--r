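test_that("paint radius 0 selects the nearest vertex; a huge radius the whole component", {
  m <- fx_sphere_mesh()
  seed <- m$vertices[10, ] + c(0.3, 0, 0)
  r0 <- paint_region(m, seed, 0)
  near <- which.min(colSums((t(m$vertices) - seed)^2))
  expect_identical(r0$vertex_ids, near)
  rall <- paint_region(m, seed, 1e4, metric = "geodesic")
  expect_identical(rall$vertex_ids, seq_len(nrow(m$vertices)))
})

test_that("geodesic patches are strictly smaller than Euclidean ones on a sphere", {
  m <- fx_sphere_mesh()
  top <- m$vertices[which.max(m$vertices[, 3]), ]
  ge <- paint_region(m, top, 10, metric = "geodesic")
  eu <- paint_region(m, top, 10, metric = "euclidean")
  expect_lt(length(ge$vertex_ids), length(eu$vertex_ids))
  # shortest-edge-path oracle: every geodesic member is a Euclidean member
  expect_true(all(ge$vertex_ids %in% eu$vertex_ids))
})

test_that("seeds far from the surface and empty paints are refused", {
  m <- fx_sphere_mesh()
  ctr <- colMeans(m$vertices)
  expect_error(paint_region(m, ctr, 5), "2 mm")
  expect_error(paint_region(m, m$vertices[1, ], -1), ">= 0")
})

test_that("regions serialize to JSON and stay bound to their mesh", {
  m <- fx_sphere_mesh()
  r <- paint_region(m, m$vertices[5, ], 4, name = "patch")
  f <- withr::local_tempfile(fileext = ".json")
  write_region(r, f)
  r2 <- read_region(f)
  expect_identical(r2$vertex_ids, r$vertex_ids)
  expect_identical(r2$mesh_checksum, attr(m, "checksum"))
  # checksum firewall: measuring against different geometry fails
  other <- apply_transform(m, rigid_transform(translation_mm = c(1, 0, 0)))
  expect_error(region_summary(r2, other, other), "checksum")
})
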