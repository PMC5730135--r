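test_that("extracted surfaces match analytic areas and volumes", {
  m <- fx_sphere_mesh()
  expect_lt(abs(mesh_area(m) - 4 * pi * 20^2) / (4 * pi * 20^2), 0.03)
  expect_lt(abs(mesh_volume(m) - 4 / 3 * pi * 20^3) / (4 / 3 * pi * 20^3), 0.02)
  box <- fx_boxjaw()$m1
  expect_lt(abs(mesh_volume(box) - 32000) / 32000, 0.02)
})

test_that("extracted phantom surfaces are closed and consistently oriented", {
  expect_identical(euler_characteristic(fx_sphere_mesh()), 2L)
  expect_identical(euler_characteristic(fx_boxjaw()$m1), 2L)
  # outward normals: along the radius for a sphere
  m <- fx_sphere_mesh()
  ctr <- colMeans(m$vertices)
  radial <- sweep(m$vertices, 2, ctr)
  radial <- radial / sqrt(rowSums(radial^2))
  expect_gt(min(rowSums(radial * m$normals)), 0.3)
  expect_gt(mean(rowSums(radial * m$normals)), 0.95)
})

test_that("absent or empty labels are refused by name", {
  lab <- fx_sphere_labels()
  expect_error(extract_surface(lab, "sphere2"), "sphere2")
  lab2 <- new_labelmap(array(0L, c(8, 8, 8)), 0.5, label_names = c(thing = 1L))
  expect_error(extract_surface(lab2, "thing"), "thing")
})

test_that("extraction commutes with rigid motion within a voxel", {
  lab <- fx_sphere_labels()
  tr <- rigid_transform(c(4, -3, 2), c(1.5, -1, 2), c(24, 24, 24))
  a <- apply_transform(extract_surface(lab, "sphere"), tr)
  b <- extract_surface(apply_transform(lab, tr), "sphere")
  # two-sided closest-point distance (discrete Hausdorff proxy)
  d_ab <- closest_point_distance(a$vertices, b)$distance_mm
  d_ba <- closest_point_distance(b$vertices, a)$distance_mm
  expect_lt(max(c(d_ab, d_ba)), 0.5)
})

test_that("binary STL round trips exactly and is refused when degenerate", {
  m <- fx_submesh()
  f <- withr::local_tempfile(fileext = ".stl")
  write_stl(m, f)
  m2 <- read_stl(f)
  expect_identical(nrow(m2$faces), nrow(m$faces))
  soup1 <- m$vertices[t(m$faces), ]
  soup2 <- m2$vertices[t(m2$faces), ]
  expect_lt(max(abs(soup1 - soup2)), 1e-5)
  # sidecar carries the label
  m3 <- read_stl(f)
  expect_identical(m3$label, m$label)
  empty <- new_mesh(matrix(0, 3, 3), matrix(integer(0), 0, 3), "x")
  expect_error(write_stl(empty, f), "zero-triangle")
})

test_that("malformed STL is reported with its byte accounting", {
  f <- withr::local_tempfile(fileext = ".stl")
  writeBin(raw(40), f)
  expect_error(read_stl(f), "84-byte")
  write_stl(fx_submesh(), f)
  sz <- file.info(f)$size
  # truncate the file mid-triangle
  writeBin(readBin(f, "raw", sz - 25), f)
  expect_error(read_stl(f), "bytes")
})

test_that("STL written here is readable by an independent mesh tool", {
  m <- fx_submesh()
  f <- tempfile(fileext = ".stl")
  on.exit(unlink(c(f, paste0(f, ".json"))))
  write_stl(m, f)
  py <- sprintf(
    "import trimesh, sys; t = trimesh.load(%s); print(len(t.faces), len(t.vertices))",
    shQuote(f))
  out <- system2("python", c("-c", shQuote(py)), stdout = TRUE)
  counts <- as.integer(strsplit(out[length(out)], " ")[[1]])
  expect_identical(counts[1], nrow(m$faces))
  expect_identical(counts[2], nrow(m$vertices))
})
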