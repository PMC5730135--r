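test_that("closest-point distances handle surface, face and oracle cases", {
  m <- fx_boxjaw()$m1
  # a vertex on the surface is at distance zero
  expect_equal(closest_point_distance(m$vertices[100, ], m)$distance_mm, 0)
  # perpendicular foot above the interior of the anterior flat face (y = 27.75)
  q <- c(28, 27.75 + 3.2, 28)
  expect_equal(closest_point_distance(q, m)$distance_mm, 3.2, tolerance = 1e-9)
  expect_error(closest_point_distance(c(0, 0, 0),
                                      new_mesh(matrix(0, 3, 3),
                                               matrix(integer(0), 0, 3), "x")),
               "empty")
})

test_that("tree-accelerated queries equal the exhaustive triangle scan", {
  m <- fx_submesh()
  set.seed(77)
  q <- matrix(runif(3 * 100, 0, 48), ncol = 3)
  got <- closest_point_distance(q, m)$distance_mm
  want <- vapply(seq_len(nrow(q)), function(i) brute_closest(q[i, ], m), 0)
  expect_lt(max(abs(got - want)), 1e-9)
})

test_that("displacement sign follows the outward normal; parity oracle agrees", {
  bj <- fx_boxjaw()
  out3 <- apply_transform(bj$m1, rigid_transform(translation_mm = c(0, 3, 0)))
  in3 <- apply_transform(bj$m1, rigid_transform(translation_mm = c(0, -3, 0)))
  face <- which(abs(bj$m1$vertices[, 2] - 27.75) < 1e-6 &
                abs(bj$m1$vertices[, 1] - 28) < 8 &
                abs(bj$m1$vertices[, 3] - 28) < 8)
  expect_equal(signed_displacement(bj$m1, out3, face), rep(3, length(face)),
               tolerance = 1e-9)
  expect_equal(signed_displacement(bj$m1, in3, face), rep(-3, length(face)),
               tolerance = 1e-9)
  # curved surface under an arbitrary rigid motion: sign must match a
  # point-in-solid parity test on the target sphere
  sph <- fx_sphere_mesh()
  tr <- rigid_transform(c(2, 1, -2), c(1.2, -0.8, 0.6), c(24, 24, 24))
  tgt <- apply_transform(sph, tr)
  set.seed(9)
  ids <- sample(nrow(sph$vertices), 200)
  s <- signed_displacement(sph, tgt, ids)
  # oracle: negative iff the closest target point falls inside the source
  # solid; for the source sphere, inside = closer to its centre than the
  # surface radius along that ray
  cp <- closest_point_distance(sph$vertices[ids, ], tgt)
  cp_pts <- cbind(cp$cp_x, cp$cp_y, cp$cp_z)
  ctr_src <- c(23.75, 23.75, 23.75)
  r_src <- mean(sqrt(colSums((t(sph$vertices) - ctr_src)^2)))
  cp_dist <- sqrt(colSums((t(cp_pts) - ctr_src)^2))
  inside_src <- cp_dist < r_src
  # judge only closest points clearly off the source surface (extraction
  # roughness is ~0.05 mm near the threshold radius)
  clear <- abs(cp_dist - r_src) > 0.2 & abs(s) > 0.2
  expect_gt(sum(clear), 50)
  expect_true(all((s[clear] < 0) == inside_src[clear]))
})

test_that("region summaries obey their invariants and the flat-face identity", {
  bj <- fx_boxjaw()
  # identical meshes: all zeros
  r <- paint_region(bj$m1, c(28, 27.75, 28), 6, name = "anterior")
  z <- region_summary(r, bj$m1, bj$m1)
  expect_equal(z$min_mm, 0); expect_equal(z$max_mm, 0)
  expect_equal(z$negative_fraction, 0)
  # 5 mm advancement along the flat anterior face normal
  s <- region_summary(r, bj$m1, bj$m2)
  expect_equal(s$mean_mm, 5, tolerance = 0.05)
  expect_equal(s$min_mm, 5, tolerance = 0.05)
  expect_equal(s$max_mm, 5, tolerance = 0.05)
  expect_true(s$min_mm <= s$mean_mm && s$mean_mm <= s$max_mm)
  expect_lte(abs(s$mean_mm), s$unsigned_mean_mm)
})

test_that("summaries equal the brute-force oracle under oblique motion", {
  m <- fx_submesh()
  tr <- rigid_transform(c(1, -2, 1), c(2.5, 3.1, -1.7), c(24, 24, 24))
  tgt <- apply_transform(m, tr)
  set.seed(21)
  ids <- sort(sample(nrow(m$vertices), 60))
  r <- region_from_vertices(m, ids, "oblique")
  s <- suppressWarnings(region_summary(r, m, tgt))
  want <- vapply(ids, function(i) brute_closest(m$vertices[i, ], tgt), 0)
  expect_equal(s$unsigned_mean_mm, mean(want), tolerance = 1e-9)
  expect_equal(s$n_vertices, length(ids))
})

test_that("rigid motion applied to both meshes leaves summaries unchanged", {
  bj <- fx_boxjaw()
  r <- paint_region(bj$m1, c(28, 27.75, 28), 6, name = "anterior")
  s0 <- region_summary(r, bj$m1, bj$m2)
  tr <- rigid_transform(c(10, -6, 4), c(7, -3, 11), c(30, 10, 20))
  m1t <- apply_transform(bj$m1, tr)
  m2t <- apply_transform(bj$m2, tr)
  rt <- region_from_vertices(m1t, r$vertex_ids, "anterior")
  s1 <- region_summary(rt, m1t, m2t)
  expect_equal(s1$mean_mm, s0$mean_mm, tolerance = 1e-6)
  expect_equal(s1$min_mm, s0$min_mm, tolerance = 1e-6)
  expect_equal(s1$max_mm, s0$max_mm, tolerance = 1e-6)
})

test_that("the label firewall refuses cross-label measurement", {
  bj <- fx_boxjaw()
  soft <- bj$m1; soft$label <- "soft_tissue"
  attr(soft, "checksum") <- dispquant:::mesh_checksum(soft)
  r <- paint_region(soft, c(28, 27.75, 28), 4, name = "soft patch")
  expect_error(region_summary(r, soft, bj$m2), "label firewall")
  expect_error(full_surface_summary(soft, bj$m2), "label firewall")
})

test_that("sign mixing triggers the nasal-base warning", {
  # a patch on the side of a sphere translated tangentially mixes inward
  # (trailing) and outward (leading) displacements, like curved nasal-base
  # areas under advancement
  sph <- fx_sphere_mesh()
  tgt <- apply_transform(sph, rigid_transform(translation_mm = c(0, 1.5, 0)))
  side <- sph$vertices[which.max(sph$vertices[, 1]), ]
  r <- paint_region(sph, side, 8, name = "curvature")
  expect_warning(s <- region_summary(r, sph, tgt), "sign mixing")
  expect_gt(s$negative_fraction, 0.05)
  expect_lt(s$negative_fraction, 0.95)
  expect_lt(abs(s$mean_mm), s$unsigned_mean_mm)
})

test_that("growing the area into overlap shrinks the mean (area-size effect)", {
  spec <- box_jaw_spec(face_mm = c(60, 60), depth_mm = 20)
  ph <- make_phantom(spec)
  t2 <- apply_surgery(ph$volume, ph$labels, surgical_plan(maxilla_advance_mm = 5))
  m1 <- extract_surface(ph$labels, "maxilla_upper_teeth")
  m2 <- extract_surface(t2$labels, "maxilla_upper_teeth")
  ctr <- c(38, 28.25 - 0.5, 38)
  front <- paint_region(m1, c(38, 27.75, 38), 10, name = "front")
  s_front <- region_summary(front, m1, m2)
  s_full <- full_surface_summary(m1, m2)
  expect_lt(s_full$unsigned_mean_mm, s_front$mean_mm)
  expect_equal(s_front$mean_mm, 5, tolerance = 0.05)
  want <- analytic_box_advance_mean(60, 60, 20, 5)
  expect_lt(abs(s_full$unsigned_mean_mm - want) / want, 0.05)
})
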