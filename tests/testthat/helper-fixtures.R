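# Shared fixtures, computed once per test run and memoized. Everything is
# generated in code; nothing is read from disk.

.fx <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# digital sphere label map, radius 20 mm at 0.5 mm spacing
fx_sphere_labels <- function(radius = 20, n = 96, sp = 0.5) {
  fx(sprintf("sphere_%g_%d", radius, n), function() {
    ctr <- (n - 1) / 2 * sp
    ax <- (0:(n - 1)) * sp
    d <- sqrt(outer(outer((ax - ctr)^2, (ax - ctr)^2, "+"), (ax - ctr)^2, "+"))
    new_labelmap(array(as.integer(d <= radius), c(n, n, n)), sp,
                 label_names = c(sphere = 1L))
  })
}

fx_sphere_mesh <- function() fx("sphere_mesh", function() {
  extract_surface(fx_sphere_labels(), "sphere")
})

# 40x40 face box-jaw phantom and its 5 mm advancement
fx_boxjaw <- function() fx("boxjaw", function() {
  spec <- box_jaw_spec()
  ph <- make_phantom(spec)
  t2 <- apply_surgery(ph$volume, ph$labels, surgical_plan(maxilla_advance_mm = 5))
  m1 <- extract_surface(ph$labels, "maxilla_upper_teeth")
  m2 <- extract_surface(t2$labels, "maxilla_upper_teeth")
  list(spec = spec, ph = ph, t2 = t2, m1 = m1, m2 = m2)
})

# a small random sub-mesh (~500 triangles) of the sphere, plus random queries
fx_submesh <- function(ntri = 500) fx(paste0("submesh", ntri), function() {
  m <- fx_sphere_mesh()
  set.seed(402)
  f <- m$faces[sample(nrow(m$faces), ntri), ]
  used <- sort(unique(as.vector(f)))
  new_mesh(m$vertices[used, ], matrix(match(f, used), ncol = 3), "sub")
})

# brute-force point-to-triangle-set distance, implemented independently of
# the compiled path (plane projection + clamped edge segments)
brute_closest <- function(q, mesh) {
  V <- mesh$vertices; F <- mesh$faces
  best <- Inf
  for (t in seq_len(nrow(F))) {
    a <- V[F[t, 1], ]; b <- V[F[t, 2], ]; cc <- V[F[t, 3], ]
    E1 <- b - a; E2 <- cc - a; w <- q - a
    A <- sum(E1 * E1); B <- sum(E1 * E2); C <- sum(E2 * E2)
    D <- sum(E1 * w); E <- sum(E2 * w)
    det <- A * C - B * B
    s <- (C * D - B * E) / det; tt <- (A * E - B * D) / det
    if (is.finite(s) && s >= 0 && tt >= 0 && s + tt <= 1) {
      p <- a + s * E1 + tt * E2
    } else {
      seg <- function(p0, p1) {
        v <- p1 - p0
        u <- sum((q - p0) * v) / sum(v * v)
        p0 + min(max(u, 0), 1) * v
      }
      cand <- rbind(seg(a, b), seg(b, cc), seg(a, cc))
      p <- cand[which.min(rowSums(sweep(cand, 2, q)^2)), ]
    }
    d <- sqrt(sum((q - p)^2))
    if (d < best) best <- d
  }
  best
}

rotation_angle_deg <- function(t) {
  R <- dispquant:::rot_matrix(t$rotation_deg)
  acos(pmin(pmax((sum(diag(R)) - 1) / 2, -1), 1)) * 180 / pi
}
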