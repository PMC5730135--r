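#' Phantom specification
#'
#' Parameterizes a synthetic two-time-point "patient": a primitive-based
#' skull (cranial-base slab, maxilla and mandible boxes with flat anterior
#' faces, soft-tissue shells in front of each jaw, and a small uncoupled
#' "nose" shell) voxelized onto an isotropic grid with CT-like intensities.
#' The anatomy is deliberately primitive — the measurement method only needs
#' surfaces, labels and known transforms, and flat anterior faces make
#' translation-along-normal displacements analytically exact.
#'
#' Geometry boxes are axis-aligned `[lo, hi)` intervals in world mm
#' (x: left-right, y: posterior-anterior, advancement is +y,
#' z: inferior-superior). A voxel belongs to a box when its centre does.
#'
#' @param grid_shape voxel counts per axis.
#' @param spacing_mm isotropic voxel size, mm (default 0.5, the working
#'   resolution scans are reformatted to).
#' @param skull_geometry named list of primitives; each is
#'   `list(lo =, hi =, label =, unit =)` with `unit` one of
#'   `"cranial"`, `"maxilla"`, `"mandible"`, `"soft_maxilla"`,
#'   `"soft_mandible"`, `"nose"` deciding which rigid motion it follows.
#' @param intensities named vector: mean image value for bone / soft / air.
#' @param noise_sd additive Gaussian intensity noise (image units).
#' @param psf_sigma_mm scanner point-spread width, mm: intensity volumes are
#'   rendered as the analytic Gaussian-blurred box fields (a product of
#'   normal CDF terms per axis), emulating the partial-volume effect of a
#'   real scanner. Without it, rotated follow-up scans would carry voxel
#'   staircase artifacts that no real acquisition has.
#' @param seed integer RNG seed for the intensity noise.
#' @return Object of class `dq_phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(128L, 224L, 208L),
                         spacing_mm = 0.5,
                         skull_geometry = default_skull_geometry(),
                         intensities = c(bone = 1200, soft = 300, air = 0),
                         noise_sd = 30,
                         psf_sigma_mm = 0.4,
                         seed = 1L) {
  spec <- structure(
    list(grid_shape = as.integer(rep_len(grid_shape, 3)),
         spacing_mm = as.numeric(spacing_mm),
         skull_geometry = skull_geometry,
         intensities = intensities, noise_sd = noise_sd,
         psf_sigma_mm = psf_sigma_mm,
         seed = as.integer(seed)),
    class = "dq_phantom_spec")
  validate_phantom_spec(spec)
  spec
}

#' Default skull geometry
#'
#' The standard phantom layout. Painted measurement areas sit at the centre
#' of the anterior faces, farther from every face edge than the largest
#' advancement the cohort generator draws, so closest-point means are not
#' contaminated by the overlapping lateral surfaces.
#'
#' @return Named list of primitives for [phantom_spec()].
#' @export
default_skull_geometry <- function() {
  # Thickness rule: every measured structure is deeper along the motion axis
  # than twice the largest displacement it can receive, so the closest point
  # from a front-face region always lies on the displaced front face, never
  # on the shell's inner surface.
  box <- function(lo, hi, label, unit)
    list(lo = lo, hi = hi, label = label, unit = unit)
  list(
    soft_maxilla  = box(c(12, 45, 52),   c(52, 59, 72),  3L, "soft_maxilla"),
    soft_mandible = box(c(12, 52, 12),   c(52, 86, 48),  3L, "soft_mandible"),
    nose          = box(c(27, 42, 73.5), c(37, 47, 77),  3L, "nose"),
    maxilla       = box(c(12, 22, 52),   c(52, 42, 72),  1L, "maxilla"),
    mandible      = box(c(12, 14, 12),   c(52, 48, 48),  2L, "mandible"),
    cranial_base  = box(c(12, 16, 78),   c(52, 48, 90),  4L, "cranial")
  )
}

#' Simple box-jaw phantom
#'
#' A reduced phantom with a single jaw box (flat anterior face of the given
#' size) plus the mandatory cranial-base slab, used for analytic displacement
#' experiments: a sagittal advancement of the jaw moves its anterior face by
#' exactly the advancement.
#'
#' @param face_mm anterior face size `c(width_x, height_z)`, mm.
#' @param depth_mm jaw depth along the advancement axis, mm.
#' @param margin_mm empty margin around the geometry, mm.
#' @param advance_room_mm extra room in +y for the planned advancement.
#' @param spacing_mm,noise_sd,seed as in [phantom_spec()].
#' @return A `dq_phantom_spec` with `maxilla` and `cranial_base` primitives.
#' @export
box_jaw_spec <- function(face_mm = c(40, 40), depth_mm = 20,
                         margin_mm = 8, advance_room_mm = 10,
                         spacing_mm = 0.5, noise_sd = 0, seed = 1L) {
  m <- margin_mm
  w <- face_mm[1]; h <- face_mm[2]; d <- depth_mm
  ext_x <- w + 2 * m
  ext_y <- d + 2 * m + advance_room_mm
  ext_z <- h + 2 * m + 16    # room for the cranial slab above
  shape <- as.integer(ceiling(c(ext_x, ext_y, ext_z) / spacing_mm))
  geom <- list(
    maxilla = list(lo = c(m, m, m), hi = c(m + w, m + d, m + h),
                   label = 1L, unit = "maxilla"),
    cranial_base = list(lo = c(m, m, m + h + 4),
                        hi = c(m + w, m + d, m + h + 12),
                        label = 4L, unit = "cranial")
  )
  phantom_spec(grid_shape = shape, spacing_mm = spacing_mm,
               skull_geometry = geom, noise_sd = noise_sd, seed = seed)
}

validate_phantom_spec <- function(spec) {
  extent <- spec$grid_shape * spec$spacing_mm
  geom <- spec$skull_geometry
  if (is.null(geom$cranial_base))
    stop("phantom geometry must contain a 'cranial_base' primitive")
  for (nm in names(geom)) {
    b <- geom[[nm]]
    if (any(b$hi <= b$lo))
      stop(sprintf("empty primitive '%s' (hi <= lo)", nm))
    if (any(b$lo < 0) || any(b$hi > extent - spec$spacing_mm / 2))
      stop(sprintf("primitive '%s' exceeds the grid (extent %s mm)",
                   nm, paste(extent, collapse = "x")))
  }
  nms <- names(geom)
  for (i in seq_along(geom)) {
    for (j in seq_len(i - 1L)) {
      a <- geom[[i]]; b <- geom[[j]]
      if (all(a$lo < b$hi & b$lo < a$hi))
        stop(sprintf("primitives '%s' and '%s' overlap", nms[i], nms[j]))
    }
  }
  invisible(spec)
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

axis_centers <- function(n, sp) (seq_len(n) - 1) * sp

paint_box_labels <- function(arr, spec, comp_names = names(spec$skull_geometry)) {
  sp <- spec$spacing_mm
  dm <- spec$grid_shape
  cx <- axis_centers(dm[1], sp); cy <- axis_centers(dm[2], sp)
  cz <- axis_centers(dm[3], sp)
  for (nm in comp_names) {
    b <- spec$skull_geometry[[nm]]
    ix <- which(cx >= b$lo[1] & cx < b$hi[1])
    iy <- which(cy >= b$lo[2] & cy < b$hi[2])
    iz <- which(cz >= b$lo[3] & cz < b$hi[3])
    arr[ix, iy, iz] <- b$label
  }
  arr
}

comp_intensity <- function(b, spec) {
  if (b$label == 3L) spec$intensities[["soft"]] else spec$intensities[["bone"]]
}

# Analytic band-limited rendering: each box convolved with the scanner PSF
# is a separable product of Gaussian-CDF terms per axis, evaluated at the
# (inverse-transformed) voxel centres. Exact; no voxelization staircase.
render_intensity <- function(spec, transforms = NULL) {
  sp <- spec$spacing_mm
  dm <- spec$grid_shape
  sig <- spec$psf_sigma_mm
  out <- array(spec$intensities[["air"]], dm)
  cxs <- list(axis_centers(dm[1], sp), axis_centers(dm[2], sp),
              axis_centers(dm[3], sp))
  margin <- max(4 * sig, sp)
  for (nm in names(spec$skull_geometry)) {
    b <- spec$skull_geometry[[nm]]
    val <- comp_intensity(b, spec) - spec$intensities[["air"]]
    tr <- if (is.null(transforms)) NULL else transforms[[nm]]
    identity_tr <- is.null(tr) ||
      (all(tr$rotation_deg == 0) && all(tr$translation_mm == 0))
    pure_translation <- !identity_tr && all(tr$rotation_deg == 0)
    if (sig <= 0) {
      wfun <- function(x, lo, hi) as.numeric(x >= lo & x < hi)
    } else {
      wfun <- function(x, lo, hi) pnorm((hi - x) / sig) - pnorm((lo - x) / sig)
    }
    if (identity_tr || pure_translation) {
      shift <- if (identity_tr) c(0, 0, 0) else tr$translation_mm
      w_ax <- sel_ax <- vector("list", 3)
      for (d in 1:3) {
        lo <- b$lo[d] + shift[d]; hi <- b$hi[d] + shift[d]
        sel_ax[[d]] <- which(cxs[[d]] > lo - margin & cxs[[d]] < hi + margin)
        w_ax[[d]] <- wfun(cxs[[d]][sel_ax[[d]]], lo, hi)
      }
      if (any(lengths(sel_ax) == 0)) next
      w <- outer(outer(w_ax[[1]], w_ax[[2]]), w_ax[[3]])
      out[sel_ax[[1]], sel_ax[[2]], sel_ax[[3]]] <-
        out[sel_ax[[1]], sel_ax[[2]], sel_ax[[3]]] + val * w
    } else {
      m <- transform_matrix(tr)
      corners <- as.matrix(expand.grid(c(b$lo[1], b$hi[1]),
                                       c(b$lo[2], b$hi[2]),
                                       c(b$lo[3], b$hi[3])))
      tc <- sweep(corners %*% t(m[1:3, 1:3]), 2, m[1:3, 4], `+`)
      sel_ax <- lapply(1:3, function(d)
        which(cxs[[d]] > min(tc[, d]) - margin &
              cxs[[d]] < max(tc[, d]) + margin))
      if (any(lengths(sel_ax) == 0)) next
      idx <- as.matrix(expand.grid(sel_ax[[1]], sel_ax[[2]], sel_ax[[3]]))
      pts <- cbind(cxs[[1]][idx[, 1]], cxs[[2]][idx[, 2]], cxs[[3]][idx[, 3]])
      mi <- transform_matrix(invert_transform(tr))
      src <- sweep(pts %*% t(mi[1:3, 1:3]), 2, mi[1:3, 4], `+`)
      w <- wfun(src[, 1], b$lo[1], b$hi[1]) *
           wfun(src[, 2], b$lo[2], b$hi[2]) *
           wfun(src[, 3], b$lo[3], b$hi[3])
      out[idx] <- out[idx] + val * w
    }
  }
  out
}

#' Generate a phantom baseline scan
#'
#' Voxelizes the spec's geometry into a label map and a CT-like intensity
#' volume (bone bright, soft tissue mid, air dark, plus Gaussian noise).
#' Deterministic: the same spec (same seed) reproduces bit-identical output.
#'
#' @param spec a [phantom_spec()].
#' @return `list(volume = dq_volume, labels = dq_labelmap)`; the label map
#'   carries the spec so [apply_surgery()] knows the component geometry.
#' @export
make_phantom <- function(spec) {
  validate_phantom_spec(spec)
  dm <- spec$grid_shape
  lab <- paint_box_labels(array(0L, dm), spec)
  vol_arr <- render_intensity(spec)
  if (spec$noise_sd > 0)
    vol_arr <- vol_arr + with_seed(spec$seed,
                                   array(stats::rnorm(prod(dm), 0, spec$noise_sd), dm))
  labels <- new_labelmap(lab, spec$spacing_mm, c(0, 0, 0))
  attr(labels, "phantom_spec") <- spec
  vol <- new_volume(vol_arr, spec$spacing_mm, c(0, 0, 0))
  attr(vol, "noise_seed") <- spec$seed
  list(volume = vol, labels = labels)
}

#' Surgical plan for a phantom
#'
#' Per-jaw sagittal advancements, a whole-head rigid nuisance pose applied to
#' the follow-up scan, and the soft-tissue coupling model: each soft shell is
#' displaced by `coupling x (its jaw's advancement)` plus an isotropic
#' per-subject jitter; the nose shell receives an independent small shift
#' (uncoupled soft tissue). Advancements must be non-negative; couplings in
#' `[0, 1.5]`.
#'
#' @param maxilla_advance_mm,mandible_advance_mm sagittal advancement, mm.
#' @param head_pose `dq_rigid` nuisance transform of the whole T2 subject.
#' @param soft_coupling_maxilla,soft_coupling_mandible scalar coupling ratio
#'   per jaw (soft displacement = ratio x hard displacement).
#' @param soft_noise_sd_mm sd of the per-subject isotropic soft-tissue
#'   jitter, mm.
#' @param nose_shift_sd_mm sd of the independent nose shift, mm.
#' @return Object of class `dq_surgical_plan`.
#' @export
surgical_plan <- function(maxilla_advance_mm = 0, mandible_advance_mm = 0,
                          head_pose = rigid_transform(),
                          soft_coupling_maxilla = 1,
                          soft_coupling_mandible = 1,
                          soft_noise_sd_mm = 0,
                          nose_shift_sd_mm = 0) {
  if (maxilla_advance_mm < 0 || mandible_advance_mm < 0)
    stop("advancements must be >= 0")
  if (soft_coupling_maxilla < 0 || soft_coupling_maxilla > 1.5 ||
      soft_coupling_mandible < 0 || soft_coupling_mandible > 1.5)
    stop("coupling ratios must lie in [0, 1.5]")
  structure(
    list(maxilla_advance_mm = maxilla_advance_mm,
         mandible_advance_mm = mandible_advance_mm,
         head_pose = head_pose,
         soft_coupling_maxilla = soft_coupling_maxilla,
         soft_coupling_mandible = soft_coupling_mandible,
         soft_noise_sd_mm = soft_noise_sd_mm,
         nose_shift_sd_mm = nose_shift_sd_mm),
    class = "dq_surgical_plan")
}

null_plan <- function(plan) {
  plan$maxilla_advance_mm == 0 && plan$mandible_advance_mm == 0 &&
    all(plan$head_pose$rotation_deg == 0) &&
    all(plan$head_pose$translation_mm == 0) &&
    plan$soft_noise_sd_mm == 0 && plan$nose_shift_sd_mm == 0
}

#' Apply a surgical plan: synthesize the follow-up scan
#'
#' Builds the T2 volume and label map: the cranial base moves only by the
#' head pose, each jaw additionally by its advancement, each soft shell by
#' the coupled (scaled + jittered) displacement of its jaw, and the nose by
#' an independent small shift. Per-component ground-truth rigid transforms
#' are returned for recovery tests. A null plan (no advancement, identity
#' pose, no jitter) with `seed = NULL` returns the inputs unchanged.
#'
#' @param volume_t1 baseline `dq_volume` from [make_phantom()].
#' @param labels_t1 baseline `dq_labelmap` from [make_phantom()] (carries the
#'   component geometry).
#' @param plan a [surgical_plan()].
#' @param seed RNG seed for the T2 intensity noise and the soft-tissue
#'   jitters (default: derived from the phantom seed).
#' @return `list(volume, labels, ground_truth)`; `ground_truth` is a tibble
#'   with one row per component: its label, the full T1->T2 rigid transform
#'   (rotation deg / translation mm, centre 0), and the pre-pose displacement
#'   vector `adv_x/adv_y/adv_z` whose magnitude a front-face region measures
#'   after cranial-base re-registration.
#' @export
apply_surgery <- function(volume_t1, labels_t1, plan, seed = NULL) {
  spec <- attr(labels_t1, "phantom_spec")
  if (is.null(spec))
    stop("labels_t1 does not carry phantom geometry; use make_phantom() output")
  if (null_plan(plan) && is.null(seed))
    return(list(volume = volume_t1, labels = labels_t1,
                ground_truth = ground_truth_table(spec, plan,
                                                  soft_jitters(plan, NULL))))
  if (is.null(seed)) seed <- spec$seed + 1L
  geom <- spec$skull_geometry
  units <- vapply(geom, `[[`, "", "unit")
  if (plan$maxilla_advance_mm > 0 && !"maxilla" %in% units)
    stop("plan advances the maxilla but the phantom has no maxilla primitive")
  if (plan$mandible_advance_mm > 0 && !"mandible" %in% units)
    stop("plan advances the mandible but the phantom has no mandible primitive")

  jit <- with_seed(seed, soft_jitters(plan, TRUE))
  gt <- ground_truth_table(spec, plan, jit)
  sp <- spec$spacing_mm
  dm <- spec$grid_shape
  extent <- dm * sp

  lab2 <- array(0L, dm)
  cxs <- list(axis_centers(dm[1], sp), axis_centers(dm[2], sp),
              axis_centers(dm[3], sp))
  for (nm in names(geom)) {
    b <- geom[[nm]]
    tr <- component_transform(nm, spec, plan, jit)
    m <- transform_matrix(tr)
    corners <- as.matrix(expand.grid(c(b$lo[1], b$hi[1]),
                                     c(b$lo[2], b$hi[2]),
                                     c(b$lo[3], b$hi[3])))
    tc <- sweep(corners %*% t(m[1:3, 1:3]), 2, m[1:3, 4], `+`)
    if (any(tc < -sp / 2) || any(sweep(tc, 2, extent - sp / 2, `>`)))
      stop(sprintf("surgery pushes primitive '%s' outside the grid", nm))
    # restrict the inverse mapping to the transformed bounding box
    lo_i <- pmax(floor(apply(tc, 2, min) / sp) - 1, 0) + 1
    hi_i <- pmin(ceiling(apply(tc, 2, max) / sp) + 1, dm - 1) + 1
    idx <- as.matrix(expand.grid(i = lo_i[1]:hi_i[1], j = lo_i[2]:hi_i[2],
                                 k = lo_i[3]:hi_i[3]))
    pts <- cbind(cxs[[1]][idx[, 1]], cxs[[2]][idx[, 2]], cxs[[3]][idx[, 3]])
    mi <- transform_matrix(invert_transform(tr))
    src <- sweep(pts %*% t(mi[1:3, 1:3]), 2, mi[1:3, 4], `+`)
    inside <- src[, 1] >= b$lo[1] & src[, 1] < b$hi[1] &
              src[, 2] >= b$lo[2] & src[, 2] < b$hi[2] &
              src[, 3] >= b$lo[3] & src[, 3] < b$hi[3]
    sel <- idx[inside, , drop = FALSE]
    lab2[cbind(sel[, 1], sel[, 2], sel[, 3])] <- b$label
  }
  trs <- lapply(names(geom), function(nm) component_transform(nm, spec, plan, jit))
  names(trs) <- names(geom)
  vol_arr <- render_intensity(spec, trs)
  if (spec$noise_sd > 0)
    vol_arr <- vol_arr + with_seed(seed + 1L,
                                   array(stats::rnorm(prod(dm), 0, spec$noise_sd), dm))
  labels2 <- new_labelmap(lab2, sp, c(0, 0, 0))
  attr(labels2, "phantom_spec") <- spec
  vol2 <- new_volume(vol_arr, sp, c(0, 0, 0))
  list(volume = vol2, labels = labels2, ground_truth = gt)
}

soft_jitters <- function(plan, draw) {
  if (is.null(draw) || plan$soft_noise_sd_mm == 0) {
    jmax <- jman <- c(0, 0, 0)
  } else {
    jmax <- stats::rnorm(3, 0, plan$soft_noise_sd_mm)
    jman <- stats::rnorm(3, 0, plan$soft_noise_sd_mm)
  }
  nose <- if (is.null(draw) || plan$nose_shift_sd_mm == 0) 0
          else stats::rnorm(1, 0, plan$nose_shift_sd_mm)
  list(soft_maxilla = jmax, soft_mandible = jman, nose = nose)
}

component_displacement <- function(unit, plan, jit) {
  switch(unit,
    cranial = c(0, 0, 0),
    maxilla = c(0, plan$maxilla_advance_mm, 0),
    mandible = c(0, plan$mandible_advance_mm, 0),
    soft_maxilla = c(0, plan$soft_coupling_maxilla * plan$maxilla_advance_mm, 0) +
      jit$soft_maxilla,
    soft_mandible = c(0, plan$soft_coupling_mandible * plan$mandible_advance_mm, 0) +
      jit$soft_mandible,
    nose = c(0, jit$nose, 0),
    stop(sprintf("unknown component unit '%s'", unit)))
}

component_transform <- function(nm, spec, plan, jit) {
  unit <- spec$skull_geometry[[nm]]$unit
  disp <- component_displacement(unit, plan, jit)
  compose_transforms(plan$head_pose,
                     rigid_transform(translation_mm = disp))
}

ground_truth_table <- function(spec, plan, jit) {
  geom <- spec$skull_geometry
  rows <- lapply(names(geom), function(nm) {
    unit <- geom[[nm]]$unit
    disp <- component_displacement(unit, plan, jit)
    tr <- component_transform(nm, spec, plan, jit)
    tibble::tibble(
      component = nm, label = geom[[nm]]$label,
      rx_deg = tr$rotation_deg[1], ry_deg = tr$rotation_deg[2],
      rz_deg = tr$rotation_deg[3],
      tx_mm = tr$translation_mm[1], ty_mm = tr$translation_mm[2],
      tz_mm = tr$translation_mm[3],
      adv_x = disp[1], adv_y = disp[2], adv_z = disp[3],
      adv_mm = sqrt(sum(disp^2)))
  })
  dplyr::bind_rows(rows)
}

#' Cohort plan distribution
#'
#' Ranges from which [make_cohort()] draws each subject's surgical plan.
#' Advancement defaults follow the bimaxillary-advancement study design
#' (maxilla U[1,5] mm, mandible U[5,15] mm); soft-tissue coupling defaults to
#' U[0.8, 1] of the bony change with 0.5 mm per-subject jitter, and the head
#' pose to uniform rotations/translations of up to 2 degrees / 2 mm.
#'
#' @param maxilla_advance,mandible_advance,coupling `c(min, max)` ranges.
#' @param soft_noise_sd,nose_shift_sd scalar sds, mm.
#' @param pose_rot,pose_trans `c(min, max)` ranges (deg / mm) for each of the
#'   six head-pose parameters.
#' @return A list of class `dq_plan_distribution`.
#' @export
plan_distribution <- function(maxilla_advance = c(1, 5),
                              mandible_advance = c(5, 15),
                              coupling = c(0.8, 1.0),
                              soft_noise_sd = 0.5,
                              nose_shift_sd = 0.5,
                              pose_rot = c(-2, 2),
                              pose_trans = c(-2, 2)) {
  rngs <- list(maxilla_advance = maxilla_advance,
               mandible_advance = mandible_advance, coupling = coupling,
               pose_rot = pose_rot, pose_trans = pose_trans)
  for (nm in names(rngs)) {
    r <- rngs[[nm]]
    if (length(r) != 2 || r[1] > r[2])
      stop(sprintf("degenerate range for '%s' (min > max)", nm))
  }
  structure(c(rngs, list(soft_noise_sd = soft_noise_sd,
                         nose_shift_sd = nose_shift_sd)),
            class = "dq_plan_distribution")
}

#' Generate a synthetic cohort
#'
#' Draws `n` independent subjects: per-subject surgical plans from the
#' distribution ranges, a fresh baseline phantom per subject, and the
#' follow-up scan from [apply_surgery()]. Deterministic for a fixed seed.
#'
#' @param n number of subjects (>= 2).
#' @param spec a [phantom_spec()] shared by all subjects.
#' @param dist a [plan_distribution()].
#' @param seed integer cohort seed.
#' @return Object of class `dq_cohort`: `subjects` (each with `id`, `plan`,
#'   `volume_t1`, `labels_t1`, `volume_t2`, `labels_t2`, `ground_truth`) and
#'   a combined `ground_truth` tibble.
#' @export
make_cohort <- function(n, spec = phantom_spec(), dist = plan_distribution(),
                        seed = 42L) {
  if (n < 2) stop("a cohort needs n >= 2 subjects")
  draws <- with_seed(seed, {
    list(seeds = sample.int(.Machine$integer.max %/% 4L, 2 * n),
         u = matrix(stats::runif(9 * n), ncol = 9))
  })
  runi <- function(r, u) r[1] + u * (r[2] - r[1])
  subjects <- vector("list", n)
  for (j in seq_len(n)) {
    u <- draws$u[j, ]
    plan <- surgical_plan(
      maxilla_advance_mm = runi(dist$maxilla_advance, u[1]),
      mandible_advance_mm = runi(dist$mandible_advance, u[2]),
      head_pose = rigid_transform(
        rotation_deg = runi(dist$pose_rot, u[3:5]),
        translation_mm = runi(dist$pose_trans, u[6:8]),
        center_mm = spec$grid_shape * spec$spacing_mm / 2),
      soft_coupling_maxilla = runi(dist$coupling, u[9]),
      soft_coupling_mandible = runi(dist$coupling, u[9]),
      soft_noise_sd_mm = dist$soft_noise_sd,
      nose_shift_sd_mm = dist$nose_shift_sd)
    spec_j <- spec
    spec_j$seed <- draws$seeds[2 * j - 1]
    t1 <- make_phantom(spec_j)
    t2 <- apply_surgery(t1$volume, t1$labels, plan, seed = draws$seeds[2 * j])
    subjects[[j]] <- list(id = sprintf("S%02d", j), plan = plan,
                          volume_t1 = t1$volume, labels_t1 = t1$labels,
                          volume_t2 = t2$volume, labels_t2 = t2$labels,
                          ground_truth = t2$ground_truth)
  }
  gt <- dplyr::bind_rows(lapply(subjects, function(s)
    dplyr::mutate(s$ground_truth, subject = s$id, .before = 1)))
  structure(list(subjects = subjects, ground_truth = gt, spec = spec,
                 dist = dist, seed = seed),
            class = "dq_cohort")
}

#' @export
print.dq_cohort <- function(x, ...) {
  cat(sprintf("<dq_cohort> %d subjects, grid %s @ %.2g mm\n",
              length(x$subjects),
              paste(x$spec$grid_shape, collapse = "x"),
              x$spec$spacing_mm))
  invisible(x)
}

#' Standard phantom measurement areas
#'
#' The fifteen study areas (4 hard, 11 soft) placed on the phantom's anterior
#' faces: maxillary areas on the maxilla and its soft shell plus the nasal
#' tip; mandibular areas on the mandible and its shell. Positions are
#' configuration, not anatomy: each area sits farther from its face's edges
#' than the largest advancement, so its closest-point mean is uncontaminated.
#'
#' @param spec the [phantom_spec()] the areas are placed on (must use the
#'   default skull geometry layout).
#' @return A tibble: `name`, `label`, `seed_x/y/z` (mm), `radius_mm`,
#'   `metric`, `jaw`.
#' @export
phantom_default_regions <- function(spec = phantom_spec()) {
  g <- spec$skull_geometry
  sp <- spec$spacing_mm
  face_y <- function(box) {
    # y of the extracted front face: half a voxel beyond the last included
    # voxel-centre plane
    kmax <- max(which(axis_centers(1e4, sp) < box$hi[2] - 1e-9))
    (kmax - 1) * sp + sp / 2
  }
  fy_max <- face_y(g$maxilla); fy_man <- face_y(g$mandible)
  fy_smax <- face_y(g$soft_maxilla); fy_sman <- face_y(g$soft_mandible)
  fy_nose <- face_y(g$nose)
  t <- tibble::tribble(
    ~name, ~label, ~seed_x, ~seed_y, ~seed_z, ~radius_mm, ~jaw,
    "Nasal Tip",           "soft_tissue",          32, fy_nose, 75.25, 1.5, "maxillary",
    "Soft A Point",        "soft_tissue",          33, fy_smax, 62,    1.5, "maxillary",
    "A Point",             "maxilla_upper_teeth",  40, fy_max,  62,    2.5, "maxillary",
    "Upper Lip",           "soft_tissue",          29, fy_smax, 62,    1.5, "maxillary",
    "Upper Incisors",      "maxilla_upper_teeth",  24, fy_max,  62,    2.5, "maxillary",
    "Left Cheilion",       "soft_tissue",          21, fy_smax, 62,    1.5, "maxillary",
    "Right Cheilion",      "soft_tissue",          41, fy_smax, 62,    1.5, "maxillary",
    "Left Supra Cheilion", "soft_tissue",          25, fy_smax, 62,    1.5, "maxillary",
    "Right Supra Cheilion","soft_tissue",          37, fy_smax, 62,    1.5, "maxillary",
    "Left Sub Cheilion",   "soft_tissue",          29, fy_sman, 30.5,  1.2, "mandibular",
    "Right Sub Cheilion",  "soft_tissue",          35, fy_sman, 29.5,  1.2, "mandibular",
    "Lower Lip",           "soft_tissue",          33, fy_sman, 30.5,  1.2, "mandibular",
    "Lower Incisors",      "mandible_lower_teeth", 34, fy_man,  30,    1.5, "mandibular",
    "Soft Pogonion",       "soft_tissue",          31, fy_sman, 29.5,  1.2, "mandibular",
    "Pogonion",            "mandible_lower_teeth", 31, fy_man,  30,    1.5, "mandibular"
  )
  t$metric <- "euclidean"
  t
}

#' Area name sets for the correlation analysis
#'
#' The maxillary set (nine areas) and mandibular set (six areas) the
#' hard-soft correlation matrices are computed over.
#'
#' @param set `"maxillary"` or `"mandibular"`.
#' @return Character vector of area names.
#' @export
area_set <- function(set = c("maxillary", "mandibular")) {
  set <- match.arg(set)
  if (set == "maxillary")
    c("Nasal Tip", "Soft A Point", "A Point", "Upper Lip", "Upper Incisors",
      "Left Cheilion", "Right Cheilion", "Left Supra Cheilion",
      "Right Supra Cheilion")
  else
    c("Left Sub Cheilion", "Right Sub Cheilion", "Lower Lip",
      "Lower Incisors", "Soft Pogonion", "Pogonion")
}
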