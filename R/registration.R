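#' Resample a volume to a new isotropic spacing
#'
#' Emulates the reformatting of scans to a common voxel size (e.g. 0.4 mm
#' acquisitions resampled to 0.5 mm) before superimposition. The world-space
#' extent is preserved to within one voxel; trilinear interpolation is convex,
#' so the scalar range never expands. Resampling to the current spacing
#' returns the identical grid.
#'
#' @param vol a `dq_volume` (or `dq_labelmap`, which forces nearest).
#' @param new_spacing_mm target isotropic voxel size, mm.
#' @param interpolation `"trilinear"` (intensities) or `"nearest"` (labels).
#' @return A `dq_volume` (or `dq_labelmap`) on the new grid.
#' @export
resample <- function(vol, new_spacing_mm,
                     interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (!is.numeric(new_spacing_mm) || length(new_spacing_mm) != 1 ||
      !is.finite(new_spacing_mm) || new_spacing_mm <= 0)
    stop("new_spacing_mm must be a positive scalar")
  is_lab <- inherits(vol, "dq_labelmap")
  if (is_lab) interpolation <- "nearest"
  dm <- dim(vol$data)
  extent <- dm * vol$spacing_mm
  new_dm <- pmax(1L, as.integer(ceiling(extent / new_spacing_mm - 1e-9)))
  if (isTRUE(all.equal(rep_len(new_spacing_mm, 3), vol$spacing_mm)))
    return(vol)
  idx <- as.matrix(expand.grid(i = seq_len(new_dm[1]), j = seq_len(new_dm[2]),
                               k = seq_len(new_dm[3])))
  pts <- sweep(sweep(idx - 1, 2, rep(new_spacing_mm, 3), `*`),
               2, vol$origin_mm, `+`)
  vals <- cpp_sample_volume(as.numeric(vol$data), dm, vol$spacing_mm,
                            vol$origin_mm, pts,
                            if (interpolation == "nearest") 0L else 1L)
  vals[is.na(vals)] <- 0
  if (is_lab) {
    new_labelmap(array(as.integer(vals), new_dm), rep(new_spacing_mm, 3),
                 vol$origin_mm, vol$label_names)
  } else {
    new_volume(array(vals, new_dm), rep(new_spacing_mm, 3), vol$origin_mm)
  }
}

bin_index <- function(x, lo, hi, bins) {
  # 0-based hard bin index over [lo, hi]
  if (hi <= lo) return(integer(length(x)))
  i <- floor((x - lo) / (hi - lo) * bins)
  as.integer(pmin(pmax(i, 0), bins - 1))
}

mi_from_joint <- function(h) {
  n <- sum(h)
  p <- h / n
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  hxy <- -sum(p[nz] * log2(p[nz]))
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hy <- -sum(py[py > 0] * log2(py[py > 0]))
  hx + hy - hxy
}

#' Mutual information between two volumes over a mask
#'
#' Shannon mutual information (bits) of the joint intensity histogram of two
#' volumes on the same grid, restricted to a voxel mask. Hard binning over
#' each image's own range within the mask, so the score is exactly symmetric
#' in its two arguments; `mutual_information(a, a)` equals the histogram
#' entropy of `a`.
#'
#' @param a,b `dq_volume`s on the same grid.
#' @param mask logical array on the same grid (or a `dq_labelmap` plus
#'   `label` to select).
#' @param bins histogram bins per image (default 32).
#' @param label optional label name/code when `mask` is a label map.
#' @return Mutual information in bits (non-negative scalar).
#' @export
mutual_information <- function(a, b, mask, bins = 32, label = NULL) {
  if (!same_grid(a, b)) stop("volumes must share one grid")
  if (inherits(mask, "dq_labelmap")) {
    if (is.null(label)) stop("give `label` when mask is a label map")
    mask <- label_mask(mask, label)
  }
  sel <- which(as.logical(mask))
  if (length(sel) == 0) stop("mask is empty")
  xa <- as.numeric(a$data)[sel]
  xb <- as.numeric(b$data)[sel]
  ia <- bin_index(xa, min(xa), max(xa), bins)
  ib <- bin_index(xb, min(xb), max(xb), bins)
  h <- matrix(cpp_joint_hist(ia, ib, as.integer(bins)), bins, bins)
  mi_from_joint(h)
}

#' Registration settings
#'
#' Tuning knobs for [register_rigid()]: histogram bins, the coarse-to-fine
#' mask subsampling schedule (strides in voxels), per-stage Nelder-Mead
#' iteration caps, and the initial simplex scale (mm / degrees).
#'
#' @param bins joint histogram bins per image.
#' @param strides mask subsampling stride per pyramid stage (coarse to fine).
#' @param maxit Nelder-Mead iteration cap per stage.
#' @param step initial simplex step, in mm and degrees, per stage.
#' @param max_points cap on mask voxels used per stage.
#' @param restarts extra restarts if the optimizer reports non-convergence.
#' @param mask_dilate_mm dilation of the mask label, mm. The mask must
#'   straddle the tissue boundary: inside solid bone the fixed intensities
#'   are featureless, so the alignment signal lives at the bone/air edge.
#' @return A list of class `dq_reg_control`.
#' @export
reg_control <- function(bins = 32, strides = c(4L, 1L),
                        maxit = c(2000L, 2000L),
                        step = c(10, 0.5), max_points = 15000L, restarts = 1L,
                        mask_dilate_mm = 3, jitter_seed = 7L) {
  structure(list(bins = as.integer(bins), strides = as.integer(strides),
                 maxit = as.integer(maxit), step = as.numeric(step),
                 max_points = as.integer(max_points),
                 restarts = as.integer(restarts),
                 mask_dilate_mm = as.numeric(mask_dilate_mm),
                 jitter_seed = as.integer(jitter_seed)),
            class = "dq_reg_control")
}

dilate_mask <- function(mask, spacing_mm, dilate_mm) {
  if (dilate_mm <= 0) return(mask)
  r <- ceiling(dilate_mm / min(spacing_mm))
  k <- rep(1, 2 * r + 1)
  arr <- cpp_convolve_axes(array(as.numeric(mask), dim(mask)), dim(mask), k)
  array(arr > 1e-9, dim(mask))
}

#' Rigid registration by mutual information over a cranial-base mask
#'
#' Recovers the six-degree-of-freedom rigid transform that maps the moving
#' (follow-up) volume into the fixed (baseline) frame, maximizing mutual
#' information computed only over the masked voxels of the fixed volume --
#' the voxel-based superimposition restricted to the surgically unaltered
#' cranial base. The fixed volume is always the reference frame.
#'
#' The optimizer is a derivative-free Nelder-Mead simplex run over a
#' coarse-to-fine mask subsampling schedule; the internal objective bins the
#' moving intensities with partial-volume (linear) weights so it varies
#' continuously with pose. Non-convergence triggers a restart and, failing
#' that, is flagged on the result (`attr(,"converged")`), never silently
#' ignored.
#'
#' @param fixed `dq_volume`, the reference (T1) scan.
#' @param moving `dq_volume`, the follow-up (T2) scan.
#' @param mask logical array on the fixed grid, or a `dq_labelmap` with
#'   `label` (default the canonical cranial base).
#' @param control a [reg_control()].
#' @param label label selecting mask voxels when `mask` is a label map.
#' @param init optional `dq_rigid` initial guess (moving -> fixed).
#' @return A `dq_rigid` mapping moving into the fixed frame, with attributes
#'   `mi` (final mutual information, bits), `converged`, and `settings`.
#' @export
register_rigid <- function(fixed, moving, mask, control = reg_control(),
                           label = "cranial_base", init = NULL) {
  if (inherits(mask, "dq_labelmap")) mask <- label_mask(mask, label)
  if (!any(mask)) stop("registration mask covers zero voxels")
  mask <- dilate_mask(mask, fixed$spacing_mm, control$mask_dilate_mm)
  sel <- which(as.logical(mask))
  dm <- dim(fixed$data)
  idx <- arrayInd(sel, dm)
  pts_all <- voxel_to_world(fixed, idx)
  # jitter sample positions off-grid (fixed, deterministic): interpolation
  # then smooths the moving image identically at every pose, removing the
  # grid-aligned mutual-information bias of on-centre sampling
  pts_all <- pts_all + with_seed(control$jitter_seed,
    matrix(stats::runif(length(pts_all), -0.5, 0.5), ncol = 3) %*%
      diag(fixed$spacing_mm))
  fvals_all <- cpp_sample_volume(as.numeric(fixed$data), dm, fixed$spacing_mm,
                                 fixed$origin_mm, pts_all, 1L)
  ok0 <- !is.na(fvals_all)
  pts_all <- pts_all[ok0, , drop = FALSE]
  fvals_all <- fvals_all[ok0]
  center <- colMeans(pts_all)
  bins <- control$bins
  mlo <- min(moving$data); mhi <- max(moving$data)
  mdata <- as.numeric(moving$data)
  mdim <- dim(moving$data)

  # p = (rx, ry, rz, tx, ty, tz) parameterizes fixed -> moving
  neg_mi <- function(p, pts, fbin) {
    tr <- rigid_transform(p[1:3], p[4:6], center)
    src <- apply_transform(pts, tr)
    mv <- cpp_sample_volume(mdata, mdim, moving$spacing_mm, moving$origin_mm,
                            src, 1L)
    ok <- !is.na(mv)
    if (sum(ok) < 50) return(1e6)
    mb <- (mv[ok] - mlo) / (mhi - mlo) * (bins - 1)
    h <- matrix(cpp_joint_hist_pv(fbin[ok], mb, as.integer(bins)), bins, bins)
    -mi_from_joint(h)
  }

  p <- rep(0, 6)
  if (!is.null(init)) {
    mi_ <- invert_transform(init)  # init maps moving->fixed; we fit fixed->moving
    p <- c(mi_$rotation_deg, mi_$translation_mm)  # centre approximation
  }
  conv <- FALSE
  for (stage in seq_along(control$strides)) {
    stride <- control$strides[stage]
    keep <- seq(1, nrow(pts_all), by = stride)
    if (length(keep) > control$max_points)
      keep <- keep[seq(1, length(keep),
                       length.out = control$max_points)]
    pts <- pts_all[keep, , drop = FALSE]
    fv <- fvals_all[keep]
    fbin <- bin_index(fv, min(fv), max(fv), bins)
    reltol <- if (stage == length(control$strides)) 1e-12 else 1e-10
    for (attempt in 0:control$restarts) {
      o <- stats::optim(p, neg_mi, method = "Nelder-Mead",
                        pts = pts, fbin = fbin,
                        control = list(
                          maxit = control$maxit[stage],
                          reltol = reltol,
                          parscale = rep(control$step[stage], 6)))
      p <- o$par
      conv <- o$convergence == 0
      if (conv) break
    }
  }
  best <- rigid_transform(p[1:3], p[4:6], center)
  out <- invert_transform(best)  # moving -> fixed
  keep <- unique(round(seq(1, nrow(pts_all),
                           length.out = min(nrow(pts_all),
                                            control$max_points))))
  fv <- fvals_all[keep]
  attr(out, "mi") <- -neg_mi(p, pts_all[keep, , drop = FALSE],
                             bin_index(fv, min(fv), max(fv), bins))
  attr(out, "converged") <- conv
  attr(out, "settings") <- control
  if (!conv) warning("register_rigid: optimizer did not report convergence")
  out
}
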