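#' Rigid 6-DOF transform
#'
#' A rigid-body transform with the six degrees of freedom used in voxel-based
#' superimposition: rotations (degrees) about the world x, y, z axes applied
#' in that order about `center_mm`, followed by a translation. A point `p`
#' maps to `R (p - c) + c + t`.
#'
#' @param rotation_deg rotations about x, y, z in degrees.
#' @param translation_mm translation vector, mm.
#' @param center_mm rotation centre, mm.
#' @return Object of class `dq_rigid`.
#' @export
rigid_transform <- function(rotation_deg = c(0, 0, 0),
                            translation_mm = c(0, 0, 0),
                            center_mm = c(0, 0, 0)) {
  structure(
    list(rotation_deg = rep_len(as.numeric(rotation_deg), 3),
         translation_mm = rep_len(as.numeric(translation_mm), 3),
         center_mm = rep_len(as.numeric(center_mm), 3)),
    class = "dq_rigid"
  )
}

#' @export
print.dq_rigid <- function(x, ...) {
  cat(sprintf(
    "<dq_rigid> rot (%s) deg, trans (%s) mm, center (%s) mm\n",
    paste(signif(x$rotation_deg, 6), collapse = ", "),
    paste(signif(x$translation_mm, 6), collapse = ", "),
    paste(signif(x$center_mm, 6), collapse = ", ")))
  invisible(x)
}

rot_matrix <- function(rotation_deg) {
  r <- rotation_deg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Homogeneous 4x4 matrix of a rigid transform
#'
#' @param t a `dq_rigid`.
#' @return 4x4 numeric matrix.
#' @export
transform_matrix <- function(t) {
  R <- rot_matrix(t$rotation_deg)
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- t$center_mm - R %*% t$center_mm + t$translation_mm
  m
}

# Euler angles (x, y, z order, R = Rz Ry Rx) from a rotation matrix
euler_from_matrix <- function(R) {
  ry <- asin(max(-1, min(1, -R[3, 1])))
  if (abs(cos(ry)) > 1e-10) {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  } else {  # gimbal lock
    rx <- atan2(-R[2, 3], R[2, 2])
    rz <- 0
  }
  c(rx, ry, rz) * 180 / pi
}

rigid_from_matrix <- function(m) {
  rigid_transform(euler_from_matrix(m[1:3, 1:3]), m[1:3, 4], c(0, 0, 0))
}

#' Compose and invert rigid transforms
#'
#' `compose_transforms(a, b)` returns the transform applying `b` first,
#' then `a`. `invert_transform(t)` returns the inverse; composing a transform
#' with its inverse is the identity to machine precision.
#'
#' @param a,b,t `dq_rigid` objects.
#' @return A `dq_rigid` (centre 0 parameterization).
#' @export
compose_transforms <- function(a, b) {
  rigid_from_matrix(transform_matrix(a) %*% transform_matrix(b))
}

#' @rdname compose_transforms
#' @export
invert_transform <- function(t) {
  m <- transform_matrix(t)
  R <- t(m[1:3, 1:3])
  mi <- diag(4)
  mi[1:3, 1:3] <- R
  mi[1:3, 4] <- -R %*% m[1:3, 4]
  rigid_from_matrix(mi)
}

#' Apply a rigid transform
#'
#' Generic over the package's spatial types: an `n x 3` point matrix, a
#' `dq_mesh` (vertices and normals move rigidly), a `dq_volume` (resampled on
#' its own grid with trilinear interpolation) or a `dq_labelmap`
#' (nearest-neighbour interpolation, so labels stay integral).
#'
#' @param x points, mesh, volume or label map.
#' @param t a `dq_rigid`.
#' @param ... passed to methods.
#' @return Same kind of object as `x`.
#' @export
apply_transform <- function(x, t, ...) UseMethod("apply_transform")

#' @export
apply_transform.default <- function(x, t, ...) {
  pts <- as.matrix(x)
  stopifnot(ncol(pts) == 3)
  m <- transform_matrix(t)
  out <- pts %*% t(m[1:3, 1:3])
  sweep(out, 2, m[1:3, 4], `+`)
}

#' @export
apply_transform.dq_mesh <- function(x, t, ...) {
  m <- transform_matrix(t)
  x$vertices <- sweep(x$vertices %*% t(m[1:3, 1:3]), 2, m[1:3, 4], `+`)
  if (!is.null(x$normals)) x$normals <- x$normals %*% t(m[1:3, 1:3])
  attr(x, "checksum") <- mesh_checksum(x)
  x
}

#' @export
apply_transform.dq_volume <- function(x, t, ..., interpolation = "trilinear") {
  # pull-back: sample the input at T^{-1}(voxel centre)
  meth <- match.arg(interpolation, c("trilinear", "nearest"))
  dm <- dim(x$data)
  idx <- as.matrix(expand.grid(i = seq_len(dm[1]), j = seq_len(dm[2]),
                               k = seq_len(dm[3])))
  pts <- voxel_to_world(x, idx)
  src <- apply_transform(pts, invert_transform(t))
  vals <- cpp_sample_volume(as.numeric(x$data), dim(x$data), x$spacing_mm,
                            x$origin_mm, src, if (meth == "nearest") 0L else 1L)
  vals[is.na(vals)] <- 0
  x$data <- array(vals, dm)
  x
}

#' @export
apply_transform.dq_labelmap <- function(x, t, ...) {
  dm <- dim(x$data)
  idx <- as.matrix(expand.grid(i = seq_len(dm[1]), j = seq_len(dm[2]),
                               k = seq_len(dm[3])))
  pts <- voxel_to_world(x, idx)
  src <- apply_transform(pts, invert_transform(t))
  vals <- cpp_sample_volume(as.numeric(x$data), dim(x$data), x$spacing_mm,
                            x$origin_mm, src, 0L)
  vals[is.na(vals)] <- 0
  x$data <- array(as.integer(vals), dm)
  x
}

#' Serialize transforms as JSON
#'
#' Angles in degrees, translations in mm, rotation centre stated.
#'
#' @param t a `dq_rigid`.
#' @param path output path.
#' @export
write_transform <- function(t, path) {
  jsonlite::write_json(
    list(rotation_deg = t$rotation_deg, translation_mm = t$translation_mm,
         center_mm = t$center_mm, units = "mm/deg"),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(j$rotation_deg, j$translation_mm, j$center_mm)
}
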