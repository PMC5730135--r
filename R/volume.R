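#' 3D scalar volume
#'
#' A minimal container for a 3D scalar grid in world millimetre coordinates:
#' a numeric array plus isotropic-or-not voxel spacing and the world position
#' of voxel `(1,1,1)`'s centre. Axis orientation is the identity (right-handed
#' world mm); every volume, label map and mesh in this package shares that one
#' frame, so there are no per-stage convention flips.
#'
#' @param data 3D numeric array.
#' @param spacing_mm voxel size per axis, mm; scalar is recycled to 3.
#' @param origin_mm world position (mm) of the centre of voxel `(1,1,1)`.
#' @return An object of class `dq_volume`.
#' @export
new_volume <- function(data, spacing_mm = 0.5, origin_mm = c(0, 0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3)
  if (any(spacing_mm <= 0)) stop("spacing_mm must be positive")
  origin_mm <- rep_len(as.numeric(origin_mm), 3)
  structure(
    list(data = data, spacing_mm = spacing_mm, origin_mm = origin_mm),
    class = "dq_volume"
  )
}

#' Integer label map
#'
#' A [new_volume()] grid whose voxels carry anatomical labels. The canonical
#' labelling separates the maxilla (with upper teeth), mandible (with lower
#' teeth), soft tissue and cranial base, so that closest-point searches can be
#' restricted to one anatomical structure (the "label firewall").
#'
#' @param data 3D integer array of label codes (0 = background).
#' @param spacing_mm,origin_mm as in [new_volume()].
#' @param label_names named integer vector mapping names to codes.
#' @return An object of class `dq_labelmap` (inherits `dq_volume`).
#' @export
new_labelmap <- function(data, spacing_mm = 0.5, origin_mm = c(0, 0, 0),
                         label_names = default_labels()) {
  v <- new_volume(data, spacing_mm, origin_mm)
  if (any(data < 0)) stop("labels must be non-negative integers")
  if (is.null(names(label_names)) || any(!nzchar(names(label_names))))
    stop("label_names must be a named integer vector")
  v$label_names <- label_names
  class(v) <- c("dq_labelmap", "dq_volume")
  v
}

#' Canonical label table
#'
#' @return Named integer vector with the four canonical labels.
#' @export
default_labels <- function() {
  c(maxilla_upper_teeth = 1L, mandible_lower_teeth = 2L,
    soft_tissue = 3L, cranial_base = 4L)
}

#' @export
print.dq_volume <- function(x, ...) {
  cat(sprintf("<dq_volume> %s voxels @ %s mm, origin (%s) mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing_mm, 4), collapse = "x"),
              paste(signif(x$origin_mm, 4), collapse = ", ")))
  invisible(x)
}

#' @export
print.dq_labelmap <- function(x, ...) {
  cat(sprintf("<dq_labelmap> %s voxels @ %s mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing_mm, 4), collapse = "x")))
  cnt <- table(x$data[x$data > 0])
  for (nm in names(x$label_names)) {
    code <- x$label_names[[nm]]
    n <- if (as.character(code) %in% names(cnt)) cnt[[as.character(code)]] else 0L
    cat(sprintf("  %-22s %d: %d voxels\n", nm, code, n))
  }
  invisible(x)
}

label_code <- function(labels, label) {
  if (is.numeric(label)) return(as.integer(label))
  if (!label %in% names(labels$label_names))
    stop(sprintf("unknown label '%s'", label))
  labels$label_names[[label]]
}

#' World coordinates of voxel centres
#'
#' @param vol a `dq_volume`.
#' @param idx n x 3 matrix of 1-based voxel indices (default: all voxels).
#' @return n x 3 matrix of world mm coordinates.
#' @export
voxel_to_world <- function(vol, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  sweep(sweep(idx - 1, 2, vol$spacing_mm, `*`), 2, vol$origin_mm, `+`)
}

#' Read / write volumes as NIfTI
#'
#' Thin wrappers over RNifti preserving spacing and origin. Label maps are
#' written as integer volumes; `read_labelmap()` restores the canonical label
#' names.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume()` a `dq_volume`; `read_labelmap()` a `dq_labelmap`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  pd <- attr(img, "pixdim")
  if (is.null(pd)) pd <- RNifti::pixdim(img)
  xf <- RNifti::xform(img)
  origin <- as.numeric(xf[1:3, 4])
  # our frame is RAS-agnostic identity; take absolute spacing
  new_volume(arr, abs(pd[1:3]), origin)
}

#' @rdname read_volume
#' @param vol volume or label map to write.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  xf <- diag(4)
  diag(xf)[1:3] <- vol$spacing_mm
  xf[1:3, 4] <- vol$origin_mm
  img <- RNifti::`sform<-`(img, structure(xf, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_volume
#' @param label_names as in [new_labelmap()].
#' @export
read_labelmap <- function(path, label_names = default_labels()) {
  v <- read_volume(path)
  new_labelmap(array(as.integer(round(v$data)), dim(v$data)),
               v$spacing_mm, v$origin_mm, label_names)
}

#' Logical mask of one label
#'
#' @param labels a `dq_labelmap`.
#' @param label label name or code.
#' @return logical array of the label's voxels.
#' @export
label_mask <- function(labels, label) {
  code <- label_code(labels, label)
  labels$data == code
}

same_grid <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    isTRUE(all.equal(a$spacing_mm, b$spacing_mm)) &&
    isTRUE(all.equal(a$origin_mm, b$origin_mm))
}
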