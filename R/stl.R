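#' Binary STL input/output
#'
#' Little-endian binary STL (80-byte header, uint32 triangle count, per
#' triangle: float32 normal, three float32 vertices, uint16 attribute).
#' STL itself carries no units; this package fixes millimetres and records
#' provenance (label, vertex/triangle counts, geometry checksum) in an
#' optional JSON sidecar next to the file.
#'
#' Writing stores the mesh as a triangle soup (the format has no shared
#' vertices); reading welds exactly coincident vertices back together, so a
#' round trip preserves triangle count exactly and vertex coordinates to
#' float32 precision.
#'
#' @param mesh a `dq_mesh` with at least one triangle.
#' @param path output `.stl` path.
#' @param sidecar write `<path>.json` provenance metadata (default TRUE).
#' @return `write_stl()` the path, invisibly; `read_stl()` a `dq_mesh`.
#' @export
write_stl <- function(mesh, path, sidecar = TRUE) {
  if (nrow(mesh$faces) == 0) stop("refusing to write a zero-triangle mesh")
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", "dispquant binary STL (mm)"))[1:80]
  writeBin(header, con)
  nf <- nrow(mesh$faces)
  writeBin(as.integer(nf), con, size = 4, endian = "little")
  fn <- face_normals(mesh)
  len <- sqrt(rowSums(fn^2)); len[len == 0] <- 1
  fn <- fn / len
  v <- mesh$vertices; f <- mesh$faces
  # 12 floats + attribute per triangle, written in one block for speed
  block <- matrix(0, 12, nf)
  block[1:3, ] <- t(fn)
  block[4:6, ] <- t(v[f[, 1], , drop = FALSE])
  block[7:9, ] <- t(v[f[, 2], , drop = FALSE])
  block[10:12, ] <- t(v[f[, 3], , drop = FALSE])
  raw_f <- writeBin(as.numeric(block), raw(), size = 4, endian = "little")
  raw_f <- matrix(raw_f, nrow = 48)
  attr_raw <- matrix(as.raw(0), nrow = 2, ncol = nf)
  writeBin(as.vector(rbind(raw_f, attr_raw)), con)
  if (sidecar) {
    jsonlite::write_json(
      list(format = "binary STL", units = "mm", label = mesh$label,
           n_vertices = nrow(mesh$vertices), n_triangles = nf,
           checksum = attr(mesh, "checksum")),
      paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_stl
#' @param label label to attach to the mesh read (default: from the sidecar
#'   if present, else `"unlabelled"`).
#' @export
read_stl <- function(path, label = NULL) {
  size <- file.info(path)$size
  if (is.na(size) || size < 84)
    stop(sprintf("malformed STL '%s': file shorter than 84-byte preamble",
                 path))
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80))
  nf <- readBin(con, "integer", 1, size = 4, endian = "little")
  expected <- 84 + nf * 50
  if (size != expected)
    stop(sprintf(
      "malformed STL '%s': %d triangles imply %d bytes, file has %d (offset 80)",
      path, nf, expected, size))
  body <- readBin(con, "raw", nf * 50)
  body <- matrix(body, nrow = 50)
  floats <- readBin(as.vector(body[1:48, ]), "numeric", n = 12 * nf,
                    size = 4, endian = "little")
  floats <- matrix(floats, nrow = 12)
  # rows of soup: tri1 corner1..3, tri2 corner1..3, ...
  soup <- t(matrix(floats[4:12, ], nrow = 3))
  key <- paste(soup[, 1], soup[, 2], soup[, 3], sep = "|")
  uid <- match(key, key[!duplicated(key)])
  verts <- soup[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid, ncol = 3, byrow = TRUE)
  if (is.null(label)) {
    sc <- paste0(path, ".json")
    label <- if (file.exists(sc)) {
      meta <- jsonlite::read_json(sc)
      if (!is.null(meta$label)) meta$label else "unlabelled"
    } else "unlabelled"
  }
  new_mesh(verts, faces, label = label)
}
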