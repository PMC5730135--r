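#' Painted surface region
#'
#' A named subset of one mesh's vertices — the "surface paint area" over
#' which displacement statistics are averaged. A region is bound to the exact
#' mesh it was painted on through the mesh checksum, and carries the mesh's
#' anatomical label so that cross-label measurements are refused by
#' construction.
#'
#' @param mesh the `dq_mesh` the region lives on.
#' @param vertex_ids integer vertex indices of the member vertices.
#' @param name region name (e.g. one of the fifteen study areas, or any
#'   user-defined name).
#' @param definition free-form description of how the region was defined.
#' @return Object of class `dq_region`.
#' @export
region_from_vertices <- function(mesh, vertex_ids, name = "region",
                                 definition = list(type = "explicit")) {
  vertex_ids <- sort(unique(as.integer(vertex_ids)))
  if (length(vertex_ids) == 0) stop("region is empty")
  if (min(vertex_ids) < 1 || max(vertex_ids) > nrow(mesh$vertices))
    stop("vertex ids outside the mesh")
  structure(
    list(name = name, label = mesh$label, vertex_ids = vertex_ids,
         definition = definition, mesh_checksum = attr(mesh, "checksum")),
    class = "dq_region"
  )
}

#' @export
print.dq_region <- function(x, ...) {
  cat(sprintf("<dq_region> '%s' on label '%s': %d vertices\n",
              x$name, x$label, length(x$vertex_ids)))
  invisible(x)
}

#' Paint a region around a seed point
#'
#' Emulates the operator's surface-paint tool: the region is every vertex
#' within `radius_mm` of the vertex nearest the seed, under the Euclidean or
#' geodesic (shortest edge-path) metric. The seed must lie within 2 mm of the
#' surface. `radius_mm = 0` selects exactly the nearest vertex; a radius at
#' least the mesh diameter selects the seed's whole connected component
#' (under the geodesic metric).
#'
#' @param mesh a `dq_mesh`.
#' @param seed_point length-3 world point, mm.
#' @param radius_mm paint radius, mm (>= 0).
#' @param metric `"euclidean"` or `"geodesic"`.
#' @param name region name.
#' @return A `dq_region`.
#' @export
paint_region <- function(mesh, seed_point, radius_mm,
                         metric = c("euclidean", "geodesic"),
                         name = "region") {
  metric <- match.arg(metric)
  if (radius_mm < 0) stop("radius_mm must be >= 0")
  seed_point <- as.numeric(seed_point)
  d2 <- colSums((t(mesh$vertices) - seed_point)^2)
  seed_v <- which.min(d2)
  if (sqrt(d2[seed_v]) > 2)
    stop(sprintf("seed point is %.2f mm from the surface (limit 2 mm)",
                 sqrt(d2[seed_v])))
  if (metric == "euclidean") {
    dd <- sqrt(colSums((t(mesh$vertices) - mesh$vertices[seed_v, ])^2))
  } else {
    g <- mesh_graph(mesh)
    dd <- as.numeric(igraph::distances(g, v = seed_v))
  }
  ids <- which(dd <= radius_mm + 1e-12)
  if (length(ids) == 0) stop("paint produced an empty region")
  region_from_vertices(
    mesh, ids, name = name,
    definition = list(type = "paint", seed_point = seed_point,
                      radius_mm = radius_mm, metric = metric))
}

check_region_binding <- function(region, source_mesh) {
  if (!identical(region$mesh_checksum, attr(source_mesh, "checksum")))
    stop("region checksum does not match the source mesh; repaint the region")
}

#' Serialize regions as JSON
#'
#' @param region a `dq_region`.
#' @param path file path.
#' @export
write_region <- function(region, path) {
  jsonlite::write_json(unclass(region), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_region
#' @export
read_region <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(name = j$name, label = j$label,
                 vertex_ids = as.integer(j$vertex_ids),
                 definition = as.list(j$definition),
                 mesh_checksum = j$mesh_checksum),
            class = "dq_region")
}
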