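#' Triangular surface mesh
#'
#' Container for a triangulated head surface in millimeter coordinates.
#' All landmark constructions (ray intersections, plane-cut contours,
#' 10-20 layouts) operate on this class.
#'
#' @param vertices Numeric `n x 3` matrix of vertex coordinates (mm).
#' @param faces Integer `m x 3` matrix of 1-based vertex indices.
#'
#' @details Faces must reference valid vertices, use three distinct indices,
#'   and have nonzero area (relative to the squared maximum edge length).
#'   Meshes need not be watertight.
#'
#' @return An object of class `tri_mesh` with elements `vertices` and `faces`.
#' @export
#' @examples
#' m <- sphere_mesh(radius = 1, refinement = 2)
#' mesh_area(m)
tri_mesh <- function(vertices, faces) {
  vertices <- as_points_matrix(vertices, "vertices")
  faces <- as.matrix(faces)
  if (ncol(faces) != 3L) stop("faces must be an m x 3 index matrix", call. = FALSE)
  storage.mode(faces) <- "integer"
  if (nrow(vertices) < 3L || nrow(faces) < 1L) {
    stop("mesh must contain at least 3 vertices and 1 face", call. = FALSE)
  }
  if (anyNA(faces) || min(faces) < 1L || max(faces) > nrow(vertices)) {
    bad <- which(is.na(faces) | faces < 1L | faces > nrow(vertices),
                 arr.ind = TRUE)[1L, 1L]
    stop(sprintf("face %d references a vertex outside [1, %d]",
                 bad, nrow(vertices)), call. = FALSE)
  }
  if (any(faces[, 1L] == faces[, 2L] | faces[, 2L] == faces[, 3L] |
            faces[, 1L] == faces[, 3L])) {
    stop("degenerate face: repeated vertex index", call. = FALSE)
  }
  a <- vertices[faces[, 2L], , drop = FALSE] - vertices[faces[, 1L], , drop = FALSE]
  b <- vertices[faces[, 3L], , drop = FALSE] - vertices[faces[, 1L], , drop = FALSE]
  cr <- cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
              a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
              a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
  area2 <- sqrt(rowSums(cr^2))
  scale2 <- max(rowSums(a^2), rowSums(b^2))
  if (any(area2 <= 1e-12 * scale2)) {
    stop("degenerate face: zero area above tolerance", call. = FALSE)
  }
  structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Mesh summary geometry
#'
#' `mesh_area()` returns the total surface area; `mesh_edge_lengths()` the
#' lengths of all unique edges; `mesh_bbox_diag()` the bounding-box diagonal,
#' used as the package's internal length scale for tolerances.
#'
#' @param mesh A [tri_mesh()].
#' @return A numeric scalar (`mesh_area`, `mesh_bbox_diag`) or vector
#'   (`mesh_edge_lengths`).
#' @export
mesh_area <- function(mesh) {
  stopifnot(inherits(mesh, "tri_mesh"))
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  b <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  cr <- cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
              a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
              a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' @rdname mesh_area
#' @export
mesh_edge_lengths <- function(mesh) {
  stopifnot(inherits(mesh, "tri_mesh"))
  f <- mesh$faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(1L, 3L)])
  e <- unique(cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L])))
  d <- mesh$vertices[e[, 1L], , drop = FALSE] - mesh$vertices[e[, 2L], , drop = FALSE]
  sqrt(rowSums(d^2))
}

#' @rdname mesh_area
#' @export
mesh_bbox_diag <- function(mesh) {
  stopifnot(inherits(mesh, "tri_mesh"))
  rng <- apply(mesh$vertices, 2L, range)
  vnorm(rng[2L, ] - rng[1L, ])
}

#' Apply an affine transform to a mesh
#'
#' @param mesh A [tri_mesh()].
#' @param transform An [affine_transform()].
#' @return A new `tri_mesh` with transformed vertices; connectivity unchanged.
#' @export
transform_mesh <- function(mesh, transform) {
  stopifnot(inherits(mesh, "tri_mesh"))
  tri_mesh(map_points(transform, mesh$vertices), mesh$faces)
}
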