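#' Subdivided sphere and ellipsoid meshes
#'
#' Analytic test substrates for the landmark constructions.  `sphere_mesh()`
#' builds a geodesic sphere by repeated 4-way subdivision of a regular
#' octahedron with re-projection to the sphere; `ellipsoid_mesh()` scales it
#' anisotropically.  The octahedral base is deliberate: the six axis points
#' `(±r,0,0)`, `(0,±r,0)`, `(0,0,±r)` are exact mesh vertices at every
#' refinement level, so canonical cranial fiducials placed there lie exactly
#' on the surface.
#'
#' @param radius Sphere radius (mm), positive.
#' @param refinement Number of subdivision rounds (>= 2).  Each round splits
#'   every triangle into four; refinement `k` yields `8 * 4^k` faces.
#' @param semiaxes Numeric length-3 vector `(a, b, c)` of ellipsoid semi-axes
#'   (mm), all positive.
#' @return A [tri_mesh()].
#' @export
#' @examples
#' s <- sphere_mesh(90, 3)
#' abs(mesh_area(s) - 4 * pi * 90^2) / (4 * pi * 90^2)  # small
sphere_mesh <- function(radius = 1, refinement = 3L) {
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0) {
    stop("radius must be a positive scalar", call. = FALSE)
  }
  refinement <- as.integer(refinement)
  if (is.na(refinement) || refinement < 2L) {
    stop("refinement must be an integer >= 2", call. = FALSE)
  }
  v <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
             c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  f <- rbind(c(1, 3, 5), c(3, 2, 5), c(2, 4, 5), c(4, 1, 5),
             c(3, 1, 6), c(2, 3, 6), c(4, 2, 6), c(1, 4, 6))
  for (round in seq_len(refinement)) {
    nv <- nrow(v)
    edge_mid <- new.env(parent = emptyenv())
    verts <- vector("list", 4L * nrow(f))
    nextv <- nv
    midpoint <- function(i, j) {
      key <- paste0(min(i, j), "_", max(i, j))
      id <- edge_mid[[key]]
      if (is.null(id)) {
        nextv <<- nextv + 1L
        id <- nextv
        m <- (v[i, ] + v[j, ]) / 2
        verts[[id - nv]] <<- m / vnorm(m)
        edge_mid[[key]] <- id
      }
      id
    }
    newf <- matrix(0L, 4L * nrow(f), 3L)
    for (k in seq_len(nrow(f))) {
      i1 <- f[k, 1L]; i2 <- f[k, 2L]; i3 <- f[k, 3L]
      m12 <- midpoint(i1, i2); m23 <- midpoint(i2, i3); m13 <- midpoint(i1, i3)
      newf[4L * k - 3L, ] <- c(i1, m12, m13)
      newf[4L * k - 2L, ] <- c(i2, m23, m12)
      newf[4L * k - 1L, ] <- c(i3, m13, m23)
      newf[4L * k, ] <- c(m12, m23, m13)
    }
    v <- rbind(v, do.call(rbind, verts[seq_len(nextv - nv)]))
    f <- newf
  }
  tri_mesh(v * radius, f)
}

#' @rdname sphere_mesh
#' @export
ellipsoid_mesh <- function(semiaxes, refinement = 3L) {
  semiaxes <- as_point3(semiaxes, "semiaxes")
  if (any(semiaxes <= 0)) stop("semiaxes must all be positive", call. = FALSE)
  unit <- sphere_mesh(1, refinement)
  tri_mesh(sweep(unit$vertices, 2L, semiaxes, "*"), unit$faces)
}
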