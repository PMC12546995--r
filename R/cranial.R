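#' Estimate the inion (Iz) from Nz, LPA and RPA
#'
#' Under the assumption that Nz, LPA, RPA and Iz lie on a common plane, the
#' inion is found as the far intersection of the head surface with the ray
#' from Nz through the midpoint of LPA and RPA.  The far hit is taken because
#' the ray first leaves the surface near Nz and exits again at the back of
#' the head; the returned point is coplanar with Nz/LPA/RPA by construction.
#'
#' @param mesh Head surface [tri_mesh()] (mm).
#' @param Nz,LPA,RPA Cranial points in the head-mm frame.
#' @return The Iz position as a 3-vector.
#' @export
estimate_iz <- function(mesh, Nz, LPA, RPA) {
  Nz <- as_point3(Nz, "Nz"); LPA <- as_point3(LPA, "LPA"); RPA <- as_point3(RPA, "RPA")
  mid <- (LPA + RPA) / 2
  dir <- mid - Nz
  if (vnorm(dir) <= 1e-12 * max(1, vnorm(Nz))) {
    stop("Nz coincides with the LPA/RPA midpoint: ray direction undefined",
         call. = FALSE)
  }
  ray_mesh_intersect(mesh, Nz, dir, select = "farthest")
}

#' Estimate the vertex (Cz) from the four planar fiducials
#'
#' Casts a ray from the LPA/RPA midpoint along the normal of the
#' Nz/Iz/LPA/RPA plane, oriented toward the top of the head, and returns the
#' far intersection with the scalp.  The superior direction is taken as the
#' cross product of (Iz - Nz) and (RPA - LPA) (the published construction
#' speaks of an "inner product" of these two vectors, but a scalar cannot
#' orient a ray; the cross product is the only product of the two vectors
#' yielding the superior axis, and is what this function uses).  If that
#' orientation does not intersect, its negation is tried; when both hit, the
#' intersection farther from the fiducial plane wins.
#'
#' @param mesh Head surface [tri_mesh()] (mm).
#' @param Nz,Iz,LPA,RPA Cranial points in the head-mm frame.
#' @param origin Ray origin: `"lpa-rpa-midpoint"` (default) or
#'   `"nz-iz-midpoint"`; the construction does not pin this down, so it is
#'   configurable.
#' @return The Cz position as a 3-vector.
#' @export
estimate_cz <- function(mesh, Nz, Iz, LPA, RPA,
                        origin = c("lpa-rpa-midpoint", "nz-iz-midpoint")) {
  origin <- match.arg(origin)
  Nz <- as_point3(Nz, "Nz"); Iz <- as_point3(Iz, "Iz")
  LPA <- as_point3(LPA, "LPA"); RPA <- as_point3(RPA, "RPA")
  ap <- Iz - Nz
  lr <- RPA - LPA
  scale <- max(vnorm(ap), vnorm(lr))
  if (vnorm(ap) <= 1e-12 * max(1, scale) || vnorm(lr) <= 1e-12 * max(1, scale)) {
    stop("degenerate fiducials: Nz==Iz or LPA==RPA", call. = FALSE)
  }
  up <- cross3(ap, lr)
  if (vnorm(up) <= 1e-9 * vnorm(ap) * vnorm(lr)) {
    stop("Nz->Iz and LPA->RPA are parallel: plane normal undefined",
         call. = FALSE)
  }
  up <- up / vnorm(up)
  o <- if (origin == "lpa-rpa-midpoint") (LPA + RPA) / 2 else (Nz + Iz) / 2
  hit_for <- function(d) {
    tryCatch(ray_mesh_intersect(mesh, o, d, select = "farthest"),
             error = function(e) NULL)
  }
  h1 <- hit_for(up)
  h2 <- hit_for(-up)
  if (is.null(h1) && is.null(h2)) {
    stop("vertex ray misses the head surface in both orientations", call. = FALSE)
  }
  plane_dist <- function(p) abs(sum((p - o) * up))
  if (is.null(h2) || (!is.null(h1) && plane_dist(h1) >= plane_dist(h2))) h1 else h2
}

#' Build the five-point cranial reference set
#'
#' Constructs a complete [cranial_landmarks()] set from Nz, LPA and RPA.  In
#' `"three-point"` mode, Iz and Cz are derived geometrically
#' ([estimate_iz()], [estimate_cz()]); in `"five-point"` mode, supplied
#' overrides are used verbatim (and any missing one is constructed).
#'
#' @param mesh Head surface [tri_mesh()] (mm).
#' @param Nz,LPA,RPA Cranial points in the head-mm frame.
#' @param method `"three-point"` or `"five-point"`.
#' @param Iz_override,Cz_override Optional 3-vectors used verbatim in
#'   five-point mode; they must lie within `on_mesh_tol` (mm) of the surface.
#' @param on_mesh_tol Tolerance for the override on-surface check, mm
#'   (default 1).
#' @return A [cranial_landmarks()] in the head-mm frame.
#' @export
build_cranial_set <- function(mesh, Nz, LPA, RPA,
                              method = c("three-point", "five-point"),
                              Iz_override = NULL, Cz_override = NULL,
                              on_mesh_tol = 1) {
  method <- match.arg(method)
  Nz <- as_point3(Nz, "Nz"); LPA <- as_point3(LPA, "LPA"); RPA <- as_point3(RPA, "RPA")
  check_on_mesh <- function(p, nm) {
    d <- point_mesh_distance(mesh, p)
    if (d > on_mesh_tol) {
      stop(sprintf("%s override lies %.3g mm from the surface (tolerance %.3g)",
                   nm, d, on_mesh_tol), call. = FALSE)
    }
    p
  }
  if (method == "three-point") {
    Iz <- estimate_iz(mesh, Nz, LPA, RPA)
    Cz <- estimate_cz(mesh, Nz, Iz, LPA, RPA)
  } else {
    Iz <- if (is.null(Iz_override)) estimate_iz(mesh, Nz, LPA, RPA) else
      check_on_mesh(as_point3(Iz_override, "Iz_override"), "Iz")
    Cz <- if (is.null(Cz_override)) estimate_cz(mesh, Nz, Iz, LPA, RPA) else
      check_on_mesh(as_point3(Cz_override, "Cz_override"), "Cz")
  }
  cranial_landmarks(list(Nz = Nz, Iz = Iz, LPA = LPA, RPA = RPA, Cz = Cz),
                    frame = "head-mm", method = method)
}

#' Distance from a point to the mesh surface
#'
#' Exact point-to-triangle distance minimized over all faces; used for
#' surface-adherence checks.
#'
#' @param mesh A [tri_mesh()].
#' @param p A 3D point.
#' @return Numeric scalar distance (mm).
#' @export
point_mesh_distance <- function(mesh, p) {
  stopifnot(inherits(mesh, "tri_mesh"))
  p <- as_point3(p)
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  cc <- v[f[, 3L], , drop = FALSE]
  # Ericson-style closest point on triangle, vectorized over faces.
  ab <- b - a; ac <- cc - a
  pm <- matrix(p, nrow(a), 3L, byrow = TRUE)
  ap <- pm - a
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- pm - b
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- pm - cc
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  va <- d3 * d6 - d5 * d4
  vb <- d5 * d2 - d1 * d6
  vc <- d1 * d4 - d3 * d2
  denom <- va + vb + vc
  vpar <- vb / ifelse(denom == 0, 1, denom)
  wpar <- vc / ifelse(denom == 0, 1, denom)
  # Start from interior projection, then clamp to edges/vertices per region.
  q <- a + ab * vpar + ac * wpar
  # Region tests (any failure falls back to edge/vertex candidates below).
  inside <- va >= 0 & vb >= 0 & vc >= 0
  cand2 <- function(p0, edge, pv) {
    tt <- pmin(pmax(rowSums((pm - p0) * edge) /
                      pmax(rowSums(edge^2), .Machine$double.eps), 0), 1)
    p0 + edge * tt
  }
  qab <- cand2(a, ab); qac <- cand2(a, ac); qbc <- cand2(b, cc - b)
  dist2 <- function(qq) rowSums((qq - pm)^2)
  dmin <- pmin(dist2(qab), dist2(qac), dist2(qbc))
  dmin[inside] <- pmin(dmin[inside], dist2(q)[inside])
  sqrt(min(dmin))
}
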