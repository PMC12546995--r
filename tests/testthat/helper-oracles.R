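# Independent oracles used to freeze expected values: closed-form quadric
# intersections, numeric ellipse perimeters, great-circle interpolation, and
# a normal-equations least-squares solver.  These are deliberately written
# against the math, not against the package implementation.

# Closed-form ray/ellipsoid intersection: origin o, unit direction d,
# semi-axes (a, b, c); returns the hit with the largest positive t.
oracle_ellipsoid_ray <- function(o, d, semiaxes, select = "farthest") {
  d <- d / sqrt(sum(d^2))
  inv2 <- 1 / semiaxes^2
  A <- sum(d^2 * inv2)
  B <- 2 * sum(o * d * inv2)
  C <- sum(o^2 * inv2) - 1
  disc <- B^2 - 4 * A * C
  if (disc < 0) return(NULL)
  ts <- (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
  ts <- ts[ts > 1e-9]
  if (!length(ts)) return(NULL)
  t_hit <- if (select == "farthest") max(ts) else min(ts)
  o + d * t_hit
}

# Numeric perimeter of an ellipse with semi-axes (a, b): arc-length
# quadrature at high resolution.
oracle_ellipse_perimeter <- function(a, b, n = 2e5) {
  th <- seq(0, 2 * pi, length.out = n + 1)
  x <- a * cos(th); y <- b * sin(th)
  sum(sqrt(diff(x)^2 + diff(y)^2))
}

# Point at angular fraction f along the unit great-circle arc from u to w
# (both unit vectors), through the minor arc.
oracle_great_circle <- function(u, w, f) {
  u <- u / sqrt(sum(u^2)); w <- w / sqrt(sum(w^2))
  ang <- acos(max(-1, min(1, sum(u * w))))
  perp <- w - sum(u * w) * u
  perp <- perp / sqrt(sum(perp^2))
  cos(f * ang) * u + sin(f * ang) * perp
}

# Per-coordinate normal-equations least squares: the reference semantics of
# the stacked pseudo-inverse solve.
oracle_lsq <- function(x, y) {
  d <- cbind(x, 1)
  solve(t(d) %*% d, t(d) %*% y)
}

# Closed-form unit-sphere positions for the sagittal/coronal/ring labels of
# a layout computed with canonical fiducials Nz=(r,0,0), Iz=(-r,0,0),
# LPA=(0,r,0), RPA=(0,-r,0), Cz=(0,0,r).
oracle_sphere_layout <- function(density = "10-20", radius = 1) {
  cat_tbl <- tentwenty_catalogue(density)
  rc <- cos(0.1 * pi); zc <- sin(0.1 * pi)
  out <- list()
  for (i in seq_len(nrow(cat_tbl))) {
    fr <- cat_tbl$fraction[i]
    p <- switch(cat_tbl$arc[i],
      sagittal = c(cos(fr * pi), 0, sin(fr * pi)),
      coronal = c(0, cos(fr * pi), sin(fr * pi)),
      ring = c(rc * cos(2 * pi * fr), rc * sin(2 * pi * fr), zc),
      NULL)
    if (!is.null(p)) out[[cat_tbl$label[i]]] <- p * radius
  }
  do.call(rbind, out)
}

max_edge <- function(mesh) max(mesh_edge_lengths(mesh))

oracle_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Random well-conditioned affine.
random_affine <- function() {
  repeat {
    A <- matrix(stats::rnorm(9), 3, 3)
    if (abs(det(A)) > 0.2) break
  }
  affine_transform(A, stats::rnorm(3))
}

# Random non-coplanar point cloud.
random_points <- function(n) matrix(stats::rnorm(3 * n), n, 3)

const_frame <- function(val = 0.5) {
  facial_landmarks(matrix(val, 24, 3), "synthetic24")
}

make_truth_map <- function(spec, seed = 42, sd = 0.3) {
  withr::with_seed(seed, {
    targets <- lapply(1:4, function(i) {
      list(A = matrix(stats::rnorm(3 * spec$count * 3, sd = sd),
                      3 * spec$count, 3),
           b = stats::rnorm(3, 0.5, 0.1))
    })
    names(targets) <- c("Iz", "LPA", "RPA", "Cz")
    linear_headmap(targets, spec)
  })
}
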