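# Small internal vector/linear-algebra helpers shared by the geometry code.
# All geometry is right-handed, millimeter units unless stated otherwise.

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vnorm <- function(v) sqrt(sum(v * v))

unitize <- function(v, what = "vector") {
  n <- vnorm(v)
  if (!is.finite(n) || n <= 0) {
    stop(sprintf("%s must have nonzero finite norm", what), call. = FALSE)
  }
  v / n
}

as_point3 <- function(x, what = "point") {
  x <- as.numeric(x)
  if (length(x) != 3L || !all(is.finite(x))) {
    stop(sprintf("%s must be a finite numeric 3-vector", what), call. = FALSE)
  }
  x
}

as_points_matrix <- function(x, what = "points") {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 3L, byrow = TRUE)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3L || !all(is.finite(x))) {
    stop(sprintf("%s must be an n x 3 matrix of finite coordinates", what),
         call. = FALSE)
  }
  x
}

# Least-squares plane through a point cloud: centroid plus the singular vector
# of the smallest singular value of the centered cloud.
fit_plane <- function(pts) {
  pts <- as_points_matrix(pts)
  if (nrow(pts) < 3L) stop("need at least 3 points to fit a plane", call. = FALSE)
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2L, ctr))
  list(point = ctr, normal = sv$v[, 3L], residual = sv$d[3L] / sqrt(nrow(pts)))
}

plane_signed_distance <- function(pts, plane_point, plane_normal) {
  n <- unitize(plane_normal, "plane normal")
  drop(sweep(as_points_matrix(pts), 2L, as_point3(plane_point)) %*% n)
}

rot_z <- function(theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3L, 3L)
}

rot_y <- function(theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3L, 3L)
}

deg2rad <- function(deg) deg * pi / 180
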