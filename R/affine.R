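#' Affine transform in 3D
#'
#' A 3x3 matrix `A` plus translation `b`, applied to points as `A p + b`.
#' Used both for the per-view frame conversion between head-model millimeter
#' coordinates and the normalized camera frame, and for atlas-to-subject
#' registration.
#'
#' @param A Numeric 3x3 matrix.
#' @param b Numeric 3-vector.
#' @return An object of class `affine_transform`.
#' @export
affine_transform <- function(A, b = c(0, 0, 0)) {
  A <- as.matrix(A)
  if (!all(dim(A) == c(3L, 3L)) || !all(is.finite(A))) {
    stop("A must be a finite 3 x 3 matrix", call. = FALSE)
  }
  structure(list(A = A, b = as_point3(b, "b")), class = "affine_transform")
}

#' @rdname affine_transform
#' @export
affine_identity <- function() affine_transform(diag(3), c(0, 0, 0))

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform>\nA =\n")
  print(x$A)
  cat("b =", format(x$b), "\n")
  invisible(x)
}

#' Apply an affine transform to points
#'
#' @param transform An [affine_transform()].
#' @param pts A 3-vector or an `n x 3` matrix of points.
#' @return Points of the same shape as the input, mapped as `A p + b`.
#' @export
map_points <- function(transform, pts) {
  stopifnot(inherits(transform, "affine_transform"))
  if (is.null(dim(pts))) {
    return(drop(transform$A %*% as_point3(pts)) + transform$b)
  }
  pts <- as_points_matrix(pts)
  sweep(pts %*% t(transform$A), 2L, transform$b, "+")
}

#' Compose and invert affine transforms
#'
#' `affine_compose(t1, t2)` returns the transform applying `t2` first and
#' `t1` second; `affine_invert` requires `det(A) != 0`.
#'
#' @param t1,t2,transform [affine_transform()] objects.
#' @return An [affine_transform()].
#' @export
affine_compose <- function(t1, t2) {
  stopifnot(inherits(t1, "affine_transform"), inherits(t2, "affine_transform"))
  affine_transform(t1$A %*% t2$A, drop(t1$A %*% t2$b) + t1$b)
}

#' @rdname affine_compose
#' @export
affine_invert <- function(transform) {
  stopifnot(inherits(transform, "affine_transform"))
  if (abs(det(transform$A)) < .Machine$double.eps * 100) {
    stop("transform is singular and cannot be inverted", call. = FALSE)
  }
  Ainv <- solve(transform$A)
  affine_transform(Ainv, drop(-Ainv %*% transform$b))
}

# Shared least-squares affine fit: minimizes sum ||A src_i + b - dst_i||^2.
# Requires >= 4 correspondences that affinely span 3D (non-coplanar).
fit_affine_lsq <- function(src, dst, what = "correspondences") {
  src <- as_points_matrix(src, "src")
  dst <- as_points_matrix(dst, "dst")
  if (nrow(src) != nrow(dst)) {
    stop("src and dst must have matching lengths", call. = FALSE)
  }
  if (nrow(src) < 4L) {
    stop("need at least 4 point correspondences", call. = FALSE)
  }
  design <- cbind(src, 1)
  qrd <- qr(design)
  if (qrd$rank < 4L) {
    stop(sprintf("rank-deficient %s: source points are coplanar or degenerate",
                 what), call. = FALSE)
  }
  coef <- qr.coef(qrd, dst)
  affine_transform(t(coef[1:3, , drop = FALSE]), coef[4L, ])
}

#' Fit the per-view affine frame conversion
#'
#' Least-squares affine between matched point sets, used to convert between
#' the head-model millimeter frame and the normalized camera frame of one
#' camera view, from a small set of correspondence landmarks (nasion, eye
#' corners, nose tip and sides, mouth corners, chin).  The fit is exact when
#' an exact affine relation holds.
#'
#' @param src,dst Matched `n x 3` point sets, `n >= 4`, `src` not all
#'   coplanar.
#' @return An [affine_transform()] minimizing
#'   `sum ||A src_i + b - dst_i||^2`.
#' @export
fit_view_affine <- function(src, dst) {
  fit_affine_lsq(src, dst, what = "view correspondences")
}
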