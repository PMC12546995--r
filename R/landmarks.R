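CRANIAL_NAMES <- c("Nz", "Iz", "LPA", "RPA", "Cz")
FRAMES <- c("head-mm", "normalized-camera")

#' Cranial landmark set
#'
#' The five cranial reference positions — nasion (Nz), inion (Iz), left/right
#' preauricular points (LPA/RPA) and vertex (Cz) — with an explicit
#' coordinate-frame tag and a record of how Iz/Cz were obtained
#' (`"three-point"`: derived geometrically under the coplanarity assumption;
#' `"five-point"`: all five points taken independently).
#'
#' @param points Named list of 3-vectors or a 5 x 3 matrix with rownames;
#'   must contain Nz, Iz, LPA, RPA, Cz.
#' @param frame `"head-mm"` (head-model millimeter coordinates) or
#'   `"normalized-camera"` (detector frame, x/y in `[0, 1]`).
#' @param method `"three-point"` or `"five-point"`.
#' @return An object of class `cranial_landmarks` with a `points` matrix
#'   (rows Nz, Iz, LPA, RPA, Cz), `frame` and `method`.
#' @export
cranial_landmarks <- function(points, frame = c("head-mm", "normalized-camera"),
                              method = c("five-point", "three-point")) {
  frame <- match.arg(frame)
  method <- match.arg(method)
  if (is.list(points)) {
    missing <- setdiff(CRANIAL_NAMES, names(points))
    if (length(missing)) {
      stop("missing cranial landmarks: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    points <- do.call(rbind, lapply(CRANIAL_NAMES, function(nm) as_point3(points[[nm]], nm)))
    rownames(points) <- CRANIAL_NAMES
  } else {
    points <- as_points_matrix(points, "cranial points")
    if (is.null(rownames(points)) && nrow(points) == 5L) {
      rownames(points) <- CRANIAL_NAMES
    }
    missing <- setdiff(CRANIAL_NAMES, rownames(points))
    if (length(missing)) {
      stop("missing cranial landmarks: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    points <- points[CRANIAL_NAMES, , drop = FALSE]
  }
  structure(list(points = points, frame = frame, method = method),
            class = "cranial_landmarks")
}

#' @export
print.cranial_landmarks <- function(x, ...) {
  cat(sprintf("<cranial_landmarks> frame=%s method=%s\n", x$frame, x$method))
  print(round(x$points, 4))
  invisible(x)
}

#' Coplanarity residual of the Nz/Iz/LPA/RPA plane
#'
#' Root-mean-square distance of Nz, Iz, LPA and RPA from their least-squares
#' plane.  Under the three-point construction the residual is at
#' floating-point level by construction.
#'
#' @param cranial A [cranial_landmarks()].
#' @return Numeric scalar (same units as the landmark frame).
#' @export
cranial_coplanarity_residual <- function(cranial) {
  stopifnot(inherits(cranial, "cranial_landmarks"))
  pts <- cranial$points[c("Nz", "Iz", "LPA", "RPA"), ]
  pl <- fit_plane(pts)
  max(abs(plane_signed_distance(pts, pl$point, pl$normal)))
}

FACIAL_CONVENTIONS <- c(camera468 = 468L, headmodel68 = 68L, synthetic24 = 24L)

#' Index of the nasion-coincident facial point
#'
#' The camera facial-landmark convention has exactly one point coinciding
#' with a cranial landmark: its point #168 (0-based, as documented by the
#' detector) is the nasion Nz.  All indices in this package are **1-based**,
#' so that point is row 169 here; the on-disk JSON format carries an explicit
#' `index_base` field to keep the two conventions unambiguous.
#'
#' @param convention One of `"camera468"`, `"headmodel68"`, `"synthetic24"`.
#' @return 1-based row index of the nasion point.
#' @export
nz_point_index <- function(convention) {
  switch(match.arg(convention, names(FACIAL_CONVENTIONS)),
         camera468 = 169L,   # detector point #168, 0-based
         headmodel68 = 28L,  # top of the nose bridge in the 68-point set
         synthetic24 = 1L)   # synthetic nasion is the first point
}

#' Facial landmark set
#'
#' Ordered 3D facial points from a detector or the synthetic generator, with
#' their source convention and coordinate-frame tag.  In the
#' `"normalized-camera"` frame, x and y lie in `[0, 1]` (up to a small
#' tolerance for landmark jitter); z is a relative depth and unrestricted.
#'
#' @param points `n x 3` matrix; `n` must match the convention size
#'   (camera468: 468, headmodel68: 68, synthetic24: 24).
#' @param convention Point-ordering convention.
#' @param frame `"head-mm"` or `"normalized-camera"`.
#' @return An object of class `facial_landmarks`.
#' @export
facial_landmarks <- function(points,
                             convention = c("camera468", "headmodel68", "synthetic24"),
                             frame = c("normalized-camera", "head-mm")) {
  convention <- match.arg(convention)
  frame <- match.arg(frame)
  points <- as_points_matrix(points, "facial points")
  expected <- FACIAL_CONVENTIONS[[convention]]
  if (nrow(points) != expected) {
    stop(sprintf("convention '%s' requires %d points, got %d",
                 convention, expected, nrow(points)), call. = FALSE)
  }
  if (frame == "normalized-camera") {
    xy <- points[, 1:2]
    if (any(xy < -0.05) || any(xy > 1.05)) {
      stop("normalized-camera facial x/y must lie within [0, 1]", call. = FALSE)
    }
  }
  structure(list(points = points, convention = convention, frame = frame),
            class = "facial_landmarks")
}

#' @export
print.facial_landmarks <- function(x, ...) {
  cat(sprintf("<facial_landmarks> %d points, convention=%s, frame=%s\n",
              nrow(x$points), x$convention, x$frame))
  invisible(x)
}
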