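#' Fit the atlas-to-subject registration
#'
#' Least-squares affine mapping atlas cranial landmarks onto the predicted
#' subject landmarks.  The correspondence set always contains all five
#' fiducials: in `"three-point"` mode Nz/Iz/LPA/RPA are coplanar by
#' construction, and four coplanar points cannot determine a 3D affine, so
#' Cz is included regardless of mode — the mode records how Iz was derived,
#' not which points are used.  The transform is fitted directly across
#' frames (atlas head-mm to subject normalized-camera): the affine absorbs
#' the scale change.
#'
#' @param predicted Subject [cranial_landmarks()] (typically
#'   [predict_cranial()] output, normalized-camera frame).
#' @param atlas Atlas [cranial_landmarks()] (head-mm frame).
#' @param mode `"five-point"` or `"three-point"` (recorded; see Details).
#' @return An [affine_transform()] carrying attributes `mode` and `frames`.
#' @export
fit_registration <- function(predicted, atlas,
                             mode = c("five-point", "three-point")) {
  mode <- match.arg(mode)
  stopifnot(inherits(predicted, "cranial_landmarks"),
            inherits(atlas, "cranial_landmarks"))
  tf <- fit_affine_lsq(atlas$points, predicted$points,
                       what = "cranial correspondences")
  attr(tf, "mode") <- mode
  attr(tf, "frames") <- c(from = atlas$frame, to = predicted$frame)
  tf
}

#' Transform an atlas layout onto a subject
#'
#' @param layout A [tentwenty_layout()] with `source = "atlas"`.
#' @param transform An [affine_transform()] (e.g. from
#'   [fit_registration()]).
#' @return The layout with every entry mapped, `source = "predicted"`;
#'   labels and region tags preserved.
#' @export
transform_layout <- function(layout, transform) {
  stopifnot(inherits(layout, "tentwenty_layout"),
            inherits(transform, "affine_transform"))
  out <- layout
  out$entries <- map_points(transform, layout$entries)
  rownames(out$entries) <- rownames(layout$entries)
  out$source <- "predicted"
  frames <- attr(transform, "frames")
  if (!is.null(frames)) out$frame <- unname(frames["to"])
  out
}

#' Apply a manual offset to a layout
#'
#' Rigid translation of every entry, compensating residual misalignment with
#' the subject's head contour.
#'
#' @param layout A [tentwenty_layout()].
#' @param offset Numeric 3-vector, same units as the layout frame.
#' @return The translated layout.
#' @export
apply_offset <- function(layout, offset) {
  stopifnot(inherits(layout, "tentwenty_layout"))
  offset <- as_point3(offset, "offset")
  layout$entries <- sweep(layout$entries, 2L, offset, "+")
  layout
}

#' Project a normalized-frame layout onto image pixels
#'
#' Drops z and scales the normalized x/y coordinates by the image size.
#' Entries outside `[0, 1]` project outside the image; they are flagged, not
#' dropped.
#'
#' @param layout A [tentwenty_layout()] in the normalized-camera frame.
#' @param image_size Integer `(width, height)` in pixels.
#' @param frame_index Optional frame counter carried through.
#' @return An `overlay_frame`: `points2d` (labels x 2 pixel matrix),
#'   `out_of_frame` (named logical), `image_size`, `frame_index`, plus the
#'   source layout's `density` and `region` tags.
#' @export
project_overlay <- function(layout, image_size = c(640L, 480L),
                            frame_index = NA_integer_) {
  stopifnot(inherits(layout, "tentwenty_layout"))
  if (layout$frame != "normalized-camera") {
    stop("overlay projection requires a normalized-camera layout", call. = FALSE)
  }
  image_size <- as.numeric(image_size)
  if (length(image_size) != 2L || any(!is.finite(image_size)) ||
        any(image_size <= 0)) {
    stop("image_size must be positive (width, height)", call. = FALSE)
  }
  xy <- layout$entries[, 1:2, drop = FALSE]
  pix <- sweep(xy, 2L, image_size, "*")
  oob <- xy[, 1L] < 0 | xy[, 1L] > 1 | xy[, 2L] < 0 | xy[, 2L] > 1
  structure(list(points2d = pix,
                 out_of_frame = stats::setNames(oob, rownames(xy)),
                 image_size = image_size, frame_index = frame_index,
                 density = layout$density, region = layout$region),
            class = "overlay_frame")
}

#' @export
print.overlay_frame <- function(x, ...) {
  cat(sprintf("<overlay_frame> %d labels on %gx%g px (%d out of frame)\n",
              nrow(x$points2d), x$image_size[1L], x$image_size[2L],
              sum(x$out_of_frame)))
  invisible(x)
}

#' Atlas bundle
#'
#' Groups an atlas head mesh, its cranial fiducials and its precomputed
#' layouts (one per density) into the unit the registration pipeline
#' consumes.
#'
#' @param mesh Atlas [tri_mesh()].
#' @param cranial Atlas [cranial_landmarks()] (head-mm).
#' @param layouts Named list of [tentwenty_layout()]s keyed by density; each
#'   must have `source = "atlas"`.
#' @return An object of class `atlas_bundle`.
#' @export
atlas_bundle <- function(mesh, cranial, layouts) {
  stopifnot(inherits(mesh, "tri_mesh"), inherits(cranial, "cranial_landmarks"))
  if (!length(layouts) || is.null(names(layouts))) {
    stop("layouts must be a named list keyed by density", call. = FALSE)
  }
  for (d in names(layouts)) {
    ly <- layouts[[d]]
    if (!inherits(ly, "tentwenty_layout") || ly$density != d) {
      stop(sprintf("layouts[['%s']] must be a tentwenty_layout of that density", d),
           call. = FALSE)
    }
  }
  structure(list(mesh = mesh, cranial = cranial, layouts = layouts),
            class = "atlas_bundle")
}

#' Build an atlas bundle from a mesh and fiducials
#'
#' Convenience wrapper computing the requested layout densities on the atlas
#' mesh.
#'
#' @param mesh Atlas [tri_mesh()].
#' @param cranial Atlas [cranial_landmarks()].
#' @param densities Character vector of densities to precompute.
#' @return An [atlas_bundle()].
#' @export
make_atlas_bundle <- function(mesh, cranial, densities = "10-20") {
  layouts <- lapply(densities, function(d) {
    compute_layout(mesh, cranial, density = d, source = "atlas")
  })
  names(layouts) <- densities
  atlas_bundle(mesh, cranial, layouts)
}
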