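# Synthetic head population: parametric ellipsoid heads with ground-truth
# cranial and facial landmarks and a nine-view camera grid.  Stands in for a
# licensed head-scan library so the full pipeline is testable from code.

# Fixed angular chart of the 24-point synthetic facial convention.
# Azimuth: degrees from the +x (face) axis, positive toward the left ear
# (+y); elevation: degrees above the horizontal plane.  Point 1 is the
# nasion (coincides with the cranial Nz direction).
SYNTHETIC24_ANGLES <- data.frame(
  role = c("nasion",
           "eye_inner_L", "eye_outer_L", "eye_inner_R", "eye_outer_R",
           "brow_L", "brow_R", "forehead",
           "nose_tip", "nose_side_L", "nose_side_R", "subnasale",
           "mouth_L", "mouth_R", "lip_upper", "lip_lower",
           "chin", "jaw_L", "jaw_R", "cheek_L", "cheek_R",
           "temple_L", "temple_R", "glabella"),
  az = c(0, 12, 32, -12, -32, 20, -20, 0, 0, 10, -10, 0,
         18, -18, 0, 0, 0, 35, -35, 25, -25, 45, -45, 0),
  el = c(0, 8, 8, 8, 8, 20, 20, 32, -14, -16, -16, -22,
         -28, -28, -26, -34, -45, -35, -35, -10, -10, 15, 15, 12),
  stringsAsFactors = FALSE
)

#' Designated view-correspondence point indices
#'
#' The 10 facial points used to fit the per-view affine frame conversion:
#' nasion, the four eye corners, the nose tip, the two nose sides and the
#' two mouth corners.  Indices are 1-based; the list is an editable design
#' table.
#'
#' @param convention `"synthetic24"` or `"camera468"`.
#' @return Integer vector of 10 point indices.
#' @export
view_correspondence_indices <- function(convention = c("synthetic24", "camera468")) {
  convention <- match.arg(convention)
  if (convention == "synthetic24") {
    c(1L, 2L, 3L, 4L, 5L, 9L, 10L, 11L, 13L, 14L)
  } else {
    1L + c(168L, 33L, 133L, 362L, 263L, 1L, 98L, 327L, 61L, 291L)
  }
}

# Snap a set of angular directions onto the mesh surface by casting rays
# from the head center; returns an n x 3 matrix of on-mesh points.
snap_directions <- function(mesh, az_deg, el_deg) {
  out <- matrix(0, length(az_deg), 3L)
  for (i in seq_along(az_deg)) {
    az <- deg2rad(az_deg[i]); el <- deg2rad(el_deg[i])
    d <- c(cos(el) * cos(az), cos(el) * sin(az), sin(el))
    out[i, ] <- ray_mesh_intersect(mesh, c(0, 0, 0), d, select = "farthest")
  }
  out
}

new_synthetic_subject <- function(mesh, semiaxes, id, seed) {
  axes_pts <- rbind(Nz = c(semiaxes[1L], 0, 0),
                    Iz = c(-semiaxes[1L], 0, 0),
                    LPA = c(0, semiaxes[2L], 0),
                    RPA = c(0, -semiaxes[2L], 0),
                    Cz = c(0, 0, semiaxes[3L]))
  cranial <- cranial_landmarks(axes_pts[CRANIAL_NAMES, ],
                               frame = "head-mm", method = "five-point")
  facial <- facial_landmarks(
    snap_directions(mesh, SYNTHETIC24_ANGLES$az, SYNTHETIC24_ANGLES$el),
    convention = "synthetic24", frame = "head-mm")
  structure(list(mesh = mesh, cranial = cranial, facial = facial,
                 shape = stats::setNames(semiaxes, c("a", "b", "c")),
                 id = id, seed = seed),
            class = "synthetic_subject")
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat(sprintf("<synthetic_subject> %s: semi-axes (%.1f, %.1f, %.1f) mm, %d faces\n",
              x$id, x$shape[1L], x$shape[2L], x$shape[3L], nrow(x$mesh$faces)))
  invisible(x)
}

#' Synthetic spherical head
#'
#' A geodesic-sphere head with ground-truth cranial fiducials at the six
#' axis vertices — Nz `(r,0,0)`, Iz `(-r,0,0)`, LPA/RPA `(0,±r,0)`,
#' Cz `(0,0,r)` — and 24 synthetic facial points snapped onto the anterior
#' surface at fixed angular positions.  Deterministic: two calls with the
#' same arguments return identical subjects.
#'
#' @param radius Head radius (mm), positive.
#' @param refinement Sphere subdivision level (>= 2); see [sphere_mesh()].
#' @param id Subject identifier.
#' @return A `synthetic_subject`: `mesh`, `cranial` (head-mm truth),
#'   `facial` (head-mm, synthetic24), `shape`, `id`, `seed`.
#' @export
make_sphere_head <- function(radius = 90, refinement = 4L, id = "sphere") {
  mesh <- sphere_mesh(radius, refinement)
  new_synthetic_subject(mesh, c(radius, radius, radius), id, seed = NA_integer_)
}

#' @rdname make_sphere_head
#' @param semiaxes Ellipsoid semi-axes `(a, b, c)` in mm: anterior-posterior,
#'   lateral, vertical.
#' @export
make_ellipsoid_head <- function(semiaxes, refinement = 3L, id = "ellipsoid") {
  semiaxes <- as_point3(semiaxes, "semiaxes")
  if (any(semiaxes <= 0)) stop("semiaxes must be positive", call. = FALSE)
  mesh <- ellipsoid_mesh(semiaxes, refinement)
  new_synthetic_subject(mesh, semiaxes, id, seed = NA_integer_)
}

#' Sample a synthetic head population
#'
#' Draws per-subject ellipsoid semi-axes from independent Gaussian priors
#' (truncated at 4 standard deviations from the mean, and required
#' positive), producing a reproducible list of subjects whose
#' facial-to-cranial geometry varies smoothly — approximately linearly —
#' with shape over the sampled range.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param mean,sd Length-3 priors for the semi-axes (mm); defaults (95, 75,
#'   88) ± (6, 5, 5) emulate adult head half-length/half-width/half-height.
#' @param seed Integer seed; the population is a pure function of
#'   `(parameters, seed)`.
#' @param refinement Mesh subdivision level per subject.
#' @return List of `synthetic_subject`s.
#' @export
sample_population <- function(n_subjects, mean = c(95, 75, 88),
                              sd = c(6, 5, 5), seed = 1L, refinement = 3L) {
  if (n_subjects < 1L) stop("n_subjects must be >= 1", call. = FALSE)
  mean <- as_point3(mean, "mean"); sd <- as.numeric(sd)
  if (length(sd) != 3L || any(!is.finite(sd)) || any(sd < 0)) {
    stop("sd must be three non-negative numbers", call. = FALSE)
  }
  if (any(mean <= 0)) stop("semi-axis prior means must be positive", call. = FALSE)
  axes <- withr::with_seed(seed, {
    m <- matrix(stats::rnorm(3L * n_subjects), n_subjects, 3L)
    m <- pmin(pmax(m, -4), 4)
    sweep(sweep(m, 2L, sd, "*"), 2L, mean, "+")
  })
  if (any(axes <= 0)) stop("sampled semi-axes not positive; shrink sd", call. = FALSE)
  lapply(seq_len(n_subjects), function(i) {
    new_synthetic_subject(ellipsoid_mesh(axes[i, ], refinement), axes[i, ],
                          id = sprintf("subj%03d", i), seed = seed)
  })
}

#' The nine-view camera grid
#'
#' Three vertical camera positions (top, middle, bottom; pitch +20/0/-20
#' degrees) crossed with three horizontal positions (left, center, right;
#' yaw -30/0/+30 degrees), emulating a multi-view rendering protocol.
#'
#' @return A data.frame with columns `view` (e.g. `"top-left"`), `yaw_deg`,
#'   `pitch_deg`.
#' @export
camera_grid <- function() {
  grid <- expand.grid(col = c("left", "center", "right"),
                      row = c("top", "middle", "bottom"),
                      stringsAsFactors = FALSE)
  yaw <- c(left = -30, center = 0, right = 30)
  pitch <- c(top = 20, middle = 0, bottom = -20)
  data.frame(view = paste(grid$row, grid$col, sep = "-"),
             yaw_deg = unname(yaw[grid$col]),
             pitch_deg = unname(pitch[grid$row]),
             stringsAsFactors = FALSE)
}

# Rigid rotation of a view.
view_rotation <- function(yaw_deg, pitch_deg) {
  rot_y(deg2rad(pitch_deg)) %*% rot_z(deg2rad(yaw_deg))
}

#' Render a subject into normalized camera frames
#'
#' For each view: the head is rigidly rotated, then orthographically scaled
#' into the `[0, 1]` normalized frame by its rotated bounding box with a
#' fixed margin (a synthetic stand-in for the detector-defined
#' normalization, which is not recoverable).  Facial landmarks receive
#' i.i.d. Gaussian jitter of standard deviation `sigma` (in normalized
#' units); cranial truth stays exact, mirroring a workflow where cranial
#' reference points are curated rather than detected.
#'
#' @param subject A `synthetic_subject`.
#' @param views A view table from [camera_grid()] (or a subset of it).
#' @param sigma Facial landmark jitter sd in normalized units (>= 0).
#' @param seed Optional integer seed making the jitter reproducible.
#' @param margin Bounding-box margin as a fraction of the largest extent
#'   (default 0.1).
#' @return A list with one element per view: `view`, `facial`
#'   ([facial_landmarks()], normalized-camera), `cranial`
#'   ([cranial_landmarks()], normalized-camera), `transform` (the exact
#'   head-mm to normalized-camera [affine_transform()]) and `scale`
#'   (normalized units per mm).
#' @export
render_views <- function(subject, views = camera_grid(), sigma = 0,
                         seed = NULL, margin = 0.1) {
  stopifnot(inherits(subject, "synthetic_subject"))
  if (nrow(views) < 1L) stop("views must be non-empty", call. = FALSE)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  render <- function() {
    lapply(seq_len(nrow(views)), function(i) {
      rot <- view_rotation(views$yaw_deg[i], views$pitch_deg[i])
      vrot <- subject$mesh$vertices %*% t(rot)
      rng <- apply(vrot, 2L, range)
      ctr <- colMeans(rng)
      extent <- max(rng[2L, ] - rng[1L, ])
      s <- (1 - 2 * margin) / extent
      tf <- affine_transform(s * rot, 0.5 - s * ctr)
      fac <- map_points(tf, subject$facial$points)
      if (sigma > 0) {
        fac <- fac + matrix(stats::rnorm(length(fac), sd = sigma),
                            nrow(fac), 3L)
      }
      list(view = views$view[i],
           facial = facial_landmarks(fac, convention = "synthetic24",
                                     frame = "normalized-camera"),
           cranial = cranial_landmarks(map_points(tf, subject$cranial$points),
                                       frame = "normalized-camera",
                                       method = subject$cranial$method),
           transform = tf,
           scale = s)
    })
  }
  if (is.null(seed)) render() else withr::with_seed(seed, render())
}

#' Build a stacked training table
#'
#' One row per (subject, view): the flattened facial landmark vector in the
#' normalized camera frame plus the four cranial regression targets.  In
#' *geometry mode* (default) the targets are each view's exact normalized
#' cranial truth; when `truth_map` is supplied, targets are generated
#' exactly from that linear model applied to the facial rows (for
#' identifiability tests).
#'
#' @param subjects List of `synthetic_subject`s.
#' @param views View table from [camera_grid()].
#' @param truth_map Optional [fit_linear_headmap()]-shaped object; when
#'   given, targets are `F A_c + b_c` instead of geometric truth.
#' @param sigma Facial jitter sd (normalized units).
#' @param seed Optional integer seed (reproducible tables).
#' @return A `training_table`: `subject`, `view` (length-n vectors),
#'   `facial` (`n x 72` flattened matrix), `targets` (list of `n x 3`
#'   matrices for Iz/LPA/RPA/Cz), `nz` (`n x 3` facial-nasion positions),
#'   `scale` (mm per normalized unit is `1/scale`), `convention`, `sigma`.
#' @export
build_training_table <- function(subjects, views = camera_grid(),
                                 truth_map = NULL, sigma = 0, seed = NULL) {
  stopifnot(length(subjects) >= 1L)
  seeds <- if (is.null(seed)) {
    rep(list(NULL), length(subjects))
  } else {
    as.list(seed + seq_along(subjects) - 1L)
  }
  rows <- list()
  for (si in seq_along(subjects)) {
    rendered <- render_views(subjects[[si]], views, sigma = sigma,
                             seed = seeds[[si]])
    for (rv in rendered) {
      rows[[length(rows) + 1L]] <- list(
        subject = subjects[[si]]$id, view = rv$view,
        facial = as.vector(t(rv$facial$points)),
        cranial = rv$cranial$points, scale = rv$scale)
    }
  }
  facial <- do.call(rbind, lapply(rows, `[[`, "facial"))
  targets <- lapply(HEADMAP_TARGETS, function(tg) {
    do.call(rbind, lapply(rows, function(r) r$cranial[tg, ]))
  })
  names(targets) <- HEADMAP_TARGETS
  if (!is.null(truth_map)) {
    targets <- predict_targets(truth_map, facial)
  }
  structure(list(
    subject = vapply(rows, `[[`, character(1L), "subject"),
    view = vapply(rows, `[[`, character(1L), "view"),
    facial = facial,
    targets = targets,
    nz = do.call(rbind, lapply(rows, function(r) r$cranial["Nz", ])),
    scale = vapply(rows, `[[`, numeric(1L), "scale"),
    convention = "synthetic24",
    sigma = sigma, seed = seed),
    class = "training_table")
}

#' @export
print.training_table <- function(x, ...) {
  cat(sprintf("<training_table> %d rows (%d subjects x views), sigma=%g\n",
              length(x$subject), length(unique(x$subject)), x$sigma))
  invisible(x)
}
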