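TENTWENTY_DENSITIES <- c("10-20", "10-10", "10-5")

# Transverse ("row") arcs: cut by the plane through a left ring/coronal
# anchor, a midline anchor, and the mirrored right anchor.
TENTWENTY_ROWS <- data.frame(
  row = c("F", "P", "FC", "CP", "AF", "PO"),
  left = c("F7", "P7", "FT7", "TP7", "AF7", "PO7"),
  mid = c("Fz", "Pz", "FCz", "CPz", "AFz", "POz"),
  right = c("F8", "P8", "FT8", "TP8", "AF8", "PO8"),
  stringsAsFactors = FALSE
)

#' Label catalogue for the 10-20 / 10-10 / 10-5 layouts
#'
#' The normative construction table: every label is assigned to one
#' generating arc (`sagittal`, `coronal`, `ring`, or a transverse row such as
#' `row:F`) together with its cumulative arc-length fraction on that arc and
#' its anterior/posterior region tag.  Region tags follow the coronal-
#' medial-line convention: labels on the T7-C3-Cz-C4-T8 line belong to
#' `"both"` regions; sagittal/ring/row labels are `"anterior"` in front of
#' that line and `"posterior"` behind it.
#'
#' Densities nest: every 10-20 label appears with identical arc and fraction
#' in 10-10, and 10-10 in 10-5.  The shipped 10-5 table extends the sagittal
#' and coronal arcs to full 5% resolution and the AF/PO rows to nine points;
#' it does not include ring interleaves or additional transverse rows, so it
#' is a documented subset of the full extended nomenclature (consumers must
#' tolerate layouts with missing labels).
#'
#' @param density `"10-20"`, `"10-10"` or `"10-5"`.
#' @return A `data.frame` with columns `label`, `arc`, `fraction`, `region`,
#'   and attribute `rows` (the transverse-arc anchor table).
#' @export
tentwenty_catalogue <- function(density = c("10-20", "10-10", "10-5")) {
  density <- match.arg(density)
  rows <- list()
  add <- function(labels, arc, fractions, region) {
    rows[[length(rows) + 1L]] <<- data.frame(
      label = labels, arc = arc, fraction = fractions, region = region,
      stringsAsFactors = FALSE)
  }
  # ---- 10-20 core ----
  add(c("Fpz", "Fz"), "sagittal", c(0.1, 0.3), "anterior")
  add("Cz", "sagittal", 0.5, "both")
  add(c("Pz", "Oz"), "sagittal", c(0.7, 0.9), "posterior")
  add(c("T7", "C3", "C4", "T8"), "coronal", c(0.1, 0.3, 0.7, 0.9), "both")
  add(c("Fp1", "F7"), "ring", c(0.05, 0.15), "anterior")
  add(c("P7", "O1"), "ring", c(0.35, 0.45), "posterior")
  add(c("O2", "P8"), "ring", c(0.55, 0.65), "posterior")
  add(c("F8", "Fp2"), "ring", c(0.85, 0.95), "anterior")
  add(c("F3", "F4"), "row:F", c(0.25, 0.75), "anterior")
  add(c("P3", "P4"), "row:P", c(0.25, 0.75), "posterior")
  if (density %in% c("10-10", "10-5")) {
    add(c("AFz", "FCz"), "sagittal", c(0.2, 0.4), "anterior")
    add(c("CPz", "POz"), "sagittal", c(0.6, 0.8), "posterior")
    add(c("C5", "C1", "C2", "C6"), "coronal", c(0.2, 0.4, 0.6, 0.8), "both")
    add(c("AF7", "FT7"), "ring", c(0.10, 0.20), "anterior")
    add(c("TP7", "PO7"), "ring", c(0.30, 0.40), "posterior")
    add(c("PO8", "TP8"), "ring", c(0.60, 0.70), "posterior")
    add(c("FT8", "AF8"), "ring", c(0.80, 0.90), "anterior")
    add(c("F5", "F1", "F2", "F6"), "row:F", c(0.125, 0.375, 0.625, 0.875), "anterior")
    add(c("FC5", "FC3", "FC1", "FC2", "FC4", "FC6"), "row:FC",
        c(0.125, 0.25, 0.375, 0.625, 0.75, 0.875), "anterior")
    add(c("CP5", "CP3", "CP1", "CP2", "CP4", "CP6"), "row:CP",
        c(0.125, 0.25, 0.375, 0.625, 0.75, 0.875), "posterior")
    add(c("P5", "P1", "P2", "P6"), "row:P", c(0.125, 0.375, 0.625, 0.875), "posterior")
    add(c("AF3", "AF4"), "row:AF", c(0.25, 0.75), "anterior")
    add(c("PO3", "PO4"), "row:PO", c(0.25, 0.75), "posterior")
  }
  if (density == "10-5") {
    add(c("NFpz", "AFpz", "AFFz", "FFCz", "FCCz"), "sagittal",
        c(0.05, 0.15, 0.25, 0.35, 0.45), "anterior")
    add(c("CCPz", "CPPz", "PPOz", "POOz", "OIz"), "sagittal",
        c(0.55, 0.65, 0.75, 0.85, 0.95), "posterior")
    add(c("T7h", "C5h", "C3h", "C1h", "C2h", "C4h", "C6h", "T8h"), "coronal",
        c(0.15, 0.25, 0.35, 0.45, 0.55, 0.65, 0.75, 0.85), "both")
    add(c("AF5", "AF1", "AF2", "AF6"), "row:AF",
        c(0.125, 0.375, 0.625, 0.875), "anterior")
    add(c("PO5", "PO1", "PO2", "PO6"), "row:PO",
        c(0.125, 0.375, 0.625, 0.875), "posterior")
  }
  out <- do.call(rbind, rows)
  stopifnot(!anyDuplicated(out$label))
  attr(out, "rows") <- TENTWENTY_ROWS
  attr(out, "density") <- density
  out
}

#' Labeled head-surface landmark layout
#'
#' Positions of the 10-20/10-10/10-5 head landmarks, as a labeled point set
#' with per-label anterior/posterior region tags and a provenance tag
#' (`atlas`: computed on an atlas mesh; `subject`: computed on the subject's
#' own mesh; `predicted`: an atlas layout registered onto a subject).
#'
#' @param entries `n x 3` matrix with unique rownames (labels); must include
#'   `Cz`.
#' @param density `"10-20"`, `"10-10"` or `"10-5"`.
#' @param source `"atlas"`, `"subject"` or `"predicted"`.
#' @param region Optional named character vector of
#'   `"anterior"`/`"posterior"`/`"both"` tags; defaults to the catalogue
#'   tags for known labels.
#' @param frame Coordinate frame of the entries.
#' @return An object of class `tentwenty_layout`.
#' @export
tentwenty_layout <- function(entries, density = c("10-20", "10-10", "10-5"),
                             source = c("atlas", "subject", "predicted"),
                             region = NULL,
                             frame = c("head-mm", "normalized-camera")) {
  density <- match.arg(density)
  source <- match.arg(source)
  frame <- match.arg(frame)
  entries <- as_points_matrix(entries, "layout entries")
  labels <- rownames(entries)
  if (is.null(labels) || anyDuplicated(labels)) {
    stop("layout entries need unique rownames (labels)", call. = FALSE)
  }
  if (!("Cz" %in% labels)) stop("layout must contain Cz", call. = FALSE)
  if (is.null(region)) {
    cat_tbl <- tentwenty_catalogue(density)
    region <- stats::setNames(cat_tbl$region, cat_tbl$label)[labels]
    names(region) <- labels
    region[is.na(region)] <- "both"
  } else {
    missing <- setdiff(labels, names(region))
    if (length(missing)) {
      stop("region tags missing for: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    region <- region[labels]
  }
  if (!all(region %in% c("anterior", "posterior", "both"))) {
    stop("region tags must be anterior/posterior/both", call. = FALSE)
  }
  structure(list(entries = entries, density = density, source = source,
                 region = region, frame = frame),
            class = "tentwenty_layout")
}

#' @export
print.tentwenty_layout <- function(x, ...) {
  cat(sprintf("<tentwenty_layout> density=%s source=%s frame=%s, %d labels\n",
              x$density, x$source, x$frame, nrow(x$entries)))
  invisible(x)
}

#' Compute a 10-20 / 10-10 / 10-5 layout on a head mesh
#'
#' Standard arc-fraction construction from the five cranial fiducials:
#' \enumerate{
#'   \item Sagittal arc: the mesh is cut by the plane through Nz, Cz and Iz;
#'     the Nz-to-Iz upper arc is subdivided at the catalogue fractions.  The
#'     50% point *redefines* Cz (the incoming Cz only seeds the cutting
#'     plane); the seed-vs-arc Cz discrepancy is reported as attribute
#'     `cz_discrepancy`.
#'   \item Coronal arc: plane through LPA, the redefined Cz, and RPA;
#'     subdivided likewise (fractions measured from LPA).
#'   \item Circumferential ring: least-squares plane through the four
#'     10%-level anchors (Fpz, T7, Oz, T8); the closed contour is
#'     parameterized from Fpz toward T7 and subdivided at fractions of its
#'     total length.
#'   \item Transverse rows (e.g. F7-Fz-F8): plane through the three placed
#'     anchors, subdivided at the row fractions.
#' }
#'
#' @param mesh Head surface [tri_mesh()] (mm).
#' @param cranial A [cranial_landmarks()] in the head-mm frame with all five
#'   points on or near the mesh.
#' @param density `"10-20"`, `"10-10"` or `"10-5"`.
#' @param source Provenance tag for the resulting layout (default
#'   `"subject"`).
#' @return A [tentwenty_layout()] in the head-mm frame.
#' @export
compute_layout <- function(mesh, cranial, density = c("10-20", "10-10", "10-5"),
                           source = c("subject", "atlas")) {
  stopifnot(inherits(mesh, "tri_mesh"), inherits(cranial, "cranial_landmarks"))
  density <- match.arg(density)
  source <- match.arg(source)
  if (cranial$frame != "head-mm") {
    stop("layout construction requires head-mm cranial landmarks", call. = FALSE)
  }
  pts <- cranial$points
  dmat <- as.matrix(stats::dist(pts))
  diag(dmat) <- Inf
  if (min(dmat) <= 1e-9 * mesh_bbox_diag(mesh)) {
    stop("cranial points must be pairwise distinct", call. = FALSE)
  }
  cat_tbl <- tentwenty_catalogue(density)
  Nz <- pts["Nz", ]; Iz <- pts["Iz", ]; Cz_seed <- pts["Cz", ]
  LPA <- pts["LPA", ]; RPA <- pts["RPA", ]
  entries <- matrix(numeric(0), 0L, 3L)
  place <- function(labels, points) {
    rownames(points) <- labels
    entries <<- rbind(entries, points)
  }
  cut_arc <- function(p1, p2, p3, anchor, arc_name) {
    normal <- cross3(p2 - p1, p3 - p1)
    if (vnorm(normal) <= 1e-12 * vnorm(p2 - p1) * vnorm(p3 - p1)) {
      stop(sprintf("%s arc: defining points are collinear", arc_name),
           call. = FALSE)
    }
    contour <- tryCatch(
      plane_mesh_contour(mesh, p1, normal, anchor),
      error = function(e) stop(sprintf("%s arc: %s", arc_name, conditionMessage(e)),
                               call. = FALSE))
    contour
  }

  # 1. Sagittal arc Nz -> Cz -> Iz.
  sag_contour <- cut_arc(Nz, Cz_seed, Iz, Nz, "sagittal")
  sag_arc <- arc_between(sag_contour, Nz, Cz_seed, Iz)
  sag <- cat_tbl[cat_tbl$arc == "sagittal", ]
  place(sag$label, subdivide_arc(sag_arc, sag$fraction))
  Cz_ref <- drop(subdivide_arc(sag_arc, 0.5))
  entries["Cz", ] <- Cz_ref
  cz_disc <- vnorm(Cz_ref - Cz_seed)

  # 2. Coronal arc LPA -> Cz -> RPA.
  cor_contour <- cut_arc(LPA, Cz_ref, RPA, Cz_ref, "coronal")
  cor_arc <- arc_between(cor_contour, LPA, Cz_ref, RPA)
  coro <- cat_tbl[cat_tbl$arc == "coronal", ]
  place(coro$label, subdivide_arc(cor_arc, coro$fraction))

  # 3. Circumferential ring through the 10%-level anchors.
  ring_anchors <- rbind(entries["Fpz", ], entries["T7", ],
                        entries["Oz", ], entries["T8", ])
  pl <- fit_plane(ring_anchors)
  ring_contour <- tryCatch(
    plane_mesh_contour(mesh, pl$point, pl$normal, entries["Fpz", ]),
    error = function(e) stop("ring arc: ", conditionMessage(e), call. = FALSE))
  if (!ring_contour$closed) {
    stop("ring arc: circumferential contour is not a closed loop", call. = FALSE)
  }
  s_fpz <- arc_project(ring_contour, entries["Fpz", ])$s
  s_t7 <- arc_project(ring_contour, entries["T7", ])$s
  total <- ring_contour$total
  forward <- ((s_t7 - s_fpz) %% total) <= total / 2
  ring <- cat_tbl[cat_tbl$arc == "ring", ]
  ring_pts <- t(vapply(ring$fraction, function(fr) {
    s <- if (forward) (s_fpz + fr * total) %% total else (s_fpz - fr * total) %% total
    arc_point_at(ring_contour, s)
  }, numeric(3L)))
  place(ring$label, ring_pts)

  # 4. Transverse rows.
  rows_tbl <- attr(cat_tbl, "rows")
  for (i in seq_len(nrow(rows_tbl))) {
    rid <- paste0("row:", rows_tbl$row[i])
    row_cat <- cat_tbl[cat_tbl$arc == rid, ]
    if (nrow(row_cat) == 0L) next
    anchors <- c(rows_tbl$left[i], rows_tbl$mid[i], rows_tbl$right[i])
    if (!all(anchors %in% rownames(entries))) {
      stop(sprintf("%s arc: anchors %s not available at density %s", rid,
                   paste(anchors, collapse = "/"), density), call. = FALSE)
    }
    pa <- entries[anchors[1L], ]; pm <- entries[anchors[2L], ]; pb <- entries[anchors[3L], ]
    contour <- cut_arc(pa, pm, pb, pm, rid)
    row_arc <- arc_between(contour, pa, pm, pb)
    place(row_cat$label, subdivide_arc(row_arc, row_cat$fraction))
  }

  layout <- tentwenty_layout(entries[cat_tbl$label, , drop = FALSE],
                             density = density, source = source,
                             region = stats::setNames(cat_tbl$region, cat_tbl$label),
                             frame = "head-mm")
  attr(layout, "cz_discrepancy") <- cz_disc
  layout
}

#' Anterior/posterior region partition of a layout
#'
#' Re-derives the region tags of every label from the shipped catalogue:
#' anterior labels lie between the coronal medial line (T7-C3-Cz-C4-T8) and
#' the nasion, posterior between that line and the inion, and medial-line
#' labels are tagged `"both"` (they are counted in both regions by the
#' error-evaluation convention).
#'
#' @param layout A [tentwenty_layout()]; labels must belong to the catalogue
#'   at the layout's density.
#' @return The layout with catalogue region tags, plus attribute `counts`
#'   (anterior/posterior/both label counts).
#' @export
region_partition <- function(layout) {
  stopifnot(inherits(layout, "tentwenty_layout"))
  cat_tbl <- tentwenty_catalogue(layout$density)
  tags <- stats::setNames(cat_tbl$region, cat_tbl$label)
  labels <- rownames(layout$entries)
  unknown <- setdiff(labels, names(tags))
  if (length(unknown)) {
    stop("unknown layout labels: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  layout$region <- tags[labels]
  attr(layout, "counts") <- c(
    anterior = sum(layout$region %in% c("anterior", "both")),
    posterior = sum(layout$region %in% c("posterior", "both")),
    both = sum(layout$region == "both"))
  layout
}
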