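HEADMAP_TARGETS <- c("Iz", "LPA", "RPA", "Cz")

#' Facial-landmark subset specification
#'
#' Names an ordered list of facial point indices used as regression inputs.
#' The default spec selects `Nf = 20` points spanning the face contour, the
#' eyes, the mouth edges and the nose outlines.  Indices are **1-based**
#' (see [nz_point_index()] for the 0/1-based convention note); the exact
#' index list is an editable design table, and every fitted map stores its
#' spec for reproducibility.
#'
#' @param name Short identifier for the spec.
#' @param indices Ordered vector of unique 1-based point indices, valid for
#'   `convention`.
#' @param convention Facial convention the indices refer to.
#' @return An object of class `subset_spec` with fields `name`, `indices`,
#'   `convention` and `count`.
#' @export
subset_spec <- function(name, indices, convention) {
  convention <- match.arg(convention, names(FACIAL_CONVENTIONS))
  indices <- as.integer(indices)
  n_max <- FACIAL_CONVENTIONS[[convention]]
  if (length(indices) < 1L || anyNA(indices) || anyDuplicated(indices) ||
        min(indices) < 1L || max(indices) > n_max) {
    stop(sprintf("indices must be unique and within [1, %d] for '%s'",
                 n_max, convention), call. = FALSE)
  }
  structure(list(name = name, indices = indices, convention = convention,
                 count = length(indices)),
            class = "subset_spec")
}

#' @rdname subset_spec
#' @param convention Facial convention.
#' @export
default_subset_spec <- function(convention = c("synthetic24", "camera468")) {
  convention <- match.arg(convention)
  if (convention == "camera468") {
    # 1-based; covers face contour, eyes, eyebrows, mouth edges, nose
    # outline and the nasion point of the 468-point camera convention.
    idx <- 1L + c(10L, 33L, 133L, 362L, 263L, 70L, 300L, 61L, 291L, 0L,
                  17L, 1L, 4L, 98L, 327L, 152L, 234L, 454L, 168L, 199L)
  } else {
    # All synthetic points except forehead/glabella/cheeks, keeping the
    # contour + eyes + mouth + nose groups (20 of 24).
    idx <- setdiff(seq_len(24L), c(8L, 20L, 21L, 24L))
  }
  subset_spec(paste0("default20-", convention), idx, convention)
}

#' @export
print.subset_spec <- function(x, ...) {
  cat(sprintf("<subset_spec> %s: %d points of '%s'\n",
              x$name, x$count, x$convention))
  invisible(x)
}

#' Flatten the selected facial points into a regression row
#'
#' Concatenates the coordinates of the selected points in spec order as
#' `(x, y, z)` triplets, producing the length-`3 * Nf` input row of the
#' face-to-head regression.
#'
#' @param f A [facial_landmarks()] object (or a bare points matrix of the
#'   spec's convention size).
#' @param spec A [subset_spec()] compatible with `f`'s convention.
#' @return Numeric vector of length `3 * spec$count`.
#' @export
select_subset <- function(f, spec) {
  stopifnot(inherits(spec, "subset_spec"))
  if (inherits(f, "facial_landmarks")) {
    if (f$convention != spec$convention) {
      stop(sprintf("subset spec is for '%s' but landmarks use '%s'",
                   spec$convention, f$convention), call. = FALSE)
    }
    pts <- f$points
  } else {
    pts <- as_points_matrix(f, "facial points")
  }
  if (max(spec$indices) > nrow(pts)) {
    stop("subset index out of range for the landmark set", call. = FALSE)
  }
  as.vector(t(pts[spec$indices, , drop = FALSE]))
}

# Columns of a full flattened facial matrix (x1,y1,z1,x2,...) selected by a
# subset spec.
subset_flat_columns <- function(spec) {
  as.vector(vapply(spec$indices, function(i) (3L * (i - 1L) + 1L):(3L * i),
                   integer(3L)))
}

#' Fit the stacked linear face-to-head mapping
#'
#' Fits, for each cranial target in {Iz, LPA, RPA, Cz}, the linear model
#' `P_c = F A_c + 1 b_c` over all stacked (subject, view) rows by least
#' squares — equivalent to three independent ordinary-least-squares problems
#' per target, one per output coordinate, and to the pseudo-inverse solution
#' of the stacked normal equations.  Nz is never regressed: it is copied
#' from the nasion-coincident facial point at prediction time.
#'
#' @param table A training table (see [build_training_table()]) or a list
#'   with elements `facial` (an `n x 3K` full flattened facial matrix) and
#'   `targets` (named list of `n x 3` matrices for Iz, LPA, RPA, Cz), plus
#'   `convention`.
#' @param subset A [subset_spec()]; default spans the standard 20 points of
#'   the table's convention.
#' @param ridge Non-negative ridge penalty on `A_c` (never on `b_c`);
#'   default 0.  With `ridge = 0` the design must be full rank and have at
#'   least `3 Nf + 1` rows per target.
#' @return An object of class `linear_headmap`: per-target `(A, b)` with the
#'   subset spec and training metadata (row count, ridge, per-target residual
#'   summary: RMS and median Euclidean residual).
#' @export
fit_linear_headmap <- function(table, subset = NULL, ridge = 0) {
  if (is.null(subset)) subset <- default_subset_spec(table$convention)
  stopifnot(inherits(subset, "subset_spec"))
  if (!is.null(table$convention) && table$convention != subset$convention) {
    stop("subset spec convention does not match the training table", call. = FALSE)
  }
  if (!is.numeric(ridge) || length(ridge) != 1L || ridge < 0) {
    stop("ridge must be a non-negative scalar", call. = FALSE)
  }
  missing_t <- setdiff(HEADMAP_TARGETS, names(table$targets))
  if (length(missing_t)) {
    stop("training table lacks targets: ", paste(missing_t, collapse = ", "),
         call. = FALSE)
  }
  x_full <- as.matrix(table$facial)
  cols <- subset_flat_columns(subset)
  if (max(cols) > ncol(x_full)) {
    stop("subset indices exceed the facial row width", call. = FALSE)
  }
  x <- x_full[, cols, drop = FALSE]
  n <- nrow(x)
  p <- ncol(x) + 1L
  if (ridge == 0 && n < p) {
    stop(sprintf("insufficient rows: %d rows for %d coefficients per target",
                 n, p), call. = FALSE)
  }
  design <- cbind(x, 1)
  if (ridge > 0) {
    design <- rbind(design, cbind(sqrt(ridge) * diag(ncol(x)), 0))
  }
  qrd <- qr(design)
  if (qrd$rank < p) {
    stop(sprintf(paste0("rank-deficient design (rank %d < %d coefficients); ",
                        "add rows, reduce the subset, or set ridge > 0"),
                 qrd$rank, p), call. = FALSE)
  }
  targets <- list()
  residuals <- list()
  for (tg in HEADMAP_TARGETS) {
    y <- as.matrix(table$targets[[tg]])
    if (nrow(y) != n || ncol(y) != 3L) {
      stop(sprintf("target %s must be an %d x 3 matrix", tg, n), call. = FALSE)
    }
    if (ridge > 0) y <- rbind(y, matrix(0, ncol(x), 3L))
    coef <- qr.coef(qrd, y)
    A <- coef[seq_len(ncol(x)), , drop = FALSE]
    b <- coef[ncol(x) + 1L, ]
    res <- sweep(x %*% A, 2L, b, "+") - as.matrix(table$targets[[tg]])
    err <- sqrt(rowSums(res^2))
    targets[[tg]] <- list(A = unname(A), b = unname(b))
    residuals[[tg]] <- c(rms = sqrt(mean(err^2)), median = stats::median(err))
  }
  structure(list(targets = targets, subset = subset,
                 meta = list(n_rows = n, ridge = ridge,
                             residuals = residuals)),
            class = "linear_headmap")
}

#' Assemble a linear head map from explicit coefficients
#'
#' Low-level constructor used by the deserializer and by tests that need a
#' map with known ground-truth coefficients.
#'
#' @param targets Named list (Iz, LPA, RPA, Cz) of lists with `A`
#'   (`3Nf x 3` matrix) and `b` (3-vector).
#' @param subset The [subset_spec()] the coefficients refer to.
#' @param meta Optional metadata list.
#' @return A `linear_headmap`.
#' @export
linear_headmap <- function(targets, subset, meta = list()) {
  stopifnot(inherits(subset, "subset_spec"))
  missing_t <- setdiff(HEADMAP_TARGETS, names(targets))
  if (length(missing_t)) {
    stop("missing targets: ", paste(missing_t, collapse = ", "), call. = FALSE)
  }
  p <- 3L * subset$count
  targets <- lapply(targets[HEADMAP_TARGETS], function(tg) {
    A <- as.matrix(tg$A)
    if (!all(dim(A) == c(p, 3L))) {
      stop(sprintf("each A must be %d x 3 for this subset", p), call. = FALSE)
    }
    list(A = unname(A), b = as_point3(tg$b, "b"))
  })
  meta <- modifyList(list(n_rows = NA_integer_, ridge = 0,
                          residuals = NULL), meta)
  structure(list(targets = targets, subset = subset, meta = meta),
            class = "linear_headmap")
}

#' @export
print.linear_headmap <- function(x, ...) {
  cat(sprintf("<linear_headmap> Nf=%d (%s), %d training rows, ridge=%g\n",
              x$subset$count, x$subset$convention, x$meta$n_rows,
              x$meta$ridge))
  invisible(x)
}

# Predict all four regressed targets for a matrix of full flattened facial
# rows; returns a named list of n x 3 matrices.
predict_targets <- function(map, facial_full) {
  stopifnot(inherits(map, "linear_headmap"))
  x <- as.matrix(facial_full)[, subset_flat_columns(map$subset), drop = FALSE]
  out <- lapply(map$targets, function(tg) {
    sweep(x %*% tg$A, 2L, tg$b, "+")
  })
  out
}

#' Predict subject cranial landmarks from facial landmarks
#'
#' Applies the fitted linear map to one facial-landmark frame: Iz, LPA, RPA
#' and Cz are regressed; Nz is copied verbatim from the nasion-coincident
#' facial point.  Because the model is affine in landmark *coordinates* (not
#' a rigid-motion model), translating the facial input by `t` does **not**
#' translate the prediction by `t` in general.
#'
#' @param map A [fit_linear_headmap()] result.
#' @param f A [facial_landmarks()] in the normalized-camera frame, with the
#'   same convention the map was trained on.
#' @return A [cranial_landmarks()] in the normalized-camera frame,
#'   method `"three-point"` (the map is trained on coplanar-constructed Iz).
#' @export
predict_cranial <- function(map, f) {
  stopifnot(inherits(map, "linear_headmap"), inherits(f, "facial_landmarks"))
  if (f$convention != map$subset$convention) {
    stop(sprintf("map was trained on '%s' landmarks but got '%s'",
                 map$subset$convention, f$convention), call. = FALSE)
  }
  x <- matrix(as.vector(t(f$points)), 1L)
  preds <- predict_targets(map, x)
  pts <- list(Nz = f$points[nz_point_index(f$convention), ])
  for (tg in HEADMAP_TARGETS) pts[[tg]] <- drop(preds[[tg]])
  cranial_landmarks(pts, frame = "normalized-camera", method = "three-point")
}
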