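#' Landmark error report
#'
#' Raw per-item Euclidean errors with grouping keys, plus median/IQR
#' summaries recomputable from the raw table (which is always stored
#' alongside).  Median and IQR are the primary summaries throughout the
#' package.
#'
#' @param raw A data.frame with a numeric `error` column and arbitrary
#'   grouping columns (e.g. `landmark`, `view`, `label`, `region`, `fold`).
#' @param unit Unit label for the errors (e.g. `"mm"`,
#'   `"normalized"`).
#' @return An object of class `error_report` with elements `raw`, `unit`,
#'   and `summary` (list of per-group median/IQR tables; overall always
#'   present).
#' @export
error_report <- function(raw, unit = "mm") {
  stopifnot(is.data.frame(raw), "error" %in% names(raw))
  if (any(raw$error < 0) || any(!is.finite(raw$error))) {
    stop("errors must be finite and non-negative", call. = FALSE)
  }
  group_cols <- setdiff(names(raw), "error")
  summ <- list(overall = data.frame(
    n = nrow(raw), median = stats::median(raw$error),
    iqr = unname(diff(stats::quantile(raw$error, c(0.25, 0.75))))))
  for (gc in group_cols) {
    split_errs <- split(raw$error, raw[[gc]])
    summ[[gc]] <- data.frame(
      group = names(split_errs),
      n = vapply(split_errs, length, integer(1L)),
      median = vapply(split_errs, stats::median, numeric(1L)),
      iqr = vapply(split_errs, function(e)
        unname(diff(stats::quantile(e, c(0.25, 0.75)))), numeric(1L)),
      row.names = NULL)
  }
  structure(list(raw = raw, unit = unit, summary = summ),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  ov <- x$summary$overall
  cat(sprintf("<error_report> n=%d, median=%.4g %s (IQR %.4g)\n",
              ov$n, ov$median, x$unit, ov$iqr))
  invisible(x)
}

#' Subject-level k-fold split
#'
#' Partitions subject ids into `k` disjoint test folds covering every
#' subject exactly once.  Splitting is always by subject, never by view, so
#' no subject contributes rows to both the training and the test side of a
#' fold.
#'
#' @param ids Character or integer vector of subject identifiers (unique).
#' @param k Number of folds (default 5).
#' @param seed Integer seed; the split is a pure function of `(ids, k,
#'   seed)`.
#' @return List of `k` lists with elements `train` and `test`.
#' @export
kfold_split <- function(ids, k = 5L, seed = 1L) {
  ids <- unique(ids)
  k <- as.integer(k)
  if (k < 2L || k > length(ids)) {
    stop(sprintf("k must be in [2, %d]", length(ids)), call. = FALSE)
  }
  shuffled <- withr::with_seed(seed, sample(ids))
  fold_id <- rep(seq_len(k), length.out = length(ids))
  # rep(...) assigns cyclically so fold sizes differ by at most one.
  lapply(seq_len(k), function(i) {
    list(train = shuffled[fold_id != i], test = shuffled[fold_id == i])
  })
}

# Subset a training table to a set of subjects.
table_subset <- function(table, subjects) {
  keep <- table$subject %in% subjects
  out <- table
  out$subject <- table$subject[keep]
  out$view <- table$view[keep]
  out$facial <- table$facial[keep, , drop = FALSE]
  out$targets <- lapply(table$targets, function(m) m[keep, , drop = FALSE])
  out$nz <- table$nz[keep, , drop = FALSE]
  out$scale <- table$scale[keep]
  out
}

#' Cross-validated cranial prediction errors
#'
#' Runs a subject-level k-fold cross-validation of the linear face-to-head
#' map over a training table: per fold the map is fitted on the training
#' subjects and applied to the held-out subjects' rows; per-landmark
#' Euclidean errors are pooled over folds.  Each (subject, view, landmark)
#' triplet receives exactly one prediction.
#'
#' @param table A [build_training_table()] result (targets are the ground
#'   truth).
#' @param k Number of folds.
#' @param seed Seed for the fold split.
#' @param subset,ridge Passed to [fit_linear_headmap()].
#' @param unit `"normalized"` (default) reports errors in normalized camera
#'   units; `"mm"` divides each row's error by its view scale.
#' @return An [error_report()] with grouping keys `landmark`, `view`,
#'   `subject` and `fold`; attribute `folds` stores the split.
#' @export
evaluate_cranial <- function(table, k = 5L, seed = 1L, subset = NULL,
                             ridge = 0, unit = c("normalized", "mm")) {
  unit <- match.arg(unit)
  folds <- kfold_split(unique(table$subject), k = k, seed = seed)
  rows <- list()
  for (fi in seq_along(folds)) {
    train <- table_subset(table, folds[[fi]]$train)
    test <- table_subset(table, folds[[fi]]$test)
    map <- fit_linear_headmap(train, subset = subset, ridge = ridge)
    preds <- predict_targets(map, test$facial)
    for (tg in HEADMAP_TARGETS) {
      err <- sqrt(rowSums((preds[[tg]] - test$targets[[tg]])^2))
      if (unit == "mm") err <- err / test$scale
      rows[[length(rows) + 1L]] <- data.frame(
        landmark = tg, subject = test$subject, view = test$view,
        fold = fi, error = err)
    }
  }
  raw <- do.call(rbind, rows)
  rep <- error_report(raw, unit = unit)
  attr(rep, "folds") <- folds
  rep
}

#' Layout prediction errors with anterior/posterior partition
#'
#' Per-label Euclidean distances between a predicted layout and a reference
#' layout, over the intersection of their label sets (mismatched labels are
#' reported in attribute `dropped`).  Region medians follow the
#' coronal-medial-line convention: labels tagged `"both"` contribute to the
#' anterior and the posterior pools.
#'
#' @param predicted,truth [tentwenty_layout()]s in the same frame.
#' @param unit Unit label for the report.
#' @return An [error_report()] with keys `label` and `region`; its summary
#'   gains a `region_pooled` table with anterior/posterior medians under the
#'   double-counting convention.
#' @export
evaluate_layout <- function(predicted, truth, unit = "mm") {
  stopifnot(inherits(predicted, "tentwenty_layout"),
            inherits(truth, "tentwenty_layout"))
  labels <- intersect(rownames(predicted$entries), rownames(truth$entries))
  if (length(labels) == 0L) {
    stop("predicted and truth layouts share no labels", call. = FALSE)
  }
  dropped <- union(setdiff(rownames(predicted$entries), labels),
                   setdiff(rownames(truth$entries), labels))
  err <- sqrt(rowSums((predicted$entries[labels, , drop = FALSE] -
                         truth$entries[labels, , drop = FALSE])^2))
  region <- region_partition(truth)$region[labels]
  raw <- data.frame(label = labels, region = unname(region), error = unname(err))
  rep <- error_report(raw, unit = unit)
  pool <- function(tags) raw$error[raw$region %in% tags]
  ant <- pool(c("anterior", "both")); post <- pool(c("posterior", "both"))
  rep$summary$region_pooled <- data.frame(
    group = c("anterior", "posterior"),
    n = c(length(ant), length(post)),
    median = c(stats::median(ant), stats::median(post)),
    iqr = c(unname(diff(stats::quantile(ant, c(0.25, 0.75)))),
            unname(diff(stats::quantile(post, c(0.25, 0.75))))))
  attr(rep, "dropped") <- dropped
  rep
}

#' Noise-induced uncertainty of the predicted layout, by window length
#'
#' Emulates the detector-noise experiment in landmark space: a single
#' subject/view is rendered `n_repeats` times with i.i.d. Gaussian facial
#' jitter of sd `sigma`; the full per-frame pipeline (stabilize, predict,
#' register, transform) is run for each moving-average window length, and
#' the standard deviation of every layout label's predicted position across
#' repeats is reported (positional sd = square root of the summed
#' per-coordinate variances, steady-state frames only).
#'
#' @param subject A `synthetic_subject`.
#' @param map A fitted [fit_linear_headmap()].
#' @param atlas An [atlas_bundle()].
#' @param sigma Facial jitter sd (normalized units).
#' @param n_repeats Number of jittered frames (>= 2; default 100).
#' @param windows Moving-average window lengths (default 1, 3, 5, 8, 10).
#' @param view Which camera-grid view to use (default `"middle-center"`).
#' @param density Layout density (default `"10-20"`).
#' @param seed Integer seed.
#' @return A labels x windows matrix of positional standard deviations
#'   (normalized units), with attribute `sigma`.
#' @export
noise_uncertainty_experiment <- function(subject, map, atlas, sigma,
                                         n_repeats = 100L,
                                         windows = c(1L, 3L, 5L, 8L, 10L),
                                         view = "middle-center",
                                         density = "10-20", seed = 1L) {
  n_repeats <- as.integer(n_repeats)
  if (n_repeats < 2L) stop("n_repeats must be >= 2", call. = FALSE)
  views <- camera_grid()
  views <- views[views$view == view, , drop = FALSE]
  if (nrow(views) != 1L) stop("unknown view id", call. = FALSE)
  max_w <- max(windows)
  n_frames <- n_repeats + max_w - 1L
  frames <- withr::with_seed(seed, {
    lapply(seq_len(n_frames), function(i) {
      render_views(subject, views, sigma = sigma, seed = NULL)[[1L]]$facial
    })
  })
  layout0 <- atlas$layouts[[density]]
  if (is.null(layout0)) stop("atlas bundle lacks density ", density, call. = FALSE)
  labels <- rownames(layout0$entries)
  out <- matrix(NA_real_, length(labels), length(windows),
                dimnames = list(labels, paste0("w", windows)))
  for (wi in seq_along(windows)) {
    w <- windows[wi]
    st <- stabilizer(w)
    positions <- array(NA_real_, c(length(labels), 3L, n_repeats))
    kept <- 0L
    for (i in seq_len(n_frames)) {
      sp <- stabilizer_push(st, frames[[i]])
      st <- sp$state
      if (i < w) next  # warm-up: not yet at steady-state window occupancy
      pred <- predict_cranial(map, sp$frame)
      tf <- fit_registration(pred, atlas$cranial, mode = "five-point")
      ly <- transform_layout(layout0, tf)
      kept <- kept + 1L
      if (kept > n_repeats) break
      positions[, , kept] <- ly$entries[labels, ]
    }
    n_used <- min(kept, n_repeats)
    v <- apply(positions[, , seq_len(n_used), drop = FALSE], c(1L, 2L), stats::var)
    out[, wi] <- sqrt(rowSums(v))
  }
  attr(out, "sigma") <- sigma
  out
}

#' End-to-end synthetic accuracy study
#'
#' The desk-scale analogue of a population head-model study: samples an
#' ellipsoid head population, renders the nine-view camera grid with
#' optional facial jitter, stacks the geometry-mode training table, and
#' runs the subject-level five-fold cross-validation of the linear
#' face-to-head map.
#'
#' @param n_subjects Population size (default 100).
#' @param sigma Facial jitter sd in normalized units (default 0).
#' @param seed Integer master seed (population, jitter and folds all derive
#'   from it).
#' @param refinement Subject mesh refinement (default 3).
#' @param k Folds (default 5).
#' @param unit Error unit for the report (see [evaluate_cranial()]).
#' @return A list with `table`, `report` (an [error_report()]) and
#'   `population`.
#' @export
run_synthetic_study <- function(n_subjects = 100L, sigma = 0, seed = 1L,
                                refinement = 3L, k = 5L,
                                unit = c("normalized", "mm")) {
  unit <- match.arg(unit)
  population <- sample_population(n_subjects, seed = seed,
                                  refinement = refinement)
  table <- build_training_table(population, camera_grid(), sigma = sigma,
                                seed = seed + 1000L)
  report <- evaluate_cranial(table, k = k, seed = seed + 2000L, unit = unit)
  list(table = table, report = report, population = population)
}
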