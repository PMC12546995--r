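test_that("k-fold splits are disjoint, covering, balanced and reproducible", {
  ids <- sprintf("s%02d", 1:10)
  folds <- kfold_split(ids, k = 5, seed = 2)
  tests <- unlist(lapply(folds, `[[`, "test"))
  expect_setequal(tests, ids)
  expect_length(tests, 10L)
  for (f in folds) {
    expect_length(f$test, 2L)
    expect_length(intersect(f$train, f$test), 0L)
    expect_setequal(c(f$train, f$test), ids)
  }
  expect_identical(kfold_split(ids, 5, seed = 2), folds)
  expect_false(identical(kfold_split(ids, 5, seed = 3), folds))
  expect_error(kfold_split(ids, k = 11), "k must be")

  big <- sprintf("s%03d", 1:872)
  sizes <- sort(unique(lengths(lapply(kfold_split(big, 5, 1), `[[`, "test"))))
  expect_identical(sizes, c(174L, 175L))
  expect_length(unlist(lapply(kfold_split(big, 5, 1), `[[`, "test")), 872L)
})

test_that("cross-validated errors vanish on exactly linear data", {
  spec <- subset_spec("compact8", c(1L, 3L, 5L, 9L, 13L, 14L, 17L, 22L),
                      "synthetic24")
  truth <- make_truth_map(spec, seed = 17)
  pop <- sample_population(15, seed = 18)
  tab <- build_training_table(pop, truth_map = truth, sigma = 0, seed = 19)
  rep <- evaluate_cranial(tab, k = 5, seed = 20, subset = spec)
  expect_lt(rep$summary$overall$median, 1e-6)
  expect_identical(nrow(rep$summary$view), 9L)
  expect_identical(sort(unique(rep$raw$landmark)),
                   sort(c("Iz", "LPA", "RPA", "Cz")))
  # one prediction per (subject, view, landmark)
  key <- with(rep$raw, paste(subject, view, landmark))
  expect_false(any(duplicated(key)))
  expect_length(key, 15L * 9L * 4L)
})

test_that("a mean predictor's error distribution matches the direct computation", {
  pop <- sample_population(12, seed = 23)
  tab <- build_training_table(pop, sigma = 0, seed = 24)
  spec <- default_subset_spec("synthetic24")
  mean_map <- linear_headmap(
    stats::setNames(lapply(c("Iz", "LPA", "RPA", "Cz"), function(tg)
      list(A = matrix(0, 60, 3), b = colMeans(tab$targets[[tg]]))),
      c("Iz", "LPA", "RPA", "Cz")), spec)
  preds <- cranioguide:::predict_targets(mean_map, tab$facial)
  direct <- sqrt(rowSums((tab$targets$Cz -
                            matrix(colMeans(tab$targets$Cz),
                                   nrow(tab$targets$Cz), 3, byrow = TRUE))^2))
  expect_equal(sqrt(rowSums((preds$Cz - tab$targets$Cz)^2)), direct,
               tolerance = 1e-12)
})

test_that("layout evaluation reports exact errors and the region convention", {
  sub <- make_sphere_head(90, 3)
  ly <- compute_layout(sub$mesh, sub$cranial, "10-10")
  same <- evaluate_layout(ly, ly)
  expect_identical(same$summary$overall$median, 0)
  d <- c(3, -4, 12)
  shifted <- apply_offset(ly, d)
  rep <- evaluate_layout(shifted, ly)
  expect_equal(rep$raw$error, rep(sqrt(sum(d^2)), nrow(ly$entries)),
               tolerance = 1e-9)
  # anterior + posterior multiset sizes = total + |medial-line labels|
  rp <- rep$summary$region_pooled
  n_both <- sum(region_partition(ly)$region == "both")
  expect_identical(sum(rp$n), nrow(ly$entries) + n_both)
  # label mismatch handling
  subset_ly <- ly
  subset_ly$entries <- ly$entries[1:10, ]
  subset_ly$region <- ly$region[1:10]
  rep2 <- evaluate_layout(subset_ly, ly)
  expect_identical(nrow(rep2$raw), 10L)
  empty <- ly
  rownames(empty$entries) <- paste0(rownames(ly$entries), "_x")
  names(empty$region) <- rownames(empty$entries)
  empty$entries <- rbind(empty$entries, Cz = c(0, 0, 0))
  empty$region <- c(empty$region, Cz = "both")
  expect_identical(nrow(evaluate_layout(empty, ly)$raw), 1L)
})

test_that("error reports store raw errors consistent with their summaries", {
  raw <- data.frame(landmark = rep(c("Iz", "Cz"), each = 5),
                    error = c(1:5, 11:15))
  rep <- error_report(raw)
  expect_identical(rep$summary$overall$median, median(raw$error))
  by_lm <- rep$summary$landmark
  expect_equal(by_lm$median[by_lm$group == "Iz"], median(1:5))
  expect_equal(by_lm$iqr[by_lm$group == "Cz"],
               unname(diff(quantile(11:15, c(0.25, 0.75)))))
  expect_error(error_report(data.frame(error = c(1, -2))), "non-negative")
})

test_that("noise-free pipelines have zero positional uncertainty", {
  sub <- make_sphere_head(0.35, 3)
  shift <- affine_transform(diag(3), c(0.5, 0.5, 0.5))
  mesh <- transform_mesh(sub$mesh, shift)
  cranial <- cranial_landmarks(map_points(shift, sub$cranial$points),
                               frame = "head-mm", method = "five-point")
  bundle <- make_atlas_bundle(mesh, cranial, "10-20")
  spec <- default_subset_spec("synthetic24")
  map <- make_truth_map(spec, seed = 30, sd = 0.02)
  subject <- make_ellipsoid_head(c(95, 75, 88), 2)
  stds0 <- noise_uncertainty_experiment(subject, map, bundle, sigma = 0,
                                        n_repeats = 5, windows = c(1L, 3L),
                                        seed = 31)
  expect_lt(max(stds0), 1e-12)
})

test_that("window averaging orders the layout uncertainty", {
  sub <- make_sphere_head(0.35, 3)
  shift <- affine_transform(diag(3), c(0.5, 0.5, 0.5))
  bundle <- make_atlas_bundle(
    transform_mesh(sub$mesh, shift),
    cranial_landmarks(map_points(shift, sub$cranial$points),
                      frame = "head-mm", method = "five-point"), "10-20")
  spec <- default_subset_spec("synthetic24")
  map <- make_truth_map(spec, seed = 32, sd = 0.02)
  subject <- make_ellipsoid_head(c(95, 75, 88), 2)
  stds <- noise_uncertainty_experiment(subject, map, bundle, sigma = 0.005,
                                       n_repeats = 400,
                                       windows = c(1L, 3L, 10L), seed = 33)
  med <- apply(stds, 2, median)
  expect_true(med[["w10"]] < med[["w3"]] && med[["w3"]] < med[["w1"]])
})
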