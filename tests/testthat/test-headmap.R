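test_that("view affine fitting recovers exact affine relations", {
  withr::with_seed(21, {
    src <- random_points(10)
    expect_equal(fit_view_affine(src, src)$A, diag(3), tolerance = 1e-12)
    expect_equal(fit_view_affine(src, src)$b, c(0, 0, 0), tolerance = 1e-12)
    shifted <- sweep(src, 2, c(0.1, 0.2, 0.3), "+")
    tf <- fit_view_affine(src, shifted)
    expect_equal(tf$A, diag(3), tolerance = 1e-10)
    expect_equal(tf$b, c(0.1, 0.2, 0.3), tolerance = 1e-10)
    for (i in 1:10) {
      gen <- random_affine()
      tf <- fit_view_affine(src, map_points(gen, src))
      expect_lt(max(abs(tf$A - gen$A)), 1e-8)
      expect_lt(max(abs(tf$b - gen$b)), 1e-8)
    }
  })
  coplanar <- cbind(matrix(rnorm(20), 10, 2), 0)
  expect_error(fit_view_affine(coplanar, coplanar), "rank-deficient")
  expect_error(fit_view_affine(random_points(5), random_points(6)),
               "matching lengths")
})

test_that("map_points applies and inverts affine maps", {
  expect_equal(map_points(affine_identity(), c(1, 2, 3)), c(1, 2, 3))
  expect_equal(map_points(affine_transform(2 * diag(3)), c(1, 1, 1)),
               c(2, 2, 2))
  withr::with_seed(9, {
    for (i in 1:10) {
      tf <- random_affine()
      pts <- random_points(7)
      expect_equal(map_points(affine_invert(tf), map_points(tf, pts)), pts,
                   tolerance = 1e-9)
    }
  })
  comp <- affine_compose(affine_transform(2 * diag(3), c(1, 0, 0)),
                         affine_transform(diag(3), c(0, 1, 0)))
  expect_equal(map_points(comp, c(0, 0, 0)), c(1, 2, 0))
})

test_that("subset selection flattens (x,y,z) triplets in spec order", {
  f <- facial_landmarks(matrix(seq_len(72) / 100, 24, 3, byrow = TRUE),
                        "synthetic24", frame = "head-mm")
  one <- subset_spec("one", 5L, "synthetic24")
  expect_equal(select_subset(f, one), f$points[5, ], ignore_attr = TRUE)
  spec20 <- default_subset_spec("synthetic24")
  expect_length(select_subset(f, spec20), 60L)
  expect_identical(spec20$count, 20L)
  perm <- subset_spec("perm", rev(spec20$indices), "synthetic24")
  v1 <- matrix(select_subset(f, spec20), ncol = 3, byrow = TRUE)
  v2 <- matrix(select_subset(f, perm), ncol = 3, byrow = TRUE)
  expect_equal(v2, v1[rev(seq_len(20)), ])
  expect_error(subset_spec("bad", c(1L, 30L), "synthetic24"), "within")
})

test_that("the stacked fit equals the per-coordinate normal-equations oracle", {
  withr::with_seed(33, {
    for (i in 1:10) {
      nf <- sample(c(5L, 20L), 1)
      n <- sample(c(70L, 200L), 1)
      x_full <- matrix(rnorm(n * 72), n, 72)
      spec <- subset_spec("rnd", sort(sample(24L, nf)), "synthetic24")
      targets <- lapply(1:4, function(k) matrix(rnorm(n * 3), n, 3))
      names(targets) <- c("Iz", "LPA", "RPA", "Cz")
      tab <- list(facial = x_full, targets = targets,
                  convention = "synthetic24")
      map <- fit_linear_headmap(tab, subset = spec)
      xs <- x_full[, cranioguide:::subset_flat_columns(spec)]
      for (tg in names(targets)) {
        coef <- oracle_lsq(xs, targets[[tg]])
        expect_lt(max(abs(map$targets[[tg]]$A - coef[seq_len(3 * nf), ])), 1e-8)
        expect_lt(max(abs(map$targets[[tg]]$b - coef[3 * nf + 1, ])), 1e-8)
      }
    }
  })
})

test_that("noiseless generative coefficients are identified exactly", {
  spec <- default_subset_spec("synthetic24")
  truth <- make_truth_map(spec, seed = 2)
  withr::with_seed(3, {
    n <- 150
    x_full <- matrix(runif(n * 72), n, 72)
    targets <- cranioguide:::predict_targets(truth, x_full)
    tab <- list(facial = x_full, targets = targets, convention = "synthetic24")
    map <- fit_linear_headmap(tab)
    for (tg in names(targets)) {
      expect_lt(max(abs(map$targets[[tg]]$A - truth$targets[[tg]]$A)), 1e-8)
      expect_lt(max(abs(map$targets[[tg]]$b - truth$targets[[tg]]$b)), 1e-8)
    }
    expect_lt(map$meta$residuals$Iz[["rms"]], 1e-10)
  })
})

test_that("constant targets yield zero coefficients and the constant offset", {
  withr::with_seed(5, {
    n <- 100
    x_full <- matrix(rnorm(n * 72), n, 72)
    p0 <- c(0.4, 0.5, 0.6)
    targets <- lapply(1:4, function(k) matrix(p0, n, 3, byrow = TRUE))
    names(targets) <- c("Iz", "LPA", "RPA", "Cz")
    map <- fit_linear_headmap(list(facial = x_full, targets = targets,
                                   convention = "synthetic24"))
    expect_lt(max(abs(map$targets$Cz$A)), 1e-10)
    expect_equal(map$targets$Cz$b, p0, tolerance = 1e-10)
  })
})

test_that("deficient designs error without ridge and fit with it", {
  n <- 30  # fewer rows than the 61 coefficients
  x_full <- matrix(rnorm(n * 72), n, 72)
  targets <- lapply(1:4, function(k) matrix(rnorm(n * 3), n, 3))
  names(targets) <- c("Iz", "LPA", "RPA", "Cz")
  tab <- list(facial = x_full, targets = targets, convention = "synthetic24")
  expect_error(fit_linear_headmap(tab), "insufficient rows")
  expect_s3_class(fit_linear_headmap(tab, ridge = 1e-6), "linear_headmap")
  expect_error(fit_linear_headmap(tab, ridge = -1), "non-negative")
})

test_that("prediction copies Nz and reproduces noiseless training rows", {
  spec <- default_subset_spec("synthetic24")
  zero_map <- linear_headmap(
    stats::setNames(lapply(1:4, function(k)
      list(A = matrix(0, 60, 3), b = c(0.1 * k, 0.2, 0.3))),
      c("Iz", "LPA", "RPA", "Cz")), spec)
  f <- facial_landmarks(matrix(0.5, 24, 3), "synthetic24")
  pred <- predict_cranial(zero_map, f)
  expect_equal(unname(pred$points["Iz", ]), c(0.1, 0.2, 0.3))
  expect_equal(unname(pred$points["Nz", ]), f$points[nz_point_index("synthetic24"), ],
               ignore_attr = TRUE)
  expect_identical(pred$frame, "normalized-camera")
  expect_identical(pred$method, "three-point")

  truth <- make_truth_map(spec, seed = 8)
  withr::with_seed(10, {
    x <- matrix(runif(72, 0.2, 0.8), 24, 3)
    fl <- facial_landmarks(x, "synthetic24")
    row <- matrix(as.vector(t(x)), 1)
    expected <- cranioguide:::predict_targets(truth, row)
    got <- predict_cranial(truth, fl)
    expect_equal(unname(got$points["Cz", ]), drop(expected$Cz), tolerance = 1e-10)
  })
  # translation does NOT carry through as a translation
  shifted <- facial_landmarks(x + 0.01, "synthetic24")
  d <- predict_cranial(truth, shifted)$points["Cz", ] -
    predict_cranial(truth, fl)$points["Cz", ]
  expect_gt(max(abs(d - 0.01)), 1e-4)
  # convention mismatch errors
  f68 <- facial_landmarks(matrix(0.5, 68, 3), "headmodel68")
  expect_error(predict_cranial(truth, f68), "trained on")
})
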