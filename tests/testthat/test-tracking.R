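test_that("the stabilizer is a moving average with warm-up", {
  st <- stabilizer(3)
  for (i in 1:5) {
    out <- stabilizer_push(st, const_frame())
    st <- out$state
    expect_equal(out$frame$points, const_frame()$points)
  }
  # w = 1 is a pass-through
  st1 <- stabilizer(1)
  withr::with_seed(1, {
    f <- facial_landmarks(matrix(runif(72), 24, 3), "synthetic24")
  })
  expect_equal(stabilizer_push(st1, f)$frame$points, f$points)
  expect_error(stabilizer(0), "positive")
})

test_that("a step input reaches steady state in exactly w frames", {
  for (w in c(3L, 5L, 8L)) {
    st <- stabilizer(w)
    # warm the buffer at level 0.2 until steady
    for (i in 1:(2 * w)) {
      out <- stabilizer_push(st, const_frame(0.2)); st <- out$state
    }
    vals <- numeric(w + 2)
    for (i in seq_along(vals)) {
      out <- stabilizer_push(st, const_frame(0.8)); st <- out$state
      vals[i] <- out$frame$points[1, 1]
    }
    expect_lt(vals[w - 1], 0.8 - 1e-12)     # still lagging
    expect_equal(vals[w], 0.8, tolerance = 1e-12)  # settled at frame w
    expect_equal(vals[w + 1], 0.8, tolerance = 1e-12)
  }
})

test_that("averaging reduces jitter variance by about 1/sqrt(w)", {
  sigma <- 0.01
  n <- 4000
  withr::with_seed(77, {
    noise <- array(rnorm(n * 72, sd = sigma), c(n, 24, 3))
  })
  for (w in c(2L, 5L)) {
    st <- stabilizer(w)
    outs <- numeric(n)
    for (i in 1:n) {
      f <- facial_landmarks(0.5 + noise[i, , ], "synthetic24")
      out <- stabilizer_push(st, f); st <- out$state
      outs[i] <- out$frame$points[1, 1]
    }
    ratio <- sd(outs[w:n]) / (sigma / sqrt(w))
    expect_lt(abs(ratio - 1), 0.1)
  }
})

test_that("the stabilizer rejects a convention change mid-stream", {
  st <- stabilizer(3)
  out <- stabilizer_push(st, const_frame())
  f68 <- facial_landmarks(matrix(0.5, 68, 3), "headmodel68")
  expect_error(stabilizer_push(out$state, f68), "convention changed")
})

stream_setup <- function() {
  sub <- make_sphere_head(0.35, 3)
  shift <- affine_transform(diag(3), c(0.5, 0.5, 0.5))
  mesh <- transform_mesh(sub$mesh, shift)
  cranial <- cranial_landmarks(map_points(shift, sub$cranial$points),
                               frame = "head-mm", method = "five-point")
  bundle <- make_atlas_bundle(mesh, cranial, "10-20")
  facial <- facial_landmarks(map_points(shift, sub$facial$points),
                             "synthetic24", frame = "normalized-camera")
  spec <- default_subset_spec("synthetic24")
  # A map that predicts the atlas cranial set exactly, whatever the input.
  map <- linear_headmap(
    stats::setNames(lapply(c("Iz", "LPA", "RPA", "Cz"), function(nm)
      list(A = matrix(0, 60, 3), b = unname(cranial$points[nm, ]))),
      c("Iz", "LPA", "RPA", "Cz")), spec)
  list(bundle = bundle, facial = facial, map = map)
}

test_that("a subject identical to the atlas reproduces the atlas overlay", {
  s <- stream_setup()
  overlays <- process_stream(list(s$facial), s$map, s$bundle,
                             config = list(window = 1L))
  expected <- project_overlay(
    tentwenty_layout(s$bundle$layouts[["10-20"]]$entries, "10-20", "predicted",
                     frame = "normalized-camera"))
  expect_lt(max(abs(overlays[[1]]$points2d - expected$points2d)), 1e-6)
})

test_that("identical streams give identical overlays; jitter shrinks with window", {
  s <- stream_setup()
  frames <- rep(list(s$facial), 4)
  o1 <- process_stream(frames, s$map, s$bundle)
  o2 <- process_stream(frames, s$map, s$bundle)
  expect_identical(lapply(o1, `[[`, "points2d"), lapply(o2, `[[`, "points2d"))

  # jittered facial input mapped through a non-trivial map
  spec <- default_subset_spec("synthetic24")
  map <- make_truth_map(spec, seed = 6, sd = 0.02)
  n <- 120
  withr::with_seed(42, {
    jittered <- lapply(1:n, function(i) {
      facial_landmarks(pmin(pmax(
        s$facial$points + matrix(rnorm(72, sd = 0.004), 24, 3), 0), 1),
        "synthetic24")
    })
  })
  sds <- sapply(c(1L, 10L), function(w) {
    ov <- process_stream(jittered, map, s$bundle, config = list(window = w))
    cz <- t(sapply(ov[w:n], function(o) o$points2d["Cz", ]))
    mean(apply(cz, 2, sd))
  })
  expect_lt(sds[2], sds[1])
})

test_that("undetected frames are skipped without touching the buffer", {
  s <- stream_setup()
  frames <- list(s$facial, NULL, s$facial)
  overlays <- process_stream(frames, s$map, s$bundle)
  expect_length(overlays, 2L)
  expect_identical(sapply(overlays, `[[`, "frame_index"), c(1L, 3L))
  log <- attr(overlays, "log")
  expect_identical(nrow(log), 2L)
  expect_error(process_stream(list(), s$map, s$bundle), "empty")
})
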