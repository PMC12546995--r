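test_that("tri_mesh validates connectivity and rejects degenerate faces", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_s3_class(tri_mesh(v, rbind(c(1, 2, 3), c(1, 2, 4))), "tri_mesh")
  expect_error(tri_mesh(v, rbind(c(1, 2, 5))), "outside")
  expect_error(tri_mesh(v, rbind(c(1, 2, 2))), "repeated")
  expect_error(tri_mesh(rbind(v, c(2, 0, 0)), rbind(c(1, 2, 5))), "zero area")
})

test_that("ray intersection matches quadric closed forms", {
  s <- sphere_mesh(1, 4)
  hit <- ray_mesh_intersect(s, c(0, 0, 0), c(1, 0, 0), "farthest")
  expect_lt(sqrt(sum((hit - c(1, 0, 0))^2)), max_edge(s))
  expect_error(ray_mesh_intersect(s, c(2, 0, 0), c(1, 0, 0)), "misses")
  expect_error(ray_mesh_intersect(s, c(0, 0, 0), c(0, 0, 0)), "nonzero")

  semi <- c(1.0, 0.8, 0.9)
  e <- ellipsoid_mesh(semi, 4)
  hit_z <- ray_mesh_intersect(e, c(0, 0, 0), c(0, 0, 1), "farthest")
  expect_lt(sqrt(sum((hit_z - c(0, 0, 0.9))^2)), max_edge(e))
  withr::with_seed(11, {
    for (i in 1:20) {
      d <- rnorm(3)
      o <- rnorm(3, sd = 0.2)
      expected <- oracle_ellipsoid_ray(o, d, semi)
      got <- ray_mesh_intersect(e, o, d, "farthest")
      expect_lt(sqrt(sum((got - expected)^2)), max_edge(e))
    }
  })
})

test_that("nearest/farthest hit selection orders by ray parameter", {
  s <- sphere_mesh(1, 3)
  near <- ray_mesh_intersect(s, c(-2, 0, 0), c(1, 0, 0), "nearest")
  far <- ray_mesh_intersect(s, c(-2, 0, 0), c(1, 0, 0), "farthest")
  expect_lt(sqrt(sum((near - c(-1, 0, 0))^2)), max_edge(s))
  expect_lt(sqrt(sum((far - c(1, 0, 0))^2)), max_edge(s))
})

test_that("plane contours recover analytic section perimeters", {
  s <- sphere_mesh(1, 4)
  ct <- plane_mesh_contour(s, c(0, 0, 0), c(0, 0, 1), c(1, 0, 0))
  expect_true(ct$closed)
  expect_lt(abs(arc_length(ct) - 2 * pi) / (2 * pi), 0.01)
  expect_error(plane_mesh_contour(s, c(0, 0, 2), c(0, 0, 1), c(1, 0, 0)),
               "misses")

  e <- ellipsoid_mesh(c(1.0, 0.8, 0.9), 4)
  ct_e <- plane_mesh_contour(e, c(0, 0, 0), c(0, 1, 0), c(1, 0, 0))
  expect_true(ct_e$closed)
  expect_lt(abs(arc_length(ct_e) - oracle_ellipse_perimeter(1.0, 0.9)) /
              oracle_ellipse_perimeter(1.0, 0.9), 0.01)
})

test_that("a cutting plane passing exactly through vertices still stitches", {
  # The octahedral sphere has a full great circle of vertices in the y = 0
  # plane; the cut must return that single closed loop without duplicates.
  s <- sphere_mesh(1, 3)
  ct <- plane_mesh_contour(s, c(0, 0, 0), c(0, 1, 0), c(1, 0, 0))
  expect_true(ct$closed)
  expect_lt(abs(arc_length(ct) - 2 * pi) / (2 * pi), 0.01)
  expect_true(all(abs(ct$points[, 2]) < 1e-12))
})

test_that("contour length error decreases monotonically with refinement", {
  errs <- sapply(3:5, function(r) {
    ct <- plane_mesh_contour(sphere_mesh(1, r), c(0, 0, 0), c(0, 0, 1),
                             c(1, 0, 0))
    abs(arc_length(ct) - 2 * pi)
  })
  expect_true(all(diff(errs) < 0))
})

test_that("arc_between extracts the traversal passing the via point", {
  s <- sphere_mesh(1, 4)
  ct <- plane_mesh_contour(s, c(0, 0, 0), c(0, 1, 0), c(1, 0, 0))
  upper <- arc_between(ct, c(1, 0, 0), c(0, 0, 1), c(-1, 0, 0))
  expect_false(upper$closed)
  expect_lt(abs(arc_length(upper) - pi) / pi, 0.01)
  lower <- arc_between(ct, c(1, 0, 0), c(0, 0, -1), c(-1, 0, 0))
  expect_lt(abs(arc_length(lower) - pi) / pi, 0.01)
  expect_true(all(upper$points[, 3] > -1e-9))
  expect_true(all(lower$points[, 3] < 1e-9))
  expect_error(arc_between(ct, c(1, 0, 0), c(0, 0, 1), c(1, 0, 0)),
               "zero-length")
})

test_that("arc_between is symmetric under start/end exchange plus reversal", {
  s <- sphere_mesh(1, 3)
  ct <- plane_mesh_contour(s, c(0, 0, 0), c(0, 1, 0), c(1, 0, 0))
  ab <- arc_between(ct, c(1, 0, 0), c(0, 0, 1), c(-1, 0, 0))
  ba <- arc_between(ct, c(-1, 0, 0), c(0, 0, 1), c(1, 0, 0))
  expect_equal(ab$points, arc_reverse(ba)$points, tolerance = 1e-12)
})

test_that("subdivide_arc interpolates exact arc-length fractions", {
  straight <- polyline_arc(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
  expect_equal(drop(subdivide_arc(straight, 0.5)), c(1, 0, 0))
  expect_equal(subdivide_arc(straight, c(0, 1)),
               rbind(c(0, 0, 0), c(2, 0, 0)), ignore_attr = TRUE)
  expect_identical(nrow(subdivide_arc(straight, numeric(0))), 0L)
  expect_error(subdivide_arc(straight, c(0.5, 1.2)), "within")

  s <- sphere_mesh(1, 4)
  ct <- plane_mesh_contour(s, c(0, 0, 0), c(0, 1, 0), c(1, 0, 0))
  upper <- arc_between(ct, c(1, 0, 0), c(0, 0, 1), c(-1, 0, 0))
  fr <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  got <- subdivide_arc(upper, fr)
  for (i in seq_along(fr)) {
    expected <- oracle_great_circle(c(1, 0, 0), c(-1e-9, 0, 1), fr[i] * 2)
    # fractions of the half-circle arc = angle fr*pi from (1,0,0) in x-z
    expected <- c(cos(fr[i] * pi), 0, sin(fr[i] * pi))
    expect_lt(sqrt(sum((got[i, ] - expected)^2)), max_edge(s))
  }
})

test_that("equally spaced fractions give equal spacing on a constant-speed arc", {
  th <- seq(0, pi, length.out = 20001)
  arc <- polyline_arc(cbind(cos(th), sin(th), 0))
  pts <- subdivide_arc(arc, seq(0, 1, by = 0.1))
  gaps <- sqrt(rowSums(diff(pts)^2))
  expect_lt(max(gaps) - min(gaps), 1e-9)
})
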