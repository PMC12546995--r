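canonical_cranial <- function(r = 1) {
  cranial_landmarks(list(Nz = c(r, 0, 0), Iz = c(-r, 0, 0), LPA = c(0, r, 0),
                         RPA = c(0, -r, 0), Cz = c(0, 0, r)),
                    frame = "head-mm", method = "five-point")
}

test_that("catalogue densities nest and have unique labels", {
  c20 <- tentwenty_catalogue("10-20")
  c10 <- tentwenty_catalogue("10-10")
  c5 <- tentwenty_catalogue("10-5")
  expect_identical(nrow(c20), 21L)
  expect_true(all(c20$label %in% c10$label))
  expect_true(all(c10$label %in% c5$label))
  for (tbl in list(c20, c10, c5)) {
    expect_false(any(duplicated(tbl$label)))
    expect_true("Cz" %in% tbl$label)
  }
  # shared labels keep the same generating arc and fraction
  m <- merge(c20, c10, by = "label")
  expect_identical(m$arc.x, m$arc.y)
  expect_equal(m$fraction.x, m$fraction.y)
})

test_that("sphere layout matches closed-form great-circle positions", {
  sub <- make_sphere_head(1, 4)
  ly <- compute_layout(sub$mesh, canonical_cranial(), "10-20")
  expect_identical(nrow(ly$entries), nrow(tentwenty_catalogue("10-20")))
  oracle <- oracle_sphere_layout("10-20")
  tol <- max_edge(sub$mesh)
  for (l in rownames(oracle)) {
    expect_lt(sqrt(sum((ly$entries[l, ] - oracle[l, ])^2)), tol)
  }
  # named spot checks
  expect_lt(sqrt(sum((ly$entries["Fpz", ] -
                        c(cos(pi / 10), 0, sin(pi / 10)))^2)), tol)
  expect_lt(sqrt(sum((ly$entries["Oz", ] -
                        c(-cos(pi / 10), 0, sin(pi / 10)))^2)), tol)
  expect_equal(unname(ly$entries["Cz", ]), c(0, 0, 1), tolerance = tol)
})

test_that("sphere layout error decreases monotonically with refinement", {
  oracle <- oracle_sphere_layout("10-20")
  errs <- sapply(3:5, function(r) {
    sub <- make_sphere_head(1, r)
    ly <- compute_layout(sub$mesh, canonical_cranial(), "10-20")
    max(sqrt(rowSums((ly$entries[rownames(oracle), ] - oracle)^2)))
  })
  expect_true(all(diff(errs) < 0))
})

test_that("densities agree on shared labels computed on the same mesh", {
  sub <- make_sphere_head(1, 3)
  cr <- canonical_cranial()
  ly20 <- compute_layout(sub$mesh, cr, "10-20")
  ly10 <- compute_layout(sub$mesh, cr, "10-10")
  ly5 <- compute_layout(sub$mesh, cr, "10-5")
  sh1 <- rownames(ly20$entries)
  expect_lt(max(abs(ly20$entries[sh1, ] - ly10$entries[sh1, ])), 1e-9)
  sh2 <- rownames(ly10$entries)
  expect_lt(max(abs(ly10$entries[sh2, ] - ly5$entries[sh2, ])), 1e-9)
})

test_that("layouts are symmetric across the mid-sagittal plane", {
  sub <- make_ellipsoid_head(c(95, 75, 88), 4)
  ly <- compute_layout(sub$mesh, sub$cranial, "10-10")
  pairs <- rbind(c("C3", "C4"), c("F7", "F8"), c("F3", "F4"), c("T7", "T8"),
                 c("P7", "P8"), c("O1", "O2"), c("Fp1", "Fp2"),
                 c("AF7", "AF8"), c("FC5", "FC6"), c("CP3", "CP4"))
  tol <- max_edge(sub$mesh)
  for (i in seq_len(nrow(pairs))) {
    left <- ly$entries[pairs[i, 1], ]
    right <- ly$entries[pairs[i, 2], ]
    expect_lt(sqrt(sum((left * c(1, -1, 1) - right)^2)), tol)
  }
  midline <- c("Fpz", "AFz", "Fz", "FCz", "Cz", "CPz", "Pz", "POz", "Oz")
  expect_lt(max(abs(ly$entries[midline, 2])), tol)
})

test_that("every layout entry adheres to the generating surface", {
  sub <- make_ellipsoid_head(c(95, 75, 88), 3)
  ly <- compute_layout(sub$mesh, sub$cranial, "10-10")
  tol <- max_edge(sub$mesh)
  dists <- apply(ly$entries, 1, function(p) point_mesh_distance(sub$mesh, p))
  expect_lt(max(dists), tol)
})

test_that("recomputed sagittal arc fractions match the catalogue", {
  sub <- make_ellipsoid_head(c(95, 75, 88), 3)
  ly <- compute_layout(sub$mesh, sub$cranial, "10-20")
  pts <- sub$cranial$points
  n <- oracle_cross(pts["Cz", ] - pts["Nz", ], pts["Iz", ] - pts["Nz", ])
  ct <- plane_mesh_contour(sub$mesh, pts["Nz", ], n, pts["Nz", ])
  sag <- arc_between(ct, pts["Nz", ], ly$entries["Cz", ], pts["Iz", ])
  cat_tbl <- tentwenty_catalogue("10-20")
  sag_tbl <- cat_tbl[cat_tbl$arc == "sagittal", ]
  for (i in seq_len(nrow(sag_tbl))) {
    pr <- cranioguide:::arc_project(sag, ly$entries[sag_tbl$label[i], ])
    expect_lt(abs(pr$s / arc_length(sag) - sag_tbl$fraction[i]), 1e-6)
    expect_lt(pr$distance, 1e-6 * arc_length(sag))
  }
})

test_that("region partition follows the coronal medial line convention", {
  sub <- make_sphere_head(1, 3)
  ly <- region_partition(compute_layout(sub$mesh, canonical_cranial(), "10-10"))
  expect_identical(unname(ly$region["Fpz"]), "anterior")
  expect_identical(unname(ly$region["Oz"]), "posterior")
  expect_identical(unname(ly$region[c("Cz", "C3", "C4")]),
                   rep("both", 3))
  counts <- attr(ly, "counts")
  expect_identical(unname(counts["anterior"] + counts["posterior"] -
                            counts["both"]), nrow(ly$entries))
  bad <- ly
  rownames(bad$entries)[1] <- "XX9"
  expect_error(region_partition(bad), "unknown")
})

test_that("degenerate cranial input fails with a named arc", {
  sub <- make_sphere_head(1, 3)
  cr <- canonical_cranial()
  cr$points["Iz", ] <- cr$points["Nz", ]
  expect_error(compute_layout(sub$mesh, cr, "10-20"), "distinct")
})
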