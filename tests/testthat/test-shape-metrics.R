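# Analytic oracle: a uniform solid ellipsoid with semi-axes (a, b, c) has
# point-cloud covariance diag(a^2, b^2, c^2) / 5, so eigenvalue ratios are
# squared axis ratios.

test_that("covariance eigenvalues match the brute-force voxel oracle exactly", {
  ph <- make_phantom(phantom_spec(shape = "ellipsoid",
                                  semi_axes = c(14, 9, 7), grid = 36))
  ev <- covariance_eigenvalues(ph$volume, 1)
  bf <- brute_force_eigen(ph$volume, 1)
  expect_equal(c(ev$l1, ev$l2, ev$l3), bf, tolerance = 1e-9)
})

test_that("a voxelized sphere has three equal eigenvalues", {
  ev <- covariance_eigenvalues(small_sphere()$volume, 1)
  expect_equal(ev$l2 / ev$l1, 1, tolerance = 0.01)
  expect_equal(ev$l3 / ev$l2, 1, tolerance = 0.01)
  expect_false(ev$degenerate)
})

test_that("a 2:1:1 ellipsoid shows the analytic eigenvalue ratios", {
  ph <- make_phantom(phantom_spec(shape = "ellipsoid",
                                  semi_axes = c(24, 12, 12), grid = 56))
  ev <- covariance_eigenvalues(ph$volume, 1)
  expect_equal(ev$l2 / ev$l1, 0.25, tolerance = 0.02)
  expect_equal(ev$l3 / ev$l2, 1, tolerance = 0.02)
})

test_that("eigenvalues are invariant to rotation of the phantom", {
  base <- make_phantom(phantom_spec(shape = "ellipsoid",
                                    semi_axes = c(24, 12, 12), grid = 64))
  rot <- make_phantom(phantom_spec(shape = "ellipsoid",
                                   semi_axes = c(24, 12, 12), grid = 64,
                                   orientation = c(0, pi / 6, 0)))
  e1 <- covariance_eigenvalues(base$volume, 1)
  e2 <- covariance_eigenvalues(rot$volume, 1)
  expect_equal(c(e2$l1, e2$l2, e2$l3) / c(e1$l1, e1$l2, e1$l3),
               rep(1, 3), tolerance = 0.01)
})

test_that("eigenvalues are invariant to translation and axis permutation", {
  ph <- make_phantom(phantom_spec(shape = "ellipsoid",
                                  semi_axes = c(12, 8, 6), grid = 32))
  g <- ph$volume$grid
  shifted <- array(0L, dim = dim(g) + c(6, 2, 4))
  shifted[7:(6 + dim(g)[1]), 3:(2 + dim(g)[2]), 5:(4 + dim(g)[3])] <- g
  e1 <- covariance_eigenvalues(ph$volume, 1)
  e2 <- covariance_eigenvalues(voxel_volume(shifted, 0.01), 1)
  expect_equal(c(e1$l1, e1$l2, e1$l3), c(e2$l1, e2$l2, e2$l3),
               tolerance = 1e-12)
  perm <- voxel_volume(aperm(g, c(3, 1, 2)), 0.01)
  e3 <- covariance_eigenvalues(perm, 1)
  expect_equal(c(e1$l1, e1$l2, e1$l3), c(e3$l1, e3$l2, e3$l3),
               tolerance = 1e-12)
})

test_that("degenerate labels are rejected, not propagated as NaN", {
  g <- array(0L, dim = c(8, 8, 8))
  g[3, 3, 3] <- 1L
  expect_error(covariance_eigenvalues(voxel_volume(g, 0.01), 1), ">= 4")
  g[3:6, 3, 3] <- 1L  # collinear
  expect_error(compute_shape_metrics(voxel_volume(g, 0.01), 1),
               "coplanar|collinear")
  g2 <- array(0L, dim = c(8, 8, 8))
  g2[3:6, 3:6, 4] <- 1L  # coplanar sheet
  expect_error(compute_shape_metrics(voxel_volume(g2, 0.01), 1),
               "coplanar|collinear")
})

test_that("sphere metrics sit at the spherical reference values", {
  m <- compute_shape_metrics(small_sphere()$volume, 1)
  expect_lt(m$anisotropy, 0.02)
  expect_equal(m$flatness, 1, tolerance = 0.02)
  expect_equal(m$elongation, 1, tolerance = 0.02)
  expect_equal(m$sphericity, 1, tolerance = 0.02)
})

test_that("an axially flattened 0.5:1:1 spheroid loads on anisotropy and flatness", {
  ph <- make_phantom(phantom_spec(shape = "ellipsoid",
                                  semi_axes = c(12, 24, 24), grid = 56))
  m <- compute_shape_metrics(ph$volume, 1)
  expect_equal(m$anisotropy, 0.75, tolerance = 0.02)
  expect_equal(m$elongation, 1, tolerance = 0.02)
  expect_equal(m$flatness, 0.25, tolerance = 0.02)
})

test_that("cube sphericity approaches the closed form (pi/6)^(1/3)", {
  # smoothing rounds the cube's corners, so convergence with resolution is
  # slow; assert monotone approach and closeness at the finest size
  target <- (pi / 6)^(1 / 3)
  errs <- vapply(c(16, 32, 48), function(edge) {
    g <- array(0L, dim = rep(edge + 8L, 3))
    idx <- 5:(4 + edge)
    g[idx, idx, idx] <- 1L
    m <- compute_shape_metrics(voxel_volume(g, 0.01), 1)
    abs(m$sphericity - target)
  }, 0)
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.05)
})

test_that("anisotropy = 1 - flatness x elongation holds to machine precision", {
  for (axes in list(c(10, 10, 10), c(18, 9, 7), c(15, 12, 5))) {
    ph <- make_phantom(phantom_spec(shape = "ellipsoid", semi_axes = axes,
                                    grid = 44))
    ev <- covariance_eigenvalues(ph$volume, 1)
    m <- compute_shape_metrics(ph$volume, 1)
    expect_equal(m$anisotropy, 1 - m$flatness * m$elongation,
                 tolerance = 1e-12)
    expect_equal(m$volume_mm3, ev$n_voxels * prod(ph$volume$spacing),
                 tolerance = 1e-12)
  }
})

test_that("shape is scale invariant; volume and area scale as mm^3 and mm^2", {
  ph <- make_phantom(phantom_spec(shape = "ellipsoid",
                                  semi_axes = c(14, 10, 8), grid = 36))
  m1 <- compute_shape_metrics(ph$volume, 1)
  doubled <- voxel_volume(ph$volume$grid, ph$volume$spacing * 2)
  m2 <- compute_shape_metrics(doubled, 1)
  for (f in c("anisotropy", "flatness", "elongation", "sphericity")) {
    expect_equal(m2[[f]], m1[[f]], tolerance = 1e-10)
  }
  expect_equal(m2$volume_mm3, 8 * m1$volume_mm3, tolerance = 1e-12)
  expect_equal(m2$surface_area_mm2, 4 * m1$surface_area_mm2,
               tolerance = 1e-12)
})

test_that("progressive flattening raises anisotropy and lowers sphericity monotonically", {
  flat <- seq(1, 0.4, length.out = 6)
  res <- t(vapply(flat, function(f) {
    ph <- make_phantom(phantom_spec(shape = "ellipsoid",
                                    semi_axes = c(20 * f, 20, 20),
                                    grid = 52))
    m <- compute_shape_metrics(ph$volume, 1)
    c(m$anisotropy, m$sphericity)
  }, c(0, 0)))
  expect_true(all(diff(res[, 1]) > 0))   # anisotropy strictly increasing
  expect_true(all(diff(res[-1, 2]) < 0)) # sphericity strictly decreasing
  expect_lt(res[2, 2], res[1, 2] + 1e-6) # sphere is the maximum
})

test_that("transverse diameters report the maximum caliper extent", {
  expect_equal(transverse_diameter(small_sphere()$volume, 1, "naso-temporal"),
               0.32, tolerance = 0.01 / 0.32)
  ph <- make_phantom(phantom_spec(shape = "ellipsoid",
                                  semi_axes = c(10, 14, 18), grid = 44))
  expect_equal(transverse_diameter(ph$volume, 1, 3), 36 * 0.01,
               tolerance = 0.01 / 0.36)
  expect_equal(transverse_diameter(ph$volume, 1, "anterior-posterior"),
               20 * 0.01, tolerance = 0.01 / 0.20)
  expect_error(transverse_diameter(ph$volume, 1, "sideways"), "unknown axis")
})

test_that("both-eye measurements average the per-label diameters", {
  g <- array(0L, dim = c(30, 30, 30))
  g[10:20, 10:20, 5:14] <- 1L    # extent 10 voxels along axis 3
  g[10:20, 10:20, 17:28] <- 2L   # extent 12 voxels
  vol <- voxel_volume(g, 0.01)
  d1 <- transverse_diameter(vol, 1, 3)
  d2 <- transverse_diameter(vol, 2, 3)
  expect_equal(paired_eye_diameter(vol, c(1, 2), 3), (d1 + d2) / 2)
  tab <- shape_metric_table(list(sp1 = vol), labels = c(1, 2),
                            mesh_smoothing = 5)
  expect_equal(nrow(tab), 2)
  expect_named(tab, c("specimen_id", "label", "anisotropy", "flatness",
                      "elongation", "sphericity", "volume_mm3",
                      "surface_area_mm2", "diameter_mm"))
})
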