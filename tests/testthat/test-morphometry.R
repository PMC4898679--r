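test_that("vertex areas partition the mesh and converge to the sphere area", {
  s <- icosphere(4, 1)
  av <- mapValues(vertexArea(s))
  expect_equal(sum(av), surfaceArea(s))
  expect_lt(abs(sum(av) - 4 * pi) / (4 * pi), 0.01)
  # barycentric split of a single triangle
  tri <- triSurface(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                    matrix(c(1L, 2L, 3L), 1))
  expect_equal(mapValues(vertexArea(tri)), rep(0.5 / 3, 3))
  # dimensional scaling: coordinates x2 -> areas x4
  s2 <- triSurface(vertices(s) * 2, triangles(s))
  expect_equal(mapValues(vertexArea(s2)), av * 4, tolerance = 1e-12)
})

test_that("mean curvature of a sphere is 1/R and scales as 1/s", {
  for (R in c(20, 50)) {
    h <- mapValues(computeMeanCurvature(icosphere(4, R)))
    expect_equal(mean(h), 1 / R, tolerance = 1e-3)
    expect_lt(sd(h) / mean(h), 0.05)
  }
})

test_that("thickness and sulcal depth behave on concentric spheres", {
  pial <- icosphere(3, 50)
  white <- icosphere(3, 48)
  thk <- mapValues(computeThickness(white, pial))
  expect_true(all(abs(thk - 2) < 0.1))
  expect_error(computeThickness(icosphere(2, 48), pial), "mismatched")
  hull <- computeOuterHull(pial, 15)
  dep <- mapValues(computeSulcalDepth(pial, hull))
  expect_true(all(abs(dep) < 0.2))
})

test_that("outer hull closes sulci, encloses the pial surface, and is the
           identity for convex input or a zero-diameter element", {
  sph <- icosphere(3, 30)
  hull <- computeOuterHull(sph, 15)
  expect_lt(abs(surfaceArea(hull) - surfaceArea(sph)) / surfaceArea(sph), 0.03)
  fx <- foldedFixture(4L)
  expect_lt(surfaceArea(fx$hull), surfaceArea(fx$pial))
  # enclosure: hull radius >= pial radius along every ray
  rp <- sqrt(rowSums(vertices(fx$pial)^2))
  rh <- sqrt(rowSums(vertices(fx$hull)^2))
  expect_true(all(rh >= rp - 1e-9))
  ident <- computeOuterHull(fx$pial, 0)
  expect_equal(vertices(ident), vertices(fx$pial), tolerance = 1e-12)
})

test_that("lGI is 1 on a sphere and matches the parametric area oracle on
           the folded fixture", {
  sph <- icosphere(4, 30)
  hull <- computeOuterHull(sph, 15)
  lgi <- mapValues(computeLGI(sph, hull, radius = 8))
  expect_true(all(abs(lgi - 1) < 0.02))
  fx <- foldedFixture(5L)
  pc <- fx$spec$patch_center
  ctr <- which.max(vertices(fx$pial) %*% pc /
                   sqrt(rowSums(vertices(fx$pial)^2)))
  radius <- 8
  lgiC <- mapValues(computeLGI(fx$pial, fx$hull, radius, at = ctr))[ctr]
  oracle <- parametricPatchAreas(fx$spec, cap = radius / fx$spec$base_radius)
  expect_lt(abs(lgiC - oracle$lgi) / oracle$lgi, 0.05)
})

test_that("peak lGI strictly increases with fold amplitude", {
  vals <- vapply(c(1.5, 3, 4.5), function(a) {
    fs <- generateFoldedSurface(
      foldSpec(fold_amplitude = a, subdivision_level = 4L,
               phase_jitter_sd = 0), seed = 7L)
    hull <- computeOuterHull(fs$pial, 15)
    ctr <- which.max(vertices(fs$pial) %*% foldSpec()$patch_center /
                     sqrt(rowSums(vertices(fs$pial)^2)))
    mapValues(computeLGI(fs$pial, hull, 8, at = ctr))[ctr]
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("lGI rejects a radius below the mesh resolution or beyond the
           surface extent", {
  sph <- icosphere(2, 30)
  hull <- computeOuterHull(sph, 15)
  expect_error(computeLGI(sph, hull, radius = 1), "edge length")
  expect_error(computeLGI(sph, hull, radius = 1000), "extent")
})

test_that("surface smoothing conserves the integral, fixes constants, and
           matches a planar Gaussian kernel", {
  fx <- foldedFixture(4L)
  aw <- mapValues(vertexArea(fx$pial))
  set.seed(3)
  m <- scalarMap(runif(nVertices(fx$pial)), "mm")
  sm <- smoothScalar(fx$pial, m, 5)
  expect_equal(sum(aw * mapValues(sm)), sum(aw * mapValues(m)),
               tolerance = 1e-3)
  expect_true(all(mapValues(sm) > 0))          # positivity preserved
  cst <- scalarMap(rep(2.5, nVertices(fx$pial)))
  expect_identical(mapValues(smoothScalar(fx$pial, cst, 5)),
                   mapValues(cst))
  expect_identical(mapValues(smoothScalar(fx$pial, m, 0)), mapValues(m))
  # impulse on a flat sheet spreads into a 2-D Gaussian of the same FWHM
  sheet <- flatSheet(41L, 41L, 1)
  ctr <- which(vertices(sheet)[, 1] == 0 & vertices(sheet)[, 2] == 0)
  imp <- numeric(nVertices(sheet)); imp[ctr] <- 1
  sm <- mapValues(smoothScalar(sheet, scalarMap(imp), 5))
  r2 <- rowSums(vertices(sheet)[, 1:2]^2)
  sigma2 <- 5^2 / (8 * log(2))
  core <- r2 < (2.5 * sqrt(sigma2))^2
  model <- exp(-r2 / (2 * sigma2))
  model <- model / sum(model)
  aw <- mapValues(vertexArea(sheet))
  obs <- sm * aw / sum(sm * aw)
  expect_lt(max(abs(obs[core] - model[core])) / max(model), 0.10)
})
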