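test_that("tensor metrics match the closed forms", {
  iso <- tensorMetrics(c(1, 1, 1) * 1e-3)
  expect_equal(iso$fa, 0, tolerance = 1e-12)
  expect_equal(iso$md, 1e-3, tolerance = 1e-15)
  expect_equal(iso$ad, 1e-3); expect_equal(iso$rd, 1e-3)
  m <- tensorMetrics(c(1.7, 0.2, 0.2) * 1e-3)
  expect_equal(m$md, 0.7e-3, tolerance = 1e-15)
  expect_equal(m$ad, 1.7e-3); expect_equal(m$rd, 0.2e-3)
  lam <- c(1.7, 0.2, 0.2); md <- mean(lam)
  faRef <- sqrt(1.5 * sum((lam - md)^2) / sum(lam^2))
  expect_equal(m$fa, faRef, tolerance = 1e-12)
  # limiting anisotropy
  expect_equal(tensorMetrics(c(2e-3, 0, 0))$fa, 1, tolerance = 1e-12)
  # all-zero tensor flagged
  expect_true(is.na(tensorMetrics(c(0, 0, 0))$fa))
  expect_error(tensorMetrics(c(0.2, 1.7, 0.2)), "sorted")
  # eigenvalue ordering implies AD >= MD >= RD
  set.seed(1)
  ev <- t(apply(matrix(runif(300, 1e-4, 3e-3), ncol = 3), 1, sort,
                decreasing = TRUE))
  tm <- tensorMetrics(ev)
  expect_true(all(tm$ad >= tm$md & tm$md >= tm$rd))
  expect_true(all(tm$fa >= 0 & tm$fa <= 1))
})

test_that("a planted straight bundle is recovered at its analytic length", {
  vol <- straightPhantom()
  st <- trackWholeVolume(vol)
  expect_gt(nStreamlines(st), 100)
  lens <- streamlineLengths(st)
  expect_true(all(abs(lens - 60) <= 2))
  # planted-bundle traversal: >= 90% of streamlines cover >= 90% of length
  expect_gte(mean(lens >= 0.9 * 60), 0.9)
  # determinism and seed-order invariance (no randomness in tracking)
  st2 <- trackWholeVolume(vol)
  expect_identical(streamlines(st), streamlines(st2))
  # constant-field metric oracle
  mm <- streamlineMeanMetrics(st, vol)
  expect_equal(unname(mm$summary["ad"]), 1.7e-3, tolerance = 0.01)
  expect_equal(unname(mm$summary["md"]), 0.7e-3, tolerance = 0.01)
})

test_that("the 35-degree angle rule splits a right-angle bend", {
  b1 <- bundleSpec("straight", rbind(c(0, 0, -25), c(0, 0, 0)),
                   crossSectionRadius = 3)
  b2 <- bundleSpec("straight", rbind(c(0, 0, 0), c(0, 25, 0)),
                   crossSectionRadius = 3)
  vol <- suppressMessages(
    generateTensorVolume(c(20L, 60L, 60L), 1, list(b1, b2)))
  st <- trackWholeVolume(vol)
  expect_gt(nStreamlines(st), 50)
  # no streamline spans both 25 mm arms
  expect_lt(max(streamlineLengths(st)), 40)
})

test_that("an isotropic volume yields no seeds and a warning", {
  vol <- generateTensorVolume(c(8L, 8L, 8L), 2)
  expect_warning(st <- trackWholeVolume(vol), "FA seed threshold")
  expect_equal(nStreamlines(st), 0L)
})

test_that("surface-ROI voxelization marks centres within the band and is
           translation-equivariant", {
  aff <- diag(4)
  surf <- triSurface(rbind(c(2, 3, 4), c(0, 0, 0)), matrix(integer(0), 0, 3))
  m <- voxelizeSurfaceROI(1L, surf, aff, c(8L, 8L, 8L), band = 0.4)
  expect_true(maskArray(m)[3, 4, 5])
  expect_equal(sum(maskArray(m)), 1L)
  aff2 <- diag(4); aff2[1:3, 4] <- c(1, 0, 0)   # grid shifted +x
  m2 <- voxelizeSurfaceROI(1L, surf, aff2, c(8L, 8L, 8L), band = 0.4)
  expect_true(maskArray(m2)[2, 4, 5])
  expect_equal(sum(maskArray(m2)), 1L)
  # out-of-grid ROI: empty with warning
  far <- triSurface(rbind(c(100, 100, 100)), matrix(integer(0), 0, 3))
  expect_warning(m3 <- voxelizeSurfaceROI(1L, far, aff, c(8L, 8L, 8L)),
                 "outside")
  expect_equal(sum(maskArray(m3)), 0L)
})

test_that("voxel count of a patch mask is proportional to patch area", {
  sph <- icosphere(4, 30)
  dirs <- vertices(sph) / 30
  aff <- diag(c(2, 2, 2, 1)); aff[1:3, 4] <- -47
  aw <- mapValues(vertexArea(sph))
  counts <- vapply(c(0.3, 0.45), function(w) {
    idx <- which(acos(pmin(1, dirs[, 1])) < w)
    m <- voxelizeSurfaceROI(idx, sph, aff, c(48L, 48L, 48L), band = 1)
    c(sum(maskArray(m)), sum(aw[idx]))
  }, numeric(2))
  ratio <- counts[1, ] / counts[2, ]
  expect_lt(abs(ratio[1] / ratio[2] - 1), 0.2)
})

test_that("endpoint dissection keeps endpoint hits, drops pass-throughs,
           and is an idempotent subset", {
  aff <- diag(4)
  mask <- array(FALSE, c(10, 10, 10))
  mask[5:6, 5:6, 5:6] <- TRUE
  vm <- new("VoxelMask", mask = mask, affine = aff)
  inside <- cbind(4.2, 4.2, seq(4.2, 5.2, length.out = 5))       # ends inside
  through <- cbind(seq(0, 9, length.out = 12), 4.8, 4.8)         # passes through
  outside <- cbind(seq(0, 2, length.out = 5), 1, 1)
  st <- streamlineSet(list(inside, through, outside))
  d <- dissectByEndpoints(st, vm)
  expect_equal(nStreamlines(d), 1L)
  expect_equal(streamlines(d)[[1]], inside)
  expect_identical(streamlines(dissectByEndpoints(d, vm)), streamlines(d))
  empty <- new("VoxelMask", mask = array(FALSE, c(10, 10, 10)), affine = aff)
  expect_equal(nStreamlines(dissectByEndpoints(st, empty)), 0L)
})

test_that("set-level means average streamline means unweighted, with
           explicit missing values for empty sets", {
  b1 <- bundleSpec("straight", rbind(c(-6, 0, -15), c(-6, 0, 15)),
                   crossSectionRadius = 2.5,
                   eigenvalues = c(1.0, 0.3, 0.3) * 1e-3)
  b2 <- bundleSpec("straight", rbind(c(6, 0, -15), c(6, 0, 15)),
                   crossSectionRadius = 2.5,
                   eigenvalues = c(2.0, 0.3, 0.3) * 1e-3)
  vol <- generateTensorVolume(c(24L, 12L, 40L), 1, list(b1, b2))
  st <- trackWholeVolume(vol)
  mm <- streamlineMeanMetrics(st, vol)
  per <- streamlineMetrics(mm$streams)
  n1 <- sum(abs(per$ad - 1.0e-3) < 1e-4)
  n2 <- sum(abs(per$ad - 2.0e-3) < 1e-4)
  expect_gt(min(n1, n2), 50)
  # the set mean equals the count-weighted average of the two bundle means
  expect_equal(unname(mm$summary["ad"]),
               (n1 * 1.0e-3 + n2 * 2.0e-3) / (n1 + n2), tolerance = 0.02)
  empty <- streamlineSet(list())
  em <- streamlineMeanMetrics(empty, vol)
  expect_true(all(is.na(em$summary)))
})
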