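test_that("folded surface generation is deterministic and controlled by the
           fold amplitude", {
  sp <- foldSpec(fold_amplitude = 0)
  fs <- generateFoldedSurface(sp, seed = 3L)
  # zero amplitude: exact sphere of the base radius
  expect_equal(sqrt(rowSums(vertices(fs$pial)^2)),
               rep(sp$base_radius, nVertices(fs$pial)), tolerance = 1e-12)
  sp2 <- foldSpec(fold_amplitude = 3)
  a1 <- generateFoldedSurface(sp2, seed = 5L)
  a2 <- generateFoldedSurface(sp2, seed = 5L)
  expect_identical(vertices(a1$pial), vertices(a2$pial))
  expect_false(identical(vertices(a1$pial),
                         vertices(generateFoldedSurface(sp2, 6L)$pial)))
  # doubling the amplitude strictly increases total pial area
  a4 <- generateFoldedSurface(foldSpec(fold_amplitude = 6), seed = 5L)
  expect_gt(surfaceArea(a4$pial), surfaceArea(a1$pial))
  # white surface is offset inward by the spec thickness
  d <- sqrt(rowSums((vertices(a1$pial) - vertices(a1$white))^2))
  expect_equal(d, rep(sp2$thickness, length(d)), tolerance = 1e-9)
  # self-intersecting requests are rejected with a diagnostic: amplitude
  # exceeding the radius, or an inward offset exceeding the sulcal
  # curvature radius
  expect_error(generateFoldedSurface(
    foldSpec(base_radius = 30, fold_amplitude = 31), seed = 1L),
    "non-positive")
  expect_error(generateFoldedSurface(
    foldSpec(fold_amplitude = 6, thickness = 8), seed = 1L),
    "self-intersecting white")
})

test_that("tensor phantom voxels carry the requested anisotropy and the
           background stays below the tracking threshold", {
  vol <- straightPhantom()
  fa <- faMap(vol)
  # background isotropic: FA exactly 0
  expect_equal(fa[1, 1, 1], 0)
  expect_lt(max(fa[, , 1]), 0.2)
  # bundle-core voxel matches the closed-form FA of (1.7, 0.2, 0.2)e-3
  ctr <- (dim(fa) + 1) %/% 2
  faRef <- tensorMetrics(c(1.7, 0.2, 0.2) * 1e-3)$fa
  expect_equal(fa[ctr[1], ctr[2], 20], faRef, tolerance = 1e-12)
  # planted U-bundle arc length matches the analytic value
  ub <- bundleSpec("u_shaped", rbind(c(-11, 0, 0), c(0, -5, 0), c(11, 0, 0)),
                   crossSectionRadius = 2.5)
  chord <- 22; sag <- 5
  rho <- (chord^2 / 4 + sag^2) / (2 * sag)
  expect_equal(bundleLength(ub), 2 * rho * asin(chord / 2 / rho),
               tolerance = 1e-6)
  # overlapping bundles resolved by precedence, reported
  b1 <- bundleSpec("straight", rbind(c(0, 0, -10), c(0, 0, 10)),
                   crossSectionRadius = 3,
                   eigenvalues = c(1.7, 0.2, 0.2) * 1e-3)
  b2 <- bundleSpec("straight", rbind(c(0, -10, 0), c(0, 10, 0)),
                   crossSectionRadius = 3,
                   eigenvalues = c(1.2, 0.3, 0.3) * 1e-3)
  expect_message(v2 <- generateTensorVolume(c(16L, 16L, 16L), 2,
                                            list(b1, b2)), "overlap")
  expect_gt(attr(v2@data, "overlap"), 0)
  # the contested centre voxel belongs to the first bundle (z tangent)
  ctr <- c(8, 8, 8)
  expect_equal(v2@data[8, 8, 8, 6], 1.7e-3, tolerance = 1e-9)
  # a bundle outside the grid is rejected
  expect_error(generateTensorVolume(c(10L, 10L, 10L), 1, list(b1)), "bounds")
})

test_that("cohort generator reproduces the planted group structure", {
  spec <- cohortSpec()
  coh <- generateCohort(spec)
  expect_equal(nrow(coh), 99L)
  expect_equal(sum(coh$group == 1), 51L)
  expect_equal(sum(coh$group == 0), 48L)
  expect_identical(coh, generateCohort(spec))     # deterministic
  # large-n convergence of the planted means/SDs (within 2%)
  big <- cohortSpec(n_group1 = 5000L, n_group2 = 5000L, seed = 9L)
  bc <- generateCohort(big)
  expect_lt(abs(mean(bc$lgi[bc$group == 0]) - big$lgi_mean) / big$lgi_mean,
            0.02)
  expect_lt(abs(sd(bc$ad_short) / 0.04e-3 - 1), 0.10)
  totalDelta <- big$group_ad_delta + big$coupling_slope * big$group_lgi_delta
  obsDelta <- mean(bc$ad_short[bc$group == 1]) -
    mean(bc$ad_short[bc$group == 0])
  expect_lt(abs(obsDelta - totalDelta) / totalDelta, 0.10)
  # null generator: downstream coupling slope estimate ~ 0
  null <- cohortSpec(group_lgi_delta = 0, group_ad_delta = 0,
                     coupling_slope = 0, seed = 4L)
  nc <- generateCohort(null)
  sl <- coef(lm(ad_short ~ lgi, nc))["lgi"]
  se <- summary(lm(ad_short ~ lgi, nc))$coefficients["lgi", "Std. Error"]
  expect_lt(abs(sl), 3 * se)
})

test_that("ordinary least squares recovers the planted coupling slope", {
  # Monte-Carlo over replicate cohorts with small noise
  slopes <- vapply(1:200, function(r) {
    spec <- cohortSpec(coupling_slope = 3e-4, noise_sd_ad = 1e-5, seed = r)
    coh <- generateCohort(spec)
    coef(lm(ad_short ~ lgi + group + center, coh))["lgi"]
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 3e-4) / 3e-4, 0.10)
})

test_that("cohort AD summaries emulate the reported short-streamline row", {
  # group means ~ 1.10 vs 1.08 (x10^-3 mm^2/s), SD ~ 0.04
  reps <- vapply(1:40, function(r) {
    coh <- generateCohort(cohortSpec(seed = r))
    c(mean(coh$ad_short[coh$group == 1]), mean(coh$ad_short[coh$group == 0]),
      sd(coh$ad_short[coh$group == 1]), sd(coh$ad_short[coh$group == 0]))
  }, numeric(4))
  m <- rowMeans(reps) * 1e3
  expect_equal(round(m[1], 2), 1.10)
  expect_equal(round(m[2], 2), 1.08)
  expect_equal(m[3], 0.04, tolerance = 0.15)
  expect_equal(m[4], 0.04, tolerance = 0.15)
})

test_that("a majority of replicate cohorts show the planted short-tract AD
           group effect at the initial test-wise rate", {
  hits <- vapply(1:100, function(r) {
    coh <- generateCohort(cohortSpec(seed = 1000L + r))
    g <- fitGroupGLM(coh$ad_short, coh$group, coh$center, coh$age, coh$fsiq)
    g$p < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})
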