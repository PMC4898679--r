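test_that("dip statistic reproduces analytic point-mass values and floors", {
  # two point masses: dip = min(p, 1-p)/2, independent of spacing
  for (n in c(8L, 20L, 50L)) {
    for (p in c(0.5, 0.3, 0.1)) {
      m <- round(n * p)
      x <- c(rep(0, m), rep(7.3, n - m))
      expect_equal(dipStatistic(x), min(m, n - m) / (2 * n),
                   tolerance = 1e-12)
    }
  }
  # identical values: the minimum attainable dip for that n
  expect_equal(dipStatistic(rep(3, 10)), 1 / 20)
  # three equal masses
  expect_equal(dipStatistic(rep(c(0, 1, 2), each = 10)), 1 / 6,
               tolerance = 1e-12)
  # quantile grid of a unimodal distribution: dip at the 1/(2n) floor
  x <- qnorm((1:200 - 0.5) / 200)
  expect_equal(dipStatistic(x), 1 / 400, tolerance = 1e-9)
  expect_error(dipStatistic(c(1, 2, 3)), "n >= 4")
})

test_that("dip agrees with the band-feasibility brute-force oracle on random
           small samples", {
  set.seed(42)
  for (r in 1:60) {
    n <- sample(5:30, 1)
    x <- switch(sample(3, 1),
                rnorm(n),
                c(rnorm(ceiling(n / 2)), rnorm(floor(n / 2), 4, 0.3)),
                sample(0:3, n, replace = TRUE))
    expect_equal(dipStatistic(x), dipOracle(x), tolerance = 1e-6,
                 info = paste("replicate", r))
  }
})

test_that("dip separates bimodal from uniform samples and is affine
           invariant", {
  set.seed(2)
  bim <- c(rnorm(150, 22, 2), rnorm(150, 60, 3))
  uni <- runif(300)
  expect_gt(dipStatistic(bim), 3 * dipStatistic(uni))
  z <- rnorm(100)
  expect_equal(dipStatistic(z), dipStatistic(5 - 2 * z), tolerance = 1e-12)
})

test_that("dip p-value is deterministic given the seed and powerful for
           strong bimodality", {
  set.seed(8)
  x <- c(rnorm(500, 20, 2), rnorm(500, 60, 3))
  d <- dipStatistic(x)
  p1 <- dipPvalue(d, length(x), nBoot = 1000L, seed = 5L)$p
  p2 <- dipPvalue(d, length(x), nBoot = 1000L, seed = 5L)$p
  expect_identical(p1, p2)
  expect_lt(p1, 0.001)
})

test_that("EM recovers single-Gaussian and mixture parameters", {
  set.seed(31)
  x <- rnorm(2000, 50, 7)
  f1 <- fitGmmEM(x, 1)
  expect_equal(f1@means, mean(x), tolerance = 1e-12)
  expect_equal(f1@sds, sqrt(mean((x - mean(x))^2)), tolerance = 1e-12)
  expect_equal(f1@weights, 1)
  # component recovery within ~2 SE at n = 2000
  expect_lt(abs(f1@means - 50), 2 * 7 / sqrt(2000) * 2)
  # weights sum to one; density integrates to one
  set.seed(32)
  y <- c(rnorm(1200, 22, 5), rnorm(700, 55, 12), rnorm(100, 110, 20))
  f3 <- fitGmmEM(y, 3, seed = 2)
  expect_equal(sum(f3@weights), 1, tolerance = 1e-8)
  grid <- seq(-200, 400, length.out = 20001)
  dens <- mixtureDensity(f3, grid)
  expect_equal(sum(dens) * diff(grid)[1], 1, tolerance = 1e-6)
  expect_false(is.unsorted(f3@means))
})

test_that("EM matches the reference mixture fitter on a fixed sample", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  set.seed(33)
  y <- c(rnorm(1500, 25, 5), rnorm(1500, 60, 10))
  f <- fitGmmEM(y, 2, seed = 3, nRestarts = 4L)
  ref <- mclust::Mclust(y, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(f@means), sort(as.numeric(ref$parameters$mean)),
               tolerance = 0.02)
  expect_equal(f@logLik, ref$loglik, tolerance = 1e-4)
})

test_that("cutoffs sit at the posterior-0.5 density crossing", {
  m <- new("MixtureModel", k = 2L, weights = c(0.5, 0.5),
           means = c(20, 60), sds = c(5, 5), logLik = 0)
  expect_equal(classCutoffs(m), 40, tolerance = 1e-9)  # symmetric midpoint
  # equal sds, unequal weights: the boundary shifts toward the lighter
  # component
  mW <- new("MixtureModel", k = 2L, weights = c(0.8, 0.2),
            means = c(20, 60), sds = c(5, 5), logLik = 0)
  expect_gt(classCutoffs(mW), 40)
  # general case matches a fine-grid density-crossing scan
  m2 <- new("MixtureModel", k = 2L, weights = c(0.8, 0.2),
            means = c(20, 60), sds = c(5, 8), logLik = 0)
  cut2 <- classCutoffs(m2)
  grid <- seq(20, 60, length.out = 200001)
  d1 <- 0.8 * dnorm(grid, 20, 5); d2 <- 0.2 * dnorm(grid, 60, 8)
  gridCut <- grid[which(d1 > d2 & c(d1[-1] <= d2[-1], FALSE))[1]]
  expect_equal(cut2, gridCut, tolerance = 1e-3)
  # cutoffs lie strictly between adjacent means
  expect_true(cut2 > 20 && cut2 < 60)
  expect_error(classCutoffs(fitGmmEM(rnorm(100), 1)), "2 components")
})

test_that("short/long splitting uses half-open boundary semantics and
           conserves counts", {
  pts <- lapply(c(25, 30, 100, 160), function(L)
    cbind(0, 0, seq(0, L, by = 1)))
  st <- streamlineSet(pts)
  sp <- splitShortLong(st, cutoffMm = 30, upperMm = 150)
  expect_equal(streamlineLengths(sp$short), 25)
  expect_equal(sort(streamlineLengths(sp$long)), c(30, 100))
  expect_equal(sp$nExcluded, 1L)
  expect_equal(nStreamlines(sp$short) + nStreamlines(sp$long) + sp$nExcluded,
               nStreamlines(st))
  # cutoff at the minimum length: short class empty
  sp2 <- splitShortLong(st, cutoffMm = 25, upperMm = 150)
  expect_equal(nStreamlines(sp2$short), 0L)
})

test_that("split-half cross-validation prefers one component for Gaussian
           data", {
  set.seed(44)
  x <- rnorm(3000, 40, 8)
  sel <- selectKCrossval(x, 1:3, seed = 9L)
  expect_equal(sel$k, 1L)
})
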