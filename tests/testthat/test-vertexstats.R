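# small shared simulation helpers for the vertex-statistics tests
vsFixture <- function() {
  fixture("vsFixture", function() {
    surf <- icosphere(3, 30)
    op <- foldconn:::smoothingOperator(surf, 10)
    smooth <- function(M) {
      for (i in seq_len(op$niter)) M <- as.matrix(op$S %*% M)
      M
    }
    list(surf = surf, smooth = smooth, V = nVertices(surf))
  })
}

test_that("the vertex GLM reproduces the classical two-sample t and flags
           degenerate vertices", {
  set.seed(21)
  n <- 24; V <- 50
  g <- rep(0:1, each = n / 2)
  Y <- matrix(rnorm(V * n), V, n)
  Y[1, ] <- 5                                  # constant map: t undefined
  X <- cbind(1, group = g); colnames(X) <- c("(Intercept)", "group")
  fit <- fitVertexGLM(Y, X)
  tref <- apply(Y[-1, ], 1, function(y)
    t.test(y[g == 1], y[g == 0], var.equal = TRUE)$statistic)
  expect_equal(mapValues(fit$t)[-1], unname(tref), tolerance = 1e-10)
  expect_true(is.na(mapValues(fit$t)[1]))
  expect_equal(fit$df, n - 2)
  # rank-deficient design names the collinear column
  Xbad <- cbind(X, dup = g)
  expect_error(fitVertexGLM(Y, Xbad), "collinear.*dup")
})

test_that("planted group effects yield the closed-form expected t inside the
           patch and null t elsewhere", {
  fx <- vsFixture()
  set.seed(22)
  n <- 30; g <- rep(0:1, each = 15)
  delta <- 1; sigma <- 1
  patch <- which(vertices(fx$surf)[, 3] > 27)
  reps <- 60
  tbar <- 0
  for (r in seq_len(reps)) {
    Y <- matrix(rnorm(fx$V * n, 0, sigma), fx$V, n)
    Y[patch, g == 1] <- Y[patch, g == 1] + delta
    X <- cbind(1, group = g); colnames(X) <- c("(Intercept)", "group")
    tbar <- tbar + mean(mapValues(fitVertexGLM(Y, X)$t)[patch])
  }
  tbar <- tbar / reps
  expected <- delta / (sigma * sqrt(1 / 15 + 1 / 15))
  expect_equal(tbar, expected, tolerance = 0.1)
})

test_that("null t-maps follow the Student t distribution", {
  fx <- vsFixture()
  set.seed(23)
  n <- 20; g <- rep(0:1, each = 10)
  X <- cbind(1, group = g); colnames(X) <- c("(Intercept)", "group")
  tv <- c()
  for (r in 1:10) {
    Y <- matrix(rnorm(fx$V * n), fx$V, n)
    tv <- c(tv, mapValues(fitVertexGLM(Y, X)$t))
  }
  ks <- ks.test(tv, function(q) pt(q, n - 2))
  expect_gt(ks$p.value, 0.01)
})

test_that("a degenerate cluster-forming threshold returns one cluster
           covering the surface, and empty suprathreshold sets are fine", {
  fx <- vsFixture()
  set.seed(24)
  n <- 20; g <- rep(0:1, each = 10)
  X <- cbind(1, group = g); colnames(X) <- c("(Intercept)", "group")
  Y <- fx$smooth(matrix(rnorm(fx$V * n), fx$V, n))
  fit <- fitVertexGLM(Y, X)
  rcAll <- rftClusterCorrect(fit$t, fit$residuals, fx$surf, fit$df,
                             clusterFormingP = 1, twoTailed = FALSE)
  expect_equal(length(rcAll$clusters), 1L)
  expect_equal(length(clusterVertices(rcAll$clusters[[1]])), fx$V)
  rcNone <- rftClusterCorrect(scalarMap(rep(0.1, fx$V), "t"), fit$residuals,
                              fx$surf, fit$df, clusterFormingP = 1e-8)
  expect_equal(length(rcNone$clusters), 0L)
})

test_that("a planted strong focal effect produces exactly one significant
           cluster containing the patch centre", {
  fx <- vsFixture()
  set.seed(25)
  n <- 40; g <- rep(0:1, each = 20)
  X <- cbind(1, group = g); colnames(X) <- c("(Intercept)", "group")
  ctr <- which.max(vertices(fx$surf)[, 3])
  patch <- which(vertices(fx$surf)[, 3] > 25)
  Y <- fx$smooth(matrix(rnorm(fx$V * n), fx$V, n))
  Y[patch, g == 1] <- Y[patch, g == 1] + 2
  fit <- fitVertexGLM(Y, X)
  rc <- rftClusterCorrect(fit$t, fit$residuals, fx$surf, fit$df)
  sig <- rc$clusters[rc$significant]
  expect_equal(length(sig), 1L)
  expect_true(ctr %in% clusterVertices(sig[[1]]))
})

test_that("RFT and permutation cluster p-values agree for moderate effects", {
  fx <- vsFixture()
  set.seed(26)
  n <- 40; g <- rep(0:1, each = 20)
  center <- rep(c("c1", "c2"), n / 2)
  X <- model.matrix(~ g + factor(center))
  colnames(X)[2] <- "group"
  patch <- which(vertices(fx$surf)[, 3] > 24)
  diffs <- c()
  for (r in 1:3) {
    Y <- fx$smooth(matrix(rnorm(fx$V * n), fx$V, n))
    Y[patch, g == 1] <- Y[patch, g == 1] + 0.55   # marginal effect
    fit <- fitVertexGLM(Y, X)
    rc <- rftClusterCorrect(fit$t, fit$residuals, fx$surf, fit$df)
    if (!length(rc$clusters)) next
    po <- permutationClusterOracle(Y, g, center, surface = fx$surf,
                                   nPerm = 600L, seed = 100L + r)
    # match clusters by peak t
    for (ci in seq_along(rc$clusters)) {
      pk <- rc$clusters[[ci]]@peakT
      j <- which.min(abs(po$peakT - pk))
      pR <- rc$clusters[[ci]]@p; pP <- po$pPerm[j]
      if (pP >= 0.01 && pP <= 0.2) diffs <- c(diffs, pR - pP)
    }
  }
  expect_gt(length(diffs), 0)
  expect_lt(max(abs(diffs)), 0.05)
  # determinism of the permutation oracle
  set.seed(27)
  Y <- fx$smooth(matrix(rnorm(fx$V * n), fx$V, n))
  Y[patch, g == 1] <- Y[patch, g == 1] + 0.8
  p1 <- permutationClusterOracle(Y, g, center, surface = fx$surf,
                                 nPerm = 500L, seed = 7L)
  p2 <- permutationClusterOracle(Y, g, center, surface = fx$surf,
                                 nPerm = 500L, seed = 7L)
  expect_identical(p1$pPerm, p2$pPerm)
})

test_that("cluster mirroring is an involution that preserves cardinality and
           maps a lateral patch to a disjoint homolog", {
  surf <- icosphere(3, 30)
  corr <- mirrorCorrespondence(surf)
  ctr <- which.max(vertices(surf)[, 1] * 0.8 + vertices(surf)[, 2] * 0.5)
  d <- geodesicDistances(surf, from = ctr)
  roi <- which(d[1, ] < 12)
  cl <- new("ClusterResult", vertices = as.integer(roi), peakT = 5,
            peakVertex = as.integer(ctr), p = 0.01, areaMM2 = 1,
            resels = 1, sign = 1)
  mir <- mirrorCluster(cl, corr)
  expect_equal(length(mir), length(roi))
  expect_length(intersect(mir, roi), 0)
  expect_setequal(corr[mir], roi)             # involution
  aw <- mapValues(vertexArea(surf))
  expect_equal(sum(aw[mir]), sum(aw[roi]), tolerance = 0.01)
  expect_error(mirrorCluster(cl, corr[1:10]), "correspondence")
})
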