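test_that("Bonferroni threshold arithmetic", {
  expect_equal(bonferroniThreshold(0.05, 8), 0.00625)
  expect_equal(bonferroniThreshold(0.04, 1), 0.04)
  expect_equal(bonferroniThreshold(0.05, 5), 0.01)
  expect_error(bonferroniThreshold(1.2, 4))
})

test_that("group GLM with intercept and group only reproduces the two-sample
           t (F = t^2), and collinearity errors are explicit", {
  set.seed(51)
  g <- rep(0:1, each = 20)
  y <- rnorm(40) + 0.5 * g
  one <- rep("c1", 40)
  fitF <- fitGroupGLM(y, g, one)$F
  tt <- t.test(y[g == 1], y[g == 0], var.equal = TRUE)$statistic
  expect_equal(fitF, unname(tt^2), tolerance = 1e-10)
  # group fully confounded with center
  expect_error(fitGroupGLM(y, g, ifelse(g == 1, "c1", "c2")), "collinear")
})

test_that("group GLM null p-values are uniform", {
  set.seed(52)
  ps <- vapply(1:400, function(r) {
    coh <- generateCohort(cohortSpec(n_group1 = 30L, n_group2 = 30L,
                                     group_lgi_delta = 0, group_ad_delta = 0,
                                     coupling_slope = 0, seed = 5000L + r))
    fitGroupGLM(coh$ad_short, coh$group, coh$center, coh$age, coh$fsiq)$p
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.03)
})

test_that("moderation GLM recovers a planted slope, keeps the interaction
           null calibrated, and flags degenerate fits", {
  set.seed(53)
  nRep <- 200
  z <- matrix(NA_real_, nRep, 2)  # slope estimate, interaction p
  for (r in seq_len(nRep)) {
    n <- 99
    g <- rep(0:1, length.out = n)
    ctr <- rep(c("c1", "c1", "c2"), length.out = n)
    x <- rnorm(n)
    y <- 0.5 * x + rnorm(n, 0, 1)
    f <- fitModerationGLM(y, x, g, ctr, standardize = FALSE)
    z[r, ] <- c(f$coef["x"], f$p["interaction"])
  }
  expect_lt(abs(mean(z[, 1]) - 0.5), 2 * sd(z[, 1]) / sqrt(nRep) * 3)
  expect_lt(abs(mean(z[, 2] < 0.05) - 0.05), 0.04)
  # pure group effect with zero slope: predictor p uniform-ish, group strong
  set.seed(54)
  pg <- vapply(1:150, function(r) {
    n <- 99; g <- rep(0:1, length.out = n)
    ctr <- rep(c("c1", "c1", "c2"), length.out = n)
    x <- rnorm(n)
    y <- 1.0 * g + rnorm(n)
    f <- fitModerationGLM(y, x, g, ctr, standardize = FALSE)
    c(f$p["group"], f$p["predictor"])
  }, numeric(2))
  expect_gt(mean(pg[1, ] < 0.05), 0.9)
  expect_lt(abs(mean(pg[2, ] < 0.05) - 0.05), 0.05)
  # response == predictor: degenerate-fit flag (lm also warns about the
  # perfect fit, hence capture_warnings)
  x <- rnorm(60)
  w <- capture_warnings(
    f <- fitModerationGLM(x, x, rep(0:1, 30), rep("c1", 60),
                          standardize = FALSE))
  expect_true(any(grepl("degenerate", w)))
  expect_true(f$degenerate)
  expect_equal(unname(f$coef["x"]), 1, tolerance = 1e-8)
})

test_that("SURE equals OLS under identical regressors and its chi-squared
           equality test is calibrated under the null", {
  set.seed(55)
  n <- 99
  X <- cbind(1, g = rep(0:1, length.out = n), z = rnorm(n))
  y1 <- X %*% c(0, 0.4, 0.2) + rnorm(n)
  y2 <- X %*% c(1, 0.1, -0.3) + rnorm(n)
  s <- sureFit(y1, X, y2, X)
  b1 <- qr.solve(X, y1); b2 <- qr.solve(X, y2)
  expect_equal(unname(s$coef[1:3]), unname(drop(b1)), tolerance = 1e-8)
  expect_equal(unname(s$coef[4:6]), unname(drop(b2)), tolerance = 1e-8)
  # null calibration of the cross-equation test with equal true effects
  rej <- vapply(1:2000, function(r) {
    set.seed(60000 + r)
    g <- rep(0:1, length.out = n)
    X <- cbind("(Intercept)" = 1, g = g)
    e <- matrix(rnorm(2 * n), n, 2) %*% chol(matrix(c(1, .5, .5, 1), 2))
    y1 <- 0.3 * g + e[, 1]
    y2 <- 0.3 * g + e[, 2]
    s <- sureFit(y1, X, y2, X)
    sureCompare(s, c("eq1:g", "eq2:g"))$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.02)
  # power grows with the planted cross-equation asymmetry
  power <- vapply(c(0.3, 0.6), function(delta) {
    mean(vapply(1:200, function(r) {
      set.seed(70000 + 1000 * delta + r)
      g <- rep(0:1, length.out = n)
      X <- cbind("(Intercept)" = 1, g = g)
      y1 <- (0.2 + delta) * g + rnorm(n)
      y2 <- 0.2 * g + rnorm(n)
      s <- sureFit(y1, X, y2, X)
      sureCompare(s, c("eq1:g", "eq2:g"))$p < 0.05
    }, logical(1)))
  }, numeric(1))
  expect_gt(power[2], power[1])
  expect_gt(power[2], 0.5)
  expect_error(sureCompare(s, c("eq1:g", "nope")), "unknown")
})

test_that("partial correlation reduces to Pearson, honors deterministic
           relations, and removes covariate-mediated association", {
  set.seed(56)
  x <- rnorm(80); y <- 0.5 * x + rnorm(80)
  pc <- partialCorrelation(x, y)
  expect_equal(pc$r, cor(x, y), tolerance = 1e-12)
  expect_equal(pc$p, cor.test(x, y)$p.value, tolerance = 1e-10)
  z <- rnorm(80)
  expect_equal(partialCorrelation(x, x + 0 * z, data.frame(z = z))$r, 1,
               tolerance = 1e-8)
  # x and y associated only through z: partial r ~ 0 while raw r is not
  set.seed(57)
  rs <- vapply(1:100, function(r) {
    z <- rnorm(120)
    x <- z + rnorm(120, 0, 0.5)
    y <- z + rnorm(120, 0, 0.5)
    c(raw = cor(x, y), par = partialCorrelation(x, y, data.frame(z))$r)
  }, numeric(2))
  expect_gt(mean(rs["raw", ]), 0.5)
  expect_lt(abs(mean(rs["par", ])), 0.05)
  expect_error(partialCorrelation(rep(1, 50), rnorm(50)), "constant")
})
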