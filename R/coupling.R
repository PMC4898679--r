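#' Per-metric group GLM for tract diffusion measures
#'
#' Linear model `metric ~ group + center + age + fsiq` per metric, with the
#' F-test (df = 1) for the group coefficient.  Subjects with a missing
#' metric value (e.g. an empty tract class) are dropped from that model
#' only, with the count reported.
#'
#' @param metric numeric response vector (one value per subject; NA
#'   allowed).
#' @param group 0/1 group indicator.
#' @param center acquisition-center factor.
#' @param age,fsiq continuous covariates (optional, NULL to omit).
#' @return list with `F` (df = 1), `p`, `beta` (group coefficient), `df2`,
#'   `nDropped`, and the fitted `lm` object.
#' @export
fitGroupGLM <- function(metric, group, center, age = NULL, fsiq = NULL) {
  if (length(metric) <= 6) stop("need more than 6 subjects")
  d <- data.frame(y = metric, group = group, center = factor(center))
  if (nlevels(d$center) < 2L) d$center <- NULL   # single-center data
  if (!is.null(age)) d$age <- age
  if (!is.null(fsiq)) d$fsiq <- fsiq
  ok <- complete.cases(d)
  d <- d[ok, , drop = FALSE]
  X <- model.matrix(~ ., d[, -1, drop = FALSE])
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient design: group is collinear with ",
         paste(colnames(X)[-(1:2)], collapse = "/"))
  fit <- lm(y ~ ., data = d)
  sm <- summary(fit)
  co <- sm$coefficients["group", ]
  Fg <- co["t value"]^2
  list(F = unname(Fg), p = unname(co["Pr(>|t|)"]), beta = unname(co["Estimate"]),
       df2 = fit$df.residual, nDropped = sum(!ok), fit = fit)
}

#' Bonferroni-corrected per-test threshold
#'
#' @param alpha family-wise error rate, in (0, 1).
#' @param nTests number of independent comparisons (>= 1).
#' @return the corrected test-wise threshold `alpha / nTests` (e.g. 0.05
#'   over 8 tract-class x metric tests gives 0.00625).
#' @export
bonferroniThreshold <- function(alpha, nTests) {
  stopifnot(alpha > 0, alpha < 1, nTests >= 1)
  alpha / nTests
}

#' Moderation GLM between a diffusion metric and local gyrification
#'
#' Fits `response ~ group + predictor + group:predictor + center`, the
#' model used in both directions (diffusivity on lGI and lGI on
#' diffusivity).  The continuous predictor is z-standardized before the
#' interaction is formed, so main effects are interpretable at the mean
#' and cross-direction coefficients are on a common scale; the response is
#' standardized too when `standardize = TRUE` (default).
#'
#' @param response numeric vector.
#' @param predictor numeric vector.
#' @param group 0/1 indicator.
#' @param center center factor.
#' @param standardize z-score response and predictor first (default TRUE).
#' @return list with per-term `F` (df = 1) and `p` (terms: group,
#'   predictor, interaction), `coef`, `df2`, `degenerate` (TRUE when the
#'   fit has ~zero residual variance), and the `lm` fit.
#' @export
fitModerationGLM <- function(response, predictor, group, center,
                             standardize = TRUE) {
  z <- function(v) {
    s <- sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0) stop("constant variable cannot be modeled")
    (v - mean(v, na.rm = TRUE)) / s
  }
  d <- data.frame(y = if (standardize) z(response) else response,
                  x = if (standardize) z(predictor) else
                    predictor - mean(predictor, na.rm = TRUE),
                  group = group, center = factor(center))
  d <- d[complete.cases(d), , drop = FALSE]
  form <- if (nlevels(droplevels(d$center)) >= 2L)
    y ~ group + x + group:x + center else y ~ group + x + group:x
  fit <- lm(form, data = d)
  if (qr(model.matrix(fit))$rank < ncol(model.matrix(fit)))
    stop("rank-deficient moderation design")
  sm <- summary(fit)
  co <- sm$coefficients
  terms <- c(group = "group", predictor = "x", interaction = "group:x")
  Fv <- setNames(co[terms, "t value"]^2, names(terms))
  pv <- setNames(co[terms, "Pr(>|t|)"], names(terms))
  degenerate <- sm$sigma^2 < 1e-12 * var(d$y)
  if (degenerate)
    warning("degenerate fit: residual variance is (near) zero")
  list(F = Fv, p = pv, coef = co[, "Estimate"], df2 = fit$df.residual,
       degenerate = degenerate, fit = fit)
}

#' Seemingly unrelated regression of two equations
#'
#' Joint feasible-generalized-least-squares estimation of two regressions
#' sharing the same subjects, with cross-equation residual covariance
#' estimated from equation-wise OLS.  With identical regressor matrices
#' SURE collapses to equation-by-equation OLS (the classical degeneracy).
#'
#' @param y1,y2 response vectors (same subjects).
#' @param X1,X2 design matrices including intercepts.
#' @return a `SureResult` (classed list): `coef` (named
#'   "eq1:<col>"/"eq2:<col>"), `vcov`, `sigma` (2 x 2 residual
#'   covariance), `n`.
#' @export
sureFit <- function(y1, X1, y2, X2) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  n <- length(y1)
  stopifnot(length(y2) == n, nrow(X1) == n, nrow(X2) == n)
  b1 <- qr.solve(X1, y1); b2 <- qr.solve(X2, y2)
  r1 <- y1 - X1 %*% b1; r2 <- y2 - X2 %*% b2
  S <- matrix(c(mean(r1^2), mean(r1 * r2), mean(r1 * r2), mean(r2^2)), 2)
  if (abs(det(S)) < 1e-300) stop("singular cross-equation residual covariance")
  W <- solve(S)  # precision of the 2-vector of equation errors
  p1 <- ncol(X1); p2 <- ncol(X2)
  # stacked GLS with Omega^-1 = W (x) I_n
  A11 <- W[1, 1] * crossprod(X1)
  A12 <- W[1, 2] * crossprod(X1, X2)
  A22 <- W[2, 2] * crossprod(X2)
  A <- rbind(cbind(A11, A12), cbind(t(A12), A22))
  b <- c(W[1, 1] * crossprod(X1, y1) + W[1, 2] * crossprod(X1, y2),
         W[1, 2] * crossprod(X2, y1) + W[2, 2] * crossprod(X2, y2))
  V <- solve(A)
  beta <- drop(V %*% b)
  nm1 <- colnames(X1); if (is.null(nm1)) nm1 <- paste0("x", seq_len(p1))
  nm2 <- colnames(X2); if (is.null(nm2)) nm2 <- paste0("x", seq_len(p2))
  names(beta) <- c(paste0("eq1:", nm1), paste0("eq2:", nm2))
  dimnames(V) <- list(names(beta), names(beta))
  structure(list(coef = beta, vcov = V, sigma = S, n = n,
                 p = c(p1, p2)), class = "SureResult")
}

#' Cross-equation equality test on a SURE system
#'
#' Chi-squared (df = 1) comparison of the model in which the named
#' parameter is fixed across the two equations against the model in which
#' it varies: the Wald statistic of the coefficient difference under the
#' joint FGLS covariance.
#'
#' @param result a `SureResult` from [sureFit()].
#' @param pair character length-2: the two coefficient names to compare
#'   (e.g. `c("eq1:group", "eq2:group")`).
#' @return list with `chisq`, `df` (= 1), `p`, `delta` (coefficient
#'   difference).
#' @export
sureCompare <- function(result, pair) {
  stopifnot(inherits(result, "SureResult"), length(pair) == 2)
  if (!all(pair %in% names(result$coef)))
    stop("unknown coefficient(s): ", paste(setdiff(pair, names(result$coef)),
                                           collapse = ", "))
  cvec <- setNames(numeric(length(result$coef)), names(result$coef))
  cvec[pair[1]] <- 1; cvec[pair[2]] <- -1
  delta <- sum(cvec * result$coef)
  v <- drop(t(cvec) %*% result$vcov %*% cvec)
  chisq <- delta^2 / v
  list(chisq = chisq, df = 1L, p = pchisq(chisq, 1, lower.tail = FALSE),
       delta = delta)
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation of the residuals of `x` and `y` after regressing
#' each on the covariates (with intercept); the p-value uses the t
#' transform with n - k - 2 degrees of freedom (k covariates).  With no
#' covariates this is the ordinary Pearson correlation.
#'
#' @param x,y numeric vectors.
#' @param covariates data.frame / matrix of covariates, or NULL.
#' @return list with `r`, `p`, `df`.
#' @export
partialCorrelation <- function(x, y, covariates = NULL) {
  keep <- complete.cases(x, y, if (is.null(covariates)) rep(TRUE, length(x))
                         else covariates)
  x <- x[keep]; y <- y[keep]
  if (sd(x) == 0 || sd(y) == 0) stop("constant input to partial correlation")
  k <- 0L
  if (!is.null(covariates)) {
    Z <- model.matrix(~ ., as.data.frame(covariates)[keep, , drop = FALSE])
    k <- ncol(Z) - 1L
    x <- lm.fit(Z, x)$residuals
    y <- lm.fit(Z, y)$residuals
  }
  n <- length(x)
  if (n <= k + 3) stop("need n > covariates + 3")
  r <- cor(x, y)
  df <- n - k - 2L
  tstat <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * pt(abs(tstat), df, lower.tail = FALSE), df = df)
}
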