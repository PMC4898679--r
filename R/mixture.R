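#' Hartigan's dip statistic
#'
#' The dip is the minimax sup-norm distance between the empirical CDF and
#' the closest unimodal CDF.  A unimodal CDF is convex up to its mode and
#' concave after it, and may jump only at the mode; the jump decouples the
#' two flanks, so for a fixed mode the minimal sup-error on each flank is
#' half the largest deviation of the empirical CDF from its greatest convex
#' minorant (left flank, fitted to the pre-jump step values) or least
#' concave majorant (right flank, post-jump values).  Both flank errors are
#' monotone in the mode position, so the optimal mode (at a data value or
#' strictly between two) is located by bisection over the sorted distinct
#' values.  Jump limits of the step function count, so the dip of any
#' sample is at least 1/(2n), with equality for n identical values.
#'
#' @param sample numeric vector, n >= 4.
#' @return the dip, a value in (0, 0.25].
#' @export
dipStatistic <- function(sample) {
  n <- length(sample)
  if (n < 4) stop("dip statistic requires n >= 4")
  x <- sort(sample)
  u <- unique(x)
  K <- length(u)
  if (K == 1L) return(1 / (2 * n))
  cc <- cumsum(tabulate(match(x, u), K))   # post-jump counts c_k
  pre <- c(0, cc[-K])                      # pre-jump counts c_{k-1}
  # dev/2 is the flank fit error in counts (hull sweeps in C++)
  lPre <- function(k) .gcmMaxDevCpp(u, cc, pre, k, TRUE)
  rPost <- function(k) .lcmMaxDevCpp(u, cc, pre, k, TRUE)
  lFull <- function(k) .gcmMaxDevCpp(u, cc, pre, k, FALSE)
  rFull <- function(k) .lcmMaxDevCpp(u, cc, pre, k, FALSE)
  # family 1: mode at a distinct value u_k (its jump is absorbed)
  best <- bisectMinimax(lPre, rPost, 1L, K)
  # family 2: mode strictly between u_k and u_{k+1} (no jump absorbed)
  if (K >= 2L)
    best <- min(best, bisectMinimax(lFull, function(k) rFull(k + 1L), 1L, K - 1L))
  max(best, 1) / (2 * n)
}

# min over k in [lo, hi] of max(f(k), g(k)) for nondecreasing f and
# nonincreasing g, by bisection on the crossing
bisectMinimax <- function(f, g, lo, hi) {
  flo <- lo; fhi <- hi
  while (fhi - flo > 1L) {
    mid <- (flo + fhi) %/% 2L
    if (f(mid) >= g(mid)) fhi <- mid else flo <- mid
  }
  min(max(f(flo), g(flo)), max(f(fhi), g(fhi)))
}

# Reference R implementations of the flank scans (mirrored in C++); kept
# for readability and as a cross-check surface.
# largest deviation of post-jump counts above the greatest convex minorant
# of the pre-jump counts over the prefix 1..k; with endPre the mode point k
# contributes its pre-jump value only (deviation 0 at the hull contact)
gcmMaxDev <- function(u, cc, pre, k, endPre) {
  h <- integer(0)   # hull contact indices into 1..k, points (u_j, pre_j)
  for (i in seq_len(k)) {
    while (length(h) >= 2L) {
      a <- h[length(h) - 1L]; b <- h[length(h)]
      if ((pre[b] - pre[a]) * (u[i] - u[a]) -
          (pre[i] - pre[a]) * (u[b] - u[a]) >= 0) h <- h[-length(h)] else break
    }
    h <- c(h, i)
  }
  line <- hullInterp(u[h], pre[h], u[seq_len(k)])
  y <- cc[seq_len(k)]
  if (endPre) y[k] <- pre[k]
  max(y - line)
}

# largest deviation of pre-jump counts below the least concave majorant of
# the post-jump counts over the suffix k..K
lcmMaxDev <- function(u, cc, pre, k, endPost) {
  K <- length(u)
  idx <- k:K
  h <- integer(0)
  for (i in idx) {
    while (length(h) >= 2L) {
      a <- h[length(h) - 1L]; b <- h[length(h)]
      if ((cc[b] - cc[a]) * (u[i] - u[a]) -
          (cc[i] - cc[a]) * (u[b] - u[a]) <= 0) h <- h[-length(h)] else break
    }
    h <- c(h, i)
  }
  line <- hullInterp(u[h], cc[h], u[idx])
  y <- pre[idx]
  if (endPost) y[1] <- cc[k]
  max(line - y)
}

# piecewise-linear interpolation through hull contacts (xh strictly
# increasing), clamped to the contact range
hullInterp <- function(xh, yh, xq) {
  if (length(xh) == 1L) return(rep(yh, length(xq)))
  seg <- findInterval(xq, xh, rightmost.closed = TRUE)
  seg <- pmin(pmax(seg, 1L), length(xh) - 1L)
  t <- (xq - xh[seg]) / (xh[seg + 1L] - xh[seg])
  t <- pmin(pmax(t, 0), 1)
  yh[seg] + t * (yh[seg + 1L] - yh[seg])
}

# package-local cache of dip null tables (keyed by n and n_boot)
.dipNullCache <- new.env(parent = emptyenv())

#' Monte-Carlo p-value for the dip test
#'
#' Calibrated against the uniform null (the statistic's standard reference
#' distribution): the p-value is the proportion of uniform samples of the
#' same size whose dip reaches the observed value.  The null table for a
#' given (n, nBoot, seed) is cached within the session, so repeated tests
#' at the same sample size reuse it.
#'
#' @param dip observed dip statistic.
#' @param n sample size of the observed sample.
#' @param nBoot number of uniform null replicates (>= 1000).
#' @param seed integer seed for the null simulation (deterministic p-value).
#' @return list with `p` and the simulated null `quantiles` (0.9/0.95/0.99).
#' @export
dipPvalue <- function(dip, n, nBoot = 2000L, seed = 1L) {
  stopifnot(nBoot >= 1000L)
  key <- paste0("n", n, "b", nBoot, "s", seed)
  null <- .dipNullCache[[key]]
  if (is.null(null)) {
    null <- withSeed(seed, {
      vapply(seq_len(nBoot), function(i) dipStatistic(runif(n)), numeric(1))
    })
    .dipNullCache[[key]] <- null
  }
  p <- (1 + sum(null >= dip)) / (nBoot + 1)
  list(p = p, quantiles = quantile(null, c(0.9, 0.95, 0.99), names = TRUE))
}

#' Fit a univariate Gaussian mixture by EM
#'
#' Expectation-maximization with k-means initialization per restart; the
#' best of `nRestarts` runs by log-likelihood is returned.  The
#' log-likelihood is non-decreasing over iterations (asserted); a restart
#' whose components collapse (sd below `sdFloor`) is discarded and retried
#' with a new initialization.
#'
#' @param sample numeric vector (n > 10 k).
#' @param k number of components.
#' @param seed integer seed (initialization only; the fit is deterministic
#'   given the seed).
#' @param nRestarts number of k-means restarts.
#' @param tol relative log-likelihood change declaring convergence.
#' @param maxIter iteration cap per restart.
#' @param sdFloor smallest admissible component sd (mm).
#' @return a [MixtureModel-class] with components sorted by mean.
#' @export
fitGmmEM <- function(sample, k, seed = 1L, nRestarts = 3L, tol = 1e-8,
                     maxIter = 500L, sdFloor = 1e-4) {
  n <- length(sample)
  stopifnot(k >= 1L)
  if (n <= 10 * k) stop("need n > 10 * k observations to fit k components")
  if (k == 1L) {
    mu <- mean(sample); sg <- sqrt(mean((sample - mu)^2))  # ML variance
    ll <- sum(dnorm(sample, mu, sg, log = TRUE))
    return(new("MixtureModel", k = 1L, weights = 1, means = mu, sds = sg,
               logLik = ll))
  }
  best <- NULL
  attempts <- 0L
  withSeed(seed, {
    r <- 0L
    while (r < nRestarts && attempts < 4L * nRestarts) {
      attempts <- attempts + 1L
      km <- suppressWarnings(kmeans(sample, centers = k, nstart = 1))
      fit <- tryCatch(
        emCore(sample, km$centers[, 1], km, tol, maxIter, sdFloor),
        error = function(e) NULL)
      if (is.null(fit)) next
      r <- r + 1L
      if (is.null(best) || fit$ll > best$ll) best <- fit
    }
  })
  if (is.null(best))
    stop("EM failed: components collapsed in every restart")
  ord <- order(best$mu)
  new("MixtureModel", k = as.integer(k), weights = best$w[ord],
      means = best$mu[ord], sds = best$sg[ord], logLik = best$ll)
}

# EM iterations from a k-means initialization
emCore <- function(x, centers, km, tol, maxIter, sdFloor) {
  n <- length(x); k <- length(centers)
  mu <- as.numeric(centers)
  w <- as.numeric(table(factor(km$cluster, levels = seq_len(k)))) / n
  sg <- vapply(seq_len(k), function(j) {
    xs <- x[km$cluster == j]
    s <- if (length(xs) > 1) sd(xs) else 0
    max(s, sd(x) / (4 * k))
  }, numeric(1))
  w <- pmax(w, 1e-6); w <- w / sum(w)
  llPrev <- -Inf
  for (it in seq_len(maxIter)) {
    dens <- vapply(seq_len(k), function(j) w[j] * dnorm(x, mu[j], sg[j]),
                   numeric(n))
    tot <- rowSums(dens)
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    ll <- sum(log(tot))
    if (ll + 1e-9 * abs(ll) < llPrev)
      stop("EM log-likelihood decreased")  # guards the monotonicity invariant
    resp <- dens / tot
    nk <- colSums(resp)
    if (any(nk < 1e-8)) stop("component starved")
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sg <- sqrt(colSums(resp * (x - rep(mu, each = n))^2) / nk)
    if (any(sg < sdFloor)) stop("component collapsed (sd -> 0)")
    if (is.finite(llPrev) && (ll - llPrev) < tol * abs(ll)) {
      llPrev <- ll
      break
    }
    llPrev <- ll
  }
  list(w = w, mu = mu, sg = sg, ll = llPrev)
}

#' Mixture density and log-likelihood helpers
#' @param model a [MixtureModel-class].
#' @param x numeric vector of evaluation points.
#' @return `mixtureDensity`: density values; `mixtureLogLik`: summed log
#'   density of `x` under the model.
#' @export
mixtureDensity <- function(model, x) {
  rowSums(vapply(seq_len(model@k), function(j)
    model@weights[j] * dnorm(x, model@means[j], model@sds[j]),
    numeric(length(x))))
}

#' @rdname mixtureDensity
#' @export
mixtureLogLik <- function(model, x) {
  d <- mixtureDensity(model, x)
  d[d < .Machine$double.xmin] <- .Machine$double.xmin
  sum(log(d))
}

#' Cross-validated choice of the number of mixture components
#'
#' Split-half cross-validation: for each k, the model is fitted on a random
#' half of the data and scored on the held-out half, averaged over
#' `nSplits` random splits.  The chosen k is the smallest whose held-out
#' log-likelihood gain from moving to k+1 falls below `gainThreshold`
#' (relative gain per observation) - i.e. the most parsimonious model
#' beyond which adding a component brings no considerable improvement.
#'
#' @param sample numeric vector.
#' @param kRange integer vector of candidate component counts.
#' @param seed integer seed (splits and EM initialization).
#' @param nSplits number of random half-splits to average.
#' @param gainThreshold relative held-out gain below which the larger model
#'   is not considered a considerable improvement (default 1%).
#' @param nRestarts EM restarts per fit.
#' @return list with `k` (chosen), `heldOutLogLik` (named per k, mean
#'   per-observation held-out log-likelihood), `gains`.
#' @export
selectKCrossval <- function(sample, kRange = 1:4, seed = 1L, nSplits = 3L,
                            gainThreshold = 0.01, nRestarts = 2L) {
  stopifnot(length(kRange) >= 1L)
  kRange <- sort(unique(as.integer(kRange)))
  n <- length(sample)
  ho <- matrix(NA_real_, nSplits, length(kRange),
               dimnames = list(NULL, paste0("k", kRange)))
  withSeed(seed, {
    for (s in seq_len(nSplits)) {
      idx <- sample.int(n, floor(n / 2))
      train <- sample[idx]; test <- sample[-idx]
      for (ki in seq_along(kRange)) {
        fit <- tryCatch(
          fitGmmEM(train, kRange[ki], seed = sample.int(1e6, 1),
                   nRestarts = nRestarts),
          error = function(e) NULL)
        ho[s, ki] <- if (is.null(fit)) -Inf else
          mixtureLogLik(fit, test) / length(test)
      }
    }
  })
  m <- colMeans(ho)
  gains <- if (length(kRange) > 1L) diff(m) / abs(m[-length(m)]) else numeric(0)
  chosen <- kRange[length(kRange)]
  for (ki in seq_along(gains)) {
    if (gains[ki] < gainThreshold) { chosen <- kRange[ki]; break }
  }
  list(k = chosen, heldOutLogLik = m, gains = gains)
}

#' Length cutoffs between adjacent mixture components
#'
#' The boundary between adjacent components is the point between their
#' means where the weighted component densities cross (posterior
#' responsibility 0.5).  If the densities do not cross between the means
#' (one component dominates throughout), the point minimising the absolute
#' log-density ratio is used and a message is emitted.
#'
#' @param model a [MixtureModel-class] with k >= 2.
#' @return numeric vector of k-1 sorted boundaries (mm).
#' @export
classCutoffs <- function(model) {
  if (model@k < 2L) stop("cutoffs require at least 2 components")
  vapply(seq_len(model@k - 1L), function(j) {
    mu1 <- model@means[j]; mu2 <- model@means[j + 1L]
    lr <- function(t)
      log(model@weights[j]) + dnorm(t, mu1, model@sds[j], log = TRUE) -
      log(model@weights[j + 1L]) - dnorm(t, mu2, model@sds[j + 1L], log = TRUE)
    grid <- seq(mu1, mu2, length.out = 2048L)
    v <- lr(grid)
    sc <- which(v[-length(v)] > 0 & v[-1] <= 0)
    if (length(sc)) {
      i <- sc[1]
      # bisection refinement on the bracketing interval
      lo <- grid[i]; hi <- grid[i + 1L]
      for (b in 1:60) {
        mid <- (lo + hi) / 2
        if (lr(mid) > 0) lo <- mid else hi <- mid
      }
      (lo + hi) / 2
    } else {
      message("components ", j, " and ", j + 1L,
              " have no density crossing between their means; ",
              "using the minimum-dominance point")
      grid[which.min(abs(v))]
    }
  }, numeric(1))
}

#' Split streamlines into short- and long-range classes
#'
#' Short = length below the cutoff; long = length from the cutoff up to
#' `upperMm` inclusive; streamlines longer than `upperMm` are excluded and
#' counted.  The partition below the upper bound is exhaustive and
#' disjoint.
#'
#' @param streams a [StreamlineSet-class].
#' @param cutoffMm short/long boundary in mm.
#' @param upperMm upper length bound for the long class (default 150).
#' @return list with `short`, `long` ([StreamlineSet-class]) and
#'   `nExcluded`.
#' @export
splitShortLong <- function(streams, cutoffMm, upperMm = 150) {
  len <- streamlineLengths(streams)
  shortIdx <- len < cutoffMm
  longIdx <- len >= cutoffMm & len <= upperMm
  list(short = subsetStreamlines(streams, shortIdx),
       long = subsetStreamlines(streams, longIdx),
       nExcluded = sum(len > upperMm))
}
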