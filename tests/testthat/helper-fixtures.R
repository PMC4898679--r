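# shared fixtures and independent oracles, built in code at test time

# cached expensive fixtures (built once per test run)
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# folded-surface fixture at high resolution for the lGI oracle
foldedFixture <- function(level = 5L) {
  fixture(paste0("folded", level), function() {
    spec <- foldSpec(subdivision_level = level, phase_jitter_sd = 0)
    fs <- generateFoldedSurface(spec, seed = 7L)
    hull <- computeOuterHull(fs$pial, 15)
    list(spec = spec, pial = fs$pial, white = fs$white, hull = hull)
  })
}

# independent parametric-area oracle: the folded fixture's pial surface is
# r(alpha) = R - a * w(alpha) * (1 + cos(2 pi f alpha + phase)) / 2 with
# w(alpha) = cos^2(pi alpha / (2 width)); its area over a spherical cap
# alpha <= cap is integral of sqrt(r^2 + r'^2) * r * sin(alpha), computed
# on a fine quadrature grid.  The hull over the patch is the base sphere
# (crests reach radius R), so the cap area on the hull is the analytic
# spherical cap area.
parametricPatchAreas <- function(spec, cap, nGrid = 20000L) {
  R <- spec$base_radius; a <- spec$fold_amplitude
  f <- spec$fold_frequency; w <- spec$patch_width
  alpha <- seq(0, cap, length.out = nGrid)
  h <- alpha[2] - alpha[1]
  wirt <- ifelse(alpha < w, cos(pi * alpha / (2 * w))^2, 0)
  wprime <- ifelse(alpha < w,
                   -pi / w * cos(pi * alpha / (2 * w)) *
                     sin(pi * alpha / (2 * w)), 0)
  cosT <- cos(2 * pi * f * alpha); sinT <- sin(2 * pi * f * alpha)
  r <- R - a * wirt * (1 + cosT) / 2
  rp <- -a * (wprime * (1 + cosT) / 2 - wirt * pi * f * sinT)
  integrand <- sqrt(r^2 + rp^2) * r * sin(alpha)
  pialArea <- 2 * pi * (sum(integrand) - (integrand[1] + integrand[nGrid]) / 2) * h
  hullArea <- 2 * pi * R^2 * (1 - cos(cap))
  list(pial = pialArea, hull = hullArea, lgi = pialArea / hullArea)
}

# brute-force dip oracle: bisection on the sup-error t with direct
# band-feasibility checks (greatest convex minorant of the upper band must
# dominate the lower band on each flank), scanning every mode placement.
# Independent of the production mode-scan/deviation formulation.
dipOracle <- function(x, tol = 1e-9) {
  n <- length(x)
  xs <- sort(x)
  u <- unique(xs)
  K <- length(u)
  if (K == 1) return(1 / (2 * n))
  cc <- cumsum(tabulate(match(xs, u), K)) / n
  pre <- c(0, cc[-K])
  gcmOfUpper <- function(ux, up) {
    # greatest convex minorant of the upper band, evaluated at ux
    if (length(ux) == 1L) return(up)
    h <- integer(0)
    for (i in seq_along(ux)) {
      while (length(h) >= 2) {
        a <- h[length(h) - 1]; b <- h[length(h)]
        if ((up[b] - up[a]) * (ux[i] - ux[a]) -
            (up[i] - up[a]) * (ux[b] - ux[a]) >= 0) h <- h[-length(h)]
        else break
      }
      h <- c(h, i)
    }
    approx(ux[h], up[h], xout = ux, rule = 2)$y
  }
  lcmOfLower <- function(ux, lo) {
    if (length(ux) == 1L) return(lo)
    h <- integer(0)
    for (i in seq_along(ux)) {
      while (length(h) >= 2) {
        a <- h[length(h) - 1]; b <- h[length(h)]
        if ((lo[b] - lo[a]) * (ux[i] - ux[a]) -
            (lo[i] - lo[a]) * (ux[b] - ux[a]) <= 0) h <- h[-length(h)]
        else break
      }
      h <- c(h, i)
    }
    approx(ux[h], lo[h], xout = ux, rule = 2)$y
  }
  feasibleFlankL <- function(k, t, modeAt) {
    if (k == 0) return(TRUE)
    up <- pre[1:k] + t
    lo <- cc[1:k] - t
    if (modeAt) lo[k] <- pre[k] - t        # mode jump absorbs point k
    g <- gcmOfUpper(u[1:k], up)
    g <- cummax(g)                         # monotone repair stays convex
    all(g >= lo - 1e-12) && all(g <= up + 1e-12)
  }
  feasibleFlankR <- function(k, t, modeAt) {
    if (k > K) return(TRUE)
    idx <- k:K
    lo <- cc[idx] - t
    up <- pre[idx] + t
    if (modeAt) up[1] <- cc[k] + t
    l <- lcmOfLower(u[idx], lo)
    l <- rev(cummin(rev(l)))
    all(l <= up + 1e-12) && all(l >= lo - 1e-12)
  }
  feasible <- function(t) {
    for (k in 1:K) {
      if (feasibleFlankL(k, t, TRUE) && feasibleFlankR(k, t, TRUE))
        return(TRUE)
    }
    for (k in 1:(K - 1)) {
      if (feasibleFlankL(k, t, FALSE) && feasibleFlankR(k + 1, t, FALSE))
        return(TRUE)
    }
    FALSE
  }
  lo <- 1 / (2 * n); hi <- 0.5
  if (feasible(lo)) return(lo)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (feasible(mid)) hi <- mid else lo <- mid
  }
  max((lo + hi) / 2, 1 / (2 * n))
}

# grid fixture: flat triangulated sheet for the smoothing oracle
flatSheet <- function(nx = 41L, ny = 41L, spacing = 1) {
  xy <- expand.grid(x = seq_len(nx) - (nx + 1) / 2,
                    y = seq_len(ny) - (ny + 1) / 2)
  v <- cbind(xy$x * spacing, xy$y * spacing, 0)
  idx <- function(i, j) (j - 1L) * nx + i
  tris <- list()
  for (j in seq_len(ny - 1L)) for (i in seq_len(nx - 1L)) {
    tris[[length(tris) + 1L]] <- c(idx(i, j), idx(i + 1L, j), idx(i, j + 1L))
    tris[[length(tris) + 1L]] <- c(idx(i + 1L, j), idx(i + 1L, j + 1L),
                                   idx(i, j + 1L))
  }
  triSurface(v, do.call(rbind, tris))
}

# straight-bundle phantom at 1 mm resolution (axis-aligned, 60 mm)
straightPhantom <- function() {
  fixture("straight60", function() {
    b <- bundleSpec("straight", rbind(c(0, 0, -30), c(0, 0, 30)),
                    crossSectionRadius = 4)
    generateTensorVolume(c(24L, 24L, 76L), voxelSize = 1, bundles = list(b))
  })
}
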