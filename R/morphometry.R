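#' Outer smooth hull of a star-shaped pial surface
#'
#' Morphological closing of the pial surface: sulci narrower than the
#' structuring element are bridged over, producing a smooth enclosing
#' envelope of the brain.  The closing is computed on the radial distance
#' field of the (star-shaped) pial surface - grayscale dilation followed by
#' erosion with a geodesic-disc structuring element of the given diameter -
#' which keeps an exact one-to-one vertex correspondence between hull and
#' pial (hull vertex i lies on the ray of pial vertex i).
#'
#' @param pial a closed, manifold, star-shaped [TriSurface-class].
#' @param closingDiameter diameter of the structuring element in mm
#'   (default 15); 0 returns the pial radii unchanged.
#' @return a [TriSurface-class] hull with the same triangulation; encloses
#'   the pial surface by construction.
#' @export
computeOuterHull <- function(pial, closingDiameter = 15) {
  stopifnot(closingDiameter >= 0)
  if (!isClosedManifold(pial))
    stop("pial surface must be a closed, consistently oriented manifold")
  v <- vertices(pial)
  av <- mapValues(vertexArea(pial))
  ctr <- colSums(v * av) / sum(av)
  rel <- sweep(v, 2, ctr)
  r <- sqrt(rowSums(rel^2))
  if (any(r <= 0)) stop("degenerate radial field")
  dirs <- rel / r
  rho <- (closingDiameter / 2) / mean(r)   # angular radius of the element
  if (rho > 0) {
    r1 <- angularMorph(dirs, r, rho, max)  # dilation
    r2 <- angularMorph(dirs, r1, rho, min) # erosion
    r2 <- pmax(r2, r)                      # guard: closing never cuts inside
  } else {
    r2 <- r
  }
  triSurface(sweep(dirs * r2, 2, ctr, "+"), triangles(pial))
}

# grayscale morphology of a radial field over sphere directions: for each
# direction, op() of the field over all directions within angular radius rho.
# Blocked so the all-pairs angle matrix never materializes for large meshes.
angularMorph <- function(dirs, r, rho, op) {
  n <- nrow(dirs)
  cmin <- cos(rho)
  out <- numeric(n)
  blk <- max(1L, floor(2e6 / n))
  i0 <- 1L
  while (i0 <= n) {
    i1 <- min(n, i0 + blk - 1L)
    ca <- tcrossprod(dirs[i0:i1, , drop = FALSE], dirs)  # cosines
    for (k in seq_len(i1 - i0 + 1L)) {
      out[i0 + k - 1L] <- op(r[ca[k, ] >= cmin - 1e-12])
    }
    i0 <- i1 + 1L
  }
  out
}

# nearest reference vertex for each query point; blocked dense distance
# computation (adequate at the package's mesh sizes)
nearestVertices <- function(query, ref) {
  n <- nrow(query)
  rn <- rowSums(ref^2)
  idx <- integer(n); d <- numeric(n)
  blk <- max(1L, floor(4e6 / nrow(ref)))
  i0 <- 1L
  while (i0 <= n) {
    i1 <- min(n, i0 + blk - 1L)
    q <- query[i0:i1, , drop = FALSE]
    d2 <- outer(rowSums(q^2), rn, "+") - 2 * tcrossprod(q, ref)
    j <- max.col(-d2, ties.method = "first")
    idx[i0:i1] <- j
    d[i0:i1] <- sqrt(pmax(d2[cbind(seq_len(nrow(q)), j)], 0))
    i0 <- i1 + 1L
  }
  list(index = idx, dist = d)
}

#' Local gyrification index
#'
#' For each hull vertex, the area of the geodesic disc of the given radius
#' on the outer hull is compared with the area of the corresponding region
#' of the pial surface: lGI = pial patch area / hull patch area.  The
#' corresponding pial region is the set of pial vertices whose closest-point
#' projection onto the hull falls inside the disc (the identity map when
#' hull and pial share a triangulation, as hulls from [computeOuterHull()]
#' do).  Values are indexed by pial vertex.
#'
#' @param pial pial [TriSurface-class].
#' @param hull outer hull [TriSurface-class] (same triangulation as the
#'   pial, or any mesh - correspondence is then built by closest-point
#'   projection).
#' @param radius geodesic disc radius in mm; must exceed the mean hull edge
#'   length and be smaller than the surface extent.
#' @param at optional integer vector of hull vertex ids at which to compute
#'   the index (default: all); other vertices get NA.
#' @return a [ScalarMap-class] (dimensionless), lGI >= 1 - 0.05 everywhere
#'   it is defined.
#' @export
computeLGI <- function(pial, hull, radius, at = NULL) {
  nvh <- nVertices(hull)
  if (is.null(at)) at <- seq_len(nvh)
  eh <- meshEdges(hull)
  el <- sqrt(rowSums((vertices(hull)[eh[, 1], ] - vertices(hull)[eh[, 2], ])^2))
  if (radius <= mean(el))
    stop("lGI radius (", radius, " mm) must exceed the mean hull edge length (",
         signif(mean(el), 3), " mm)")
  avHull <- mapValues(vertexArea(hull))
  avPial <- mapValues(vertexArea(pial))
  # pial -> hull correspondence
  if (nVertices(pial) == nvh) {
    proj <- seq_len(nvh)
  } else {
    proj <- nearestVertices(vertices(pial), vertices(hull))$index
  }
  gd <- geodesicDistances(hull, from = at)
  if (all(is.finite(gd[1, ])) && radius >= max(gd))
    stop("lGI radius exceeds the surface extent")
  # pial areas accumulated per hull vertex (projection-weighted)
  pialAtHull <- numeric(nvh)
  acc <- rowsum(avPial, proj)
  pialAtHull[as.integer(rownames(acc))] <- acc[, 1]
  lgi <- rep(NA_real_, nvh)
  for (k in seq_along(at)) {
    disc <- gd[k, ] <= radius
    ha <- sum(avHull[disc])
    pa <- sum(pialAtHull[disc])
    lgi[at[k]] <- pa / ha
  }
  # map back to pial indexing
  out <- lgi[proj]
  scalarMap(out, "")
}

#' Cortical thickness between white and pial surfaces
#'
#' Symmetric closest-point distance: the average of (pial vertex -> nearest
#' white vertex) and (white vertex -> nearest pial vertex) distances, per
#' corresponding vertex.  Requires matching vertex counts (the surfaces
#' come from the same reconstruction).
#'
#' @param white,pial [TriSurface-class] with identical vertex counts.
#' @return a [ScalarMap-class] in mm, indexed by pial vertex.
#' @export
computeThickness <- function(white, pial) {
  if (nVertices(white) != nVertices(pial))
    stop("white and pial surfaces have mismatched vertex counts (",
         nVertices(white), " vs ", nVertices(pial), ")")
  d1 <- nearestVertices(vertices(pial), vertices(white))$dist
  d2 <- nearestVertices(vertices(white), vertices(pial))$dist
  scalarMap((d1 + d2) / 2, "mm")
}

#' Sulcal depth below the outer hull
#'
#' Signed distance from each pial vertex to its corresponding hull vertex,
#' positive where the pial surface lies buried below the hull (i.e. in a
#' sulcus), ~0 on gyral crowns and convex surfaces.
#'
#' @param pial,hull [TriSurface-class]; same triangulation, or hull
#'   correspondence built by closest-point projection.
#' @return a [ScalarMap-class] in mm.
#' @export
computeSulcalDepth <- function(pial, hull) {
  vp <- vertices(pial)
  if (nVertices(pial) == nVertices(hull)) {
    vh <- vertices(hull)
  } else {
    vh <- vertices(hull)[nearestVertices(vp, vertices(hull))$index, , drop = FALSE]
  }
  delta <- vh - vp
  d <- sqrt(rowSums(delta^2))
  nrm <- vertexNormals(pial)
  sgn <- sign(rowSums(delta * nrm))
  sgn[sgn == 0] <- 1
  scalarMap(d * sgn, "mm")
}

#' Surface-based Gaussian smoothing of a scalar map
#'
#' Iterated conservative diffusion on the mesh whose accumulated kernel has
#' the requested full-width at half-maximum.  Each iteration moves value
#' along edges with symmetric conductances, so the surface integral
#' (area-weighted sum) is conserved exactly, constants are fixed points,
#' and positive maps stay positive.  The iteration count follows the heat
#' kernel relation FWHM^2 = 8 ln(2) * sigma^2 with per-iteration variance
#' measured from the mesh geometry.
#'
#' @param surface a [TriSurface-class].
#' @param map a [ScalarMap-class] on its vertices.
#' @param fwhm kernel full-width at half-maximum in mm (>= 0; 0 = identity).
#' @return the smoothed [ScalarMap-class] (same units).
#' @export
smoothScalar <- function(surface, map, fwhm) {
  stopifnot(fwhm >= 0)
  vals <- mapValues(map)
  if (fwhm == 0 || length(unique(vals[!is.na(vals)])) <= 1L) return(map)
  op <- smoothingOperator(surface, fwhm)
  v <- vals
  for (i in seq_len(op$niter)) v <- as.numeric(op$S %*% v)
  scalarMap(v, mapUnits(map))
}

# sparse one-iteration diffusion operator + iteration count for a target
# FWHM; cotangent edge conductances (clamped at zero for obtuse angles)
# make the diffusion isotropic on anisotropic triangulations while the
# symmetric flux form keeps the surface integral exactly conserved
smoothingOperator <- function(surface, fwhm) {
  v <- vertices(surface)
  f <- triangles(surface)
  a <- mapValues(vertexArea(surface))
  n <- nrow(v)
  cot3 <- function(p, q, r) {
    u <- q - p; w <- r - p
    cu <- rowSums(u * w)
    cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                u[, 3] * w[, 1] - u[, 1] * w[, 3],
                u[, 1] * w[, 2] - u[, 2] * w[, 1])
    cu / pmax(sqrt(rowSums(cr^2)), .Machine$double.eps)
  }
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  c1 <- cot3(p1, p2, p3); c2 <- cot3(p2, p3, p1); c3 <- cot3(p3, p1, p2)
  eAll <- rbind(f[, c(2, 3)], f[, c(3, 1)], f[, c(1, 2)])
  eKey <- paste(pmin(eAll[, 1], eAll[, 2]), pmax(eAll[, 1], eAll[, 2]))
  wHalf <- c(c1, c2, c3) / 2
  wEdge <- rowsum(wHalf, eKey)             # (cot a + cot b)/2 per edge
  ids <- strsplit(rownames(wEdge), " ")
  e <- cbind(as.integer(vapply(ids, `[`, "", 1)),
             as.integer(vapply(ids, `[`, "", 2)))
  cij <- pmax(wEdge[, 1], 0)
  d2 <- rowSums((v[e[, 1], ] - v[e[, 2], ])^2)
  csum <- numeric(n)
  acc1 <- rowsum(cij, e[, 1]); acc2 <- rowsum(cij, e[, 2])
  csum[as.integer(rownames(acc1))] <- acc1[, 1]
  csum[as.integer(rownames(acc2))] <- csum[as.integer(rownames(acc2))] +
    acc2[, 1]
  # stability: epsilon * sum_j c_ij / a_i <= 0.5
  epsMax <- 0.5 * min(a / pmax(csum, .Machine$double.eps))
  sigma2PerIter <- function(eps) {
    m <- numeric(n)
    contrib <- eps * cij * d2
    a1 <- rowsum(contrib, e[, 1]); a2 <- rowsum(contrib, e[, 2])
    m[as.integer(rownames(a1))] <- a1[, 1]
    m[as.integer(rownames(a2))] <- m[as.integer(rownames(a2))] + a2[, 1]
    mean(m / a) / 2                        # per-axis variance per iteration
  }
  target <- fwhm^2 / (8 * log(2))
  s2max <- sigma2PerIter(epsMax)
  niter <- max(1L, ceiling(target / s2max))
  eps <- epsMax * (target / niter) / s2max
  # S = I + eps * A^-1 * L with conductances c_ij
  ii <- c(e[, 1], e[, 2], seq_len(n))
  jj <- c(e[, 2], e[, 1], seq_len(n))
  xx <- c(eps * cij / a[e[, 1]], eps * cij / a[e[, 2]], 1 - eps * csum / a)
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  list(S = S, niter = niter, eps = eps)
}
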