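#' Specification of a planted fiber bundle
#'
#' A tube of given cross-section radius around a centerline that is either
#' a straight segment between two endpoints or a circular arc through three
#' points (start, apex, end) - the latter emulates a short U-fiber hugging
#' the cortical sheet.  Voxels inside the tube carry a tensor whose
#' principal eigenvector follows the local centerline tangent.
#'
#' @param kind "straight" or "u_shaped".
#' @param points for "straight" a 2 x 3 matrix (endpoints, mm); for
#'   "u_shaped" a 3 x 3 matrix (start, apex, end, mm).
#' @param crossSectionRadius tube radius in mm.
#' @param eigenvalues length-3, sorted descending, mm^2/s (l1 >= l2 >= l3 > 0).
#' @return a `BundleSpec` (classed list).
#' @export
bundleSpec <- function(kind = c("straight", "u_shaped"), points,
                       crossSectionRadius = 3,
                       eigenvalues = c(1.7, 0.2, 0.2) * 1e-3) {
  kind <- match.arg(kind)
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L,
            nrow(points) == if (kind == "straight") 2L else 3L,
            crossSectionRadius > 0, length(eigenvalues) == 3L,
            eigenvalues[1] >= eigenvalues[2],
            eigenvalues[2] >= eigenvalues[3], eigenvalues[3] > 0)
  structure(list(kind = kind, points = points,
                 crossSectionRadius = crossSectionRadius,
                 eigenvalues = as.numeric(eigenvalues)),
            class = "BundleSpec")
}

# densely sampled centerline (points + unit tangents) of a bundle
bundleCenterline <- function(spec, spacing) {
  p <- spec$points
  if (spec$kind == "straight") {
    d <- p[2, ] - p[1, ]
    len <- sqrt(sum(d^2))
    t <- d / len
    s <- seq(0, len, by = spacing)
    if (s[length(s)] < len) s <- c(s, len)
    list(points = outer(s, t) + matrix(p[1, ], length(s), 3, byrow = TRUE),
         tangents = matrix(t, length(s), 3, byrow = TRUE),
         length = len)
  } else {
    # circle through start, apex, end
    a <- p[1, ]; b <- p[2, ]; c3 <- p[3, ]
    u <- b - a; v <- c3 - a
    nrm <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
             u[1] * v[2] - u[2] * v[1])
    nn <- sqrt(sum(nrm^2))
    if (nn < 1e-9) stop("u_shaped bundle points are collinear")
    nrm <- nrm / nn
    # circumcenter via perpendicular bisectors in the plane
    m1 <- (a + b) / 2; m2 <- (a + c3) / 2
    d1 <- c(u[2] * nrm[3] - u[3] * nrm[2], u[3] * nrm[1] - u[1] * nrm[3],
            u[1] * nrm[2] - u[2] * nrm[1])
    d2 <- c(v[2] * nrm[3] - v[3] * nrm[2], v[3] * nrm[1] - v[1] * nrm[3],
            v[1] * nrm[2] - v[2] * nrm[1])
    A <- cbind(d1, -d2)
    sol <- qr.solve(A, m2 - m1)
    ctr <- m1 + sol[1] * d1
    r <- sqrt(sum((a - ctr)^2))
    # arc angles of the three points in the plane basis (e1, e2)
    e1 <- (a - ctr) / r
    e2 <- c(nrm[2] * e1[3] - nrm[3] * e1[2], nrm[3] * e1[1] - nrm[1] * e1[3],
            nrm[1] * e1[2] - nrm[2] * e1[1])
    ang <- function(q) atan2(sum((q - ctr) * e2), sum((q - ctr) * e1))
    thA <- 0; thB <- ang(b); thC <- ang(c3)
    # traverse from A to C passing through B
    if (thB < 0) { thB <- -thB; thC <- -thC; e2 <- -e2 }
    if (thC < thB) thC <- thC + 2 * pi
    len <- r * thC
    s <- seq(0, thC, by = spacing / r)
    if (s[length(s)] < thC) s <- c(s, thC)
    pts <- matrix(ctr, length(s), 3, byrow = TRUE) +
      r * (outer(cos(s), e1) + outer(sin(s), e2))
    tg <- -outer(sin(s), e1) + outer(cos(s), e2)
    list(points = pts, tangents = tg, length = len)
  }
}

#' Analytic centerline length of a bundle
#' @param spec a [bundleSpec()].
#' @return length in mm.
#' @export
bundleLength <- function(spec) bundleCenterline(spec, 1)$length

#' Generate a synthetic tensor volume with planted bundles
#'
#' Builds a voxel grid of symmetric diffusion tensors: voxels whose centres
#' fall inside a bundle tube carry an anisotropic tensor whose principal
#' eigenvector follows the bundle tangent (tensors are assigned in world
#' space, each voxel taking the tangent of the nearest centerline sample);
#' all other voxels carry the near-isotropic background tensor.  Where
#' bundles overlap, the earlier bundle in the list takes precedence and the
#' contested voxel count is reported via the `"overlap"` attribute.
#'
#' @param shape integer length-3 voxel counts.
#' @param voxelSize isotropic voxel edge in mm.
#' @param bundles list of [bundleSpec()]; all must lie inside the volume.
#' @param backgroundEigenvalues length-3 eigenvalues of the background
#'   tensor (default isotropic 0.7e-3, FA = 0, below any tracking
#'   threshold).
#' @param center world-mm coordinates of the volume centre (default origin).
#' @return a [TensorVolume-class]; affine maps 0-based voxel indices to
#'   world mm.
#' @export
generateTensorVolume <- function(shape, voxelSize = 2,
                                 bundles = list(),
                                 backgroundEigenvalues = c(0.7, 0.7, 0.7) * 1e-3,
                                 center = c(0, 0, 0)) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape > 0), voxelSize > 0)
  affine <- diag(c(rep(voxelSize, 3), 1))
  affine[1:3, 4] <- center - voxelSize * (shape - 1) / 2
  bg <- sort(backgroundEigenvalues, decreasing = TRUE)
  data <- array(0, c(shape, 6L))
  data[, , , 1] <- bg[1]; data[, , , 3] <- bg[2]; data[, , , 6] <- bg[3]
  if (length(bundles)) {
    owner <- array(0L, shape)
    bestD <- array(Inf, shape)
    contested <- array(FALSE, shape)
    ext <- affine[1:3, 4]
    for (bi in seq_along(bundles)) {
      sp <- bundles[[bi]]
      cl <- bundleCenterline(sp, spacing = voxelSize / 2)
      r <- sp$crossSectionRadius
      # world-space bounds check
      lo <- ext - voxelSize / 2
      hi <- ext + voxelSize * (shape - 1) + voxelSize / 2
      if (any(t(cl$points) - r < lo) || any(t(cl$points) + r > hi))
        stop("bundle ", bi, " extends outside the volume bounds")
      rad <- ceiling(r / voxelSize) + 1L
      off <- as.matrix(expand.grid(-rad:rad, -rad:rad, -rad:rad))
      for (si in seq_len(nrow(cl$points))) {
        pw <- cl$points[si, ]
        tv <- cl$tangents[si, ]
        vc <- round((pw - ext) / voxelSize)
        cand <- sweep(off, 2, vc, "+")
        keep <- cand[, 1] >= 0 & cand[, 1] < shape[1] &
                cand[, 2] >= 0 & cand[, 2] < shape[2] &
                cand[, 3] >= 0 & cand[, 3] < shape[3]
        cand <- cand[keep, , drop = FALSE]
        if (!nrow(cand)) next
        wc <- sweep(cand * voxelSize, 2, ext, "+")
        rel <- wc - matrix(pw, nrow(cand), 3, byrow = TRUE)
        ax <- drop(rel %*% tv)
        d <- sqrt(pmax(rowSums(rel^2) - ax^2, 0))   # perpendicular distance
        # flat-ended tube: each centerline sample claims a thin disc only
        sel <- d <= r & abs(ax) <= voxelSize * 0.38
        if (!any(sel)) next
        cand <- cand[sel, , drop = FALSE] + 1L
        d <- d[sel]
        lin <- cand[, 1] + shape[1] * (cand[, 2] - 1L) +
               shape[1] * shape[2] * (cand[, 3] - 1L)
        contested[lin[owner[lin] != 0L & owner[lin] != bi]] <- TRUE
        improve <- d < bestD[lin] & (owner[lin] == 0L | owner[lin] == bi)
        lin <- lin[improve]; d <- d[improve]
        if (!length(lin)) next
        owner[lin] <- bi
        bestD[lin] <- d
        D6 <- tensorFromTangent(tv, sp$eigenvalues)
        nvox <- prod(shape)
        for (c6 in 1:6) data[lin + (c6 - 1L) * nvox] <- D6[c6]
      }
    }
    attr(data, "overlap") <- sum(contested)
    if (any(contested))
      message("bundle overlap: ", sum(contested),
              " voxels contested, resolved by list order precedence")
  }
  tensorVolume(data, affine)
}

# 6-component (lower-triangular) tensor with principal axis t
tensorFromTangent <- function(t, ev) {
  t <- t / sqrt(sum(t^2))
  # orthonormal frame (t, u, w)
  a <- if (abs(t[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- c(t[2] * a[3] - t[3] * a[2], t[3] * a[1] - t[1] * a[3],
         t[1] * a[2] - t[2] * a[1])
  u <- u / sqrt(sum(u^2))
  w <- c(t[2] * u[3] - t[3] * u[2], t[3] * u[1] - t[1] * u[3],
         t[1] * u[2] - t[2] * u[1])
  D <- ev[1] * tcrossprod(t) + ev[2] * tcrossprod(u) + ev[3] * tcrossprod(w)
  c(D[1, 1], D[1, 2], D[2, 2], D[1, 3], D[2, 3], D[3, 3])
}
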