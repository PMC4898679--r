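#' Construct a TensorVolume
#'
#' @param data numeric 4-D array `(nx, ny, nz, 6)` of unique tensor elements
#'   in lower-triangular order (dxx, dxy, dyy, dxz, dyz, dzz), mm^2/s,
#'   components expressed in world axes.
#' @param affine 4x4 voxel-to-world matrix (0-based voxel indices).
#' @return a [TensorVolume-class].
#' @export
tensorVolume <- function(data, affine) {
  new("TensorVolume", data = data, affine = affine)
}

#' Construct a StreamlineSet
#'
#' @param points list of n x 3 world-mm matrices.
#' @param metrics optional data.frame of per-streamline mean fa/md/ad/rd.
#' @return a [StreamlineSet-class]; arc lengths are computed from the
#'   polylines.
#' @export
streamlineSet <- function(points, metrics = NULL) {
  lens <- vapply(points, function(p) {
    if (nrow(p) < 2L) return(0)
    sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
  }, numeric(1))
  if (is.null(metrics))
    metrics <- data.frame(fa = numeric(0), md = numeric(0), ad = numeric(0),
                          rd = numeric(0))
  new("StreamlineSet", points = points, lengths = lens, metrics = metrics)
}

#' Scalar diffusion metrics from tensor eigenvalues
#'
#' Closed forms from the sorted eigenvalues (l1 >= l2 >= l3 >= 0):
#' MD = (l1+l2+l3)/3, AD = l1 (axial, parallel), RD = (l2+l3)/2 (radial,
#' perpendicular), FA = sqrt(3/2) * ||lambda - MD|| / ||lambda||.
#'
#' @param eigenvalues numeric length-3 vector or n x 3 matrix, each row
#'   sorted descending, all non-negative, not all zero.
#' @return data.frame with columns fa, md, ad, rd; an all-zero tensor gives
#'   NA FA (flagged, excluded from tracking).
#' @export
tensorMetrics <- function(eigenvalues) {
  ev <- if (is.matrix(eigenvalues)) eigenvalues else matrix(eigenvalues, 1)
  stopifnot(ncol(ev) == 3L)
  if (any(ev < 0)) stop("eigenvalues must be non-negative")
  if (any(ev[, 1] < ev[, 2] | ev[, 2] < ev[, 3]))
    stop("eigenvalues must be sorted descending (l1 >= l2 >= l3)")
  md <- rowMeans(ev)
  num <- rowSums((ev - md)^2)
  den <- rowSums(ev^2)
  fa <- ifelse(den > 0, sqrt(1.5 * num / den), NA_real_)
  data.frame(fa = fa, md = md, ad = ev[, 1], rd = (ev[, 2] + ev[, 3]) / 2)
}

#' Voxel-wise fractional anisotropy map of a tensor volume
#' @param vol a [TensorVolume-class].
#' @return 3-D numeric array of FA (NA where the tensor is all zero).
#' @export
faMap <- function(vol) .faVolume(vol@data)

#' Whole-volume deterministic streamline tractography
#'
#' One seed per voxel centre with FA at or above the threshold (a uniform
#' grid at the data resolution); bidirectional Euler propagation along the
#' principal eigenvector of the component-wise cubic-interpolated tensor,
#' with sign continuity against the previous direction.  Propagation stops
#' when the candidate point has FA below threshold, when the turn between
#' consecutive steps exceeds the angle limit, or when the streamline leaves
#' the volume; the terminal point is the last accepted one.  Streamlines
#' shorter than the minimum length are discarded.  Tracking is fully
#' deterministic.
#'
#' @param vol a [TensorVolume-class].
#' @param faThreshold seeding and stopping FA threshold (default 0.2).
#' @param angleMaxDeg maximum step-to-step turn in degrees (default 35).
#' @param stepMm Euler step size in mm (default 1).
#' @param minLenMm minimum streamline length in mm (default 20).
#' @param maxSteps safety cap on steps per direction.
#' @return a [StreamlineSet-class] (empty, with a warning, if no voxel
#'   reaches the seed threshold).
#' @export
trackWholeVolume <- function(vol, faThreshold = 0.2, angleMaxDeg = 35,
                             stepMm = 1.0, minLenMm = 20, maxSteps = 2000L) {
  fa <- faMap(vol)
  seed <- which(!is.na(fa) & fa >= faThreshold, arr.ind = TRUE) - 1L
  if (nrow(seed) == 0L) {
    warning("no voxels at or above the FA seed threshold; empty streamline set")
    return(streamlineSet(list()))
  }
  pts <- .trackStreamlines(vol@data, vol@affine, seed, faThreshold,
                           angleMaxDeg, stepMm, minLenMm, as.integer(maxSteps))
  streamlineSet(pts)
}

#' Voxelize a surface ROI into a mask aligned to a tensor grid
#'
#' Marks the voxels whose centres lie within `band` voxel widths of any ROI
#' vertex position mapped through the affine.  The default one-voxel band
#' absorbs the discretization gap between the surface and the voxel grid.
#'
#' @param vertexSet integer ids into the surface vertices.
#' @param surface a [TriSurface-class] in world mm.
#' @param affine 4x4 voxel-to-world matrix of the target grid.
#' @param gridDim integer length-3 voxel counts of the target grid.
#' @param band band width in voxels (default 1).
#' @return a [VoxelMask-class]; empty with a warning if the ROI falls
#'   outside the grid.
#' @export
voxelizeSurfaceROI <- function(vertexSet, surface, affine, gridDim, band = 1) {
  mask <- array(FALSE, dim = gridDim)
  pos <- vertices(surface)[vertexSet, , drop = FALSE]
  if (nrow(pos)) {
    ainv <- solve(affine)
    vox <- t(ainv %*% rbind(t(pos), 1))[, 1:3, drop = FALSE]
    rad <- ceiling(band)
    off <- as.matrix(expand.grid(-rad:rad, -rad:rad, -rad:rad))
    off <- off[sqrt(rowSums(off^2)) <= band + 0.5, , drop = FALSE]
    ctr <- round(vox)
    for (o in seq_len(nrow(off))) {
      cand <- sweep(ctr, 2, off[o, ], "+")
      keep <- sqrt(rowSums((cand - vox)^2)) <= band + 0.5
      cand <- cand[keep &
                   cand[, 1] >= 0 & cand[, 1] < gridDim[1] &
                   cand[, 2] >= 0 & cand[, 2] < gridDim[2] &
                   cand[, 3] >= 0 & cand[, 3] < gridDim[3], , drop = FALSE]
      if (nrow(cand)) mask[cand + 1L] <- TRUE
    }
  }
  if (!any(mask) && nrow(pos))
    warning("ROI lies outside the voxel grid: empty mask")
  new("VoxelMask", mask = mask, affine = affine)
}

#' Dissect streamlines by their endpoints
#'
#' Keeps exactly the streamlines with at least one endpoint (first or last
#' polyline point) inside the mask; streamlines that only pass through the
#' mask mid-course are excluded.
#'
#' @param streams a [StreamlineSet-class].
#' @param mask a [VoxelMask-class].
#' @return the dissected [StreamlineSet-class] (always a subset; idempotent).
#' @export
dissectByEndpoints <- function(streams, mask) {
  if (nStreamlines(streams) == 0L) return(streams)
  inMask <- function(p) {
    v <- round(solve(mask@affine) %*% c(p, 1))[1:3]
    d <- dim(mask@mask)
    if (any(v < 0) || any(v >= d)) return(FALSE)
    mask@mask[v[1] + 1, v[2] + 1, v[3] + 1]
  }
  keep <- vapply(streams@points, function(m) {
    inMask(m[1, ]) || inMask(m[nrow(m), ])
  }, logical(1))
  sub <- streamlineSet(streams@points[keep])
  if (nrow(streams@metrics)) sub@metrics <- streams@metrics[keep, , drop = FALSE]
  sub
}

#' Subset a streamline set by index
#' @param streams a [StreamlineSet-class].
#' @param idx logical or integer index.
#' @return the subsetted [StreamlineSet-class].
#' @export
subsetStreamlines <- function(streams, idx) {
  sub <- streamlineSet(streams@points[idx])
  if (nrow(streams@metrics)) sub@metrics <- streams@metrics[idx, , drop = FALSE]
  sub
}

#' Along-tract mean diffusion metrics
#'
#' Samples FA/MD/AD/RD at every streamline point by cubic interpolation of
#' the tensor field, averages along each streamline, and attaches the
#' per-streamline means; the set-level summary is the unweighted mean over
#' streamlines.  Points outside the volume are excluded from the mean and
#' counted.
#'
#' @param streams a [StreamlineSet-class].
#' @param vol a [TensorVolume-class].
#' @return list with `streams` (metrics attached), `summary` (named vector
#'   of set-level mean fa/md/ad/rd; all NA for an empty set) and
#'   `nOutside` (points excluded).
#' @export
streamlineMeanMetrics <- function(streams, vol) {
  n <- nStreamlines(streams)
  empty <- c(fa = NA_real_, md = NA_real_, ad = NA_real_, rd = NA_real_)
  if (n == 0L) return(list(streams = streams, summary = empty, nOutside = 0L))
  per <- matrix(NA_real_, n, 4)
  nOut <- 0L
  for (i in seq_len(n)) {
    sm <- .sampleTensorMetrics(streams@points[[i]], vol@data, vol@affine)
    ok <- stats::complete.cases(sm)
    nOut <- nOut + sum(!ok)
    if (any(ok)) per[i, ] <- colMeans(sm[ok, , drop = FALSE])
  }
  colnames(per) <- c("fa", "md", "ad", "rd")
  out <- streams
  out@metrics <- as.data.frame(per)
  list(streams = out, summary = colMeans(per, na.rm = TRUE), nOutside = nOut)
}
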